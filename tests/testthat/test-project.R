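# project configuration, layers and entity management

write_json_config <- function(doc) {
  f <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null"), f)
  f
}

minimal_config <- function(root = tempfile()) {
  list(name = "p", description = "",
       pickable_objects = list(list(name = "ribosome", label = 1, radius = 150)),
       layers = list(list(uri = file.path(root, "overlay"), mode = "mutable")))
}

test_that("a minimal configuration loads and validates", {
  pr <- load_config(write_json_config(minimal_config()))
  expect_s3_class(pr, "tomopick_project")
  expect_length(pr$objects, 1L)
  expect_identical(pr$objects$ribosome$label, 1L)
  expect_identical(pr$layers[[1]]$mode, "mutable")
})

test_that("invariant violations are reported with the offending field", {
  cfg <- minimal_config()
  cfg$pickable_objects <- list(list(name = "a", label = 3, radius = 10),
                               list(name = "b", label = 3, radius = 10))
  expect_error(load_config(write_json_config(cfg)), "duplicate label")
  cfg$pickable_objects <- list(list(name = "a", label = 300, radius = 10))
  expect_error(load_config(write_json_config(cfg)), "1..255")
  cfg$pickable_objects <- list(list(name = "a", label = 1, radius = 10))
  cfg$layers <- list(list(uri = tempfile(), mode = "static"))
  expect_error(load_config(write_json_config(cfg)), "mutable")
  cfg$layers <- list(list(uri = tempfile(), mode = "mutable"),
                     list(uri = tempfile(), mode = "mutable"))
  expect_error(load_config(write_json_config(cfg)), "exactly one mutable")
  cfg$layers <- list()
  expect_error(load_config(write_json_config(cfg)), "layers")
  # particles need a radius; labels are mandatory
  cfg <- minimal_config()
  cfg$pickable_objects <- list(list(name = "a", label = 1))
  expect_error(load_config(write_json_config(cfg)), "radius")
  cfg$pickable_objects <- list(list(name = "a", radius = 5))
  expect_error(load_config(write_json_config(cfg)), "label")
  # broken JSON names the parse problem
  f <- tempfile(fileext = ".json")
  writeLines("{ not json", f)
  expect_error(load_config(f), "parse")
})

test_that("unknown config keys are ignored and mode defaults apply", {
  cfg <- minimal_config()
  cfg$future_extension <- list(a = 1)
  cfg$pickable_objects[[1]]$custom_field <- "kept-but-ignored"
  cfg$layers <- list(list(uri = tempfile()), list(uri = tempfile()))  # no modes
  pr <- load_config(write_json_config(cfg))
  expect_identical(vapply(pr$layers, `[[`, character(1), "mode"),
                   c("static", "mutable"))
})

test_that("configurations round-trip through write_config", {
  pr <- tmp_project()
  f <- tempfile(fileext = ".json")
  write_config(pr, f)
  p2 <- load_config(f)
  expect_identical(p2$name, pr$name)
  expect_identical(lapply(p2$objects, `[[`, "label"),
                   lapply(pr$objects, `[[`, "label"))
  expect_identical(lapply(p2$objects, `[[`, "radius"),
                   lapply(pr$objects, `[[`, "radius"))
  expect_identical(vapply(p2$layers, `[[`, character(1), "mode"),
                   vapply(pr$layers, `[[`, character(1), "mode"))
})

test_that("entities merge across layers with provenance and stable order", {
  pr <- tmp_project()
  sw <- static_writer(pr)
  # static layer holds pick set A; mutable holds B
  tmp <- tempfile()
  write_picks(pick_set("ribosome", "alice", "s1",
                       matrix(stats::runif(15, 0, 100), 5, 3)), tmp)
  sw$write("ExperimentRuns/run1/Picks/alice_s1_ribosome.json",
           readBin(tmp, "raw", file.info(tmp)$size))
  save_picks(pr, "run1", pick_set("ribosome", "bob", "s2",
                                  matrix(stats::runif(6, 0, 100), 2, 3)))
  es <- list_entities(pr, "run1", kind = "picks")
  expect_length(es, 2L)
  expect_true(es[[1]]$read_only)       # layer 1 (static) first
  expect_false(es[[2]]$read_only)
  expect_identical(es[[1]]$user, "alice")
  # same identity in both layers: both listed, distinguishable by layer
  save_picks(pr, "run1", pick_set("ribosome", "alice", "s1",
                                  matrix(0, 1, 3)))
  es2 <- list_entities(pr, "run1", kind = "picks", user = "alice")
  expect_length(es2, 2L)
  expect_identical(vapply(es2, `[[`, integer(1), "layer"), c(1L, 2L))
  # shadowing: default read resolves to the mutable copy
  expect_identical(nrow(load_picks(pr, "run1", "ribosome", "alice", "s1")$positions), 1L)
  expect_identical(nrow(load_picks(pr, "run1", "ribosome", "alice", "s1",
                                   layer = "static")$positions), 5L)
  # empty run / unknown run
  expect_error(list_entities(pr, "nope"), "unknown run")
})

test_that("create_entity writes only the mutable layer and detects conflicts", {
  pr <- tmp_project()
  h0 <- layer_tree_hash(pr, 1)
  e <- create_entity(pr, "runX", "picks", "ribosome", "alice", "s1")
  expect_false(e$read_only)
  expect_length(list_entities(pr, "runX", kind = "picks"), 1L)
  expect_error(create_entity(pr, "runX", "picks", "ribosome", "alice", "s1"),
               "already exists")
  expect_error(create_entity(pr, "runX", "picks", "unknown-object", "a", "s"),
               "not defined")
  expect_identical(layer_tree_hash(pr, 1), h0)
})

test_that("save conflicts respect the overwrite flag", {
  pr <- tmp_project()
  ps <- pick_set("ribosome", "u", "1", matrix(1, 1, 3))
  save_picks(pr, "r", ps)
  expect_error(save_picks(pr, "r", ps), "overwrite")
  ps2 <- pick_set("ribosome", "u", "1", matrix(2, 1, 3))
  save_picks(pr, "r", ps2, overwrite = TRUE)
  expect_equal(unname(load_picks(pr, "r", "ribosome", "u", "1")$positions[1, 1]), 2)
})

test_that("copying to the mutable layer is byte-faithful and non-destructive", {
  pr <- tmp_project()
  sw <- static_writer(pr)
  set.seed(71)
  src <- pick_set("ribosome", "ref", "0", matrix(stats::runif(15, 0, 500), 5, 3),
                  lapply(1:5, function(i) random_pose()))
  tmp <- tempfile()
  write_picks(src, tmp)
  sw$write("ExperimentRuns/r/Picks/ref_0_ribosome.json",
           readBin(tmp, "raw", file.info(tmp)$size))
  h0 <- layer_tree_hash(pr, 1)
  e <- list_entities(pr, "r", kind = "picks")[[1]]
  ne <- copy_to_mutable(pr, e)
  expect_identical(layer_tree_hash(pr, 1), h0)
  got <- load_picks(pr, "r", "ribosome", "ref", "0", layer = "mutable")
  expect_identical(got$positions, src$positions)
  expect_identical(lapply(got$transforms, unclass), lapply(src$transforms, unclass))
  # byte-for-byte payload equality
  b1 <- pr$layers[[1]]$backend$read(e$key)
  b2 <- pr$layers[[2]]$backend$read(ne$key)
  expect_identical(b1, b2)
  # copying onto an existing identity conflicts
  expect_error(copy_to_mutable(pr, e), "already exists")
  # modifying the copy leaves the original untouched
  save_picks(pr, "r", pick_set("ribosome", "ref", "0", matrix(0, 1, 3)),
             overwrite = TRUE)
  expect_identical(layer_tree_hash(pr, 1), h0)
  expect_identical(nrow(load_picks(pr, "r", "ribosome", "ref", "0",
                                   layer = "static")$positions), 5L)
})

test_that("segmentation and tomogram entities round-trip through a project", {
  pr <- tmp_project()
  set.seed(72)
  seg <- segmentation(random_mask(12, 0.3), 10, object = "membrane", label = 2L)
  save_segmentation(pr, "r", seg, "membrane", "u", "1")
  s2 <- load_segmentation(pr, "r", "membrane", "u", "1", spacing = 10)
  expect_identical(s2$mask, seg$mask)
  expect_equal(s2$spacing, 10)
  vol <- multiscale_volume(array(rnorm(12^3), c(12, 12, 12)), 10)
  save_tomogram(pr, "r", vol)
  v2 <- load_tomogram(pr, "r", 10)
  expect_identical(v2$levels, vol$levels)
  es <- list_entities(pr, "r")
  expect_setequal(vapply(es, `[[`, character(1), "kind"),
                  c("segmentation", "tomogram"))
})

test_that("static layer backends refuse writes outright", {
  pr <- tmp_project()
  expect_error(pr$layers[[1]]$backend$write("x", as.raw(1)), "read-only")
  expect_error(pr$layers[[1]]$backend$delete("x"), "read-only")
})

test_that("disjoint layer unions are additive", {
  pr <- tmp_project(n_layers = 3)
  sw1 <- static_writer(pr, 1)
  sw2 <- static_writer(pr, 2)
  tmp <- tempfile()
  write_picks(pick_set("ribosome", "a", "1", matrix(1, 1, 3)), tmp)
  raw1 <- readBin(tmp, "raw", file.info(tmp)$size)
  sw1$write("ExperimentRuns/r/Picks/a_1_ribosome.json", raw1)
  write_picks(pick_set("ribosome", "b", "1", matrix(1, 1, 3)), tmp)
  sw2$write("ExperimentRuns/r/Picks/b_1_ribosome.json",
            readBin(tmp, "raw", file.info(tmp)$size))
  es <- list_entities(pr, "r", kind = "picks")
  expect_length(es, 2L)
  expect_identical(vapply(es, `[[`, character(1), "user"), c("a", "b"))
})

test_that("unregistered remote URI schemes are refused", {
  expect_error(
    new_project("p", list(pickable_object("a", 1, radius = 5)),
                list(list(uri = "s3://bucket/x", mode = "mutable"))),
    "no storage backend")
  register_storage_backend("mem-test", function(uri, read_only)
    local_backend(file.path(tempdir(), "memtest"), read_only))
  pr <- new_project("p", list(pickable_object("a", 1, radius = 5)),
                    list(list(uri = "mem-test://x", mode = "mutable")))
  expect_s3_class(pr, "tomopick_project")
})
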