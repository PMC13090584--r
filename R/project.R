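# Project model: a JSON configuration defines the pickable objects (name,
# label, color, radius, external identifiers) and an ordered list of storage
# layers. Exactly one layer is mutable and receives all writes; static
# layers are shared read-only references, so concurrent annotators never
# overwrite each other. A Run groups everything derived from one region of
# interest; its entities are the union over all layers, identified by
# (kind, object, user, session).

#' Define a pickable object
#'
#' @param name Object name (unique within a project).
#' @param label Segmentation label, integer in 1..255 (0 is background).
#' @param is_particle Particle (`TRUE`) vs. extended structure.
#' @param color RGBA integer 4-tuple, each 0..255.
#' @param radius Particle radius in angstrom; required when `is_particle`.
#' @param pdb_id,emdb_id,go_id Optional external identifiers.
#' @param map_path Optional reference density map location.
#' @return A `pickable_object` list.
#' @export
pickable_object <- function(name, label, is_particle = TRUE,
                            color = c(128, 128, 128, 255), radius = NULL,
                            pdb_id = NULL, emdb_id = NULL, go_id = NULL,
                            map_path = NULL) {
  obj <- list(name = name, label = label, is_particle = is_particle,
              color = color, radius = radius, pdb_id = pdb_id,
              emdb_id = emdb_id, go_id = go_id, map_path = map_path)
  validate_pickable_object(obj)
}

validate_pickable_object <- function(obj) {
  if (is.null(obj$name) || !nzchar(obj$name))
    tp_stop("pickable object field 'name' is required", "tomopick_validation_error")
  lab <- obj$label
  if (is.null(lab))
    tp_stop(sprintf("object '%s': field 'label' is required", obj$name),
            "tomopick_validation_error")
  if (lab != round(lab) || lab < 1 || lab > 255)
    tp_stop(sprintf("object '%s': label %s outside 1..255 (labels must fit 8-bit segmentations; 0 is background)",
                    obj$name, format(lab)), "tomopick_validation_error")
  if (is.null(obj$is_particle)) obj$is_particle <- TRUE
  if (is.null(obj$color)) obj$color <- c(128, 128, 128, 255)
  col <- unlist(obj$color)
  if (length(col) != 4 || any(col < 0) || any(col > 255) || any(col != round(col)))
    tp_stop(sprintf("object '%s': field 'color' must be four integers 0..255", obj$name),
            "tomopick_validation_error")
  obj$color <- as.integer(col)
  if (isTRUE(obj$is_particle) && is.null(obj$radius))
    tp_stop(sprintf("object '%s': field 'radius' is required for particles", obj$name),
            "tomopick_validation_error")
  if (!is.null(obj$radius)) {
    if (obj$radius <= 0)
      tp_stop(sprintf("object '%s': field 'radius' must be positive", obj$name),
              "tomopick_validation_error")
    obj$radius <- as.numeric(obj$radius)
  }
  obj$label <- as.integer(lab)
  structure(obj, class = "pickable_object")
}

#' Assemble and validate a project
#'
#' @param name,description Project metadata strings.
#' @param objects List of [pickable_object()]s; names and labels must be
#'   unique.
#' @param layers List of layer specifications `list(uri =, mode =)`; `mode`
#'   is `"static"` or `"mutable"`. When no mode is given anywhere, the last
#'   layer is mutable and the others static. Exactly one mutable layer.
#' @return Object of class `tomopick_project` with per-layer storage
#'   backends attached (static layers get read-only backends).
#' @export
new_project <- function(name, objects, layers, description = "") {
  objects <- lapply(objects, validate_pickable_object)
  nm <- vapply(objects, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    tp_stop(paste0("duplicate object name: ", nm[duplicated(nm)][1]),
            "tomopick_validation_error")
  labs <- vapply(objects, `[[`, integer(1), "label")
  if (anyDuplicated(labs))
    tp_stop(paste0("duplicate label: ", labs[duplicated(labs)][1]),
            "tomopick_validation_error")
  if (length(layers) < 1)
    tp_stop("field 'layers': at least one layer is required",
            "tomopick_validation_error")
  modes <- vapply(layers, function(l) {
    if (is.null(l$mode)) NA_character_ else l$mode
  }, character(1))
  if (all(is.na(modes))) {
    modes <- c(rep("static", length(layers) - 1L), "mutable")
  } else if (anyNA(modes)) {
    modes[is.na(modes)] <- "static"
  }
  if (!all(modes %in% c("static", "mutable")))
    tp_stop("field 'layers': mode must be 'static' or 'mutable'",
            "tomopick_validation_error")
  if (sum(modes == "mutable") != 1L)
    tp_stop(sprintf("field 'layers': exactly one mutable layer required (found %d)",
                    sum(modes == "mutable")), "tomopick_validation_error")
  lrs <- lapply(seq_along(layers), function(i) {
    uri <- layers[[i]]$uri
    if (is.null(uri))
      tp_stop("field 'layers': each layer needs a 'uri'", "tomopick_validation_error")
    structure(list(uri = uri, mode = modes[i],
                   backend = backend_for_uri(uri, read_only = modes[i] == "static")),
              class = "layer_root")
  })
  names(objects) <- nm
  structure(list(name = name, description = description,
                 objects = objects, layers = lrs),
            class = "tomopick_project")
}

#' @export
print.tomopick_project <- function(x, ...) {
  cat(sprintf("<tomopick_project '%s': %d object(s), %d layer(s) [%s]>\n",
              x$name, length(x$objects), length(x$layers),
              paste(vapply(x$layers, `[[`, character(1), "mode"), collapse = ", ")))
  invisible(x)
}

#' Load and validate a project configuration
#'
#' The configuration is a single JSON document with keys `name`,
#' `description`, `pickable_objects` and `layers` (ordered; the last layer
#' is mutable unless modes are given explicitly). Unknown keys are ignored
#' for forward compatibility.
#'
#' @param path JSON file.
#' @return A validated `tomopick_project`.
#' @export
load_config <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    tp_stop(paste0("cannot parse project config: ",
                                   conditionMessage(e)), "tomopick_format_error"))
  if (is.null(doc$pickable_objects))
    tp_stop("missing required field 'pickable_objects'", "tomopick_validation_error")
  if (is.null(doc$layers))
    tp_stop("missing required field 'layers'", "tomopick_validation_error")
  new_project(name = if (is.null(doc$name)) "" else doc$name,
              description = if (is.null(doc$description)) "" else doc$description,
              objects = doc$pickable_objects,
              layers = doc$layers)
}

#' Write a project configuration to JSON
#'
#' Inverse of [load_config()]: `load_config(write_config(p))` yields an
#' equivalent project.
#'
#' @param project A `tomopick_project`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_config <- function(project, path) {
  objs <- lapply(project$objects, function(o) {
    o <- unclass(o)
    o[!vapply(o, is.null, logical(1))]
  })
  doc <- list(
    name = project$name,
    description = project$description,
    pickable_objects = unname(objs),
    layers = lapply(project$layers, function(l) list(uri = l$uri, mode = l$mode))
  )
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                           pretty = TRUE)), path)
  invisible(path)
}

mutable_layer <- function(project) {
  i <- which(vapply(project$layers, `[[`, character(1), "mode") == "mutable")
  project$layers[[i]]
}

# ---- on-disk layout ---------------------------------------------------------
# <root>/ExperimentRuns/<run>/Picks/<user>_<session>_<object>.json
# <root>/ExperimentRuns/<run>/Meshes/<user>_<session>_<object>.glb
# <root>/ExperimentRuns/<run>/Segmentations/<spacing %.3f>_<user>_<session>_<object>.zarr/
# <root>/ExperimentRuns/<run>/VoxelSpacing<%.3f>/<name>.zarr/
# <root>/Objects/<name>.zarr/

fmt_spacing <- function(s) sprintf("%.3f", s)

entity_key <- function(run, kind, object, user, session, spacing = NULL,
                       name = NULL) {
  base <- paste0("ExperimentRuns/", run)
  switch(kind,
    picks = sprintf("%s/Picks/%s_%s_%s.json", base, user, session, object),
    mesh = sprintf("%s/Meshes/%s_%s_%s.glb", base, user, session, object),
    segmentation = sprintf("%s/Segmentations/%s_%s_%s_%s.zarr", base,
                           fmt_spacing(spacing), user, session, object),
    tomogram = sprintf("%s/VoxelSpacing%s/%s.zarr", base, fmt_spacing(spacing),
                       name),
    tp_stop(paste0("unknown entity kind: ", kind), "tomopick_value_error"))
}

entity_descriptor <- function(kind, run, object, user, session, layer_index,
                              layer, key, spacing = NA_real_, name = NA_character_) {
  structure(list(kind = kind, run = run, object = object, user = user,
                 session = session, layer = layer_index, layer_uri = layer$uri,
                 read_only = layer$mode == "static", key = key,
                 spacing = spacing, name = name),
            class = "tomopick_entity")
}

#' @export
print.tomopick_entity <- function(x, ...) {
  cat(sprintf("<entity %s run=%s object=%s user=%s session=%s layer=%d%s>\n",
              x$kind, x$run, x$object, x$user, x$session, x$layer,
              if (x$read_only) " (read-only)" else ""))
  invisible(x)
}

scan_layer_entities <- function(layer, layer_index, run) {
  base <- paste0("ExperimentRuns/", run)
  keys <- layer$backend$list(base)
  out <- list()
  add <- function(e) out[[length(out) + 1L]] <<- e
  pk <- grep(paste0("^", base, "/Picks/[^/]+\\.json$"), keys, value = TRUE)
  for (k in pk) {
    m <- regmatches(basename(k),
                    regexec("^([^_]+)_([^_]+)_(.+)\\.json$", basename(k)))[[1]]
    if (length(m) == 4)
      add(entity_descriptor("picks", run, m[4], m[2], m[3], layer_index, layer, k))
  }
  mk <- grep(paste0("^", base, "/Meshes/[^/]+\\.glb$"), keys, value = TRUE)
  for (k in mk) {
    m <- regmatches(basename(k),
                    regexec("^([^_]+)_([^_]+)_(.+)\\.glb$", basename(k)))[[1]]
    if (length(m) == 4)
      add(entity_descriptor("mesh", run, m[4], m[2], m[3], layer_index, layer, k))
  }
  sk <- grep(paste0("^", base, "/Segmentations/[^/]+\\.zarr/"), keys, value = TRUE)
  for (d in unique(sub("\\.zarr/.*$", ".zarr", sk))) {
    m <- regmatches(basename(d),
                    regexec("^([0-9.]+)_([^_]+)_([^_]+)_(.+)\\.zarr$", basename(d)))[[1]]
    if (length(m) == 5)
      add(entity_descriptor("segmentation", run, m[5], m[3], m[4], layer_index,
                            layer, d, spacing = as.numeric(m[2])))
  }
  tk <- grep(paste0("^", base, "/VoxelSpacing[0-9.]+/[^/]+\\.zarr/"), keys,
             value = TRUE)
  for (d in unique(sub("\\.zarr/.*$", ".zarr", tk))) {
    sp <- as.numeric(sub("^.*VoxelSpacing([0-9.]+)/.*$", "\\1", d))
    nm <- sub("\\.zarr$", "", basename(d))
    add(entity_descriptor("tomogram", run, nm, "", "", layer_index, layer, d,
                          spacing = sp, name = nm))
  }
  out
}

#' List runs known to any project layer
#' @param project A `tomopick_project`.
#' @return Character vector of run names.
#' @export
list_runs <- function(project) {
  runs <- character()
  for (l in project$layers) {
    keys <- l$backend$list("ExperimentRuns")
    runs <- c(runs, unique(sub("^ExperimentRuns/([^/]+)/.*$", "\\1", keys)))
  }
  sort(unique(runs))
}

#' List the entities of a run across all layers
#'
#' Returns the union over layers; descriptors from static layers carry
#' `read_only = TRUE`. The order is deterministic: layer order, then
#' lexicographic identity (kind, object, user, session).
#'
#' @param project A `tomopick_project`.
#' @param run Run name.
#' @param kind Optional filter: `"picks"`, `"mesh"`, `"segmentation"`,
#'   `"tomogram"`.
#' @param object,user,session Optional identity filters.
#' @return List of `tomopick_entity` descriptors.
#' @export
list_entities <- function(project, run, kind = NULL, object = NULL,
                          user = NULL, session = NULL) {
  known <- run %in% list_runs(project)
  if (!known)
    tp_stop(paste0("unknown run: ", run), "tomopick_notfound_error")
  out <- list()
  for (i in seq_along(project$layers)) {
    es <- scan_layer_entities(project$layers[[i]], i, run)
    if (length(es)) {
      key <- vapply(es, function(e)
        paste(e$kind, e$object, e$user, e$session, e$name), character(1))
      es <- es[order(key)]
    }
    out <- c(out, es)
  }
  keep <- vapply(out, function(e) {
    (is.null(kind) || e$kind == kind) &&
      (is.null(object) || identical(e$object, object)) &&
      (is.null(user) || identical(e$user, user)) &&
      (is.null(session) || identical(e$session, session))
  }, logical(1))
  out[keep]
}

find_entity <- function(project, run, kind, object, user, session,
                        layer = c("auto", "mutable", "static")) {
  layer <- match.arg(layer)
  es <- list_entities(project, run, kind = kind, object = object,
                      user = user, session = session)
  if (layer == "mutable") es <- Filter(function(e) !e$read_only, es)
  if (layer == "static") es <- Filter(function(e) e$read_only, es)
  if (length(es) == 0) return(NULL)
  if (layer == "auto") {
    # shadowing: refinement in the mutable layer takes precedence
    mut <- Filter(function(e) !e$read_only, es)
    if (length(mut)) return(mut[[length(mut)]])
  }
  es[[length(es)]]
}

#' Create a new (empty) entity in the mutable layer
#'
#' Runs are created on demand. The identity (kind, object, user, session)
#' must not already exist in the mutable layer; static layers are never
#' written.
#'
#' @param project A `tomopick_project`.
#' @param run Run name.
#' @param kind `"picks"`, `"mesh"` or `"segmentation"`.
#' @param object Object name, which must be defined in the project config.
#' @param user,session Identity of the annotator and session.
#' @param spacing Voxel spacing (required for segmentations).
#' @return The new entity descriptor.
#' @export
create_entity <- function(project, run, kind, object, user, session,
                          spacing = NULL) {
  if (!object %in% names(project$objects))
    tp_stop(paste0("object '", object, "' is not defined in the project config"),
            "tomopick_config_error")
  ml <- mutable_layer(project)
  mi <- which(vapply(project$layers, `[[`, character(1), "mode") == "mutable")
  key <- entity_key(run, kind, object, user, session, spacing = spacing)
  probe <- switch(kind, picks = key, mesh = key,
                  segmentation = paste0(key, "/.zgroup"),
                  tp_stop(paste0("cannot create entity of kind: ", kind),
                          "tomopick_value_error"))
  if (ml$backend$exists(probe))
    tp_stop(paste0("entity already exists in the mutable layer: ", key),
            "tomopick_conflict_error")
  if (kind == "picks") {
    ml$backend$write(key, picks_to_json(pick_set(object, user, session)))
  } else if (kind == "mesh") {
    tmp <- tempfile(fileext = ".glb")
    write_glb(tri_mesh(matrix(numeric(), 0, 3), matrix(integer(), 0, 3)),
              tmp, allow_empty = TRUE)
    ml$backend$write(key, readBin(tmp, "raw", file.info(tmp)$size))
    unlink(tmp)
  } else {
    zarr_write_group_attrs(ml$backend, key, list(tomopick = list(
      role = "segmentation", object = object)))
  }
  entity_descriptor(kind, run, object, user, session, mi, ml, key,
                    spacing = if (is.null(spacing)) NA_real_ else spacing)
}

#' Copy an entity into the mutable layer
#'
#' The payload is copied byte for byte; the copy is stored under the
#' caller's user/session identity. The source layer is untouched
#' (verifiable with [layer_tree_hash()]).
#'
#' @param project A `tomopick_project`.
#' @param entity Source `tomopick_entity` descriptor.
#' @param user,session Identity for the copy (defaults: same as source).
#' @return Descriptor of the new mutable entity.
#' @export
copy_to_mutable <- function(project, entity, user = entity$user,
                            session = entity$session) {
  src_layer <- project$layers[[entity$layer]]
  ml <- mutable_layer(project)
  mi <- which(vapply(project$layers, `[[`, character(1), "mode") == "mutable")
  dst_key <- entity_key(entity$run, entity$kind, entity$object, user, session,
                        spacing = if (is.na(entity$spacing)) NULL else entity$spacing,
                        name = entity$name)
  exists_dst <- if (entity$kind %in% c("picks", "mesh")) ml$backend$exists(dst_key)
                else length(ml$backend$list(dst_key)) > 0
  if (exists_dst)
    tp_stop(paste0("target identity already exists in the mutable layer: ", dst_key),
            "tomopick_conflict_error")
  if (entity$kind %in% c("picks", "mesh")) {
    ml$backend$write(dst_key, src_layer$backend$read(entity$key))
  } else {
    for (k in src_layer$backend$list(entity$key)) {
      rel <- sub(paste0("^", entity$key, "/"), "", k)
      ml$backend$write(paste0(dst_key, "/", rel), src_layer$backend$read(k))
    }
  }
  entity_descriptor(entity$kind, entity$run, entity$object, user, session,
                    mi, ml, dst_key, spacing = entity$spacing, name = entity$name)
}

#' Content hash of a layer tree
#'
#' MD5 over the sorted relative paths and per-file MD5 digests of every
#' file under the layer root. Unchanged hash proves that no byte under the
#' layer was touched.
#'
#' @param x A `tomopick_project`, layer root path, or `tomopick_backend`.
#' @param layer Layer index when `x` is a project.
#' @return Hex digest string.
#' @export
layer_tree_hash <- function(x, layer = 1L) {
  root <- if (inherits(x, "tomopick_project")) x$layers[[layer]]$backend$root
          else if (inherits(x, "tomopick_backend")) x$root
          else x
  files <- sort(list.files(root, recursive = TRUE, all.files = TRUE, no.. = TRUE))
  if (length(files) == 0) return("empty")
  sums <- tools::md5sum(file.path(root, files))
  desc <- paste(files, unname(sums), sep = ":", collapse = "\n")
  tmp <- tempfile()
  writeLines(desc, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

# ---- typed save/load over entity identities ---------------------------------

#' Save a pick set into the mutable layer
#' @param project A `tomopick_project`.
#' @param run Run name.
#' @param ps A `pick_set` (its object/user/session form the identity).
#' @param overwrite Replace an existing entity (default `FALSE`: conflict).
#' @return Entity descriptor, invisibly.
#' @export
save_picks <- function(project, run, ps, overwrite = FALSE) {
  if (!ps$object %in% names(project$objects))
    tp_stop(paste0("object '", ps$object, "' is not defined in the project config"),
            "tomopick_config_error")
  ml <- mutable_layer(project)
  mi <- which(vapply(project$layers, `[[`, character(1), "mode") == "mutable")
  key <- entity_key(run, "picks", ps$object, ps$user, ps$session)
  if (ml$backend$exists(key) && !overwrite)
    tp_stop(paste0("entity already exists (use overwrite): ", key),
            "tomopick_conflict_error")
  ml$backend$write(key, picks_to_json(ps))
  invisible(entity_descriptor("picks", run, ps$object, ps$user, ps$session,
                              mi, ml, key))
}

#' Load a pick set
#' @param project A `tomopick_project`.
#' @param run Run name.
#' @param object,user,session Entity identity.
#' @param layer `"auto"` (mutable shadows static), `"mutable"`, `"static"`.
#' @return A `pick_set`.
#' @export
load_picks <- function(project, run, object, user, session, layer = "auto") {
  e <- find_entity(project, run, "picks", object, user, session, layer)
  if (is.null(e))
    tp_stop("no such pick entity", "tomopick_notfound_error")
  lb <- project$layers[[e$layer]]$backend
  json_to_picks(jsonlite::fromJSON(rawToChar(lb$read(e$key)),
                                   simplifyVector = FALSE))
}

#' Save a mesh into the mutable layer
#' @inheritParams save_picks
#' @param mesh A `tri_mesh`.
#' @param object,user,session Entity identity.
#' @return Entity descriptor, invisibly.
#' @export
save_mesh <- function(project, run, mesh, object, user, session,
                      overwrite = FALSE) {
  ml <- mutable_layer(project)
  mi <- which(vapply(project$layers, `[[`, character(1), "mode") == "mutable")
  key <- entity_key(run, "mesh", object, user, session)
  if (ml$backend$exists(key) && !overwrite)
    tp_stop(paste0("entity already exists (use overwrite): ", key),
            "tomopick_conflict_error")
  tmp <- tempfile(fileext = ".glb")
  write_glb(mesh, tmp, allow_empty = TRUE)
  ml$backend$write(key, readBin(tmp, "raw", file.info(tmp)$size))
  unlink(tmp)
  invisible(entity_descriptor("mesh", run, object, user, session, mi, ml, key))
}

#' Load a mesh
#' @inheritParams load_picks
#' @return A `tri_mesh`.
#' @export
load_mesh <- function(project, run, object, user, session, layer = "auto") {
  e <- find_entity(project, run, "mesh", object, user, session, layer)
  if (is.null(e)) tp_stop("no such mesh entity", "tomopick_notfound_error")
  lb <- project$layers[[e$layer]]$backend
  tmp <- tempfile(fileext = ".glb")
  writeBin(lb$read(e$key), tmp)
  on.exit(unlink(tmp))
  read_glb(tmp, allow_empty = TRUE)
}

#' Save a segmentation into the mutable layer (multiscale OME-Zarr)
#' @inheritParams save_picks
#' @param seg A `segmentation`.
#' @param object,user,session Entity identity.
#' @return Entity descriptor, invisibly.
#' @export
save_segmentation <- function(project, run, seg, object, user, session,
                              overwrite = FALSE) {
  ml <- mutable_layer(project)
  mi <- which(vapply(project$layers, `[[`, character(1), "mode") == "mutable")
  key <- entity_key(run, "segmentation", object, user, session,
                    spacing = seg$spacing)
  if (length(ml$backend$list(key)) > 0) {
    if (!overwrite)
      tp_stop(paste0("entity already exists (use overwrite): ", key),
              "tomopick_conflict_error")
    ml$backend$delete(key)
  }
  vol <- multiscale_volume(seg$mask, seg$spacing, role = "segmentation",
                           multilabel = seg$multilabel)
  write_ome_zarr(vol, ml$backend, key)
  invisible(entity_descriptor("segmentation", run, object, user, session,
                              mi, ml, key, spacing = seg$spacing))
}

#' Load a segmentation (level 0 of its multiscale store)
#' @inheritParams load_picks
#' @param spacing Voxel spacing identifying the entity.
#' @return A `segmentation`.
#' @export
load_segmentation <- function(project, run, object, user, session,
                              spacing = NULL, layer = "auto") {
  e <- find_entity(project, run, "segmentation", object, user, session, layer)
  if (is.null(e)) tp_stop("no such segmentation entity", "tomopick_notfound_error")
  lb <- project$layers[[e$layer]]$backend
  vol <- read_ome_zarr(lb, e$key)
  lab <- if (!is.null(project$objects[[object]])) project$objects[[object]]$label else 1L
  segmentation(vol$levels[[1]], vol$spacing, object = object, label = lab,
               multilabel = vol$multilabel)
}

#' Save a tomogram into the mutable layer
#' @inheritParams save_picks
#' @param vol A `multiscale_volume`.
#' @param name Tomogram name (e.g. reconstruction algorithm), default "wbp".
#' @return Entity descriptor, invisibly.
#' @export
save_tomogram <- function(project, run, vol, name = "wbp", overwrite = FALSE) {
  ml <- mutable_layer(project)
  mi <- which(vapply(project$layers, `[[`, character(1), "mode") == "mutable")
  key <- entity_key(run, "tomogram", NULL, NULL, NULL, spacing = vol$spacing,
                    name = name)
  if (length(ml$backend$list(key)) > 0 && !overwrite)
    tp_stop(paste0("entity already exists (use overwrite): ", key),
            "tomopick_conflict_error")
  write_ome_zarr(vol, ml$backend, key)
  invisible(entity_descriptor("tomogram", run, NA_character_, "", "", mi, ml,
                              key, spacing = vol$spacing, name = name))
}

#' Load a tomogram
#' @param project A `tomopick_project`.
#' @param run Run name.
#' @param spacing Voxel spacing of the tomogram set.
#' @param name Tomogram name.
#' @param layer `"auto"`, `"mutable"` or `"static"`.
#' @return A `multiscale_volume`.
#' @export
load_tomogram <- function(project, run, spacing, name = "wbp", layer = "auto") {
  es <- list_entities(project, run, kind = "tomogram")
  es <- Filter(function(e) e$name == name &&
                 abs(e$spacing - spacing) < 1e-6, es)
  if (layer == "mutable") es <- Filter(function(e) !e$read_only, es)
  if (layer == "static") es <- Filter(function(e) e$read_only, es)
  if (length(es) == 0) tp_stop("no such tomogram", "tomopick_notfound_error")
  e <- if (layer == "auto") {
    mut <- Filter(function(e) !e$read_only, es)
    if (length(mut)) mut[[1]] else es[[1]]
  } else es[[1]]
  read_ome_zarr(project$layers[[e$layer]]$backend, e$key)
}
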