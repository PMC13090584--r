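# multiscale volumes, chunked storage, format import/export

test_that("pyramid shapes follow the ceil-division law at binnings 1/2/4", {
  set.seed(21)
  for (rep in 1:8) {
    d <- sample(5:40, 3, replace = TRUE)
    v <- multiscale_volume(array(rnorm(prod(d)), d), 10, "tomogram")
    expect_length(v$levels, 3L)
    for (l in 0:2)
      expect_identical(dim(v$levels[[l + 1]]), as.integer(ceiling(d / 2^l)))
  }
  # the worked example: 70 -> 35 -> 18
  v <- multiscale_volume(array(0, c(70, 70, 70)), 10)
  expect_equal(t(sapply(v$levels, dim)), rbind(c(70, 70, 70), c(35, 35, 35), c(18, 18, 18)))
})

test_that("mean binning conserves the mean and fixes constants", {
  a <- array(7, c(8, 8, 8))
  v <- build_pyramid(a, "tomogram")
  expect_true(all(vapply(v, function(l) all(l == 7), logical(1))))
  expect_equal(build_pyramid(array(0:7, c(2, 2, 2)), "tomogram", 2)[[2]][1], 3.5)
  set.seed(22)
  b <- array(rnorm(32^3), c(32, 32, 32))
  pb <- build_pyramid(b, "tomogram")
  expect_equal(mean(pb[[2]]), mean(pb[[1]]), tolerance = 1e-6)
  expect_equal(mean(pb[[3]]), mean(pb[[1]]), tolerance = 1e-6)
})

test_that("segmentation binning is a majority vote biased to smaller labels", {
  blk <- array(c(rep(0L, 7), 2L), c(2, 2, 2))
  expect_identical(build_pyramid(blk, "segmentation", 2)[[2]][1], 0L)
  tie <- array(c(rep(3L, 4), rep(5L, 4)), c(2, 2, 2))
  expect_identical(build_pyramid(tie, "segmentation", 2)[[2]][1], 3L)
  set.seed(23)
  for (rep in 1:5) {
    m <- array(sample(c(0L, 1L, 4L, 9L), 17^3, TRUE), c(17, 17, 17))
    p <- build_pyramid(m, "segmentation")
    for (l in 2:3)
      expect_true(all(unique(as.vector(p[[l]])) %in% unique(as.vector(m))))
  }
})

test_that("OME-Zarr stores round-trip bit-identically for all dtype roles", {
  set.seed(24)
  a <- array(rnorm(31 * 22 * 17), c(31, 22, 17))
  v <- multiscale_volume(a, 6.5, "tomogram", chunk_shape = c(16, 16, 16))
  d <- tempfile()
  write_ome_zarr(v, d)
  v2 <- read_ome_zarr(d)
  expect_identical(v2$levels, v$levels)
  expect_equal(v2$spacing, 6.5)
  expect_equal(v2$role, "tomogram")

  m <- array(sample(0:255, 20^3, TRUE), c(20, 20, 20))
  vs <- multiscale_volume(m, 10, "segmentation", chunk_shape = c(7, 7, 7))
  ds <- tempfile()
  write_ome_zarr(vs, ds)
  vs2 <- read_ome_zarr(ds)
  expect_identical(vs2$levels, vs$levels)
  expect_true(is.integer(vs2$levels[[1]]))

  big <- array(sample(0:3000, 6^3, TRUE), c(6, 6, 6))
  vm <- multiscale_volume(big, 10, "segmentation", multilabel = TRUE)
  dm <- tempfile()
  write_ome_zarr(vm, dm)
  expect_identical(read_ome_zarr(dm)$levels, vm$levels)
})

test_that("chunk layout defaults to 256 cubed, clipped for small volumes", {
  v <- multiscale_volume(array(0, c(20, 20, 20)), 10)
  expect_identical(v$chunk_shape, c(256L, 256L, 256L))
  d <- tempfile()
  write_ome_zarr(v, d)
  meta <- jsonlite::fromJSON(file.path(d, "0", ".zarray"))
  expect_identical(as.integer(meta$chunks), c(20L, 20L, 20L))
  expect_identical(meta$dtype, "<f4")
  expect_identical(meta$compressor$id, "lz4")
})

test_that("region reads equal array slices and touch only intersecting chunks", {
  set.seed(25)
  a <- array(rnorm(48^3), c(48, 48, 48))
  v <- multiscale_volume(a, 10, chunk_shape = c(16, 16, 16))
  root <- tempfile()
  write_ome_zarr(v, root)
  cb <- counting_backend(local_backend(root))
  st <- ome_zarr_store(cb)
  for (rep in 1:10) {
    lo <- sapply(1:3, function(i) sample(0:40, 1))
    hi <- pmin(lo + sapply(1:3, function(i) sample(1:8, 1)), 48)
    reg <- volume_region(0, c(lo[1], hi[1]), c(lo[2], hi[2]), c(lo[3], hi[3]))
    got <- read_region(st, reg)
    expect_identical(got, v$levels[[1]][(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                                        (lo[3] + 1):hi[3], drop = FALSE])
  }
  # single-voxel read inside one chunk touches exactly one chunk file
  cb$log$reads <- character()
  read_region(st, volume_region(0, c(0, 1), c(0, 1), c(0, 1)))
  chunkreads <- grep("zarray", cb$log$reads, invert = TRUE, value = TRUE)
  expect_identical(chunkreads, "0/0.0.0")
  # corner voxel
  expect_identical(read_region(st, volume_region(0, c(0, 1), c(0, 1), c(0, 1)))[1],
                   v$levels[[1]][1, 1, 1])
  expect_error(read_region(st, volume_region(0, c(0, 49), c(0, 1), c(0, 1))),
               "out of bounds")
  expect_error(volume_region(0, c(3, 3), c(0, 1), c(0, 1)), "start < stop")
})

test_that("MRC export obeys the 1024-byte-header size law and round-trips", {
  set.seed(26)
  a <- array(rnorm(8), c(2, 2, 2))
  v <- multiscale_volume(a, 12, "tomogram")
  f <- tempfile(fileext = ".mrc")
  export_volume(v, f)
  expect_identical(file.info(f)$size, 1024 + 32)
  expect_identical(mrc_file_size(c(2, 2, 2)), 1024 + 32)
  r <- read_mrc(f)
  expect_identical(r$data, v$levels[[1]])
  expect_equal(r$spacing, 12)
  # a larger, non-cubic export
  b <- array(rnorm(24 * 20 * 16), c(24, 20, 16))
  vb <- multiscale_volume(b, 5, "tomogram")
  fb <- tempfile(fileext = ".mrc")
  export_volume(vb, fb)
  expect_identical(file.info(fb)$size, mrc_file_size(c(24, 20, 16)))
  expect_identical(read_mrc(fb)$data, vb$levels[[1]])
  # the size law extrapolates with the same accounting the writer uses
  expect_identical(mrc_file_size(c(492, 1260, 1260)), 3124397824)
})

test_that("EM and TIFF volumes import and export losslessly", {
  set.seed(27)
  a <- tomopick:::snap_f4(array(rnorm(10 * 12 * 14), c(10, 12, 14)))
  fe <- tempfile(fileext = ".em")
  write_em(a, fe)
  expect_identical(read_em(fe)$data, a)
  ft <- tempfile(fileext = ".tif")
  write_tiff_volume(a, ft)
  expect_equal(read_tiff_volume(ft), a, tolerance = 0)
  # import goes through the pyramid and keeps float32 precision
  v <- import_volume(ft, role = "tomogram", spacing = 4)
  expect_identical(v$levels[[1]], a)
  expect_length(v$levels, 3L)
})

test_that("float64 input is stored at 32-bit float precision", {
  x <- array(pi, c(4, 4, 4))  # pi is not representable in float32
  v <- multiscale_volume(x, 10)
  expect_false(identical(v$levels[[1]][1], pi))
  expect_equal(v$levels[[1]][1], pi, tolerance = 1e-7)
  d <- tempfile()
  write_ome_zarr(v, d)
  expect_identical(read_ome_zarr(d)$levels[[1]], v$levels[[1]])
})

test_that("invalid imports are rejected with informative errors", {
  v <- multiscale_volume(array(0, c(4, 4, 4)), 10)
  f <- tempfile(fileext = ".xyz")
  writeLines("x", f)
  expect_error(import_volume(f), "unknown volume format")
  expect_error(multiscale_volume(array(0, c(4, 4, 4)), -1), "positive")
  expect_error(multiscale_volume(array(300L, c(2, 2, 2)), 10, "segmentation"),
               "0..255")
  fe <- tempfile(fileext = ".em")
  write_em(tomopick:::snap_f4(array(1, c(2, 2, 2))), fe)
  expect_error(import_volume(fe, role = "tomogram"), "spacing")
})
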