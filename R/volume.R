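# Multiscale volumes: a three-level resolution pyramid (full, 2x and 4x
# binned) of 3D arrays in ZYX axis order, with an isotropic voxel spacing in
# angstrom at level 0. Continuous data (tomograms, feature maps) are held as
# 32-bit floats, semantic segmentations as 8-bit unsigned integers.

snap_f4 <- function(a) {
  # snap doubles to their 32-bit float representation so that in-memory
  # values equal what a lossless store will return
  v <- readBin(writeBin(as.numeric(a), raw(), size = 4L), "numeric",
               n = length(a), size = 4L)
  if (is.null(dim(a))) v else array(v, dim(a))
}

#' Construct a multiscale volume
#'
#' Builds the resolution pyramid from a full-resolution 3D array. Continuous
#' roles (`"tomogram"`, `"feature"`) are binned by 2x2x2 block mean and cast
#' to 32-bit float precision; `"segmentation"` uses 2x2x2 majority vote
#' (ties toward the smaller label) and 8-bit unsigned integer storage.
#'
#' @param level0 3D array in ZYX order (`dim = c(nz, ny, nx)`).
#' @param spacing Voxel spacing at level 0, in angstrom per voxel (> 0).
#' @param role One of `"tomogram"`, `"segmentation"`, `"feature"`.
#' @param levels Number of pyramid levels (default 3: binnings 1, 2, 4).
#' @param chunk_shape Chunk shape used when the volume is stored; clipped to
#'   the array shape for small volumes. Default `c(256, 256, 256)`.
#' @param multilabel For segmentations: allow labels above 255 (stored as
#'   16-bit unsigned integers and flagged in metadata).
#' @return An object of class `multiscale_volume` with elements `levels`
#'   (list of arrays), `spacing`, `role`, `chunk_shape`.
#' @export
multiscale_volume <- function(level0, spacing, role = c("tomogram", "segmentation", "feature"),
                              levels = 3L, chunk_shape = c(256L, 256L, 256L),
                              multilabel = FALSE) {
  role <- match.arg(role)
  if (length(dim(level0)) != 3L)
    tp_stop("level0 must be a 3D array (ZYX)", "tomopick_shape_error")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    tp_stop("voxel spacing must be a positive number", "tomopick_value_error")
  if (role == "segmentation") {
    vmax <- if (multilabel) 65535 else 255
    if (any(level0 < 0) || any(level0 > vmax) || any(level0 != round(level0)))
      tp_stop(sprintf("segmentation values must be integers in 0..%d", vmax),
              "tomopick_range_error")
    storage.mode(level0) <- "integer"
  } else {
    level0 <- snap_f4(level0)
  }
  structure(list(
    levels = build_pyramid(level0, role, levels = levels),
    spacing = spacing,
    role = role,
    multilabel = multilabel,
    chunk_shape = as.integer(chunk_shape)
  ), class = "multiscale_volume")
}

#' @export
print.multiscale_volume <- function(x, ...) {
  cat(sprintf("<multiscale_volume role=%s spacing=%g A/vx levels=%d shape0=%s>\n",
              x$role, x$spacing, length(x$levels),
              paste(dim(x$levels[[1]]), collapse = "x")))
  invisible(x)
}

bin2_mean <- function(a) {
  d <- dim(a)
  nd <- as.integer(ceiling(d / 2))
  s <- array(0, nd)
  cnt <- array(0, nd)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    if (1L + dz > d[1] || 1L + dy > d[2] || 1L + dx > d[3]) next
    iz <- seq.int(1L + dz, d[1], by = 2L)
    iy <- seq.int(1L + dy, d[2], by = 2L)
    ix <- seq.int(1L + dx, d[3], by = 2L)
    sub <- a[iz, iy, ix, drop = FALSE]
    sd <- dim(sub)
    s[seq_len(sd[1]), seq_len(sd[2]), seq_len(sd[3])] <-
      s[seq_len(sd[1]), seq_len(sd[2]), seq_len(sd[3]), drop = FALSE] + sub
    cnt[seq_len(sd[1]), seq_len(sd[2]), seq_len(sd[3])] <-
      cnt[seq_len(sd[1]), seq_len(sd[2]), seq_len(sd[3]), drop = FALSE] + 1
  }
  s / cnt  # edge blocks average over the voxels actually present
}

bin2_mode <- function(a) {
  d <- dim(a)
  nd <- as.integer(ceiling(d / 2))
  labels <- sort(unique(as.vector(a)))
  best <- array(labels[1], nd)
  bestc <- array(-1L, nd)
  for (l in labels) {  # ascending: strict > breaks ties toward smaller label
    cntl <- array(0L, nd)
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      if (1L + dz > d[1] || 1L + dy > d[2] || 1L + dx > d[3]) next
      iz <- seq.int(1L + dz, d[1], by = 2L)
      iy <- seq.int(1L + dy, d[2], by = 2L)
      ix <- seq.int(1L + dx, d[3], by = 2L)
      sub <- a[iz, iy, ix, drop = FALSE] == l
      sd <- dim(sub)
      cntl[seq_len(sd[1]), seq_len(sd[2]), seq_len(sd[3])] <-
        cntl[seq_len(sd[1]), seq_len(sd[2]), seq_len(sd[3]), drop = FALSE] + sub
    }
    sel <- cntl > bestc
    best[sel] <- l
    bestc[sel] <- cntl[sel]
  }
  storage.mode(best) <- "integer"
  best
}

#' Build a resolution pyramid
#'
#' Level L has shape `ceiling(shape0 / 2^L)` per axis. Continuous data are
#' binned by 2x2x2 block mean (edge blocks average over available voxels);
#' label data by 2x2x2 majority vote with ties broken toward the smaller
#' label, so no level introduces a label absent from level 0.
#'
#' @param level0 3D array (ZYX).
#' @param role `"tomogram"`, `"feature"` (mean) or `"segmentation"` (mode).
#' @param levels Number of levels including level 0.
#' @return List of arrays.
#' @export
build_pyramid <- function(level0, role = "tomogram", levels = 3L) {
  if (length(dim(level0)) != 3L)
    tp_stop("expected a 3D array", "tomopick_shape_error")
  out <- vector("list", levels)
  out[[1]] <- level0
  for (l in seq_len(levels - 1L)) {
    out[[l + 1L]] <- if (role == "segmentation") bin2_mode(out[[l]]) else {
      snap_f4(bin2_mean(out[[l]]))
    }
  }
  out
}

ome_attrs <- function(vol) {
  axes <- lapply(c("z", "y", "x"), function(n)
    list(name = n, type = "space", unit = "angstrom"))
  datasets <- lapply(seq_along(vol$levels) - 1L, function(l) {
    s <- vol$spacing * 2^l
    list(path = as.character(l),
         coordinateTransformations = list(list(type = "scale", scale = c(s, s, s))))
  })
  list(
    multiscales = list(list(
      version = "0.4",
      name = "",
      axes = axes,
      datasets = datasets,
      type = if (vol$role == "segmentation") "mode" else "mean"
    )),
    tomopick = list(role = vol$role, multilabel = vol$multilabel)
  )
}

#' Write a multiscale volume as an OME-Zarr v0.4 store
#'
#' One zarr array per pyramid level (`0`, `1`, `2`), voxel spacing encoded as
#' per-level scale transformations in the group metadata, chunks compressed
#' with the byte-shuffle + LZ4 pipeline.
#'
#' @param vol A `multiscale_volume`.
#' @param dest Directory path for the store, or a `tomopick_backend`.
#' @param key Key prefix inside the backend (default `""`, the root).
#' @return The store handle (`ome_zarr_store`), invisibly.
#' @export
write_ome_zarr <- function(vol, dest, key = "") {
  backend <- if (inherits(dest, "tomopick_backend")) dest else local_backend(dest)
  zarr_write_group_attrs(backend, key, ome_attrs(vol))
  dtype <- zarr_dtype_for_role(vol$role, vol$multilabel)
  for (l in seq_along(vol$levels)) {
    zarr_write_array(backend, zjoin(key, as.character(l - 1L)), vol$levels[[l]],
                     dtype = dtype, chunks = vol$chunk_shape)
  }
  invisible(ome_zarr_store(backend, key))
}

#' Handle to an OME-Zarr store on a backend
#'
#' @param dest Directory path or `tomopick_backend`.
#' @param key Key prefix of the zarr group.
#' @return An `ome_zarr_store` object.
#' @export
ome_zarr_store <- function(dest, key = "") {
  backend <- if (inherits(dest, "tomopick_backend")) dest else local_backend(dest)
  structure(list(backend = backend, key = key), class = "ome_zarr_store")
}

#' Read a full multiscale volume from an OME-Zarr store
#'
#' @param dest Directory path, `tomopick_backend`, or `ome_zarr_store`.
#' @param key Key prefix (ignored when `dest` is a store handle).
#' @return A `multiscale_volume`.
#' @export
read_ome_zarr <- function(dest, key = "") {
  st <- if (inherits(dest, "ome_zarr_store")) dest else ome_zarr_store(dest, key)
  attrs <- zarr_read_group_attrs(st$backend, st$key)
  ms <- attrs$multiscales[[1]]
  spacing <- ms$datasets[[1]]$coordinateTransformations[[1]]$scale[[1]]
  role <- if (!is.null(attrs$tomopick)) attrs$tomopick$role else {
    if (identical(ms$type, "mode")) "segmentation" else "tomogram"
  }
  multilabel <- isTRUE(attrs$tomopick$multilabel)
  levels <- lapply(ms$datasets, function(d)
    zarr_read_array(st$backend, zjoin(st$key, d$path)))
  meta <- zarr_read_meta(st$backend, zjoin(st$key, ms$datasets[[1]]$path))
  structure(list(levels = levels, spacing = spacing, role = role,
                 multilabel = multilabel, chunk_shape = meta$chunks),
            class = "multiscale_volume")
}

#' Describe a region of one pyramid level
#'
#' Half-open, zero-based voxel ranges per axis (ZYX order).
#'
#' @param level Pyramid level index (0-based).
#' @param z,y,x Two-element vectors `c(start, stop)`, half-open.
#' @return A `volume_region`.
#' @export
volume_region <- function(level, z, y, x) {
  for (r in list(z, y, x)) {
    if (length(r) != 2L || r[1] < 0 || r[1] >= r[2])
      tp_stop("region ranges must be c(start, stop) with 0 <= start < stop",
              "tomopick_range_error")
  }
  structure(list(level = as.integer(level),
                 ranges = list(as.integer(z), as.integer(y), as.integer(x))),
            class = "volume_region")
}

#' Read a sub-region of a volume
#'
#' Equivalent to slicing the full level array with the same half-open
#' ranges. When reading from an `ome_zarr_store`, only chunks intersecting
#' the region are touched.
#'
#' @param x A `multiscale_volume` (in memory) or an `ome_zarr_store`.
#' @param region A `volume_region`.
#' @return 3D array (ZYX).
#' @export
read_region <- function(x, region) UseMethod("read_region")

#' @export
read_region.multiscale_volume <- function(x, region) {
  lv <- x$levels[[region$level + 1L]]
  if (is.null(lv)) tp_stop("no such pyramid level", "tomopick_range_error")
  d <- dim(lv)
  r <- region$ranges
  for (a in 1:3) if (r[[a]][2] > d[a])
    tp_stop("region out of bounds", "tomopick_range_error")
  lv[(r[[1]][1] + 1L):r[[1]][2],
     (r[[2]][1] + 1L):r[[2]][2],
     (r[[3]][1] + 1L):r[[3]][2], drop = FALSE]
}

#' @export
read_region.ome_zarr_store <- function(x, region) {
  zarr_read_region(x$backend, zjoin(x$key, as.character(region$level)),
                   region$ranges)
}

#' Import a volume from MRC, EM or TIFF
#'
#' Detects the format from the file extension (overridable), reads the array
#' in ZYX order, and builds the three-level pyramid. Continuous data are cast
#' to 32-bit float, segmentations to 8-bit unsigned integers. For MRC input,
#' the voxel spacing is taken from the header when present; an explicit
#' `spacing` argument overrides it.
#'
#' @param path Input file.
#' @param role `"tomogram"`, `"segmentation"` or `"feature"`.
#' @param spacing Voxel spacing in angstrom; required when the source format
#'   carries none.
#' @param format `"mrc"`, `"em"` or `"tiff"`; default from extension.
#' @param chunk_shape Chunk shape for subsequent storage.
#' @return A `multiscale_volume`.
#' @export
import_volume <- function(path, role = c("tomogram", "segmentation", "feature"),
                          spacing = NULL, format = NULL,
                          chunk_shape = c(256L, 256L, 256L)) {
  role <- match.arg(role)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      mrc = , rec = , map = , st = "mrc",
      em = "em",
      tif = , tiff = "tiff",
      tp_stop(paste0("unknown volume format: .", ext), "tomopick_format_error"))
  }
  res <- switch(format,
    mrc = read_mrc(path),
    em = read_em(path),
    tiff = list(data = read_tiff_volume(path), spacing = NULL),
    tp_stop(paste0("unknown volume format: ", format), "tomopick_format_error"))
  if (is.null(spacing)) spacing <- res$spacing
  if (is.null(spacing))
    tp_stop("source carries no voxel spacing; supply `spacing`",
            "tomopick_value_error")
  multiscale_volume(res$data, spacing = spacing, role = role,
                    chunk_shape = chunk_shape)
}

#' Export one pyramid level to MRC, EM or TIFF
#'
#' MRC export writes a standard 1024-byte header with no extended header,
#' mode 2 for float data, and the voxel spacing in the cell dimension
#' fields, so a float export occupies exactly `1024 + 4 * n_voxels` bytes.
#'
#' @param vol A `multiscale_volume`.
#' @param dest Output file path.
#' @param level Pyramid level to export (0-based, default 0).
#' @param format `"mrc"`, `"em"` or `"tiff"`; default from extension.
#' @return `dest`, invisibly.
#' @export
export_volume <- function(vol, dest, level = 0L, format = NULL) {
  if (level < 0L || level >= length(vol$levels))
    tp_stop("no such pyramid level", "tomopick_range_error")
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(dest))
    format <- switch(ext, mrc = , rec = , map = "mrc", em = "em",
                     tif = , tiff = "tiff",
                     tp_stop(paste0("unknown volume format: .", ext),
                             "tomopick_format_error"))
  }
  arr <- vol$levels[[level + 1L]]
  spacing <- vol$spacing * 2^level
  switch(format,
    mrc = write_mrc(arr, dest, spacing = spacing),
    em = write_em(arr, dest),
    tiff = write_tiff_volume(arr, dest),
    tp_stop(paste0("unknown volume format: ", format), "tomopick_format_error"))
  invisible(dest)
}

#' Predicted on-disk size of an MRC export
#'
#' The same accounting the writer uses: a fixed 1024-byte header (no
#' extended header) plus one element per voxel.
#'
#' @param dim Volume dimensions (any order; only the product matters).
#' @param bytes_per_voxel Element size (4 for mode-2 float).
#' @return Size in bytes.
#' @export
mrc_file_size <- function(dim, bytes_per_voxel = 4) {
  1024 + prod(as.numeric(dim)) * bytes_per_voxel
}
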