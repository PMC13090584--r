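# Conventional cryoET volume formats. MRC2014: 1024-byte header, data with
# columns = X (fastest), rows = Y, sections = Z, matching ZYX arrays after a
# transpose. EM format: 512-byte header, same axis layout. TIFF: one 2D page
# per Z section; reading uses the tiff package, writing emits baseline
# little-endian 32-bit float TIFFs (one strip per page) because generic TIFF
# writers rescale float data to [0, 1], which would break lossless round
# trips of physical densities.

.mrc_modes <- list(
  `0` = list(what = "integer", size = 1L, signed = TRUE),
  `1` = list(what = "integer", size = 2L, signed = TRUE),
  `2` = list(what = "numeric", size = 4L, signed = TRUE),
  `6` = list(what = "integer", size = 2L, signed = FALSE)
)

#' Read an MRC2014 volume
#'
#' Accepts modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16). Returns
#' the array in ZYX order plus the voxel spacing derived from the cell
#' dimensions when present.
#'
#' @param path MRC file.
#' @return List with `data` (3D array, ZYX), `spacing` (angstrom or `NULL`),
#'   `mode`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256L, size = 4L, endian = "little")
  seek(con, 0)
  hdr_flt <- readBin(con, "numeric", n = 256L, size = 4L, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  mx <- hdr_int[8]
  cella_x <- hdr_flt[11]
  nsymbt <- hdr_int[24]
  spec <- .mrc_modes[[as.character(mode)]]
  if (is.null(spec))
    tp_stop(paste0("unsupported MRC mode: ", mode), "tomopick_format_error")
  if (nx <= 0 || ny <= 0 || nz <= 0)
    tp_stop("corrupt MRC header: nonpositive dimensions", "tomopick_format_error")
  seek(con, 1024 + nsymbt)
  n <- as.numeric(nx) * ny * nz
  data <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = "little")
  if (length(data) != n)
    tp_stop("truncated MRC payload", "tomopick_format_error")
  arr <- aperm(array(data, c(nx, ny, nz)), c(3L, 2L, 1L))
  spacing <- if (mx > 0 && cella_x > 0) cella_x / mx else NULL
  list(data = arr, spacing = spacing, mode = mode)
}

#' Write an MRC2014 volume
#'
#' Standard 1024-byte header, no extended header; float data are written in
#' mode 2, integer data (0..65535) in mode 6. Voxel spacing goes into the
#' cell dimension fields (`cella = n * spacing`, grid size = `n`).
#'
#' @param arr 3D array in ZYX order.
#' @param path Destination file.
#' @param spacing Voxel spacing in angstrom (default 1).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(arr, path, spacing = 1) {
  d <- dim(arr)
  if (length(d) != 3L) tp_stop("expected a 3D array", "tomopick_shape_error")
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  mode <- if (is.integer(arr)) 6L else 2L
  hdr_i <- integer(256)
  hdr_f <- numeric(256)
  use_f <- logical(256)
  hdr_i[1:3] <- c(nx, ny, nz)
  hdr_i[4] <- mode
  hdr_i[8:10] <- c(nx, ny, nz)                       # grid size mx, my, mz
  hdr_f[11:13] <- c(nx, ny, nz) * spacing; use_f[11:13] <- TRUE  # cell A
  hdr_f[14:16] <- 90; use_f[14:16] <- TRUE           # cell angles
  hdr_i[17:19] <- c(1L, 2L, 3L)                      # axis order cols=X..secs=Z
  hdr_f[20] <- min(arr); hdr_f[21] <- max(arr)
  hdr_f[22] <- mean(arr); use_f[20:22] <- TRUE
  hdr_i[23] <- 1L                                    # spacegroup: volume
  hdr_i[24] <- 0L                                    # nsymbt: no extended header
  hdr_i[53] <- readBin(charToRaw("MAP "), "integer", size = 4L, endian = "little")
  hdr_i[54] <- readBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), "integer",
                       size = 4L, endian = "little") # machine stamp: little-endian
  hdr_f[55] <- stats::sd(as.vector(arr)); use_f[55] <- TRUE
  con <- file(path, "wb")
  on.exit(close(con))
  for (w in 1:256) {
    if (use_f[w]) writeBin(hdr_f[w], con, size = 4L, endian = "little")
    else writeBin(hdr_i[w], con, size = 4L, endian = "little")
  }
  payload <- as.vector(aperm(arr, c(3L, 2L, 1L)))    # X fastest
  if (mode == 2L) writeBin(as.numeric(payload), con, size = 4L, endian = "little")
  else writeBin(as.integer(payload), con, size = 2L, endian = "little")
  invisible(path)
}

.em_types <- list(
  `1` = list(what = "integer", size = 1L, signed = FALSE),
  `2` = list(what = "integer", size = 2L, signed = TRUE),
  `4` = list(what = "integer", size = 4L, signed = TRUE),
  `5` = list(what = "numeric", size = 4L, signed = TRUE),
  `9` = list(what = "numeric", size = 8L, signed = TRUE)
)

#' Read an EM-format volume
#'
#' Parses the fixed 512-byte header (machine code, data type code, X/Y/Z
#' dimensions) and the raw payload.
#'
#' @param path EM file.
#' @return List with `data` (3D array, ZYX) and `spacing = NULL` (the format
#'   carries no calibrated spacing in its fixed fields).
#' @export
read_em <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readBin(con, "integer", n = 4L, size = 1L, signed = TRUE)
  dtype <- h[4]
  dims <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  spec <- .em_types[[as.character(dtype)]]
  if (is.null(spec))
    tp_stop(paste0("unsupported EM data type code: ", dtype), "tomopick_format_error")
  if (any(dims <= 0))
    tp_stop("corrupt EM header: nonpositive dimensions", "tomopick_format_error")
  seek(con, 512)
  n <- prod(as.numeric(dims))
  data <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = "little")
  if (length(data) != n) tp_stop("truncated EM payload", "tomopick_format_error")
  list(data = aperm(array(data, dims), c(3L, 2L, 1L)), spacing = NULL)
}

#' Write an EM-format volume (float32)
#'
#' @param arr 3D array in ZYX order.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_em <- function(arr, path) {
  d <- dim(arr)
  if (length(d) != 3L) tp_stop("expected a 3D array", "tomopick_shape_error")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(6L, 0L, 0L, 5L)), con, size = 1L)  # PC byte order, float32
  writeBin(as.integer(c(d[3], d[2], d[1])), con, size = 4L, endian = "little")
  writeBin(raw(512 - 16), con)
  writeBin(as.numeric(as.vector(aperm(arr, c(3L, 2L, 1L)))), con,
           size = 4L, endian = "little")
  invisible(path)
}

#' Read a single- or multi-page TIFF as a ZYX volume
#' @param path TIFF file.
#' @return 3D array (ZYX); one page becomes a single Z section.
#' @export
read_tiff_volume <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) tiff::readTIFF(path, all = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(length(pages), ny, nx))
  for (z in seq_along(pages)) {
    p <- pages[[z]]
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first channel of multi-channel
    arr[z, , ] <- p
  }
  arr
}

#' Write a ZYX volume as a multi-page 32-bit float TIFF
#'
#' Baseline little-endian TIFF, one IFD and one uncompressed strip per Z
#' section, SampleFormat = IEEE float.
#'
#' @param arr 3D array in ZYX order.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_tiff_volume <- function(arr, path) {
  d <- dim(arr)
  if (length(d) != 3L) tp_stop("expected a 3D array", "tomopick_shape_error")
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  strip_bytes <- nx * ny * 4L
  n_entries <- 9L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  writeBin(charToRaw("II"), con); w16(42L); w32(8L)  # header; first IFD at 8
  # layout: IFDs first (starting at 8), then strips
  strips0 <- 8L + nz * ifd_bytes
  entry <- function(tag, type, count, value) { w16(tag); w16(type); w32(count); w32(value) }
  for (z in seq_len(nz)) {
    off <- strips0 + (z - 1L) * strip_bytes
    w16(n_entries)
    entry(256L, 3L, 1L, nx)            # ImageWidth
    entry(257L, 3L, 1L, ny)            # ImageLength
    entry(258L, 3L, 1L, 32L)           # BitsPerSample
    entry(259L, 3L, 1L, 1L)            # Compression: none
    entry(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
    entry(273L, 4L, 1L, off)           # StripOffsets
    entry(278L, 3L, 1L, ny)            # RowsPerStrip
    entry(279L, 4L, 1L, strip_bytes)   # StripByteCounts
    entry(339L, 3L, 1L, 3L)            # SampleFormat: IEEE float
    w32(if (z < nz) 8L + z * ifd_bytes else 0L)  # next IFD
  }
  for (z in seq_len(nz)) {
    # row-major page: x fastest within each row, rows top to bottom
    writeBin(as.numeric(as.vector(t(arr[z, , ]))), con, size = 4L, endian = "little")
  }
  invisible(path)
}
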