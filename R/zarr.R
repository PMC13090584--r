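# Minimal zarr v2 directory store used for chunked, compressed volume data.
# Arrays are written C-order (shape [nz, ny, nx]) with a byte-shuffle filter
# and the LZ4 block codec, matching the numcodecs "shuffle" and "lz4" codec
# ids so stores remain readable by other zarr implementations. R arrays carry
# dim = c(nz, ny, nx); serialization transposes to C order.

zjoin <- function(key, x) if (nzchar(key)) paste(key, x, sep = "/") else x

.zarr_dtypes <- list(
  "<f4" = list(
    size = 4L,
    encode = function(v) writeBin(as.numeric(v), raw(), size = 4L, endian = "little"),
    decode = function(r, n) readBin(r, "numeric", n = n, size = 4L, endian = "little")
  ),
  "|u1" = list(
    size = 1L,
    encode = function(v) as.raw(v),
    decode = function(r, n) as.integer(r[seq_len(n)])
  ),
  "<u2" = list(
    size = 2L,
    encode = function(v) writeBin(as.integer(v), raw(), size = 2L, endian = "little"),
    decode = function(r, n) readBin(r, "integer", n = n, size = 2L,
                                    signed = FALSE, endian = "little")
  )
)

zarr_dtype_for_role <- function(role, multilabel = FALSE) {
  switch(role,
    tomogram = "<f4",
    feature = "<f4",
    segmentation = if (multilabel) "<u2" else "|u1",
    tp_stop(paste0("unknown volume role: ", role), "tomopick_value_error")
  )
}

encode_chunk <- function(values, dtype, compressor) {
  dt <- .zarr_dtypes[[dtype]]
  bytes <- dt$encode(values)
  if (dt$size > 1L) bytes <- byte_shuffle(bytes, dt$size)
  if (identical(compressor, "lz4")) bytes <- lz4_compress_raw(bytes)
  bytes
}

decode_chunk <- function(bytes, dtype, n, compressor, shuffled) {
  dt <- .zarr_dtypes[[dtype]]
  if (identical(compressor, "lz4")) bytes <- lz4_decompress_raw(bytes)
  if (shuffled && dt$size > 1L) bytes <- byte_unshuffle(bytes, dt$size)
  dt$decode(bytes, n)
}

# arr: R array dim c(nz, ny, nx). key: zarr array node ("0", "1", ...).
zarr_write_array <- function(backend, key, arr, dtype,
                             chunks = c(256L, 256L, 256L),
                             compressor = "lz4") {
  shape <- dim(arr)
  if (length(shape) != 3L)
    tp_stop("expected a 3D array", "tomopick_shape_error")
  chunks <- pmin(as.integer(chunks), as.integer(shape))
  dt <- .zarr_dtypes[[dtype]]
  if (is.null(dt)) tp_stop(paste0("unsupported dtype: ", dtype), "tomopick_value_error")
  meta <- paste0(
    '{"zarr_format":2,"shape":[', paste(shape, collapse = ","),
    '],"chunks":[', paste(chunks, collapse = ","),
    '],"dtype":"', dtype, '",',
    if (identical(compressor, "lz4"))
      '"compressor":{"id":"lz4","acceleration":1},' else '"compressor":null,',
    if (dt$size > 1L)
      paste0('"filters":[{"id":"shuffle","elementsize":', dt$size, '}],')
    else '"filters":null,',
    '"fill_value":0,"order":"C","dimension_separator":"."}'
  )
  backend$write(zjoin(key, ".zarray"), charToRaw(meta))
  nch <- as.integer(ceiling(shape / chunks))
  for (cx in 0:(nch[3] - 1L)) for (cy in 0:(nch[2] - 1L)) for (cz in 0:(nch[1] - 1L)) {
    zr <- (cz * chunks[1] + 1L):min((cz + 1L) * chunks[1], shape[1])
    yr <- (cy * chunks[2] + 1L):min((cy + 1L) * chunks[2], shape[2])
    xr <- (cx * chunks[3] + 1L):min((cx + 1L) * chunks[3], shape[3])
    sub <- arr[zr, yr, xr, drop = FALSE]
    if (any(dim(sub) != chunks)) {  # pad edge chunks with fill value
      padded <- array(if (dtype == "<f4") 0 else 0L, chunks)
      padded[seq_along(zr), seq_along(yr), seq_along(xr)] <- sub
      sub <- padded
    }
    values <- as.vector(aperm(sub, c(3L, 2L, 1L)))  # C order: x fastest
    backend$write(zjoin(key, paste(cz, cy, cx, sep = ".")),
                  encode_chunk(values, dtype, compressor))
  }
  invisible(key)
}

zarr_read_meta <- function(backend, key) {
  meta <- jsonlite::fromJSON(rawToChar(backend$read(zjoin(key, ".zarray"))),
                             simplifyVector = TRUE)
  meta$shape <- as.integer(meta$shape)
  meta$chunks <- as.integer(meta$chunks)
  meta
}

# ranges: list of three c(start, stop), 0-based half-open, axes (z, y, x).
# Reads only chunks intersecting the requested region.
zarr_read_region <- function(backend, key, ranges) {
  meta <- zarr_read_meta(backend, key)
  shape <- meta$shape
  chunks <- meta$chunks
  for (a in 1:3) {
    r <- ranges[[a]]
    if (length(r) != 2L || r[1] >= r[2])
      tp_stop("region ranges must satisfy start < stop", "tomopick_range_error")
    if (r[1] < 0 || r[2] > shape[a])
      tp_stop("region out of bounds", "tomopick_range_error")
  }
  compressor <- if (!is.null(meta$compressor) && length(meta$compressor) > 0)
    meta$compressor$id else NULL
  shuffled <- !is.null(meta$filters)
  dtype <- meta$dtype
  intval <- dtype != "<f4"
  outshape <- vapply(ranges, function(r) as.integer(r[2] - r[1]), integer(1))
  out <- array(if (intval) 0L else 0, outshape)
  cfrom <- vapply(1:3, function(a) ranges[[a]][1] %/% chunks[a], numeric(1))
  cto <- vapply(1:3, function(a) (ranges[[a]][2] - 1L) %/% chunks[a], numeric(1))
  n <- prod(chunks)
  for (cz in cfrom[1]:cto[1]) for (cy in cfrom[2]:cto[2]) for (cx in cfrom[3]:cto[3]) {
    ck <- zjoin(key, paste(cz, cy, cx, sep = "."))
    cidx <- c(cz, cy, cx)
    if (backend$exists(ck)) {
      values <- decode_chunk(backend$read(ck), dtype, n, compressor, shuffled)
      carr <- aperm(array(values, rev(chunks)), c(3L, 2L, 1L))
    } else {
      carr <- array(if (intval) 0L else 0, chunks)  # missing chunk = fill value
    }
    for (a in 1:3) {
      r <- ranges[[a]]
      lo <- max(r[1], cidx[a] * chunks[a])
      hi <- min(r[2], (cidx[a] + 1L) * chunks[a])
      assign(c("sz", "sy", "sx")[a], (lo - cidx[a] * chunks[a] + 1L):(hi - cidx[a] * chunks[a]))
      assign(c("oz", "oy", "ox")[a], (lo - r[1] + 1L):(hi - r[1]))
    }
    out[oz, oy, ox] <- carr[sz, sy, sx, drop = FALSE]
  }
  out
}

zarr_read_array <- function(backend, key) {
  meta <- zarr_read_meta(backend, key)
  zarr_read_region(backend, key, lapply(meta$shape, function(s) c(0L, s)))
}

zarr_write_group_attrs <- function(backend, key, attrs) {
  backend$write(zjoin(key, ".zgroup"), charToRaw('{"zarr_format":2}'))
  backend$write(zjoin(key, ".zattrs"),
                charToRaw(jsonlite::toJSON(attrs, auto_unbox = TRUE, digits = NA,
                                           null = "null")))
  invisible(key)
}

zarr_read_group_attrs <- function(backend, key) {
  jsonlite::fromJSON(rawToChar(backend$read(zjoin(key, ".zattrs"))),
                     simplifyVector = FALSE)
}
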