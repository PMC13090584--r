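# Triangle mesh annotations. Vertices are in angstrom, in the same
# corner-origin frame as picks and voxel data; faces are triangles indexing
# vertices (1-based in R, serialized 0-based). Container format is binary
# glTF 2.0 (GLB): a JSON chunk describing one mesh primitive plus a binary
# chunk holding uint32 indices and float32 positions.

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix (x, y, z in angstrom).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return Object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  if (ncol(faces) != 3L)
    tp_stop("faces must be triangles (3 columns)", "tomopick_geometry_error")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    tp_stop("face indices out of range", "tomopick_geometry_error")
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh vertices=%d faces=%d>\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Check whether a mesh is watertight
#'
#' Every undirected edge must be used an even number of times with balanced
#' directions, so that inside/outside parity is well defined.
#'
#' @param mesh A `tri_mesh`.
#' @return Logical; attribute `boundary_edges` counts offending edges.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(structure(FALSE, boundary_edges = 0L))
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  odd <- sum(table(key) %% 2 != 0)
  # direction balance: each undirected edge traversed equally both ways
  dirkey <- paste(ed[, 1], ed[, 2])
  revkey <- paste(ed[, 2], ed[, 1])
  u <- unique(c(dirkey, revkey))
  balance <- tabulate(match(dirkey, u), nbins = length(u)) -
    tabulate(match(revkey, u), nbins = length(u))
  ok <- (odd == 0) && all(balance == 0)
  structure(ok, boundary_edges = odd)
}

#' Total surface area of a mesh (square angstrom)
#' @param mesh A `tri_mesh`.
#' @return Numeric scalar.
#' @export
mesh_area <- function(mesh) {
  sum(face_areas(mesh))
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0) return(numeric())
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Signed enclosed volume of a closed mesh (cubic angstrom)
#'
#' Sum of signed tetrahedra against the origin; positive for consistently
#' outward-oriented surfaces.
#'
#' @param mesh A `tri_mesh`.
#' @return Numeric scalar.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0) return(0)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

pad4 <- function(bytes, fill = as.raw(0)) {
  r <- length(bytes) %% 4L
  if (r == 0L) bytes else c(bytes, rep(fill, 4L - r))
}

#' Write a mesh as binary glTF (GLB)
#'
#' @param mesh A `tri_mesh`.
#' @param path Destination file.
#' @param allow_empty Permit writing a mesh with no faces (default `FALSE`:
#'   degenerate meshes raise an error).
#' @return `path`, invisibly.
#' @export
write_glb <- function(mesh, path, allow_empty = FALSE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  if ((nv == 0 || nf == 0) && !allow_empty)
    tp_stop("refusing to write an empty mesh (set allow_empty = TRUE to force)",
            "tomopick_geometry_error")
  idx <- as.integer(t(mesh$faces)) - 1L
  ibytes <- writeBin(idx, raw(), size = 4L, endian = "little")
  vbytes <- writeBin(as.numeric(t(mesh$vertices)), raw(), size = 4L, endian = "little")
  ioff <- length(ibytes)
  vmin <- if (nv) apply(mesh$vertices, 2, min) else c(0, 0, 0)
  vmax <- if (nv) apply(mesh$vertices, 2, max) else c(0, 0, 0)
  json <- list(
    asset = list(version = "2.0", generator = "tomopick"),
    scene = 0L, scenes = list(list(nodes = list(0L))),
    nodes = list(list(mesh = 0L)),
    meshes = list(list(primitives = list(list(
      attributes = list(POSITION = 1L), indices = 0L, mode = 4L)))),
    buffers = list(list(byteLength = ioff + length(vbytes))),
    bufferViews = list(
      list(buffer = 0L, byteOffset = 0L, byteLength = ioff, target = 34963L),
      list(buffer = 0L, byteOffset = ioff, byteLength = length(vbytes),
           target = 34962L)),
    accessors = list(
      list(bufferView = 0L, componentType = 5125L, count = length(idx),
           type = "SCALAR"),
      list(bufferView = 1L, componentType = 5126L, count = nv, type = "VEC3",
           min = snap_f4(vmin), max = snap_f4(vmax)))
  )
  jraw <- pad4(charToRaw(as.character(
    jsonlite::toJSON(json, auto_unbox = TRUE, digits = NA))), as.raw(0x20))
  braw <- pad4(c(ibytes, vbytes))
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  writeBin(charToRaw("glTF"), con)
  w32(2L)
  w32(12L + 8L + length(jraw) + 8L + length(braw))
  w32(length(jraw)); writeBin(charToRaw("JSON"), con); writeBin(jraw, con)
  w32(length(braw)); writeBin(c(charToRaw("BIN"), as.raw(0)), con); writeBin(braw, con)
  invisible(path)
}

#' Read a mesh from binary glTF (GLB)
#'
#' Reads the first primitive of the first mesh; positions must be float32
#' VEC3, indices uint16 or uint32 triangles.
#'
#' @param path GLB file.
#' @param allow_empty Permit a mesh with no faces.
#' @return A `tri_mesh`.
#' @export
read_glb <- function(path, allow_empty = FALSE) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  r32 <- function(off) readBin(bytes[(off + 1):(off + 4)], "integer",
                               size = 4L, endian = "little")
  if (rawToChar(bytes[1:4]) != "glTF")
    tp_stop("not a GLB file", "tomopick_format_error")
  jlen <- r32(12)
  json <- jsonlite::fromJSON(rawToChar(bytes[(20 + 1):(20 + jlen)]),
                             simplifyVector = FALSE)
  boff <- 20 + jlen + 8
  blen <- r32(20 + jlen)
  bin <- bytes[(boff + 1):(boff + blen)]
  prim <- json$meshes[[1]]$primitives[[1]]
  if (!is.null(prim$mode) && prim$mode != 4)
    tp_stop("only triangle primitives are supported", "tomopick_geometry_error")
  get_accessor <- function(ai) {
    acc <- json$accessors[[ai + 1]]
    bv <- json$bufferViews[[acc$bufferView + 1]]
    off <- (if (is.null(bv$byteOffset)) 0L else bv$byteOffset) +
      (if (is.null(acc$byteOffset)) 0L else acc$byteOffset)
    ncomp <- switch(acc$type, SCALAR = 1L, VEC3 = 3L,
                    tp_stop("unsupported accessor type", "tomopick_format_error"))
    n <- acc$count * ncomp
    if (acc$componentType == 5126)
      readBin(bin[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4L,
              endian = "little")
    else if (acc$componentType == 5125)
      readBin(bin[(off + 1):(off + 4 * n)], "integer", n = n, size = 4L,
              endian = "little")
    else if (acc$componentType == 5123)
      readBin(bin[(off + 1):(off + 2 * n)], "integer", n = n, size = 2L,
              signed = FALSE, endian = "little")
    else tp_stop("unsupported accessor component type", "tomopick_format_error")
  }
  pos <- get_accessor(prim$attributes$POSITION)
  vertices <- matrix(pos, ncol = 3, byrow = TRUE)
  faces <- if (!is.null(prim$indices)) {
    matrix(get_accessor(prim$indices) + 1L, ncol = 3, byrow = TRUE)
  } else matrix(integer(), 0, 3)
  if (nrow(faces) == 0 && !allow_empty)
    tp_stop("mesh has no faces", "tomopick_geometry_error")
  tri_mesh(vertices, faces)
}
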