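# Mesh-domain annotation operations. Surface extraction uses the cuberille
# construction: each foreground voxel occupies the cube
# [index*s - s/2, index*s + s/2]^3 and every face adjacent to background
# contributes an outward-facing quad (two triangles) at the 0.5 level of
# the nearest-neighbor-interpolated binary field. The result is closed by
# construction and encloses every foreground voxel center exactly.

shift_bg <- function(fg, axis, dir) {
  # TRUE where the neighbor of a voxel along +/-axis is background/outside
  d <- dim(fg)
  out <- array(TRUE, d)
  n <- d[axis]
  if (n == 1) return(out)
  src <- switch(axis, `1` = fg[-1, , , drop = FALSE],
                      `2` = fg[, -1, , drop = FALSE],
                      `3` = fg[, , -1, drop = FALSE])
  if (dir > 0) {
    # neighbor at +1: for voxels 1..n-1 neighbor is fg[i+1]
    switch(axis,
      `1` = { out[-n, , ] <- !src },
      `2` = { out[, -n, ] <- !src },
      `3` = { out[, , -n] <- !src })
  } else {
    switch(axis,
      `1` = { out[-1, , ] <- !fg[-n, , , drop = FALSE] },
      `2` = { out[, -1, ] <- !fg[, -n, , drop = FALSE] },
      `3` = { out[, , -1] <- !fg[, , -n, drop = FALSE] })
  }
  out
}

#' Extract a closed surface mesh around a binary segmentation
#'
#' Emits the boundary faces between foreground and background voxels at the
#' 0.5 iso-level of the binary field, with vertices on the half-voxel
#' lattice scaled to angstrom. The surface is watertight and encloses all
#' foreground voxel centers. Optional Laplacian smoothing relaxes the
#' blocky surface (and may shrink it slightly; default off).
#'
#' @param seg A `segmentation` with at least one foreground voxel.
#' @param smooth_iterations Laplacian smoothing passes (default 0).
#' @return A `tri_mesh` in angstrom.
#' @export
segmentation_to_mesh <- function(seg, smooth_iterations = 0L) {
  fg <- seg$mask != 0L
  if (!any(fg)) tp_stop("empty mask has no surface", "tomopick_value_error")
  d <- dim(fg)
  s <- seg$spacing
  # corner lattice key for corner (kz, ky, kx) in 0..d (position (k-0.5)*s)
  nk <- d + 1L
  corner_key <- function(kz, ky, kx) kz + nk[1] * (ky + nk[2] * kx)
  vkeys <- integer()
  faces <- integer()
  # face tables: for each of 6 directions, the 4 corner offsets (zyx) in
  # counterclockwise order seen from outside
  dirs <- list(
    list(ax = 1L, dir = +1L, quad = rbind(c(1,0,0), c(1,0,1), c(1,1,1), c(1,1,0))),
    list(ax = 1L, dir = -1L, quad = rbind(c(0,0,0), c(0,1,0), c(0,1,1), c(0,0,1))),
    list(ax = 2L, dir = +1L, quad = rbind(c(0,1,0), c(1,1,0), c(1,1,1), c(0,1,1))),
    list(ax = 2L, dir = -1L, quad = rbind(c(0,0,0), c(0,0,1), c(1,0,1), c(1,0,0))),
    list(ax = 3L, dir = +1L, quad = rbind(c(0,0,1), c(0,1,1), c(1,1,1), c(1,0,1))),
    list(ax = 3L, dir = -1L, quad = rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)))
  )
  all_quads <- vector("list", length(dirs))
  for (k in seq_along(dirs)) {
    dd <- dirs[[k]]
    exposed <- fg & shift_bg(fg, dd$ax, dd$dir)
    idx <- which(exposed, arr.ind = TRUE)  # z, y, x 1-based
    if (nrow(idx) == 0) next
    base <- idx - 1L
    q <- matrix(0L, nrow(idx), 4L)
    for (c4 in 1:4) {
      off <- dd$quad[c4, ]
      q[, c4] <- corner_key(base[, 1] + off[1], base[, 2] + off[2],
                            base[, 3] + off[3])
    }
    all_quads[[k]] <- q
  }
  quads <- do.call(rbind, all_quads)
  ukeys <- sort(unique(as.vector(quads)))
  qi <- matrix(match(quads, ukeys), nrow(quads), 4L)
  faces <- rbind(qi[, c(1, 2, 3)], qi[, c(1, 3, 4)])
  kz <- ukeys %% nk[1]
  ky <- (ukeys %/% nk[1]) %% nk[2]
  kx <- ukeys %/% (nk[1] * nk[2])
  verts <- cbind(x = (kx - 0.5) * s, y = (ky - 0.5) * s, z = (kz - 0.5) * s)
  mesh <- tri_mesh(verts, faces)
  if (smooth_iterations > 0) mesh <- laplacian_smooth(mesh, smooth_iterations)
  mesh
}

laplacian_smooth <- function(mesh, iterations = 1L, lambda = 0.5) {
  v <- mesh$vertices
  f <- mesh$faces
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)], f[, 2:1], f[, 3:2], f[, c(1, 3)])
  for (it in seq_len(iterations)) {
    nb <- rowsum(v[ed[, 2], , drop = FALSE], ed[, 1])
    cnt <- tabulate(ed[, 1], nbins = nrow(v))
    mean_nb <- nb[order(as.integer(rownames(nb))), , drop = FALSE] / cnt
    v <- v + lambda * (mean_nb - v)
  }
  tri_mesh(v, f)
}

#' Voxelize a watertight mesh
#'
#' A voxel is foreground iff its position (`index * spacing`) lies inside
#' the closed surface; points on the boundary count as inside. Containment
#' uses a ray-parity test with grazing-ray retry.
#'
#' @param mesh A watertight `tri_mesh`.
#' @param shape Grid shape `c(nz, ny, nx)`.
#' @param spacing Voxel spacing in angstrom.
#' @param label Output label.
#' @return A `segmentation`.
#' @export
mesh_to_segmentation <- function(mesh, shape, spacing, label = 1L) {
  wt <- mesh_is_watertight(mesh)
  if (!wt)
    tp_stop(sprintf("mesh is not watertight (%d boundary edge(s))",
                    attr(wt, "boundary_edges")), "tomopick_geometry_error")
  shape <- as.integer(shape)
  mask <- array(0L, shape)
  # restrict the parity test to voxels inside the mesh bounding box
  vmin <- apply(mesh$vertices, 2, min)
  vmax <- apply(mesh$vertices, 2, max)
  lo <- pmax(ceiling(rev(vmin) / spacing), 0)       # zyx
  hi <- pmin(floor(rev(vmax) / spacing), shape - 1)
  if (any(lo > hi)) return(segmentation(mask, spacing, label = label))
  grid <- expand.grid(iz = lo[1]:hi[1], iy = lo[2]:hi[2], ix = lo[3]:hi[3])
  pts <- cbind(grid$ix, grid$iy, grid$iz) * spacing  # x, y, z
  inside <- points_in_mesh(pts, mesh$vertices, mesh$faces - 1L,
                           eps = 1e-9 * max(1, max(abs(mesh$vertices))))
  sel <- cbind(grid$iz, grid$iy, grid$ix)[inside, , drop = FALSE] + 1L
  mask[sel] <- as.integer(label)
  segmentation(mask, spacing, label = label)
}

#' Sample points uniformly on a mesh surface
#'
#' Faces are chosen with probability proportional to area and points
#' uniformly in barycentric coordinates; reproducible via `seed`.
#'
#' @param mesh A `tri_mesh` with positive total area.
#' @param n Number of points (>= 1).
#' @param seed Integer seed for the sampler.
#' @param object,user,session Attribution for the resulting pick set.
#' @return A `pick_set` with identity orientations; the seed used is stored
#'   in attribute `seed`.
#' @export
mesh_sample_points <- function(mesh, n, seed = 1L, object = "surface",
                               user = "sampler", session = "0") {
  if (n < 1) tp_stop("n must be >= 1", "tomopick_value_error")
  areas <- face_areas(mesh)
  if (length(areas) == 0 || sum(areas) <= 0)
    tp_stop("mesh has zero surface area", "tomopick_geometry_error")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fi <- sample.int(length(areas), n, replace = TRUE, prob = areas)
  u <- stats::runif(n)
  v <- stats::runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]
  v[flip] <- 1 - v[flip]
  a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
  pos <- a + u * (b - a) + v * (cc - a)
  out <- pick_set(object, user, session, pos)
  attr(out, "seed") <- seed
  out
}

surface_distances <- function(picks, surface) {
  if (inherits(surface, "tri_mesh")) {
    if (nrow(surface$faces) == 0)
      tp_stop("empty surface", "tomopick_value_error")
    point_mesh_distance(picks$positions, surface$vertices, surface$faces - 1L)
  } else if (inherits(surface, "segmentation")) {
    centers <- foreground_centers(surface)
    if (nrow(centers) == 0) tp_stop("empty surface", "tomopick_value_error")
    point_cloud_min_distance(picks$positions, centers)
  } else {
    tp_stop("surface must be a tri_mesh or segmentation", "tomopick_value_error")
  }
}

#' Filter picks by distance to a surface
#'
#' For meshes the distance is the exact minimum point-to-triangle distance;
#' for segmentations, the minimum distance to any foreground voxel center.
#' `keep_within` retains picks with distance <= `dmax` (inclusive).
#'
#' @param picks A `pick_set`.
#' @param surface A `tri_mesh` or `segmentation`.
#' @param dmax Distance threshold in angstrom (>= 0).
#' @param mode `"keep_within"` or `"keep_beyond"`.
#' @return Filtered `pick_set`; attributes `dropped` (count) and
#'   `distances` (per input pick) report provenance.
#' @export
distance_filter <- function(picks, surface, dmax,
                            mode = c("keep_within", "keep_beyond")) {
  mode <- match.arg(mode)
  if (dmax < 0) tp_stop("dmax must be >= 0", "tomopick_value_error")
  d <- surface_distances(picks, surface)
  keep <- if (mode == "keep_within") d <= dmax else d > dmax
  out <- subset_picks(picks, keep)
  attr(out, "dropped") <- sum(!keep)
  attr(out, "distances") <- d
  out
}

#' Containment test for picks
#'
#' Mesh regions use the ray-parity inside test (boundary counts as inside);
#' segmentation regions test the foreground value at the nearest voxel
#' index of each point.
#'
#' @param picks A `pick_set`.
#' @param region A watertight `tri_mesh` or a `segmentation`.
#' @return Logical vector, one entry per pick.
#' @export
contains_picks <- function(picks, region) {
  pts <- picks$positions
  if (inherits(region, "tri_mesh")) {
    wt <- mesh_is_watertight(region)
    if (!wt)
      tp_stop(sprintf("mesh is not watertight (%d boundary edge(s))",
                      attr(wt, "boundary_edges")), "tomopick_geometry_error")
    points_in_mesh(pts, region$vertices, region$faces - 1L,
                   eps = 1e-9 * max(1, max(abs(region$vertices))))
  } else if (inherits(region, "segmentation")) {
    idx <- physical_to_index(pts, region$spacing)
    d <- dim(region$mask)
    ok <- idx[, 1] >= 0 & idx[, 1] < d[1] &
          idx[, 2] >= 0 & idx[, 2] < d[2] &
          idx[, 3] >= 0 & idx[, 3] < d[3]
    res <- logical(nrow(pts))
    if (any(ok))
      res[ok] <- region$mask[idx[ok, , drop = FALSE] + 1L] != 0L
    res
  } else {
    tp_stop("region must be a tri_mesh or segmentation", "tomopick_value_error")
  }
}

#' Convex hull of picks or segmentation foreground
#'
#' Incremental 3D hull over pick positions or foreground voxel centers (in
#' angstrom). Every input point lies inside or on the hull within 1e-6
#' (relative to the point cloud scale).
#'
#' @param x A `pick_set` or `segmentation`.
#' @return A watertight, outward-oriented `tri_mesh`.
#' @export
convex_hull <- function(x) {
  pts <- if (inherits(x, "pick_set")) x$positions
         else if (inherits(x, "segmentation")) foreground_centers(x)
         else tp_stop("input must be a pick_set or segmentation",
                      "tomopick_value_error")
  convex_hull_points(pts)
}

convex_hull_points <- function(pts) {
  pts <- unique(round(pts, 12))
  n <- nrow(pts)
  if (n < 4)
    tp_stop("convex hull needs at least 4 points", "tomopick_degenerate_error")
  scale <- max(abs(pts), 1)
  tol <- 1e-9 * scale
  # initial simplex: extremes, then farthest from line/plane
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (max(abs(pts[i1, ] - pts[i2, ])) < tol)
    tp_stop("degenerate input: all points coincide", "tomopick_degenerate_error")
  d12 <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  crossn <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  proj <- rel - outer(drop(rel %*% d12) / sum(d12^2), d12)
  i3 <- which.max(rowSums(proj^2))
  if (sqrt(sum(proj[i3, ]^2)) < tol)
    tp_stop("degenerate input: points are collinear", "tomopick_degenerate_error")
  nrm <- crossn(d12, pts[i3, ] - pts[i1, ])
  h <- drop(rel %*% nrm)
  i4 <- which.max(abs(h))
  if (abs(h[i4]) / sqrt(sum(nrm^2)) < tol)
    tp_stop("degenerate input: points are coplanar", "tomopick_degenerate_error")
  faces <- if (h[i4] > 0) {
    rbind(c(i1, i3, i2), c(i1, i2, i4), c(i2, i3, i4), c(i3, i1, i4))
  } else {
    rbind(c(i1, i2, i3), c(i1, i4, i2), c(i2, i4, i3), c(i3, i4, i1))
  }
  face_normal <- function(f) {
    u <- pts[f[2], ] - pts[f[1], ]
    v <- pts[f[3], ] - pts[f[1], ]
    crossn(u, v)
  }
  used <- c(i1, i2, i3, i4)
  for (p in setdiff(seq_len(n), used)) {
    nrms <- t(apply(faces, 1, face_normal))
    nlen <- sqrt(rowSums(nrms^2))
    d0 <- rowSums(nrms * pts[faces[, 1], , drop = FALSE])
    vis <- (drop(nrms %*% pts[p, ]) - d0) / nlen > tol
    if (!any(vis)) next
    # horizon: directed edges of visible faces whose reverse is not visible
    vf <- faces[vis, , drop = FALSE]
    ed <- rbind(vf[, 1:2], vf[, 2:3], vf[, c(3, 1)])
    ekey <- paste(ed[, 1], ed[, 2])
    rkey <- paste(ed[, 2], ed[, 1])
    horizon <- ed[!(rkey %in% ekey), , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    faces <- rbind(faces, cbind(horizon, p))
  }
  # map to compact vertex list
  ui <- sort(unique(as.vector(faces)))
  remap <- match(faces, ui)
  tri_mesh(pts[ui, , drop = FALSE], matrix(remap, ncol = 3))
}
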