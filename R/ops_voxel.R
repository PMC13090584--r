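# Voxel-domain annotation operations: rasterization of picks, component
# analysis, Boolean algebra, size filtering and thinning. Voxel "position"
# is index * spacing exactly (no half-voxel offset), applied consistently
# across rasterization, centroids, containment and distances so that
# conversion round trips are self-consistent. All thresholds are inclusive.

#' Construct a segmentation
#'
#' @param mask 3D integer array (ZYX); 0 is background.
#' @param spacing Voxel spacing in angstrom.
#' @param object Annotated object name (optional).
#' @param label Foreground label this segmentation represents (default 1).
#' @param multilabel `TRUE` when the mask holds instance labels rather than
#'   a single semantic class.
#' @return Object of class `segmentation`.
#' @export
segmentation <- function(mask, spacing, object = NULL, label = 1L,
                         multilabel = FALSE) {
  if (length(dim(mask)) != 3L)
    tp_stop("segmentation mask must be a 3D array", "tomopick_shape_error")
  if (any(mask < 0) || any(mask != round(mask)))
    tp_stop("segmentation values must be nonnegative integers",
            "tomopick_range_error")
  if (!multilabel && any(mask > 255))
    tp_stop("semantic segmentation values must fit in 8 bits (0..255)",
            "tomopick_range_error")
  storage.mode(mask) <- "integer"
  if (spacing <= 0) tp_stop("spacing must be positive", "tomopick_value_error")
  structure(list(mask = mask, spacing = spacing, object = object,
                 label = as.integer(label), multilabel = multilabel),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation %s spacing=%g A/vx foreground=%d/%d>\n",
              paste(dim(x$mask), collapse = "x"), x$spacing,
              sum(x$mask != 0), length(x$mask)))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (any(dim(a$mask) != dim(b$mask)))
    tp_stop("segmentations have different grid shapes (no implicit resampling)",
            "tomopick_grid_error")
  if (a$spacing != b$spacing)
    tp_stop("segmentations have different voxel spacings (resample explicitly first)",
            "tomopick_grid_error")
}

# physical coordinates (x, y, z) of every foreground voxel, n x 3
foreground_centers <- function(seg) {
  idx <- which(seg$mask != 0, arr.ind = TRUE)  # columns z, y, x (1-based)
  cbind(x = (idx[, 3] - 1) * seg$spacing,
        y = (idx[, 2] - 1) * seg$spacing,
        z = (idx[, 1] - 1) * seg$spacing)
}

#' Rasterize picks into a sphere segmentation
#'
#' A voxel is foreground iff its position `index * spacing` lies within
#' `radius` (inclusive) of some pick; in addition every in-grid pick marks
#' at least its nearest voxel, so degenerate radii below the voxel pitch
#' reduce to single-voxel stamps. Overlapping spheres merge. Picks whose
#' centers fall outside the grid extent are skipped and counted in the
#' `skipped` attribute.
#'
#' @param picks A `pick_set`.
#' @param shape Grid shape `c(nz, ny, nx)`.
#' @param spacing Voxel spacing in angstrom.
#' @param radius Sphere radius in angstrom (> 0); typically the object's
#'   configured particle radius.
#' @param label Output label (default 1).
#' @return A `segmentation`.
#' @export
picks_to_segmentation <- function(picks, shape, spacing, radius, label = 1L) {
  if (radius <= 0) tp_stop("radius must be positive", "tomopick_value_error")
  shape <- as.integer(shape)
  mask <- array(0L, shape)
  extent_hi <- (shape - 1) * spacing  # position of the last voxel per axis
  skipped <- 0L
  n <- nrow(picks$positions)
  for (i in seq_len(n)) {
    p <- picks$positions[i, ]  # x, y, z
    pzyx <- c(p[3], p[2], p[1])
    if (any(pzyx < 0) || any(pzyx > extent_hi)) {
      skipped <- skipped + 1L
      next
    }
    nearest <- pmin(pmax(floor(pzyx / spacing + 0.5), 0), shape - 1)
    mask[nearest[1] + 1, nearest[2] + 1, nearest[3] + 1] <- as.integer(label)
    lo <- pmax(ceiling((pzyx - radius) / spacing), 0)
    hi <- pmin(floor((pzyx + radius) / spacing), shape - 1)
    if (any(lo > hi)) next
    iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
    dz2 <- (iz * spacing - pzyx[1])^2
    dy2 <- (iy * spacing - pzyx[2])^2
    dx2 <- (ix * spacing - pzyx[3])^2
    d2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)
    sub <- mask[iz + 1, iy + 1, ix + 1, drop = FALSE]
    sub[d2 <= radius^2] <- as.integer(label)
    mask[iz + 1, iy + 1, ix + 1] <- sub
  }
  if (skipped > 0)
    warning(sprintf("%d pick(s) outside the grid were skipped", skipped))
  out <- segmentation(mask, spacing, object = picks$object, label = label)
  attr(out, "skipped") <- skipped
  out
}

#' Connected component analysis
#'
#' Labels assigned in scan order of each component's minimum (z, y, x)
#' voxel; default connectivity 26.
#'
#' @param seg A `segmentation` (binary, or pass `label` to select one
#'   foreground value of a multilabel mask).
#' @param connectivity 6, 18 or 26.
#' @param label Optional label to select from a non-binary mask.
#' @return Object of class `labeled_components`: `labels` (3D array),
#'   `sizes` (voxel counts per component), `connectivity`, `spacing`.
#' @export
connected_components <- function(seg, connectivity = 26L, label = NULL) {
  vals <- unique(as.vector(seg$mask))
  if (is.null(label)) {
    if (length(setdiff(vals, 0L)) > 1L)
      tp_stop("mask is not binary; pass `label` to select one value",
              "tomopick_value_error")
    bin <- seg$mask != 0L
  } else {
    bin <- seg$mask == label
  }
  storage.mode(bin) <- "integer"
  labels <- label_components_3d(bin, dim(seg$mask), as.integer(connectivity))
  k <- attr(labels, "n_components")
  labels <- array(labels, dim(seg$mask))
  sizes <- tabulate(labels[labels > 0L], nbins = k)
  structure(list(labels = labels, sizes = sizes,
                 connectivity = as.integer(connectivity),
                 spacing = seg$spacing, object = seg$object,
                 label = seg$label),
            class = "labeled_components")
}

#' @export
print.labeled_components <- function(x, ...) {
  cat(sprintf("<labeled_components n=%d connectivity=%d>\n",
              length(x$sizes), x$connectivity))
  invisible(x)
}

#' One pick per connected component, at its centroid
#'
#' The centroid is the mean of the member voxel positions (`index *
#' spacing`, in angstrom); orientations are identity. Components are
#' ordered by the scan position of their first voxel.
#'
#' @param seg A `segmentation` (binary or with `label` selection).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param label Optional label selection for non-binary masks.
#' @param object,user,session Attribution for the new pick set (defaults
#'   inherit the segmentation's object).
#' @return A `pick_set`; empty mask gives an empty set.
#' @export
segmentation_to_picks <- function(seg, connectivity = 26L, label = NULL,
                                  object = NULL, user = "centroid", session = "0") {
  comps <- connected_components(seg, connectivity = connectivity, label = label)
  k <- length(comps$sizes)
  if (is.null(object)) object <- if (is.null(seg$object)) "object" else seg$object
  if (k == 0)
    return(pick_set(object, user, session))
  idx <- which(comps$labels > 0L, arr.ind = TRUE)
  lab <- comps$labels[comps$labels > 0L]
  s <- seg$spacing
  pos <- matrix(0, k, 3)
  for (a in 1:3) {
    m <- tapply((idx[, a] - 1) * s, lab, mean)
    pos[, 4 - a] <- m[order(as.integer(names(m)))]  # z,y,x cols -> x,y,z
  }
  pick_set(object, user, session, pos)
}

#' Voxelwise Boolean operation on two segmentations
#'
#' Operates on foreground sets; `subtract` is `a AND NOT b`. Grids must
#' match exactly; mixed spacings are rejected rather than resampled.
#'
#' @param a,b `segmentation`s on the same grid.
#' @param op `"and"`, `"or"`, `"xor"` or `"subtract"`.
#' @param label Output label (default: `a`'s label).
#' @return A `segmentation`.
#' @export
boolean_op <- function(a, b, op = c("and", "or", "xor", "subtract"),
                       label = NULL) {
  op <- match.arg(op)
  check_same_grid(a, b)
  fa <- a$mask != 0L
  fb <- b$mask != 0L
  out <- switch(op,
    and = fa & fb,
    or = fa | fb,
    xor = xor(fa, fb),
    subtract = fa & !fb)
  if (is.null(label)) label <- a$label
  mask <- array(0L, dim(a$mask))
  mask[out] <- as.integer(label)
  segmentation(mask, a$spacing, object = a$object, label = label)
}

#' Keep components within a size range
#'
#' Components with `min_voxels <= size <= max_voxels` (inclusive) are
#' retained and relabeled to the original object label.
#'
#' @param comps A `labeled_components`.
#' @param min_voxels,max_voxels Inclusive bounds (default 1 and `Inf`).
#' @param label Output label (default: the source segmentation's).
#' @return A `segmentation`.
#' @export
size_filter <- function(comps, min_voxels = 1, max_voxels = Inf, label = NULL) {
  if (min_voxels > max_voxels)
    tp_stop("min_voxels must not exceed max_voxels", "tomopick_value_error")
  if (is.null(label)) label <- comps$label
  keep <- which(comps$sizes >= min_voxels & comps$sizes <= max_voxels)
  mask <- array(0L, dim(comps$labels))
  mask[comps$labels %in% keep] <- as.integer(label)
  segmentation(mask, comps$spacing, object = comps$object, label = label)
}

#' Topology-preserving 3D skeletonization
#'
#' Iterative thinning that removes only simple points (voxels whose removal
#' changes neither foreground nor background topology in the (26, 6)
#' digital topology), keeping curve endpoints. The skeleton is a subset of
#' the input foreground with the same number of 26-connected components.
#'
#' @param seg A binary `segmentation`.
#' @return A `segmentation` holding the skeleton.
#' @export
skeletonize <- function(seg) {
  bin <- seg$mask != 0L
  storage.mode(bin) <- "integer"
  thin <- thin_3d(bin, dim(seg$mask))
  mask <- array(0L, dim(seg$mask))
  mask[thin != 0L] <- seg$label
  segmentation(mask, seg$spacing, object = seg$object, label = seg$label)
}

#' Resample a volume or segmentation to a new voxel spacing
#'
#' Explicit resampling for mixed-spacing workflows: nearest-neighbor for
#' label data, trilinear interpolation for continuous data.
#'
#' @param x A `segmentation` or 3D numeric array.
#' @param spacing Current spacing (taken from `x` when it is a
#'   `segmentation`).
#' @param new_spacing Target spacing in angstrom.
#' @return Same type as `x`, on the resampled grid.
#' @export
resample_to_spacing <- function(x, new_spacing, spacing = NULL) {
  is_seg <- inherits(x, "segmentation")
  arr <- if (is_seg) x$mask else x
  if (is_seg) spacing <- x$spacing
  if (is.null(spacing) || spacing <= 0 || new_spacing <= 0)
    tp_stop("spacings must be positive", "tomopick_value_error")
  d <- dim(arr)
  nd <- pmax(as.integer(floor((d - 1) * spacing / new_spacing)) + 1L, 1L)
  tz <- (seq_len(nd[1]) - 1) * new_spacing / spacing
  ty <- (seq_len(nd[2]) - 1) * new_spacing / spacing
  tx <- (seq_len(nd[3]) - 1) * new_spacing / spacing
  if (is_seg) {
    iz <- pmin(pmax(floor(tz + 0.5), 0), d[1] - 1) + 1
    iy <- pmin(pmax(floor(ty + 0.5), 0), d[2] - 1) + 1
    ix <- pmin(pmax(floor(tx + 0.5), 0), d[3] - 1) + 1
    out <- arr[iz, iy, ix, drop = FALSE]
    return(segmentation(out, new_spacing, object = x$object, label = x$label,
                        multilabel = x$multilabel))
  }
  z0 <- pmin(floor(tz), d[1] - 1); z1 <- pmin(z0 + 1, d[1] - 1); wz <- tz - z0
  y0 <- pmin(floor(ty), d[2] - 1); y1 <- pmin(y0 + 1, d[2] - 1); wy <- ty - y0
  x0 <- pmin(floor(tx), d[3] - 1); x1 <- pmin(x0 + 1, d[3] - 1); wx <- tx - x0
  g <- function(zi, yi, xi) arr[zi + 1, yi + 1, xi + 1, drop = FALSE]
  wz3 <- array(rep(wz, times = nd[2] * nd[3]), nd)
  wy3 <- array(rep(rep(wy, each = nd[1]), times = nd[3]), nd)
  wx3 <- array(rep(wx, each = nd[1] * nd[2]), nd)
  (1 - wz3) * ((1 - wy3) * ((1 - wx3) * g(z0, y0, x0) + wx3 * g(z0, y0, x1)) +
               wy3 * ((1 - wx3) * g(z0, y1, x0) + wx3 * g(z0, y1, x1))) +
  wz3 * ((1 - wy3) * ((1 - wx3) * g(z1, y0, x0) + wx3 * g(z1, y0, x1)) +
         wy3 * ((1 - wx3) * g(z1, y1, x0) + wx3 * g(z1, y1, x1)))
}
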