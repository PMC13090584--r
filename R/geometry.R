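# Coordinate conventions and particle poses. All physical positions are in
# angstrom, measured from the corner of the tomogram volume with zero-based
# indexing in a right-handed frame: a voxel index (iz, iy, ix) maps to the
# physical point (x, y, z) = (ix * s, iy * s, iz * s) with no half-voxel
# offset. Orientations are 4x4 homogeneous matrices T mapping a particle's
# reference frame into tomogram space (p_tomo = T p_ref); the rotation block
# lies in SO(3) and the translation holds post-rotation refinement shifts.

#' Voxel index to physical coordinates
#'
#' `(x, y, z) = (ix, iy, iz) * s`; index 0 maps to coordinate 0 (the volume
#' corner), with no half-voxel offset.
#'
#' @param index Integer vector `c(iz, iy, ix)` (ZYX, matching array axes) or
#'   an n x 3 matrix of such rows.
#' @param spacing Voxel spacing s in angstrom per voxel (> 0).
#' @return Numeric `c(x, y, z)` or n x 3 matrix with columns x, y, z.
#' @export
index_to_physical <- function(index, spacing) {
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    tp_stop("voxel spacing must be positive", "tomopick_value_error")
  if (is.matrix(index)) {
    out <- index[, c(3L, 2L, 1L), drop = FALSE] * spacing
    colnames(out) <- c("x", "y", "z")
    out
  } else {
    stats::setNames(index[c(3L, 2L, 1L)] * spacing, c("x", "y", "z"))
  }
}

#' Physical coordinates to voxel index
#'
#' Inverse of [index_to_physical()] with nearest-integer rounding, ties
#' half-up per axis; `mode = "floor"` selects floor semantics instead.
#'
#' @param p Numeric `c(x, y, z)` or n x 3 matrix.
#' @param spacing Voxel spacing in angstrom (> 0).
#' @param mode `"round"` (half-up, default) or `"floor"`.
#' @return Integer `c(iz, iy, ix)` or n x 3 matrix (ZYX columns).
#' @export
physical_to_index <- function(p, spacing, mode = c("round", "floor")) {
  mode <- match.arg(mode)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    tp_stop("voxel spacing must be positive", "tomopick_value_error")
  f <- function(v) if (mode == "round") floor(v / spacing + 0.5) else floor(v / spacing)
  if (is.matrix(p)) {
    out <- f(p[, c(3L, 2L, 1L), drop = FALSE])
    storage.mode(out) <- "integer"
    colnames(out) <- c("iz", "iy", "ix")
    out
  } else {
    stats::setNames(as.integer(f(p[c(3L, 2L, 1L)])), c("iz", "iy", "ix"))
  }
}

#' Construct a 4x4 particle pose transform
#'
#' @param rotation 3x3 rotation matrix in SO(3).
#' @param translation Length-3 shift in angstrom, applied after rotation.
#' @return 4x4 homogeneous matrix of class `pick_transform`.
#' @export
pick_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  T <- diag(4)
  T[1:3, 1:3] <- rotation
  T[1:3, 4] <- translation
  validate_transform(T)
}

#' Validate a pose transform
#'
#' Checks shape, bottom row `(0, 0, 0, 1)`, orthonormality of the rotation
#' block (`max |R'R - I| < tol`) and `det(R) = +1` within `tol`.
#'
#' @param T 4x4 matrix.
#' @param tol Tolerance (default 1e-6).
#' @return `T` (classed), invisibly usable; raises a validation error on
#'   failure.
#' @export
validate_transform <- function(T, tol = 1e-6) {
  if (!is.matrix(T) || any(dim(T) != c(4L, 4L)))
    tp_stop("pose transform must be a 4x4 matrix", "tomopick_validation_error")
  if (any(abs(T[4, ] - c(0, 0, 0, 1)) > tol))
    tp_stop("pose transform bottom row must be (0, 0, 0, 1)",
            "tomopick_validation_error")
  R <- T[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol)
    tp_stop("rotation block is not orthonormal", "tomopick_validation_error")
  if (abs(det(R) - 1) > tol)
    tp_stop("rotation block must have determinant +1", "tomopick_validation_error")
  structure(T, class = "pick_transform")
}

#' Apply a pose transform to a point
#'
#' Homogeneous product `T %*% (p, 1)`: rotation first, then translation.
#'
#' @param T 4x4 pose transform.
#' @param p Length-3 point `c(x, y, z)` (particle reference frame, angstrom)
#'   or an n x 3 matrix.
#' @return Transformed point(s) in tomogram coordinates.
#' @export
apply_transform <- function(T, p) {
  T <- validate_transform(unclass(T))
  if (is.matrix(p)) {
    out <- t(T[1:3, 1:3] %*% t(p)) + rep(T[1:3, 4], each = nrow(p))
    colnames(out) <- c("x", "y", "z")
    out
  } else {
    drop(T[1:3, 1:3] %*% p + T[1:3, 4])
  }
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                            3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                            3, 3, byrow = TRUE)
rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                            3, 3, byrow = TRUE)

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# ZYZ decomposition of M = Rz(a) Ry(b) Rz(c), b in [0, pi]
zyz_from_matrix <- function(M, tol = 1e-8) {
  if (M[3, 3] > 1 - tol) {
    ang <- c(atan2(M[2, 1], M[1, 1]), 0, 0)
    attr(ang, "gimbal_lock") <- TRUE
    return(ang)
  }
  if (M[3, 3] < -1 + tol) {
    ang <- c(atan2(-M[2, 1], -M[1, 1]), pi, 0)
    attr(ang, "gimbal_lock") <- TRUE
    return(ang)
  }
  b <- atan2(sqrt(M[1, 3]^2 + M[2, 3]^2), M[3, 3])
  c(atan2(M[2, 3], M[1, 3]), b, atan2(M[3, 2], -M[3, 1]))
}

# ZXZ decomposition of M = Rz(a) Rx(b) Rz(c), b in [0, pi]
zxz_from_matrix <- function(M, tol = 1e-8) {
  if (M[3, 3] > 1 - tol) {
    ang <- c(atan2(M[2, 1], M[1, 1]), 0, 0)
    attr(ang, "gimbal_lock") <- TRUE
    return(ang)
  }
  if (M[3, 3] < -1 + tol) {
    ang <- c(atan2(M[2, 1], M[1, 1]), pi, 0)
    attr(ang, "gimbal_lock") <- TRUE
    return(ang)
  }
  b <- atan2(sqrt(M[3, 1]^2 + M[3, 2]^2), M[3, 3])
  c(atan2(M[1, 3], -M[2, 3]), b, atan2(M[3, 1], M[3, 2]))
}

#' Euler angles to rotation matrix
#'
#' Angle dialects (degrees throughout):
#' * `relion`: `(rot, tilt, psi)`, ZYZ. The stored matrix maps the particle
#'   reference frame into tomogram space, i.e. the transpose of the
#'   reference-to-particle matrix `Rz(psi) Ry(tilt) Rz(rot)` used in that
#'   ecosystem: `R = Rz(-rot) Ry(-tilt) Rz(-psi)`.
#' * `dynamo`: `(tdrot, tilt, narot)`, ZXZ, applied to the template as
#'   narot, then tilt, then tdrot: `R = Rz(tdrot) Rx(tilt) Rz(narot)`.
#'
#' @param angles Length-3 numeric vector (degrees) or n x 3 matrix.
#' @param convention `"relion"` or `"dynamo"`.
#' @return 3x3 rotation matrix (or list of matrices for matrix input).
#' @export
matrix_from_euler <- function(angles, convention = c("relion", "dynamo")) {
  convention <- match.arg(convention)
  one <- function(a) {
    a <- deg2rad(a)
    if (convention == "relion")
      rot_z(-a[1]) %*% rot_y(-a[2]) %*% rot_z(-a[3])
    else
      rot_z(a[1]) %*% rot_x(a[2]) %*% rot_z(a[3])
  }
  if (is.matrix(angles)) lapply(seq_len(nrow(angles)), function(i) one(angles[i, ]))
  else one(angles)
}

#' Rotation matrix to Euler angles
#'
#' Inverse of [matrix_from_euler()]. At gimbal lock (tilt 0 or 180 degrees)
#' the third angle is set to 0, the residual in-plane rotation is folded into
#' the first angle, and the result carries attribute `gimbal_lock = TRUE`.
#'
#' @param M 3x3 rotation matrix.
#' @param convention `"relion"` or `"dynamo"`.
#' @return Length-3 numeric vector of angles in degrees.
#' @export
euler_from_matrix <- function(M, convention = c("relion", "dynamo")) {
  convention <- match.arg(convention)
  wrap180 <- function(x) ((x + 180) %% 360) - 180
  if (convention == "relion") {
    ang <- zyz_from_matrix(M)
    if (isTRUE(attr(ang, "gimbal_lock"))) {
      out <- c(wrap180(-rad2deg(ang[1])), rad2deg(ang[2]), 0)
    } else {
      # use the ZYZ solution with negative middle angle so tilt lands in
      # [0, 180], the range conventional in that ecosystem
      out <- c(wrap180(-rad2deg(ang[1]) - 180), rad2deg(ang[2]),
               wrap180(-rad2deg(ang[3]) - 180))
    }
    names(out) <- c("rot", "tilt", "psi")
  } else {
    ang <- zxz_from_matrix(M)
    out <- rad2deg(ang)
    names(out) <- c("tdrot", "tilt", "narot")
  }
  if (isTRUE(attr(ang, "gimbal_lock"))) attr(out, "gimbal_lock") <- TRUE
  out
}

#' Convert orientations between angle dialects via matrix form
#'
#' All conversions route through the rotation-matrix representation, the
#' unambiguous common language between subtomogram-averaging ecosystems.
#'
#' @param x Length-3 angle vector (degrees) or a 3x3 rotation matrix.
#' @param from,to `"relion"`, `"dynamo"` or `"matrix"`.
#' @return Angles (degrees) or a rotation matrix, per `to`.
#' @export
convert_orientation <- function(x, from, to) {
  conventions <- c("relion", "dynamo", "matrix")
  if (!from %in% conventions || !to %in% conventions)
    tp_stop("unsupported orientation convention", "tomopick_value_error")
  M <- if (from == "matrix") {
    if (!is.matrix(x) || any(dim(x) != c(3L, 3L)))
      tp_stop("matrix input must be 3x3", "tomopick_validation_error")
    x
  } else {
    matrix_from_euler(x, from)
  }
  if (to == "matrix") M else euler_from_matrix(M, to)
}
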