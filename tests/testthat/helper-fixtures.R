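# Shared generators for tests. Everything is built in code at test time;
# no binary fixtures are stored.

random_rotation <- function() {
  A <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(A) < 0) A[, 1] <- -A[, 1]
  A
}

random_pose <- function(scale = 100) {
  pick_transform(random_rotation(), stats::runif(3, 0, scale))
}

# axis-aligned closed box [lo, hi]^3 as 12 outward-oriented triangles
box_mesh <- function(lo, hi) {
  v <- as.matrix(expand.grid(x = c(lo, hi), y = c(lo, hi), z = c(lo, hi)))
  # vertices: 1:(-,-,-) 2:(+,-,-) 3:(-,+,-) 4:(+,+,-) 5:(-,-,+) 6:(+,-,+) 7:(-,+,+) 8:(+,+,+)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = lo (normal -z)
    c(5, 6, 8), c(5, 8, 7),   # z = hi (+z)
    c(1, 2, 6), c(1, 6, 5),   # y = lo (-y)
    c(3, 7, 8), c(3, 8, 4),   # y = hi (+y)
    c(1, 5, 7), c(1, 7, 3),   # x = lo (-x)
    c(2, 4, 8), c(2, 8, 6))   # x = hi (+x)
  tri_mesh(v, f)
}

# random convex mesh: hull of n random points
random_convex_mesh <- function(n = 12, scale = 50) {
  pts <- matrix(stats::runif(3 * n, 0, scale), n, 3)
  convex_hull(pick_set("obj", "t", "0", pts))
}

# solid sphere mask of radius r (voxels) centered in a d^3 grid
sphere_mask <- function(d, r, center = (d + 1) / 2) {
  idx <- as.matrix(expand.grid(z = 1:d, y = 1:d, x = 1:d))
  m <- array(0L, c(d, d, d))
  m[idx[rowSums((idx - center)^2) <= r^2, , drop = FALSE]] <- 1L
  m
}

random_mask <- function(d, p = 0.2) {
  array(as.integer(stats::runif(d^3) < p), c(d, d, d))
}

tmp_project <- function(objects = NULL, n_layers = 2) {
  root <- tempfile("proj")
  if (is.null(objects))
    objects <- list(
      pickable_object("ribosome", label = 1L, radius = 150),
      pickable_object("membrane", label = 2L, is_particle = FALSE))
  layers <- lapply(seq_len(n_layers), function(i)
    list(uri = file.path(root, paste0("layer", i)),
         mode = if (i == n_layers) "mutable" else "static"))
  new_project("test", objects, layers)
}

# a writable handle on a project's static layer, for seeding test content
static_writer <- function(project, layer = 1) {
  local_backend(project$layers[[layer]]$backend$root)
}

# one shared fixture per test session (read-only use only)
cached_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_fixture_project(fixture_spec(seed = 42L), tempfile("fxshared"))
    cache
  }
})

brute_sphere_count <- function(pos_xyz, shape, s, r) {
  # enumerate every voxel and test the distance inequality directly; every
  # pick also stamps its nearest voxel (documented degenerate-radius rule)
  idx <- as.matrix(expand.grid(iz = 0:(shape[1] - 1), iy = 0:(shape[2] - 1),
                               ix = 0:(shape[3] - 1)))
  centers <- cbind(idx[, "ix"], idx[, "iy"], idx[, "iz"]) * s
  fg <- rep(FALSE, nrow(centers))
  for (i in seq_len(nrow(pos_xyz))) {
    d2 <- rowSums(sweep(centers, 2, pos_xyz[i, ])^2)
    fg <- fg | d2 <= r^2
    near <- pmin(pmax(floor(rev(pos_xyz[i, ]) / s + 0.5), 0), shape - 1)
    fg[idx[, 1] == near[1] & idx[, 2] == near[2] & idx[, 3] == near[3]] <- TRUE
  }
  sum(fg)
}
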