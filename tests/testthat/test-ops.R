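# annotation operation suite, checked against brute-force oracles

test_that("sphere rasterization matches per-voxel enumeration", {
  ps <- pick_set("p", "u", "0", matrix(c(160, 160, 160), 1, 3))
  seg <- picks_to_segmentation(ps, c(32, 32, 32), 10, 25)
  expect_identical(sum(seg$mask != 0L), 81L)  # offsets with dz2+dy2+dx2 <= 2.5^2
  set.seed(61)
  for (rep in 1:6) {
    n <- sample(1:4, 1)
    pos <- matrix(stats::runif(3 * n, 0, 150), n, 3)
    r <- stats::runif(1, 8, 40)
    seg <- picks_to_segmentation(pick_set("p", "u", "0", pos), c(16, 16, 16), 10, r)
    expect_identical(sum(seg$mask != 0L), brute_sphere_count(pos, c(16, 16, 16), 10, r))
  }
})

test_that("degenerate radii and out-of-grid picks behave as documented", {
  ps <- pick_set("p", "u", "0", matrix(c(73, 51, 88), 1, 3))
  seg <- picks_to_segmentation(ps, c(16, 16, 16), 10, 0.005)
  expect_identical(sum(seg$mask != 0L), 1L)
  expect_identical(which(seg$mask != 0L, arr.ind = TRUE)[1, ],
                   c(dim1 = 10L, dim2 = 6L, dim3 = 8L))  # nearest voxel +1
  empty <- picks_to_segmentation(pick_set("p", "u", "0"), c(8, 8, 8), 10, 20)
  expect_true(all(empty$mask == 0L))
  outside <- pick_set("p", "u", "0", rbind(c(500, 10, 10), c(20, 20, 20)))
  expect_warning(s2 <- picks_to_segmentation(outside, c(8, 8, 8), 10, 15),
                 "skipped")
  expect_identical(attr(s2, "skipped"), 1L)
})

test_that("component centroids and ordering are deterministic", {
  m <- array(0L, c(12, 12, 12))
  m[5:7, 5:7, 5:7] <- 1L
  ps <- segmentation_to_picks(segmentation(m, 10))
  expect_equal(unname(ps$positions), matrix(c(50, 50, 50), 1, 3))
  m[1, 1, 1] <- 1L  # second component, earlier in scan order
  ps2 <- segmentation_to_picks(segmentation(m, 10))
  expect_equal(nrow(ps2$positions), 2L)
  expect_equal(unname(ps2$positions[1, ]), c(0, 0, 0))
  expect_equal(nrow(segmentation_to_picks(segmentation(array(0L, c(4, 4, 4)), 10))$positions), 0L)
})

test_that("picks -> segmentation -> picks recovers isolated positions within s/2", {
  set.seed(62)
  for (rep in 1:5) {
    pos <- as.matrix(expand.grid(x = c(60, 240), y = c(60, 240), z = c(60, 240)))
    pos <- pos + matrix(stats::runif(length(pos), -12, 12), nrow(pos), 3)
    ps <- pick_set("p", "u", "0", pos)
    seg <- picks_to_segmentation(ps, c(32, 32, 32), 10, 30)
    got <- segmentation_to_picks(seg)
    expect_equal(nrow(got$positions), nrow(pos))
    d <- as.matrix(dist(rbind(pos, got$positions)))
    d <- d[seq_len(nrow(pos)), nrow(pos) + seq_len(nrow(pos)), drop = FALSE]
    expect_lt(max(apply(d, 1, min)), 5)  # half a voxel at s = 10
  }
})

test_that("connected components follow the adjacency definition", {
  m <- array(0L, c(8, 8, 8))
  m[1:3, 1:3, 1:3] <- 1L
  m[4:6, 4:6, 4:6] <- 1L  # touching only at a corner
  expect_length(connected_components(segmentation(m, 10), 26)$sizes, 1L)
  expect_length(connected_components(segmentation(m, 10), 6)$sizes, 2L)
  expect_length(connected_components(segmentation(m, 10), 18)$sizes, 2L)
  expect_length(connected_components(segmentation(array(0L, c(4, 4, 4)), 10))$sizes, 0L)
  set.seed(63)
  for (rep in 1:5) {
    mm <- random_mask(14, 0.25)
    cc <- connected_components(segmentation(mm, 10))
    expect_identical(sum(cc$sizes), sum(mm != 0L))      # conservation
    expect_identical(sort(unique(as.vector(cc$labels[cc$labels > 0]))),
                     seq_along(cc$sizes))               # contiguous labels
  }
  expect_error(connected_components(segmentation(array(c(0L, 1L, 2L), c(3, 1, 1)), 10)),
               "binary")
})

test_that("size filtering keeps exactly the qualifying components", {
  m <- array(0L, c(16, 16, 16))
  m[1:2, 1:2, 1] <- 1L          # 4 voxels
  m[8:11, 8:11, 8:10] <- 1L     # 48 voxels
  cc <- connected_components(segmentation(m, 10, label = 5L), 26)
  kept <- size_filter(cc, min_voxels = 10)
  expect_identical(sum(kept$mask != 0L), 48L)
  expect_identical(unique(as.vector(kept$mask[kept$mask != 0L])), 5L)
  expect_identical(size_filter(cc, min_voxels = 1)$mask != 0L, m != 0L)
  expect_error(size_filter(cc, min_voxels = 10, max_voxels = 5), "exceed")
  set.seed(64)
  for (rep in 1:5) {
    mm <- random_mask(12, 0.3)
    cc <- connected_components(segmentation(mm, 10))
    lo <- sample(1:5, 1); hi <- sample(5:60, 1)
    kept <- size_filter(cc, lo, hi)
    expect_identical(sum(kept$mask != 0L),
                     sum(cc$sizes[cc$sizes >= lo & cc$sizes <= hi]))
  }
})

test_that("Boolean operations obey set algebra and the per-voxel oracle", {
  set.seed(65)
  a <- segmentation(random_mask(10, 0.4), 10, label = 1L)
  b <- segmentation(random_mask(10, 0.4), 10, label = 1L)
  empty <- segmentation(array(0L, c(10, 10, 10)), 10)
  expect_identical(boolean_op(a, a, "and")$mask != 0L, a$mask != 0L)
  expect_true(all(boolean_op(a, a, "xor")$mask == 0L))
  expect_identical(boolean_op(a, empty, "subtract")$mask != 0L, a$mask != 0L)
  expect_identical(boolean_op(a, b, "and")$mask, boolean_op(b, a, "and")$mask)
  expect_identical(boolean_op(a, b, "or")$mask, boolean_op(b, a, "or")$mask)
  # voxelwise oracle
  fa <- a$mask != 0L; fb <- b$mask != 0L
  expect_identical(boolean_op(a, b, "and")$mask != 0L, fa & fb)
  expect_identical(boolean_op(a, b, "xor")$mask != 0L, xor(fa, fb))
  expect_identical(boolean_op(a, b, "subtract")$mask != 0L, fa & !fb)
  # De Morgan via subtract: a or b = a + (b minus a)
  expect_identical(boolean_op(a, b, "or")$mask != 0L,
                   fa | (boolean_op(b, a, "subtract")$mask != 0L))
  mis <- segmentation(array(0L, c(9, 9, 9)), 10)
  expect_error(boolean_op(a, mis, "and"), "grid")
  sp <- segmentation(array(0L, c(10, 10, 10)), 5)
  expect_error(boolean_op(a, sp, "and"), "spacing")
})

test_that("overlapping sphere intersections match brute-force voxel counts", {
  set.seed(66)
  for (rep in 1:5) {
    p1 <- stats::runif(3, 40, 110)
    p2 <- p1 + stats::runif(3, -30, 30)
    r <- stats::runif(1, 20, 45)
    s1 <- picks_to_segmentation(pick_set("p", "u", "0", matrix(p1, 1)), c(16, 16, 16), 10, r)
    s2 <- picks_to_segmentation(pick_set("p", "u", "0", matrix(p2, 1)), c(16, 16, 16), 10, r)
    inter <- boolean_op(s1, s2, "and")
    idx <- as.matrix(expand.grid(iz = 0:15, iy = 0:15, ix = 0:15))
    centers <- cbind(idx[, "ix"], idx[, "iy"], idx[, "iz"]) * 10
    oracle <- sum(rowSums(sweep(centers, 2, p1)^2) <= r^2 &
                  rowSums(sweep(centers, 2, p2)^2) <= r^2)
    expect_identical(sum(inter$mask != 0L), oracle)
  }
})

test_that("cuberille surfaces are closed, local and invert to the input mask", {
  # isolated voxel: the surface is its cube; axis rays cross exactly once
  m <- array(0L, c(9, 9, 9)); m[5, 5, 5] <- 1L
  mesh <- segmentation_to_mesh(segmentation(m, 10))
  expect_true(isTRUE(mesh_is_watertight(mesh)))
  expect_identical(nrow(mesh$faces), 12L)
  expect_equal(mesh_volume(mesh), 1000)  # one voxel cube, s = 10
  # solid cube: bounding box within one voxel of the voxel extent
  m2 <- array(0L, c(12, 12, 12)); m2[2:11, 2:11, 2:11] <- 1L
  mesh2 <- segmentation_to_mesh(segmentation(m2, 10))
  expect_true(all(mesh2$vertices >= 0 & mesh2$vertices <= 11 * 10))
  expect_error(segmentation_to_mesh(segmentation(array(0L, c(4, 4, 4)), 10)), "empty")
  # sphere round trip: voxelization recovers >= 95% of the interior
  s <- segmentation(sphere_mask(16, 6), 10)
  mesh3 <- segmentation_to_mesh(s)
  back <- mesh_to_segmentation(mesh3, c(16, 16, 16), 10)
  expect_gte(sum(back$mask & s$mask) / sum(s$mask), 0.95)
  expect_identical(back$mask != 0L, s$mask != 0L)  # exact for this construction
})

test_that("mesh voxelization equals point-in-box / half-space oracles", {
  seg <- mesh_to_segmentation(box_mesh(5, 25), c(4, 4, 4), 10)
  expect_identical(sum(seg$mask != 0L), 8L)  # centers at 10 and 20 per axis
  far <- box_mesh(1000, 1100)
  expect_true(all(mesh_to_segmentation(far, c(4, 4, 4), 10)$mask == 0L))
  open_m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
  expect_error(mesh_to_segmentation(open_m, c(4, 4, 4), 10), "watertight")
  set.seed(67)
  for (rep in 1:5) {
    hull <- random_convex_mesh(15, 140)
    seg <- mesh_to_segmentation(hull, c(16, 16, 16), 10)
    idx <- as.matrix(expand.grid(iz = 0:15, iy = 0:15, ix = 0:15))
    pts <- cbind(idx[, "ix"], idx[, "iy"], idx[, "iz"]) * 10
    # half-space oracle: inside iff on the inner side of every face plane
    v <- hull$vertices; f <- hull$faces
    ctr <- colMeans(v)
    inside <- rep(TRUE, nrow(pts))
    for (k in seq_len(nrow(f))) {
      a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; cc <- v[f[k, 3], ]
      nrm <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
               (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
               (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
      if (sum((ctr - a) * nrm) > 0) nrm <- -nrm  # outward
      inside <- inside & (as.vector(pts %*% nrm) - sum(a * nrm) <= 1e-9)
    }
    got <- seg$mask[cbind(idx[, "iz"], idx[, "iy"], idx[, "ix"]) + 1L] != 0L
    expect_identical(got, inside)
  }
})

test_that("surface sampling is uniform by area, planar and reproducible", {
  tri <- tri_mesh(rbind(c(0, 0, 0), c(30, 0, 0), c(0, 40, 0)), rbind(c(1, 2, 3)))
  ps <- mesh_sample_points(tri, 200, seed = 7)
  expect_true(all(abs(ps$positions[, 3]) < 1e-6))      # in the z = 0 plane
  expect_true(all(ps$positions[, 1] >= -1e-9 & ps$positions[, 2] >= -1e-9))
  expect_identical(mesh_sample_points(tri, 200, seed = 7)$positions, ps$positions)
  expect_false(identical(mesh_sample_points(tri, 200, seed = 8)$positions, ps$positions))
  # two faces with areas 1 and 3: face-1 fraction within 3 sigma of 1/4
  quad <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(4, 0, 0), c(1, 2, 0)),
                   rbind(c(1, 2, 3), c(2, 4, 5)))
  expect_equal(unname(tomopick:::face_areas(quad)), c(1, 3))
  n <- 10000
  ps2 <- mesh_sample_points(quad, n, seed = 99)
  # triangle 1 is the set with 2x + y <= 2 (meets triangle 2 only at a vertex)
  inface1 <- 2 * ps2$positions[, 1] + ps2$positions[, 2] <= 2 + 1e-9
  p <- mean(inface1)
  expect_lt(abs(p - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  expect_error(mesh_sample_points(tri_mesh(matrix(0, 3, 3), rbind(c(1, 2, 3))), 5),
               "area")
})

test_that("distance filtering is exact, inclusive and partitions the input", {
  plane <- tri_mesh(rbind(c(-1e4, -1e4, 0), c(1e4, -1e4, 0), c(1e4, 1e4, 0),
                          c(-1e4, 1e4, 0)),
                    rbind(c(1, 2, 3), c(1, 3, 4)))
  ps <- pick_set("p", "u", "0", rbind(c(0, 0, 5), c(3, -8, 15), c(12, 5, 30)))
  kept <- distance_filter(ps, plane, 20)
  expect_identical(nrow(kept$positions), 2L)
  expect_identical(attr(kept, "dropped"), 1L)
  expect_equal(attr(kept, "distances"), c(5, 15, 30))
  # dmax = 0 keeps only picks on the surface (inclusive boundary)
  on <- pick_set("p", "u", "0", rbind(c(1, 1, 0), c(0, 0, 1)))
  expect_identical(nrow(distance_filter(on, plane, 0)$positions), 1L)
  # keep_within and keep_beyond partition the picks
  set.seed(68)
  surf <- segmentation(random_mask(10, 0.1), 10)
  rnd <- pick_set("p", "u", "0", matrix(stats::runif(60, 0, 90), 20, 3))
  a <- distance_filter(rnd, surf, 25, "keep_within")
  b <- distance_filter(rnd, surf, 25, "keep_beyond")
  expect_identical(nrow(a$positions) + nrow(b$positions), 20L)
  # segmentation distances equal brute-force voxel-center distances
  centers <- tomopick:::foreground_centers(surf)
  dd <- apply(rnd$positions, 1, function(p)
    sqrt(min(rowSums(sweep(centers, 2, p)^2))))
  expect_equal(unname(attr(a, "distances")), unname(dd))
  expect_error(distance_filter(rnd, segmentation(array(0L, c(4, 4, 4)), 10), 5),
               "empty")
  expect_error(distance_filter(rnd, surf, -1), "dmax")
})

test_that("containment agrees with convex half-space oracles", {
  box <- box_mesh(10, 40)
  ps <- pick_set("p", "u", "0", rbind(c(25, 25, 25), c(500, 500, 500), c(10, 25, 25)))
  expect_identical(contains_picks(ps, box), c(TRUE, FALSE, TRUE))  # boundary inside
  set.seed(69)
  for (rep in 1:5) {
    hull <- random_convex_mesh(10, 60)
    pts <- matrix(stats::runif(90, -10, 70), 30, 3)
    got <- contains_picks(pick_set("p", "u", "0", pts), hull)
    v <- hull$vertices; f <- hull$faces; ctr <- colMeans(v)
    inside <- rep(TRUE, nrow(pts))
    for (k in seq_len(nrow(f))) {
      a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; cc <- v[f[k, 3], ]
      nrm <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
               (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
               (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
      if (sum((ctr - a) * nrm) > 0) nrm <- -nrm
      inside <- inside & (as.vector(pts %*% nrm) - sum(a * nrm) <= 1e-9)
    }
    expect_identical(got, inside)
  }
  # segmentation containment: background voxel next to foreground is outside
  m <- array(0L, c(8, 8, 8)); m[4, 4, 4] <- 1L
  seg <- segmentation(m, 10)
  probes <- pick_set("p", "u", "0", rbind(c(30, 30, 30), c(40, 30, 30), c(31, 30, 30)))
  expect_identical(contains_picks(probes, seg), c(TRUE, FALSE, TRUE))
})

test_that("skeletonization preserves topology and thinness", {
  line <- array(0L, c(1, 1, 11)); line[1, 1, ] <- 1L
  expect_identical(skeletonize(segmentation(line, 10))$mask != 0L, line != 0L)
  bar <- array(1L, c(3, 3, 21))
  sk <- skeletonize(segmentation(bar, 10))
  expect_true(all(sk$mask[bar == 0L] == 0L))
  expect_length(connected_components(sk, 26)$sizes, 1L)
  expect_lt(sum(sk$mask != 0L), sum(bar != 0L) / 3)
  blobs <- array(0L, c(12, 12, 12))
  blobs[2:4, 2:4, 2:4] <- 1L
  blobs[8:11, 8:11, 8:11] <- 1L
  skb <- skeletonize(segmentation(blobs, 10))
  expect_length(connected_components(skb, 26)$sizes, 2L)
  expect_true(all(skb$mask[blobs == 0L] == 0L))
  empty <- skeletonize(segmentation(array(0L, c(4, 4, 4)), 10))
  expect_true(all(empty$mask == 0L))
})

test_that("convex hulls are tight, watertight and contain their inputs", {
  set.seed(70)
  corners <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  pts <- rbind(corners, matrix(stats::runif(30, 0.1, 0.9), 10, 3))
  h <- convex_hull(pick_set("p", "u", "0", pts))
  expect_identical(nrow(h$vertices), 8L)
  expect_equal(mesh_volume(h), 1)
  expect_true(isTRUE(mesh_is_watertight(h)))
  # every input point inside or on the hull
  expect_true(all(tomopick:::point_mesh_distance(pts, h$vertices, h$faces - 1L) <
                    1e-6 | contains_picks(pick_set("p", "u", "0", pts), h)))
  for (rep in 1:3) {
    cl <- matrix(stats::rnorm(60, 50, 15), 20, 3)
    hh <- convex_hull(pick_set("p", "u", "0", cl))
    expect_true(all(contains_picks(pick_set("p", "u", "0", cl), hh)))
  }
  # degenerate inputs
  flat <- cbind(matrix(stats::runif(20), 10, 2), 0)
  expect_error(convex_hull(pick_set("p", "u", "0", flat)), "coplanar")
  lin <- cbind(1:10, 1:10, 1:10)
  expect_error(convex_hull(pick_set("p", "u", "0", lin)), "collinear|degenerate")
  expect_error(convex_hull(pick_set("p", "u", "0", matrix(1:9, 3, 3))), "4 points")
  # segmentation input: hull of foreground voxel centers
  m <- array(0L, c(6, 6, 6)); m[2:5, 2:5, 2:5] <- 1L
  hs <- convex_hull(segmentation(m, 10))
  expect_equal(mesh_volume(hs), 30^3)
})

test_that("resampling uses nearest labels and interpolated intensities", {
  m <- array(0L, c(8, 8, 8)); m[3:6, 3:6, 3:6] <- 4L
  s <- segmentation(m, 10, label = 4L)
  r <- resample_to_spacing(s, 5)
  expect_identical(sort(unique(as.vector(r$mask))), c(0L, 4L))
  expect_equal(r$spacing, 5)
  expect_identical(dim(r$mask), c(15L, 15L, 15L))
  # identity resample
  expect_identical(resample_to_spacing(s, 10)$mask, m)
  a <- array(as.numeric(1:27), c(3, 3, 3))
  ra <- resample_to_spacing(a, 5, spacing = 10)
  expect_identical(dim(ra), c(5L, 5L, 5L))
  expect_equal(ra[2, 1, 1], 1.5)  # halfway between voxels 1 and 2 along z
})
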