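# Deterministic toy projects with known ground truth, so every operation is
# testable without downloading data. The tomogram is a sum of solid
# spherical densities (the "particles"), a slab or spherical-shell
# "membrane", and additive Gaussian noise on a zero background; dense
# structures are bright (the opposite sign of raw cryoET contrast, chosen
# for readability). Ground truth records all pick positions, the membrane
# mask and each particle's distance to the membrane.

#' Specify a synthetic fixture project
#'
#' @param seed RNG seed; the same seed yields a byte-identical project.
#' @param shape Volume shape `c(nz, ny, nx)`, at most 64 per axis.
#' @param spacing Voxel spacing in angstrom.
#' @param n_particles Number of particles.
#' @param particle_radius Particle radius in angstrom.
#' @param min_separation Minimum center-to-center distance (default three
#'   radii, keeping rasterized spheres well separated).
#' @param membrane `"slab"`, `"shell"` or `"none"`.
#' @param membrane_thickness Membrane thickness in angstrom.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(seed = 42L, shape = c(48L, 48L, 48L), spacing = 10,
                         n_particles = 8L, particle_radius = 30,
                         min_separation = 3 * particle_radius,
                         membrane = c("slab", "shell", "none"),
                         membrane_thickness = 20, noise_sigma = 0.1) {
  membrane <- match.arg(membrane)
  shape <- as.integer(shape)
  if (any(shape > 64L))
    tp_stop("fixture volumes are capped at 64 voxels per axis",
            "tomopick_value_error")
  extent <- (shape - 1) * spacing
  if (any(extent / 2 < particle_radius))
    tp_stop("particles do not fit inside the volume with margin >= radius",
            "tomopick_value_error")
  structure(list(seed = as.integer(seed), shape = shape, spacing = spacing,
                 n_particles = as.integer(n_particles),
                 particle_radius = particle_radius,
                 min_separation = min_separation,
                 membrane = membrane,
                 membrane_thickness = membrane_thickness,
                 noise_sigma = noise_sigma),
            class = "fixture_spec")
}

membrane_mask <- function(spec) {
  d <- spec$shape
  s <- spec$spacing
  mask <- array(0L, d)
  if (spec$membrane == "none") return(mask)
  zc <- (d[1] - 1) * s * 0.25  # slab plane / shell center offset
  if (spec$membrane == "slab") {
    zpos <- (seq_len(d[1]) - 1) * s
    sel <- abs(zpos - zc) <= spec$membrane_thickness / 2
    mask[sel, , ] <- 1L
  } else {
    ctr <- rev((d - 1) * s / 2)  # xyz center
    r0 <- min((d - 1) * s) * 0.35
    iz <- (seq_len(d[1]) - 1) * s
    iy <- (seq_len(d[2]) - 1) * s
    ix <- (seq_len(d[3]) - 1) * s
    dz2 <- (iz - ctr[3])^2
    dy2 <- (iy - ctr[2])^2
    dx2 <- (ix - ctr[1])^2
    r <- sqrt(outer(outer(dz2, dy2, `+`), dx2, `+`))
    mask[abs(r - r0) <= spec$membrane_thickness / 2] <- 1L
  }
  mask
}

#' Generate a synthetic two-layer project with ground truth
#'
#' Writes a static layer holding the tomogram, the reference picks and the
#' membrane segmentation, plus an empty mutable overlay layer, and a
#' project configuration tying them together. Particle placement avoids
#' the membrane (centers at least one particle radius plus half the
#' membrane thickness away) so particles and membrane stay disjoint.
#'
#' @param spec A `fixture_spec`.
#' @param dest Directory for the project (created).
#' @return List with `project` (loaded `tomopick_project`), `config_path`,
#'   `run`, and `ground_truth` (positions, membrane mask, per-particle
#'   membrane distances).
#' @export
make_fixture_project <- function(spec, dest) {
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  static_root <- file.path(dest, "static")
  overlay_root <- file.path(dest, "overlay")
  dir.create(overlay_root, recursive = TRUE, showWarnings = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  d <- spec$shape
  s <- spec$spacing
  memb <- membrane_mask(spec)
  memb_centers <- NULL
  if (any(memb != 0)) {
    idx <- which(memb != 0, arr.ind = TRUE)
    memb_centers <- cbind(x = (idx[, 3] - 1) * s, y = (idx[, 2] - 1) * s,
                          z = (idx[, 1] - 1) * s)
  }
  # rejection-sample particle positions clear of each other and the membrane
  pos <- matrix(NA_real_, 0, 3)
  attempts <- 0L
  max_attempts <- 2000L * spec$n_particles
  extent <- rev((d - 1) * s)
  margin <- spec$particle_radius
  clearance <- spec$particle_radius + spec$membrane_thickness / 2
  while (nrow(pos) < spec$n_particles) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      tp_stop("could not place particles with the requested separation",
              "tomopick_value_error")
    cand <- stats::runif(3, rep(margin, 3), extent - margin)
    if (nrow(pos) > 0 &&
        min(sqrt(rowSums(sweep(pos, 2, cand)^2))) < spec$min_separation) next
    if (!is.null(memb_centers) &&
        min(sqrt(rowSums(sweep(memb_centers, 2, cand)^2))) < clearance) next
    pos <- rbind(pos, cand)
  }
  colnames(pos) <- c("x", "y", "z")
  # density: solid spheres + membrane + noise, dense = bright
  gt_picks <- pick_set("particle", "reference", "0", pos)
  psph <- picks_to_segmentation(gt_picks, d, s, radius = spec$particle_radius)
  tomo <- array(stats::rnorm(prod(d), sd = spec$noise_sigma), d)
  tomo <- tomo + (psph$mask != 0) + (memb != 0)
  run <- "run001"
  # static layer content, written through a writable handle before the
  # project opens it read-only
  sb <- local_backend(static_root)
  vol <- multiscale_volume(tomo, s, role = "tomogram")
  write_ome_zarr(vol, sb, entity_key(run, "tomogram", spacing = s, name = "wbp"))
  tmp <- tempfile()
  write_picks(gt_picks, tmp)
  sb$write(entity_key(run, "picks", "particle", "reference", "0"),
           readBin(tmp, "raw", file.info(tmp)$size))
  unlink(tmp)
  if (!is.null(memb_centers)) {
    mvol <- multiscale_volume(memb, s, role = "segmentation")
    write_ome_zarr(mvol, sb,
                   entity_key(run, "segmentation", "membrane", "reference", "0",
                              spacing = s))
  }
  objects <- list(
    pickable_object("particle", label = 1L, is_particle = TRUE,
                    color = c(0L, 117L, 220L, 255L),
                    radius = spec$particle_radius),
    pickable_object("membrane", label = 2L, is_particle = FALSE,
                    color = c(153L, 221L, 136L, 255L))
  )
  project <- new_project(
    name = "toy-project",
    description = "synthetic fixture with known ground truth",
    objects = objects,
    layers = list(list(uri = static_root, mode = "static"),
                  list(uri = overlay_root, mode = "mutable")))
  config_path <- file.path(dest, "config.json")
  write_config(project, config_path)
  gt_dist <- if (!is.null(memb_centers))
    point_cloud_min_distance(pos, memb_centers) else rep(Inf, nrow(pos))
  list(project = project,
       config_path = config_path,
       run = run,
       ground_truth = list(
         positions = pos,
         membrane = segmentation(memb, s, object = "membrane", label = 2L),
         membrane_distances = as.numeric(gt_dist)))
}
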