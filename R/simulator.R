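#' Pseudo-atomic bead model
#'
#' A molecule surrogate: a mixture of isotropic 3D Gaussians ("beads") with
#' per-bead amplitude and width. Real atomic coordinates can be loaded from
#' CSV with [read_bead_csv()].
#'
#' @param coords K x 3 matrix of bead centers, Angstrom.
#' @param amplitude Per-bead amplitude (recycled).
#' @param width Per-bead Gaussian standard deviation in Angstrom
#'   (recycled, > 0).
#' @return A `cf_beads` object.
#' @export
bead_model <- function(coords, amplitude = 1, width = 2) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) >= 1)
  amplitude <- rep_len(amplitude, nrow(coords))
  width <- rep_len(width, nrow(coords))
  if (any(width <= 0)) stop("bead widths must be positive")
  structure(list(coords = coords, amplitude = amplitude, width = width),
            class = "cf_beads")
}

#' Load a bead model from CSV
#'
#' Expects columns `x, y, z` and optionally `amplitude`, `width`.
#'
#' @param path CSV file path.
#' @param amplitude,width Defaults used when the file lacks the columns.
#' @return A `cf_beads` object.
#' @export
read_bead_csv <- function(path, amplitude = 1, width = 2) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "z") %in% colnames(df)))
  bead_model(as.matrix(df[, c("x", "y", "z")]),
             amplitude = if ("amplitude" %in% colnames(df)) df$amplitude else amplitude,
             width = if ("width" %in% colnames(df)) df$width else width)
}

#' Random compact bead model
#'
#' The default synthetic fixture: beads scattered in a compact blob (a
#' Gaussian cloud truncated to a sphere) occupying roughly the central
#' half of the box.
#'
#' @param n_beads Number of beads.
#' @param radius Cloud radius in Angstrom.
#' @param amplitude,width Per-bead amplitude and width.
#' @param seed Integer seed.
#' @return A `cf_beads` object.
#' @export
random_bead_model <- function(n_beads = 24, radius = 10, amplitude = 1,
                              width = 2, seed = 1) {
  set.seed(seed)
  pts <- matrix(stats::rnorm(3 * n_beads * 4, 0, radius / 2), ncol = 3)
  pts <- pts[sqrt(rowSums(pts^2)) <= radius, , drop = FALSE]
  while (nrow(pts) < n_beads) {
    extra <- matrix(stats::rnorm(3 * n_beads, 0, radius / 2), ncol = 3)
    pts <- rbind(pts, extra[sqrt(rowSums(extra^2)) <= radius, , drop = FALSE])
  }
  bead_model(pts[seq_len(n_beads), , drop = FALSE], amplitude, width)
}

#' Two-state heterogeneity fixture
#'
#' State A is a two-cluster bead model; state B is identical except one
#' cluster is rigidly rotated about its centroid and translated, emulating
#' a discrete domain motion.
#'
#' @param n_beads Beads per cluster.
#' @param separation Distance between cluster centroids, Angstrom.
#' @param radius Cluster radius, Angstrom.
#' @param angle Rotation of the mobile cluster in state B, degrees
#'   (about the z axis through the cluster centroid; the default 60
#'   degrees with a 6 Angstrom shift is a large discrete hinge motion of
#'   the kind coarse-grained two-state benchmarks exhibit, leaving the
#'   state volumes correlated at roughly 0.6).
#' @param shift Translation of the mobile cluster in state B, Angstrom
#'   (applied along +y).
#' @param amplitude,width Bead parameters.
#' @param seed Integer seed.
#' @return List with `cf_beads` elements `A` and `B`.
#' @export
two_state_bead_model <- function(n_beads = 12, separation = 12, radius = 4.5,
                                 angle = 60, shift = 6, amplitude = 1,
                                 width = 2, seed = 1) {
  fixed <- random_bead_model(n_beads, radius, amplitude, width, seed = seed)
  mobile <- random_bead_model(n_beads, radius, amplitude, width,
                              seed = seed + 1)
  fixed$coords <- sweep(fixed$coords, 2, c(-separation / 2, 0, 0), "+")
  mobile$coords <- sweep(mobile$coords, 2, c(separation / 2, 0, 0), "+")
  A <- bead_model(rbind(fixed$coords, mobile$coords),
                  c(fixed$amplitude, mobile$amplitude),
                  c(fixed$width, mobile$width))
  cen <- colMeans(mobile$coords)
  a <- angle * pi / 180
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  moved <- sweep(sweep(mobile$coords, 2, cen) %*% t(Rz), 2,
                 cen + c(0, shift, 0), "+")
  B <- bead_model(rbind(fixed$coords, moved),
                  c(fixed$amplitude, mobile$amplitude),
                  c(fixed$width, mobile$width))
  list(A = A, B = B)
}

#' Analytic Gaussian-mixture density on a voxel lattice
#'
#' Evaluates the sum of isotropic 3D Gaussians at the centers of an `n^3`
#' lattice (no fitting; the separable Gaussian factors are combined per
#' bead).
#'
#' @param model A `cf_beads`.
#' @param n Per-axis voxel count.
#' @param pixel_size Voxel size in Angstrom.
#' @return `n^3` numeric array.
#' @export
density_from_beads <- function(model, n, pixel_size) {
  stopifnot(inherits(model, "cf_beads"))
  ax <- (seq_len(n) - 1 - n / 2 + 0.5) * pixel_size
  vol <- array(0, dim = c(n, n, n))
  for (k in seq_len(nrow(model$coords))) {
    w <- model$width[k]
    gx <- exp(-(ax - model$coords[k, 1])^2 / (2 * w^2))
    gy <- exp(-(ax - model$coords[k, 2])^2 / (2 * w^2))
    gz <- exp(-(ax - model$coords[k, 3])^2 / (2 * w^2))
    vol <- vol + model$amplitude[k] * (gx %o% gy %o% gz)
  }
  vol
}

#' Simulation configuration
#'
#' Defines the synthetic-data conditions: box and pixel size, per-pixel
#' Gaussian white-noise level (`sigma = 3` is the homogeneous operating
#' point giving the SNR 0.05 regime after amplitude calibration;
#' `sigma = 0.1` the high-signal heterogeneity regime), particle count,
#' depth samples, uniform (Haar) pose sampling with optional in-plane
#' translations, and CTF parameter ranges with realistic defocus spread.
#'
#' @param n Box size in pixels (even).
#' @param pixel_size Pixel size in Angstrom.
#' @param n_particles Number of particles.
#' @param sigma Noise standard deviation.
#' @param n_z Depth samples of the rendering grid.
#' @param defocus_range Uniform defocus sampling range (Angstrom).
#' @param astigmatism_max Max defocus difference dU - dV (Angstrom).
#' @param voltage,cs,amplitude_contrast Microscope constants.
#' @param translation_max Max |t_x|, |t_y| (Angstrom, uniform; default 0).
#' @param seed Integer seed.
#' @return A `cf_sim_config`.
#' @export
sim_config <- function(n, pixel_size = 1, n_particles = 100, sigma = 3,
                       n_z = 32, defocus_range = c(8000, 25000),
                       astigmatism_max = 500, voltage = 300, cs = 2.7,
                       amplitude_contrast = 0.1, translation_max = 0,
                       seed = 1) {
  if (n %% 2 != 0) stop("`n` must be even")
  if (n_particles < 1) stop("`n_particles` must be >= 1")
  structure(list(n = as.integer(n), pixel_size = pixel_size,
                 n_particles = as.integer(n_particles), sigma = sigma,
                 n_z = as.integer(n_z), defocus_range = defocus_range,
                 astigmatism_max = astigmatism_max, voltage = voltage,
                 cs = cs, amplitude_contrast = amplitude_contrast,
                 translation_max = translation_max, seed = seed),
            class = "cf_sim_config")
}

# Haar-uniform rotation via normalized quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Simulate a particle stack
#'
#' For each particle: a pose is drawn Haar-uniformly over SO(3) (plus an
#' optional uniform in-plane translation), CTF parameters are drawn from
#' the configured ranges, the clean projection of the (state-specific)
#' ground-truth density is rendered through the same forward model used in
#' training (the density wrapped as a voxel field; no trainable
#' parameters), the CTF is applied, and i.i.d. N(0, sigma^2) pixel noise is
#' added.
#'
#' @param model A `cf_beads`, or a list of two for discrete two-state
#'   heterogeneity (states assigned half/half).
#' @param config A `cf_sim_config`.
#' @return A `cf_particles` object: `images` (n x n x N array), `clean`
#'   (noise-free images), `poses`, `ctfs` (lists), `states` (0-based
#'   integer), `gt_volumes` (list of ground-truth arrays), `config`.
#' @export
simulate_particles <- function(model, config) {
  stopifnot(inherits(config, "cf_sim_config"))
  models <- if (inherits(model, "cf_beads")) list(model) else model
  set.seed(config$seed)
  n <- config$n
  vols <- lapply(models, density_from_beads, n = n,
                 pixel_size = config$pixel_size)
  extent <- n * config$pixel_size
  fields <- lapply(vols, function(v) field_voxel(extent, n, v))
  grid <- build_grid(n, config$pixel_size, config$n_z)
  proj <- build_projection_map(grid)

  N <- config$n_particles
  images <- array(0, dim = c(n, n, N))
  clean <- array(0, dim = c(n, n, N))
  poses <- vector("list", N)
  ctfs <- vector("list", N)
  states <- if (length(models) > 1) {
    rep(seq_along(models) - 1L, length.out = N)[sample.int(N)]
  } else rep(0L, N)

  for (i in seq_len(N)) {
    R <- random_rotation()
    tx <- ty <- 0
    if (config$translation_max > 0) {
      tx <- stats::runif(1, -config$translation_max, config$translation_max)
      ty <- stats::runif(1, -config$translation_max, config$translation_max)
    }
    poses[[i]] <- pose(R, tx, ty)
    du <- stats::runif(1, config$defocus_range[1], config$defocus_range[2])
    dv <- du - stats::runif(1, 0, config$astigmatism_max)
    ang <- stats::runif(1, 0, 180)
    ctfs[[i]] <- imaging_params(voltage = config$voltage, cs = config$cs,
                                amplitude_contrast = config$amplitude_contrast,
                                defocus_u = du, defocus_v = dv,
                                astigmatism_angle = ang,
                                pixel_size = config$pixel_size)
    img <- render_particle(fields[[states[i] + 1L]], grid, poses[[i]],
                           ctf = ctfs[[i]], proj = proj)
    clean[, , i] <- img
    images[, , i] <- img +
      matrix(stats::rnorm(n * n, 0, config$sigma), n, n)
  }
  structure(list(images = images, clean = clean, poses = poses, ctfs = ctfs,
                 states = states, gt_volumes = vols, config = config),
            class = "cf_particles")
}

#' @export
print.cf_particles <- function(x, ...) {
  cat(sprintf("<cf_particles> %d images of %d x %d px, sigma = %g, %d state(s)\n",
              dim(x$images)[3], dim(x$images)[1], dim(x$images)[2],
              x$config$sigma, length(x$gt_volumes)))
  invisible(x)
}

#' Signal-to-noise ratio of simulated particles
#'
#' Per-image SNR is the variance of the clean (noise-free) pixel signal
#' over the noise variance `sigma^2`; the summary is the mean and standard
#' deviation over images (before any expectation over images).
#'
#' @param clean n x n x N array of clean images (e.g. `$clean` from
#'   [simulate_particles()]).
#' @param sigma Noise standard deviation (> 0).
#' @return List with `per_image` (length-N vector), `mean`, `sd`.
#' @export
snr <- function(clean, sigma) {
  if (sigma <= 0) stop("`sigma` must be positive")
  if (is.matrix(clean)) clean <- array(clean, dim = c(dim(clean), 1))
  per <- apply(clean, 3, function(im) mean((im - mean(im))^2)) / sigma^2
  list(per_image = per, mean = mean(per), sd = stats::sd(per))
}

#' Calibrate bead amplitude to a target SNR
#'
#' Clean images scale linearly with the bead amplitude, so their variance
#' scales quadratically; one small pilot simulation gives the closed-form
#' rescaling that hits the target mean SNR at the configured noise level.
#'
#' @param model A `cf_beads`.
#' @param config A `cf_sim_config`.
#' @param target_snr Target mean SNR (default 0.05, the sigma = 3
#'   operating point).
#' @param n_pilot Pilot particles used to estimate the current signal
#'   variance (default 20).
#' @return The model with rescaled amplitudes.
#' @export
calibrate_bead_amplitude <- function(model, config, target_snr = 0.05,
                                     n_pilot = 20) {
  pilot <- config
  pilot$n_particles <- as.integer(n_pilot)
  sim <- simulate_particles(model, pilot)
  cur <- snr(sim$clean, config$sigma)$mean
  if (cur <= 0) stop("pilot images carry no signal")
  model$amplitude <- model$amplitude * sqrt(target_snr / cur)
  model
}

#' Write a particle stack and its metadata
#'
#' Emits `<basename>.mrcs` (the image stack) and `<basename>.star`
#' (RELION-dialect metadata: ZYZ Euler angles in degrees, origin shifts in
#' Angstrom, standard CTF labels, plus a state-label column), and
#' optionally the ground-truth volumes as `<basename>_state<k>.mrc`.
#'
#' @param particles A `cf_particles`.
#' @param dir Output directory (created if needed).
#' @param basename File basename (default "particles").
#' @param write_volumes Also write ground-truth state volumes
#'   (default TRUE).
#' @return Named list of written paths, invisibly.
#' @export
write_particles <- function(particles, dir, basename = "particles",
                            write_volumes = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ps <- particles$config$pixel_size
  mrcs <- file.path(dir, paste0(basename, ".mrcs"))
  write_mrc(particles$images, mrcs, pixel_size = ps, is_stack = TRUE)
  N <- dim(particles$images)[3]
  eul <- t(vapply(particles$poses, pose_to_euler, numeric(3)))
  df <- data.frame(
    rlnImageName = sprintf("%06d@%s", seq_len(N), paste0(basename, ".mrcs")),
    rlnAngleRot = eul[, 1], rlnAngleTilt = eul[, 2], rlnAnglePsi = eul[, 3],
    rlnOriginXAngst = vapply(particles$poses, function(p) p$t_x, 0),
    rlnOriginYAngst = vapply(particles$poses, function(p) p$t_y, 0),
    rlnDefocusU = vapply(particles$ctfs, function(c) c$defocus_u, 0),
    rlnDefocusV = vapply(particles$ctfs, function(c) c$defocus_v, 0),
    rlnDefocusAngle = vapply(particles$ctfs, function(c) c$astigmatism_angle, 0),
    rlnVoltage = vapply(particles$ctfs, function(c) c$voltage, 0),
    rlnSphericalAberration = vapply(particles$ctfs, function(c) c$cs, 0),
    rlnAmplitudeContrast = vapply(particles$ctfs, function(c) c$amplitude_contrast, 0),
    rlnPhaseShift = vapply(particles$ctfs, function(c) c$phase_shift, 0),
    rlnImagePixelSize = rep(ps, N),
    cfStateLabel = particles$states)
  star <- file.path(dir, paste0(basename, ".star"))
  write_star(df, star)
  out <- list(mrcs = mrcs, star = star)
  if (write_volumes) {
    for (k in seq_along(particles$gt_volumes)) {
      p <- file.path(dir, sprintf("%s_state%d.mrc", basename, k - 1))
      write_mrc(particles$gt_volumes[[k]], p, pixel_size = ps)
      out[[sprintf("volume%d", k - 1)]] <- p
    }
  }
  invisible(out)
}

#' Read a particle stack from STAR + MRCS files
#'
#' @param star_path STAR metadata path (as written by
#'   [write_particles()] or RELION-style tools).
#' @param mrcs_path Image stack path; defaults to the `rlnImageName`
#'   reference resolved relative to the STAR file's directory.
#' @return A `cf_particles` object (without `clean` or `gt_volumes`).
#' @export
read_particles <- function(star_path, mrcs_path = NULL) {
  df <- read_star(star_path)
  need <- c("rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi", "rlnDefocusU",
            "rlnDefocusV", "rlnVoltage", "rlnSphericalAberration",
            "rlnAmplitudeContrast")
  missing <- setdiff(need, colnames(df))
  if (length(missing) > 0)
    stop("STAR file lacks required labels: ", paste(missing, collapse = ", "))
  if (is.null(mrcs_path)) {
    ref <- sub("^\\d+@", "", df$rlnImageName[1])
    mrcs_path <- file.path(dirname(star_path), ref)
  }
  m <- read_mrc(mrcs_path)
  N <- nrow(df)
  gv <- function(col, default) if (col %in% colnames(df)) df[[col]] else rep(default, N)
  tx <- gv("rlnOriginXAngst", 0); ty <- gv("rlnOriginYAngst", 0)
  dang <- gv("rlnDefocusAngle", 0); phs <- gv("rlnPhaseShift", 0)
  ps <- if ("rlnImagePixelSize" %in% colnames(df)) df$rlnImagePixelSize[1] else m$pixel_size
  poses <- lapply(seq_len(N), function(i)
    pose_from_euler(df$rlnAngleRot[i], df$rlnAngleTilt[i], df$rlnAnglePsi[i],
                    tx[i], ty[i]))
  ctfs <- lapply(seq_len(N), function(i)
    imaging_params(voltage = df$rlnVoltage[i],
                   cs = df$rlnSphericalAberration[i],
                   amplitude_contrast = df$rlnAmplitudeContrast[i],
                   defocus_u = df$rlnDefocusU[i], defocus_v = df$rlnDefocusV[i],
                   astigmatism_angle = dang[i], phase_shift = phs[i],
                   pixel_size = ps))
  states <- if ("cfStateLabel" %in% colnames(df)) as.integer(df$cfStateLabel)
            else rep(0L, N)
  structure(list(images = m$data, clean = NULL, poses = poses, ctfs = ctfs,
                 states = states, gt_volumes = NULL,
                 config = sim_config(n = dim(m$data)[1], pixel_size = ps,
                                     n_particles = N)),
            class = "cf_particles")
}
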