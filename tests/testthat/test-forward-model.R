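test_that("projection map has one-hot columns and n_z-hot rows", {
  g <- build_grid(2, 1.0, 3)
  pm <- build_projection_map(g)
  expect_equal(dim(pm$M), c(4, 12))
  expect_true(all(Matrix::colSums(pm$M) == 1))
  expect_true(all(Matrix::rowSums(pm$M) == 3))

  g1 <- build_grid(3, 1.0, 1)
  pm1 <- build_projection_map(g1)
  expect_true(all(Matrix::rowSums(pm1$M) == 1))  # permutation-like

  # masking drops matching columns: keep a single z-column of points
  g2 <- build_grid(2, 1.0, 3)
  keep <- g2$index_map[, 1] == 1 & g2$index_map[, 2] == 0
  g2$points <- g2$points[keep, , drop = FALSE]
  g2$index_map <- g2$index_map[keep, , drop = FALSE]
  pm2 <- build_projection_map(g2)
  rs <- Matrix::rowSums(pm2$M)
  expect_equal(rs[[2]], 3)  # pixel (a=1, b=0) -> row 2
  expect_equal(sum(rs), 3)
})

test_that("projection equals dense z-summation and conserves mass", {
  set.seed(3)
  for (nz in c(1, 4)) {
    g <- build_grid(4, 1.0, nz)
    pm <- build_projection_map(g)
    dens <- rnorm(nrow(g$points))
    img <- project_densities(dens, pm)
    expect_equal(img, dense_projection_oracle(g, dens), tolerance = 1e-12)
    expect_equal(sum(img), sum(dens))
  }

  g <- build_grid(3, 1.0, 2)
  pm <- build_projection_map(g)
  expect_true(all(project_densities(rep(1, 18), pm) == 2))

  dens <- rep(0, 18)
  k <- which(g$index_map[, 1] == 2 & g$index_map[, 2] == 1 &
               g$index_map[, 3] == 0)
  dens[k] <- 5
  img <- project_densities(dens, pm)
  expect_equal(img[3, 2], 5)
  expect_equal(sum(img != 0), 1L)

  expect_error(project_densities(rep(1, 5), pm), "expected")
})

test_that("CTF reduces to the identity filter in the A = 1, chi = pi limit", {
  ctf <- imaging_params(defocus_u = 0, cs = 0, amplitude_contrast = 1,
                        phase_shift = 180, pixel_size = 1)
  H <- ctf_evaluate(ctf, 8)
  expect_equal(H, matrix(1, 8, 8), tolerance = 1e-12)
  img <- matrix(rnorm(64), 8, 8)
  expect_equal(apply_ctf(img, ctf), img, tolerance = 1e-6)
})

test_that("CTF application is linear and matches the analytic curve", {
  ctf <- imaging_params(defocus_u = 15000, defocus_v = 13000,
                        astigmatism_angle = 30, pixel_size = 1.2)
  set.seed(8)
  x <- matrix(rnorm(256), 16, 16)
  y <- matrix(rnorm(256), 16, 16)
  lhs <- apply_ctf(2 * x + 3 * y, ctf)
  rhs <- 2 * apply_ctf(x, ctf) + 3 * apply_ctf(y, ctf)
  expect_equal(lhs, rhs, tolerance = 1e-6)

  # delta image -> PSF whose spectrum is the analytic CTF (odd box:
  # every lattice frequency has its conjugate mirror on the lattice)
  delta <- matrix(0, 15, 15); delta[1, 1] <- 1
  psf <- apply_ctf(delta, ctf)
  expect_equal(Re(stats::fft(psf)), ctf_evaluate(ctf, 15), tolerance = 1e-6)

  expect_error(apply_ctf(matrix(0, 2, 3), ctf), "square")
})

test_that("CTF operator is self-adjoint on the image space", {
  ctf <- imaging_params(defocus_u = 18000, pixel_size = 1)
  set.seed(12)
  a <- matrix(rnorm(64), 8, 8)
  b <- matrix(rnorm(64), 8, 8)
  expect_equal(sum(apply_ctf(a, ctf) * b), sum(a * apply_ctf(b, ctf)),
               tolerance = 1e-8)
})

test_that("render_particle composes the pipeline correctly", {
  n <- 8; ps <- 1.5
  g <- build_grid(n, ps, 4)

  zero <- field_function(function(p) rep(0, nrow(p)), extent = n * ps)
  expect_true(all(render_particle(zero, g, pose()) == 0))

  # identity pose, no CTF, voxel field at the grid's own z-sampling:
  # the image is the z-sum of the interpolated voxel values
  set.seed(5)
  vox <- field_voxel(extent = n * ps, n_voxels = n,
                     data = array(rnorm(n^3), c(n, n, n)))
  img <- render_particle(vox, g, pose())
  dens <- query_field(vox, g$points)
  expect_equal(img, dense_projection_oracle(g, dens), tolerance = 1e-12)

  # with n_z = n the voxel field is sampled at its own nodes: exact z-sum
  g8 <- build_grid(n, ps, n)
  img8 <- render_particle(vox, g8, pose())
  expect_equal(img8, apply(vox$vol, c(1, 2), sum), tolerance = 1e-10)

  # jitter renders are seed-deterministic
  blob <- field_function(function(p) exp(-rowSums(p^2) / 8), extent = n * ps)
  r1 <- render_particle(blob, g, pose(), J = 1, jitter_seed = 3)
  r2 <- render_particle(blob, g, pose(), J = 1, jitter_seed = 3)
  r3 <- render_particle(blob, g, pose(), J = 1, jitter_seed = 4)
  expect_identical(r1, r2)
  expect_false(identical(r1, r3))
})

test_that("spherically symmetric fields render pose-invariantly", {
  n <- 8; ps <- 2
  g <- build_grid(n, ps, 8)
  blob <- field_function(function(p) exp(-rowSums(p^2) / 18), extent = n * ps)
  ref <- render_particle(blob, g, pose())
  set.seed(21)
  for (i in 1:3) {
    p <- pose_from_euler(runif(1, 0, 360), runif(1, 0, 180), runif(1, 0, 360))
    expect_equal(render_particle(blob, g, p), ref, tolerance = 1e-4)
  }
})

test_that("positive translations shift image content positively", {
  n <- 12; ps <- 2
  g <- build_grid(n, ps, 6)
  blob <- field_function(function(p)
    exp(-rowSums(sweep(p, 2, c(2, -3, 1))^2) / 6), extent = n * ps)
  base <- render_particle(blob, g, pose())
  shifted <- render_particle(blob, g, pose(diag(3), t_x = 2 * ps))
  # content moves +2 pixels along x
  expect_equal(shifted[3:n, ], base[1:(n - 2), ], tolerance = 1e-10)
})

test_that("average of jittered renders approximates the top-hat convolution", {
  # 1D check through the full jitter machinery: Gaussian profile along x
  w <- 1.2; J <- 2.0
  f <- function(p) exp(-p[, 1]^2 / (2 * w^2))
  xs <- seq(-4, 4, length.out = 33)
  pts <- cbind(xs, 0, 0)
  set.seed(31)
  M <- 2000
  acc <- numeric(length(xs))
  for (m in 1:M) acc <- acc + f(jitter_points(pts, J))
  avg <- acc / M
  tophat <- (w * sqrt(2 * pi) / J) *
    (pnorm((xs + J / 2) / w) - pnorm((xs - J / 2) / w))
  # per-point MC sd is bounded by the signal range (<= 1): allow 6 sigma
  expect_lt(max(abs(avg - tophat)), 6 * 0.5 / sqrt(M))
})

test_that("end-to-end gradients agree with finite differences", {
  set.seed(1)
  n <- 8; ps <- 2
  g <- build_grid(n, ps, 4)
  proj <- build_projection_map(g)
  f <- field_hashgrid(extent = n * ps,
                      hash_grid_config(L = 2, log2_hashmap_size = 6,
                                       base_resolution = 4,
                                       finest_resolution = 8, mlp_hidden = 8),
                      seed = 5)
  # give the tables trained-scale magnitudes so ReLU pre-activations sit
  # well away from their kinks (finite differences are clean there)
  pr <- cryofield:::field_params(f)
  for (nm in grep("^table", names(pr), value = TRUE))
    pr[[nm]][] <- rnorm(length(pr[[nm]]), sd = 0.3)
  f <- cryofield:::field_set_params(f, pr)
  p <- pose_from_euler(10, 30, 50)
  H <- ctf_evaluate(imaging_params(defocus_u = 10000, pixel_size = ps), n)
  y <- matrix(rnorm(n * n), n)
  fwd <- function(field)
    loss_mse(y, render_particle(field, g, p, ctf = H, proj = proj), 1)

  pts <- pose_grid(g, p)
  u <- cryofield:::normalize_points(pts, f$extent)
  fw <- cryofield:::field_forward(f, u)
  pred <- apply_ctf(project_densities(fw$y, proj), H)
  lg <- cryofield:::loss_mse_grad(y, pred, 1)
  dd <- cryofield:::project_backward(apply_ctf(lg$grad, H), proj)
  bw <- cryofield:::field_backward(f, fw$cache, dd, want_posgrad = TRUE)

  params <- cryofield:::field_params(f)
  # directional derivative along the analytic gradient: the cleanest
  # aggregate finite-difference check of every parameter at once
  gnorm2 <- sum(vapply(bw$grads, function(g) sum(g^2), 0))
  eps <- 1e-7 / sqrt(gnorm2)
  shift <- function(s) {
    pp <- params
    for (nm in names(pp)) pp[[nm]] <- pp[[nm]] + s * bw$grads[[nm]]
    fwd(cryofield:::field_set_params(f, pp))
  }
  fd_dir <- (shift(eps) - shift(-eps)) / (2 * eps)
  expect_equal(fd_dir, gnorm2, tolerance = 1e-4)

  # spot checks on individual coordinates
  for (probe in list(c("table1", 5), c("W2", 7), c("b3", 1))) {
    nm <- probe[1]; i <- as.integer(probe[2])
    h <- 1e-6
    pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
    up <- fwd(cryofield:::field_set_params(f, pp))
    pp[[nm]][i] <- params[[nm]][i] - h
    dn <- fwd(cryofield:::field_set_params(f, pp))
    fd <- (up - dn) / (2 * h)
    an <- bw$grads[[nm]][i]
    expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-3), 1e-3)
  }

  # position gradients (used by the heterogeneity bend)
  k <- 17
  for (ax in 1:3) {
    eps <- 1e-6
    u1 <- u; u1[k, ax] <- u1[k, ax] + eps
    u2 <- u; u2[k, ax] <- u2[k, ax] - eps
    l1 <- sum(dd * cryofield:::field_forward(f, u1)$y)
    l2 <- sum(dd * cryofield:::field_forward(f, u2)$y)
    fd <- (l1 - l2) / (2 * eps)
    expect_equal(bw$du[k, ax], fd, tolerance = 1e-4)
  }
})
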