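test_that("build_grid lays out centered pixel-matched lattices", {
  g <- build_grid(100, 1.0, 64)
  expect_equal(nrow(g$points), 100 * 100 * 64)

  g2 <- build_grid(2, 1.0, 1)
  expect_equal(nrow(g2$points), 4L)
  expect_true(all(g2$points[, 3] == 0))
  expect_equal(sort(unique(g2$points[, 1])), c(-0.5, 0.5))
  expect_equal(colSums(g2$points), c(x = 0, y = 0, z = 0))

  # hand-enumerated 4 x 4 x 2 lattice at 2 A pixels
  g3 <- build_grid(4, 2.0, 2)
  expect_equal(nrow(g3$points), 32L)
  expect_equal(diff(range(g3$points[, 1])), 6.0)       # point extent in x
  expect_equal(g3$spacing_z, g3$extent / 2)             # z covers the box
  expect_equal(sort(unique(g3$points[, 3])), c(-2, 2))
  expect_equal(sort(unique(g3$points[, 1])), c(-3, -1, 1, 3))

  expect_error(build_grid(1, 1, 4), "n_pixels")
  expect_error(build_grid(8, -1, 4), "pixel_size")
  expect_error(build_grid(8, 1, 0), "n_z")
})

test_that("grid z extent always matches x extent", {
  for (nz in c(1, 2, 8, 33)) {
    g <- build_grid(10, 1.3, nz)
    expect_equal(g$spacing_z * g$n_z, g$extent)
  }
})

test_that("pose validation rejects non-rotations", {
  expect_error(pose(matrix(1, 3, 3)), "orthogonal")
  expect_error(pose(diag(c(1, 1, -1))), "determinant")
  p <- pose(diag(3), 1, 2)
  expect_equal(p$t_x, 1)
})

test_that("pose_grid applies R^-1 p + (-t, 0)", {
  g <- build_grid(4, 1.0, 2)

  expect_equal(pose_grid(g, pose()), g$points, ignore_attr = TRUE)

  # rotation by pi about z maps (x, y, z) -> (-x, -y, z)
  Rz <- matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3)
  flipped <- pose_grid(g, pose(Rz))
  expect_equal(flipped[, 1], -g$points[, 1])
  expect_equal(flipped[, 2], -g$points[, 2])
  expect_equal(flipped[, 3], g$points[, 3])

  # hand matrix algebra: 90 deg about z, t = (1, 0), point (1, 0, 0)
  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  gp <- g
  gp$points <- matrix(c(1, 0, 0), 1, 3)
  got <- pose_grid(gp, pose(R90, t_x = 1))
  expected <- as.numeric(t(R90) %*% c(1, 0, 0) + c(-1, 0, 0))
  expect_equal(as.numeric(got), expected, tolerance = 1e-12)

  # index map is pose-independent
  expect_identical(g$index_map, g$index_map)
})

test_that("pose composition matches multiplied rotations", {
  set.seed(1)
  g <- build_grid(4, 1.0, 3)
  for (i in 1:5) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R1 <- pose_from_euler(runif(1, 0, 360), runif(1, 0, 180),
                          runif(1, 0, 360))$R
    R2 <- pose_from_euler(runif(1, 0, 360), runif(1, 0, 180),
                          runif(1, 0, 360))$R
    two_step <- pose_grid(g, pose(R1))
    gtmp <- g
    gtmp$points <- two_step
    two_step <- pose_grid(gtmp, pose(R2))
    combined <- pose_grid(g, pose(R1 %*% R2))
    expect_lt(max(abs(two_step - combined)), 1e-10)
  }
})

test_that("euler angles round-trip through the rotation matrix", {
  set.seed(7)
  for (i in 1:10) {
    p <- pose_from_euler(runif(1, -180, 180), runif(1, 1, 179),
                         runif(1, -180, 180))
    e <- pose_to_euler(p)
    p2 <- pose_from_euler(e["rot"], e["tilt"], e["psi"])
    expect_lt(max(abs(p$R - p2$R)), 1e-10)
  }
})

test_that("jitter has Uniform(-J/2, J/2) moments and is seed-deterministic", {
  pts <- matrix(0, 4e5, 3)
  j1 <- jitter_points(pts, J = 1, seed = 99)
  expect_lt(max(abs(colMeans(j1))), 3 * sqrt(1 / 12 / 4e5))
  expect_equal(apply(j1, 2, var), rep(1 / 12, 3), tolerance = 0.02)
  expect_true(all(abs(j1) <= 0.5))

  expect_identical(j1, jitter_points(pts, J = 1, seed = 99))
  expect_false(identical(j1, jitter_points(pts, J = 1, seed = 100)))

  p <- matrix(rnorm(30), 10, 3)
  expect_identical(jitter_points(p, 0), p)
  expect_error(jitter_points(p, -1), "J")
})

test_that("jittered means converge to the point at the MC rate", {
  p <- matrix(c(1, 2, 3), 1, 3)
  J <- 2
  for (N in c(100, 10000)) {
    reps <- jitter_points(p[rep(1, N), , drop = FALSE], J, seed = N)
    err <- abs(colMeans(reps) - as.numeric(p))
    expect_lt(max(err), 5 * (J / sqrt(12)) / sqrt(N))
  }
})

test_that("mask subsetting keeps points above cutoff and is idempotent", {
  g <- build_grid(4, 1.0, 4)

  ones <- mask_volume(array(1, c(4, 4, 4)), spacing = 1, cutoff = 0)
  kept <- subset_by_mask(g, ones)
  expect_equal(nrow(kept$points), nrow(g$points))

  zeros <- array(0, c(4, 4, 4))
  expect_error(mask_volume(zeros - 1, 1), "non-negative")
  expect_error(subset_by_mask(g, mask_volume(zeros, 1)), "cutoff")

  # spherical soft mask versus brute-force interpolation check
  ax <- (0:3 - 2 + 0.5) * 1.0
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  sphere <- mask_volume(array(as.numeric(r2 <= 1.6), c(4, 4, 4)),
                        spacing = 1, cutoff = 0)
  sub <- subset_by_mask(g, sphere)
  vals <- interpolate_mask(sphere, g$points)
  expect_equal(nrow(sub$points), sum(vals > 0))
  expect_true(all(sub$kept %in% seq_len(nrow(g$points))))

  again <- subset_by_mask(sub, sphere)
  expect_equal(again$kept, sub$kept)
  expect_equal(again$points, sub$points)
})
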