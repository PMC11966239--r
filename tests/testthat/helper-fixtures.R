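# Shared fixtures, built in code at test time.

# small Gaussian-blob phantom and matching clean particle set
make_tiny_sim <- function(n = 16, ps = 1.5, n_particles = 10, sigma = 0,
                          n_z = 8, seed = 42, translation_max = 0) {
  beads <- random_bead_model(8, radius = n * ps / 5, width = 2, seed = seed)
  cfg <- sim_config(n, ps, n_particles = n_particles, sigma = sigma,
                    n_z = n_z, seed = seed,
                    translation_max = translation_max)
  simulate_particles(beads, cfg)
}

# independent R-side trilinear interpolation oracle on a (n,n,n) array with
# voxel centers at (i + 0.5)/n in normalized coordinates; zero outside.
trilinear_oracle <- function(vol, u) {
  n <- dim(vol)[1]
  vapply(seq_len(nrow(u)), function(k) {
    p <- u[k, ] * n - 0.5
    i0 <- floor(p)
    f <- p - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ii <- i0 + c(dx, dy, dz)
      if (any(ii < 0) || any(ii >= n)) next
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      acc <- acc + w * vol[ii[1] + 1, ii[2] + 1, ii[3] + 1]
    }
    acc
  }, 0)
}

# dense z-summation oracle for the sparse projection
dense_projection_oracle <- function(grid, densities) {
  n <- grid$n_x
  img <- matrix(0, n, n)
  for (k in seq_len(nrow(grid$index_map))) {
    a <- grid$index_map[k, 1] + 1
    b <- grid$index_map[k, 2] + 1
    img[a, b] <- img[a, b] + densities[k]
  }
  img
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(max(abs(y)), 1e-12), tol)
}
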