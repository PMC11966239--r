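test_that("hash encoding interpolates stored features trilinearly", {
  cfgl <- hash_grid_config(L = 1, F = 2, log2_hashmap_size = 10,
                           base_resolution = 4, finest_resolution = 4)
  f <- field_hashgrid(extent = 1, cfgl, seed = 3)
  tab <- f$tables[[1]]  # dense: (4+1)^3 = 125 rows <= 1024
  enc <- function(u) cryofield:::cpp_hash_encode(u, f$resolutions, f$tables)

  # exactly on a lattice corner: the stored row comes back
  corner <- c(2, 3, 1)
  u <- matrix(corner / 4, 1, 3)
  row <- corner[1] + 5 * (corner[2] + 5 * corner[3]) + 1
  expect_equal(as.numeric(enc(u)), as.numeric(tab[row, ]), tolerance = 1e-12)

  # at a cell center: mean of the 8 corner vectors
  u <- matrix((c(1, 2, 0) + 0.5) / 4, 1, 3)
  rows <- c()
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    rows <- c(rows, (1 + dx) + 5 * (2 + dy + 5 * (0 + dz)) + 1)
  expect_equal(as.numeric(enc(u)), colMeans(tab[rows, ]), tolerance = 1e-12)

  # random points against an independent trilinear oracle
  set.seed(11)
  U <- matrix(runif(60), 20, 3)
  vol1 <- array(0, c(5, 5, 5)); vol2 <- array(0, c(5, 5, 5))
  vol1[] <- tab[, 1]; vol2[] <- tab[, 2]
  oracle <- function(vol, u) {
    vapply(seq_len(nrow(u)), function(k) {
      p <- u[k, ] * 4
      i0 <- pmin(floor(p), 3)
      fr <- p - i0
      acc <- 0
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
        acc <- acc + w * vol[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
      }
      acc
    }, 0)
  }
  got <- enc(U)
  expect_equal(got[, 1], oracle(vol1, U), tolerance = 1e-12)
  expect_equal(got[, 2], oracle(vol2, U), tolerance = 1e-12)
})

test_that("hash encoding is multilinear within a cell", {
  cfgl <- hash_grid_config(L = 2, F = 2, log2_hashmap_size = 8,
                           base_resolution = 4, finest_resolution = 8)
  f <- field_hashgrid(extent = 1, cfgl, seed = 5)
  enc <- function(u) cryofield:::cpp_hash_encode(u, f$resolutions, f$tables)
  # vary one coordinate inside the finest cell [0.5, 0.625): second
  # differences vanish for a function linear in that coordinate
  base <- c(0.51, 0.53, 0.55)
  h <- 0.02
  for (ax in 1:3) {
    u0 <- matrix(base, 1, 3)
    u1 <- u0; u1[ax] <- u1[ax] + h
    u2 <- u0; u2[ax] <- u2[ax] + 2 * h
    second_diff <- enc(u2) - 2 * enc(u1) + enc(u0)
    expect_lt(max(abs(second_diff)), 1e-12)
  }
})

test_that("hash-grid parameter count matches the closed form", {
  cfg <- hash_grid_config(L = 8, F = 2, log2_hashmap_size = 10,
                          base_resolution = 16, finest_resolution = 80,
                          mlp_hidden = 128, mlp_layers = 2)
  f <- field_hashgrid(extent = 160, cfg)
  # all levels exceed the 2^10 table -> L * F * 2^10 for the encoding
  enc_params <- 8 * 2 * 1024
  mlp_params <- (16 * 128 + 128) + (128 * 128 + 128) + (128 + 1)
  expect_equal(field_n_params(f), enc_params + mlp_params)
  # the ~35k operating point of the smallest published configuration
  expect_true(abs(field_n_params(f) - 35000) / 35000 < 0.05)
})

test_that("level resolutions grow geometrically from base to finest", {
  cfg <- hash_grid_config(L = 8, base_resolution = 16, finest_resolution = 64)
  res <- cryofield:::hash_level_resolutions(cfg)
  expect_equal(res[1], 16L)
  expect_equal(res[8], 64L)
  expect_true(all(diff(res) >= 0))
  ratios <- res[-1] / res[-8]
  expect_equal(ratios, rep((64 / 16)^(1 / 7), 7), tolerance = 0.06)
})

test_that("voxel field query honours the zero-padding contract", {
  f <- field_voxel(extent = 8, n_voxels = 4)
  f$vol[2, 3, 4] <- 7
  # voxel (2,3,4) center in Angstrom: ((i - 1 + 0.5)/4 - 0.5) * 8
  ctr <- (c(2, 3, 4) - 1 + 0.5) / 4 * 8 - 4
  expect_equal(query_field(f, matrix(ctr, 1, 3)), 7)
  expect_equal(query_field(f, matrix(c(100, 0, 0), 1, 3)), 0)
  expect_equal(query_field(f, matrix(c(-4.1, 0, 0), 1, 3)), 0)

  set.seed(4)
  f$vol[] <- rnorm(64)
  U <- matrix(runif(90, 0.05, 0.95), 30, 3)
  pts <- (U - 0.5) * 8
  expect_equal(query_field(f, pts), trilinear_oracle(f$vol, U),
               tolerance = 1e-6)
})

test_that("render_volume matches direct evaluation and native lattices", {
  const <- field_function(function(p) rep(2.5, nrow(p)), extent = 10)
  expect_true(all(render_volume(const, 4, 2.5) == 2.5))

  set.seed(9)
  vf <- field_voxel(extent = 12, n_voxels = 6,
                    data = array(rnorm(216), c(6, 6, 6)))
  expect_equal(render_volume(vf, 6, 2), vf$vol, tolerance = 1e-12)

  gauss <- field_function(function(p) exp(-rowSums(p^2) / (2 * 4)),
                          extent = 12)
  v <- render_volume(gauss, 8, 1.5)
  ax <- (0:7 - 4 + 0.5) * 1.5
  direct <- exp(-outer(outer(ax^2, ax^2, "+"), ax^2, "+") / 8)
  expect_equal(v, direct, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a trained hash grid beats its initialization on an analytic target", {
  set.seed(2)
  cfg <- hash_grid_config(L = 4, F = 2, log2_hashmap_size = 12,
                          base_resolution = 4, finest_resolution = 16,
                          mlp_hidden = 32)
  f <- field_hashgrid(extent = 2, cfg, seed = 2)
  U <- matrix(runif(1500), 500, 3)
  pts <- (U - 0.5) * 2
  target <- exp(-rowSums(pts^2) / (2 * 0.15))

  rms <- function(field) {
    sqrt(mean((cryofield:::field_forward(field, U)$y - target)^2))
  }
  rms0 <- rms(f)

  params <- cryofield:::field_params(f)
  state <- cryofield:::adamw_init(params)
  for (it in 1:300) {
    fw <- cryofield:::field_forward(f, U)
    dy <- 2 * (fw$y - target) / length(target)
    bw <- cryofield:::field_backward(f, fw$cache, dy)
    upd <- cryofield:::adamw_step(state, cryofield:::field_params(f),
                                  bw$grads, function(nm) 1e-2)
    state <- upd$state
    f <- cryofield:::field_set_params(f, upd$params)
  }
  expect_lt(rms(f), rms0 / 10)
})

test_that("hash-table gradients touch only looked-up rows", {
  cfgl <- hash_grid_config(L = 2, F = 2, log2_hashmap_size = 12,
                           base_resolution = 4, finest_resolution = 8)
  f <- field_hashgrid(extent = 1, cfgl, seed = 1)
  u <- matrix(c(0.3, 0.6, 0.2), 1, 3)
  fw <- cryofield:::field_forward(f, u)
  bw <- cryofield:::field_backward(f, fw$cache, 1)
  for (l in 1:2) {
    touched <- which(rowSums(abs(bw$grads[[paste0("table", l)]])) > 0)
    expect_lte(length(touched), 8)
    expect_gte(length(touched), 1)
  }
})

test_that("field queries reject non-finite points and unknown kinds", {
  f <- field_voxel(extent = 4, n_voxels = 2)
  expect_error(query_field(structure(list(), class = "list"), matrix(0, 1, 3)),
               "unknown")
  fh <- field_hashgrid(extent = 4, hash_grid_config(L = 1,
    log2_hashmap_size = 6, base_resolution = 4, finest_resolution = 4))
  expect_error(query_field(fh, matrix(c(NA, 0, 0), 1, 3)), "finite")
})

test_that("checkpoints round-trip bit-exactly", {
  f <- field_hashgrid(extent = 8, hash_grid_config(L = 2,
    log2_hashmap_size = 8, base_resolution = 4, finest_resolution = 8),
    seed = 6)
  path <- tempfile(fileext = ".rds")
  save_field(f, path)
  g <- load_field(path)
  expect_identical(render_volume(g, 6, 8 / 6), render_volume(f, 6, 8 / 6))
})
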