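# Small smoke-scale training runs; the full scaled-down reconstruction
# protocols live in test-acceptance.R.

tiny_run_config <- function(..., seed = 1) {
  run_config(field = "hashgrid",
             hash_config = hash_grid_config(L = 4, log2_hashmap_size = 10,
                                            base_resolution = 4,
                                            finest_resolution = 8,
                                            mlp_hidden = 16),
             n_z = 6, loss = loss_spec("cc", sigma = 3), batch_size = 4,
             seed = seed, val_fraction = 0, ...)
}

test_that("training reduces the loss and is reproducible from the seed", {
  sim <- make_tiny_sim(n = 12, n_particles = 16, sigma = 0, n_z = 6)
  cfg <- tiny_run_config(epochs = 2)
  res1 <- train_field(sim, cfg)
  res2 <- train_field(sim, cfg)
  expect_identical(res1$log$train_loss, res2$log$train_loss)

  first <- mean(head(res1$log$train_loss, 2))
  last <- mean(tail(res1$log$train_loss, 2))
  expect_lt(last, first)

  # one full pass over N particles = ceiling(N / batch) steps per epoch
  expect_equal(nrow(res1$log), 2 * ceiling(16 / 4))
})

test_that("a gradient step on a batch does not increase that batch's loss", {
  sim <- make_tiny_sim(n = 12, n_particles = 4, sigma = 0, n_z = 6)
  grid <- build_grid(12, 1.5, 6)
  proj <- build_projection_map(grid)
  cfg <- tiny_run_config(lr_encoding = 1e-3, lr_mlp = 1e-3)
  f <- cryofield:::make_field(cfg, extent = 18, n_pixels = 12)
  Hs <- lapply(sim$ctfs, ctf_evaluate, n = 12)
  idx <- 1:4
  p1 <- cryofield:::batch_pass(f, NULL, grid, proj, sim, idx, cfg, Hs)
  upd <- cryofield:::adamw_step(cryofield:::adamw_init(cryofield:::field_params(f)),
                                cryofield:::field_params(f), p1$field_grads,
                                function(nm) 1e-3)
  f2 <- cryofield:::field_set_params(f, upd$params)
  p2 <- cryofield:::batch_pass(f2, NULL, grid, proj, sim, idx, cfg, Hs,
                               compute_grads = FALSE)
  expect_lte(p2$loss, p1$loss + 1e-8)
})

test_that("epochs = 0 leaves the field at its checkpointable initialization", {
  sim <- make_tiny_sim(n = 12, n_particles = 6, sigma = 0, n_z = 6)
  cfg <- tiny_run_config(epochs = 0)
  res <- train_field(sim, cfg)
  expect_equal(nrow(res$log), 0)
  path <- tempfile(fileext = ".rds")
  save_field(res$field, path)
  expect_identical(render_volume(load_field(path), 12, 1.5),
                   render_volume(res$field, 12, 1.5))
  # equals a freshly initialized field under the same seed
  f0 <- cryofield:::make_field(cfg, extent = 18, n_pixels = 12)
  expect_identical(render_volume(f0, 12, 1.5),
                   render_volume(res$field, 12, 1.5))
})

test_that("snapshots and CSV logs are emitted during training", {
  sim <- make_tiny_sim(n = 12, n_particles = 8, sigma = 0, n_z = 6)
  log_path <- tempfile(fileext = ".csv")
  cfg <- tiny_run_config(snapshot_steps = c(1, 2), log_csv = log_path)
  res <- train_field(sim, cfg)
  expect_named(res$snapshots, c("1", "2"))
  expect_s3_class(res$snapshots[["1"]], "cf_field")
  logged <- read.csv(log_path)
  expect_equal(nrow(logged), nrow(res$log))
  expect_true(all(c("step", "train_loss") %in% colnames(logged)))
})

test_that("masked training restricts the grid and still optimizes", {
  sim <- make_tiny_sim(n = 12, n_particles = 8, sigma = 0, n_z = 6)
  ax <- (0:11 - 6 + 0.5) * 1.5
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  mask <- mask_volume(array(as.numeric(r2 < 36), c(12, 12, 12)),
                      spacing = 1.5)
  cfg <- tiny_run_config(mask = mask)
  res <- train_field(sim, cfg)
  expect_lt(nrow(res$grid$points), 12 * 12 * 6)
  expect_true(all(is.finite(res$log$train_loss)))
})

test_that("half-map training validates splits and reports FSC", {
  sim <- make_tiny_sim(n = 12, n_particles = 12, sigma = 0, n_z = 6)
  cfg <- tiny_run_config()
  expect_error(run_half_maps(sim, cfg, split = list(1:7, 6:12)),
               "disjoint")
  expect_error(run_half_maps(sim, cfg, split = list(1:5, 7:12)),
               "exhaustive")

  res <- run_half_maps(sim, cfg, reference = sim$gt_volumes[[1]])
  expect_equal(sort(c(res$split[[1]], res$split[[2]])), 1:12)
  expect_equal(length(res$split[[1]]), 6)
  expect_s3_class(res$fsc_half, "cf_fsc")
  expect_equal(length(res$fsc_ref), 2L)
  # trained half-maps agree at the lowest shells
  expect_gt(res$fsc_half$fsc[2], 0.5)
})

test_that("heterogeneous runs start at the homogeneous model", {
  sim <- make_tiny_sim(n = 12, n_particles = 8, sigma = 0.1, n_z = 6)
  cfg <- tiny_run_config(hetero = TRUE, n_F = 4, epochs = 1,
                         hetero_warmup = 1)
  res <- train_field(sim, cfg)
  # warmup covers the whole run: encoder still at identity
  vf <- predict_field(res$vfmodel, sim$images[, , 1])
  expect_true(all(vf == 0))

  cfg2 <- tiny_run_config(hetero = TRUE, n_F = 4, epochs = 2,
                          hetero_warmup = 1)
  res2 <- train_field(sim, cfg2)
  vf2 <- predict_field(res2$vfmodel, sim$images[, , 1])
  expect_gt(max(abs(vf2)), 0)
})
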