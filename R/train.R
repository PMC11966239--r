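#' Training run configuration
#'
#' Bundles every knob of a reconstruction run. Defaults follow the
#' package's standard operating point: hash-grid field, cross-correlation
#' loss with sigma = 3, AdamW with learning rate 1e-2 for the encoding
#' tables / voxel array and for the MLPs (single-epoch training needs the
#' decoder to keep pace with the tables), batch size 8, one epoch.
#'
#' @param field One of "hashgrid", "voxel", "frequency".
#' @param hash_config A [hash_grid_config()] (hashgrid field only).
#' @param n_z Depth samples of the query grid (default 64).
#' @param J Jitter width in Angstrom (default 0; re-drawn every forward
#'   pass).
#' @param loss A [loss_spec()].
#' @param lr_encoding,lr_mlp Learning rates for encoding parameters and
#'   network weights.
#' @param weight_decay AdamW weight decay (default 0).
#' @param batch_size Minibatch size (default 8).
#' @param epochs Full passes over the training particles (default 1;
#'   0 = evaluation only).
#' @param seed Integer seed governing initialization, batching and jitter.
#' @param hetero Enable per-image deformation inference.
#' @param n_F Canonical vector-field resolution (hetero only, default 8).
#' @param hetero_warmup Number of initial epochs during which the
#'   deformation encoder is frozen at the identity so the canonical
#'   density forms first (default 1; the deformation model is defined
#'   relative to that reference).
#' @param hetero_weight_decay AdamW weight decay applied to the encoder
#'   only (default 1e-4), a mild ridge toward the identity deformation.
#' @param hetero_penalty L2 penalty weight on the per-image deformation
#'   field (default 1e-3): because any image-independent deformation is
#'   exactly redundant with the canonical density, the joint problem has
#'   a loss-neutral direction along which first-order optimizers drift;
#'   a mild ridge toward the identity removes the drift while
#'   loss-reducing (image-specific) deformation re-earns itself.
#' @param hetero_pool Pooled image side fed to the deformation encoder
#'   (default: the full image side, capped at 24).
#' @param lr_hetero Learning rate of the deformation encoder (default:
#'   `lr_mlp`).
#' @param val_fraction Held-out validation fraction (default 0.05).
#' @param val_every Steps between validation evaluations (default 100).
#' @param snapshot_steps Integer vector of step counts after which a copy
#'   of the field is stored in the result's `$snapshots`.
#' @param mask Optional `cf_mask`: training restricted to grid points
#'   inside the mask.
#' @param log_csv Optional path; per-step losses are appended as CSV.
#' @return A `cf_run_config`.
#' @export
run_config <- function(field = c("hashgrid", "voxel", "frequency"),
                       hash_config = hash_grid_config(), n_z = 64, J = 0,
                       loss = loss_spec(), lr_encoding = 1e-2,
                       lr_mlp = 1e-2, weight_decay = 0, batch_size = 8,
                       epochs = 1, seed = 1, hetero = FALSE, n_F = 8,
                       hetero_warmup = 1, hetero_weight_decay = 1e-4,
                       hetero_penalty = 1e-3,
                       hetero_pool = NULL, lr_hetero = NULL,
                       val_fraction = 0.05, val_every = 100,
                       snapshot_steps = integer(0), mask = NULL,
                       log_csv = NULL) {
  field <- match.arg(field)
  stopifnot(n_z >= 1, epochs >= 0, batch_size >= 1,
            val_fraction >= 0, val_fraction < 1)
  structure(list(field = field, hash_config = hash_config, n_z = n_z, J = J,
                 loss = loss, lr_encoding = lr_encoding, lr_mlp = lr_mlp,
                 weight_decay = weight_decay, batch_size = batch_size,
                 epochs = epochs, seed = seed, hetero = hetero, n_F = n_F,
                 hetero_warmup = hetero_warmup,
                 hetero_weight_decay = hetero_weight_decay,
                 hetero_penalty = hetero_penalty,
                 hetero_pool = hetero_pool, lr_hetero = lr_hetero,
                 val_fraction = val_fraction, val_every = val_every,
                 snapshot_steps = as.integer(snapshot_steps), mask = mask,
                 log_csv = log_csv), class = "cf_run_config")
}

make_field <- function(config, extent, n_pixels) {
  switch(config$field,
         hashgrid = field_hashgrid(extent, config$hash_config,
                                   n_pixels = n_pixels, seed = config$seed),
         voxel = field_voxel(extent, n_pixels),
         frequency = field_frequency(extent, seed = config$seed))
}

# forward + backward over one minibatch; returns loss and gradients
batch_pass <- function(field, vfmodel, grid, proj, particles, idx, config,
                       Hs, compute_grads = TRUE) {
  K <- nrow(grid$points)
  nb <- length(idx)
  U <- matrix(0, K * nb, 3)
  vf_caches <- vector("list", nb)
  pts_list <- vector("list", nb)
  extent <- field$extent
  for (b in seq_len(nb)) {
    i <- idx[b]
    pts <- pose_grid(grid, particles$poses[[i]])
    if (config$J > 0) pts <- jitter_points(pts, config$J)
    if (!is.null(vfmodel)) {
      pf <- predict_field_forward(vfmodel, particles$images[, , i])
      vf_caches[[b]] <- pf
      pts_list[[b]] <- pts
      pts <- bend_points(pts, pf$vf, extent)
    }
    U[((b - 1) * K + 1):(b * K), ] <- normalize_points(pts, extent)
  }
  fw <- field_forward(field, U)

  total <- 0
  dDens <- if (compute_grads) numeric(K * nb) else NULL
  dimgs <- vector("list", nb)
  for (b in seq_len(nb)) {
    i <- idx[b]
    rows <- ((b - 1) * K + 1):(b * K)
    img <- project_densities(fw$y[rows], proj)
    pred <- apply_ctf(img, Hs[[i]])
    lg <- loss_eval_grad(config$loss, particles$images[, , i], pred)
    total <- total + lg$value
    if (compute_grads) {
      draw <- apply_ctf(lg$grad, Hs[[i]])  # CTF operator is self-adjoint
      dDens[rows] <- project_backward(draw, proj)
    }
  }
  if (!compute_grads) return(list(loss = total))

  bw <- field_backward(field, fw$cache, dDens,
                       want_posgrad = !is.null(vfmodel))
  out <- list(loss = total, field_grads = bw$grads)
  if (!is.null(vfmodel)) {
    lam <- config$hetero_penalty %||% 0
    enc_grads <- NULL
    for (b in seq_len(nb)) {
      rows <- ((b - 1) * K + 1):(b * K)
      dbent <- bw$du[rows, , drop = FALSE] / extent  # d(normalized)/d(Angstrom)
      dvf <- bend_backward(pts_list[[b]], dim(vf_caches[[b]]$vf), extent,
                           dbent)
      if (lam > 0) {
        dvf <- dvf + 2 * lam * vf_caches[[b]]$vf
        out$loss <- out$loss + lam * sum(vf_caches[[b]]$vf^2)
      }
      g <- predict_field_backward(vfmodel, vf_caches[[b]]$cache, dvf)
      enc_grads <- if (is.null(enc_grads)) g else accumulate_grads(enc_grads, g)
    }
    out$enc_grads <- enc_grads
  }
  out
}

#' Train a scalar field on a particle stack
#'
#' End-to-end gradient-based reconstruction: per minibatch the predicted
#' images are rendered through the differentiable forward model (pose,
#' jitter, optional per-image bending, field query, sparse projection,
#' CTF), the batch loss (sum over particles) is evaluated, and the field
#' parameters (and, when `hetero = TRUE`, the deformation-encoder
#' parameters) are updated with AdamW. Runs `ceiling(N_train / batch)`
#' steps per epoch; fully reproducible from the config seed.
#'
#' @param particles A `cf_particles` (all of `poses`, `ctfs` must be
#'   complete; see [read_particles()]).
#' @param config A [run_config()].
#' @return List: `field` (trained), `vfmodel` (or NULL), `log` (data frame
#'   step / train_loss / val_loss / seconds), `snapshots` (fields copied at
#'   `snapshot_steps`), `grid`, `config`.
#' @export
train_field <- function(particles, config) {
  stopifnot(inherits(particles, "cf_particles"),
            inherits(config, "cf_run_config"))
  n <- dim(particles$images)[1]
  ps <- particles$config$pixel_size
  N <- dim(particles$images)[3]
  set.seed(config$seed)

  grid <- build_grid(n, ps, config$n_z)
  if (!is.null(config$mask)) grid <- subset_by_mask(grid, config$mask)
  proj <- build_projection_map(grid)
  field <- make_field(config, extent = n * ps, n_pixels = n)
  vfmodel <- if (config$hetero) {
    pool <- config$hetero_pool %||% min(n, 24)
    vector_field_model(n, n_F = config$n_F, pool = pool,
                       seed = config$seed)
  } else NULL
  Hs <- lapply(particles$ctfs, ctf_evaluate, n = n)

  n_val <- floor(config$val_fraction * N)
  perm <- sample.int(N)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  train_idx <- setdiff(perm, val_idx)

  lr_for <- function(nm) {
    if (grepl("^table", nm) || nm == "vol") config$lr_encoding else config$lr_mlp
  }
  fstate <- adamw_init(field_params(field))
  estate <- if (config$hetero) adamw_init(vfmodel_params(vfmodel)) else NULL

  log <- data.frame(step = integer(), train_loss = numeric(),
                    val_loss = numeric(), seconds = numeric())
  snapshots <- list()
  step <- 0
  t0 <- proc.time()[3]
  eval_val <- function() {
    if (length(val_idx) == 0) return(NA_real_)
    cfg0 <- config
    cfg0$J <- 0  # deterministic validation renders
    tot <- 0
    for (chunk in split(val_idx, ceiling(seq_along(val_idx) / config$batch_size)))
      tot <- tot + batch_pass(field, vfmodel, grid, proj, particles, chunk,
                              cfg0, Hs, compute_grads = FALSE)$loss
    tot / length(val_idx)
  }

  if (config$epochs > 0) {
    for (ep in seq_len(config$epochs)) {
      hetero_active <- config$hetero && ep > config$hetero_warmup
      order <- sample(train_idx)
      batches <- split(order, ceiling(seq_along(order) / config$batch_size))
      for (bt in batches) {
        step <- step + 1
        pass <- batch_pass(field, if (hetero_active) vfmodel else NULL,
                           grid, proj, particles, bt, config, Hs)
        upd <- adamw_step(fstate, field_params(field), pass$field_grads,
                          lr_for, weight_decay = config$weight_decay)
        fstate <- upd$state
        field <- field_set_params(field, upd$params)
        if (hetero_active) {
          lr_enc <- config$lr_hetero %||% config$lr_mlp
          eupd <- adamw_step(estate, vfmodel_params(vfmodel), pass$enc_grads,
                             function(nm) lr_enc,
                             weight_decay = config$hetero_weight_decay)
          estate <- eupd$state
          vfmodel <- vfmodel_set_params(vfmodel, eupd$params)
        }
        vl <- if (step %% config$val_every == 0) eval_val() else NA_real_
        row <- data.frame(step = step, train_loss = pass$loss / length(bt),
                          val_loss = vl, seconds = proc.time()[3] - t0)
        log <- rbind(log, row)
        if (!is.null(config$log_csv))
          utils::write.table(row, config$log_csv, append = file.exists(config$log_csv),
                             col.names = !file.exists(config$log_csv),
                             row.names = FALSE, sep = ",")
        if (step %in% config$snapshot_steps)
          snapshots[[as.character(step)]] <- field
      }
    }
  }
  final_val <- eval_val()
  if (!is.na(final_val) && nrow(log) > 0) log$val_loss[nrow(log)] <- final_val

  list(field = field, vfmodel = vfmodel, log = log, snapshots = snapshots,
       grid = grid, config = config)
}

#' Train two independent half-set reconstructions
#'
#' Splits the particles into two disjoint halves (or uses a supplied
#' split), trains a field independently on each, and reports the half-map
#' FSC, optionally also each half's FSC to a reference volume. Note the
#' caveat this protocol carries for representations with strong inductive
#' bias: half-maps can correlate with each other through shared training
#' bias without correlating with the true map, so an FSC to an independent
#' reference is also offered.
#'
#' @param particles A `cf_particles`.
#' @param config A [run_config()]; half 2 uses `seed + 1` for its
#'   independent initialization.
#' @param split Optional list of two disjoint, exhaustive index vectors.
#' @param reference Optional reference volume array for FSC-to-reference.
#' @return List: `fields` (2), `fsc_half` (`cf_fsc`), `fsc_ref` (list of 2
#'   or NULL), `split`, `volumes`.
#' @export
run_half_maps <- function(particles, config, split = NULL,
                          reference = NULL) {
  N <- dim(particles$images)[3]
  if (is.null(split)) {
    set.seed(config$seed)
    perm <- sample.int(N)
    split <- list(sort(perm[seq_len(floor(N / 2))]),
                  sort(perm[(floor(N / 2) + 1):N]))
  }
  if (length(intersect(split[[1]], split[[2]])) > 0)
    stop("half-set split is not disjoint")
  if (!setequal(c(split[[1]], split[[2]]), seq_len(N)))
    stop("half-set split must be exhaustive")

  halves <- lapply(1:2, function(h) {
    sub <- particles
    sub$images <- particles$images[, , split[[h]], drop = FALSE]
    sub$poses <- particles$poses[split[[h]]]
    sub$ctfs <- particles$ctfs[split[[h]]]
    sub$states <- particles$states[split[[h]]]
    cfg <- config
    cfg$seed <- config$seed + (h - 1)
    train_field(sub, cfg)
  })
  n <- dim(particles$images)[1]
  ps <- particles$config$pixel_size
  vols <- lapply(halves, function(r) render_volume(r$field, n, ps))
  out <- list(fields = lapply(halves, `[[`, "field"),
              fsc_half = fsc(vols[[1]], vols[[2]], ps),
              split = split, volumes = vols)
  if (!is.null(reference))
    out$fsc_ref <- lapply(vols, fsc, B = reference, pixel_size = ps)
  out
}
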