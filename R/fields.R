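#' Multi-resolution hash-grid configuration
#'
#' Hyperparameters of the hash-grid scalar field: `L` geometrically scaled
#' resolution levels, each holding a table of `2^log2_hashmap_size` trainable
#' feature rows of length `F`, decoded by a small ReLU MLP. Per-level
#' resolutions grow geometrically from `base_resolution` to
#' `finest_resolution`; levels whose full lattice fits in the table are
#' indexed densely, finer levels through the spatial hash.
#'
#' @param L Number of levels (default 8).
#' @param F Features per level (default 2).
#' @param log2_hashmap_size log2 of the per-level table size (default 14).
#' @param base_resolution Coarsest per-axis resolution (default 16).
#' @param finest_resolution Finest per-axis resolution; defaults to the
#'   Nyquist-matched value `n/2` when a box size `n` is known at field
#'   construction, else 64.
#' @param mlp_hidden Neurons per hidden decoder layer (default 64).
#' @param mlp_layers Hidden decoder layers (default 2).
#' @return A `cf_hash_config` list.
#' @export
hash_grid_config <- function(L = 8, F = 2, log2_hashmap_size = 14,
                             base_resolution = 16, finest_resolution = NULL,
                             mlp_hidden = 64, mlp_layers = 2) {
  stopifnot(L >= 1, F >= 1, log2_hashmap_size >= 4, base_resolution >= 2)
  structure(list(L = L, F = F, log2_hashmap_size = log2_hashmap_size,
                 base_resolution = base_resolution,
                 finest_resolution = finest_resolution,
                 mlp_hidden = mlp_hidden, mlp_layers = mlp_layers),
            class = "cf_hash_config")
}

hash_level_resolutions <- function(config) {
  base <- config$base_resolution
  fine <- config$finest_resolution
  if (is.null(fine)) fine <- 64
  fine <- max(fine, base)
  L <- config$L
  if (L == 1) return(as.integer(fine))
  growth <- (fine / base)^(1 / (L - 1))
  as.integer(round(base * growth^(0:(L - 1))))
}

#' Create a hash-grid scalar field
#'
#' The flagship trainable density representation: a coordinate in the box is
#' hash-encoded at `L` resolution levels (trilinear interpolation of `F`
#' learnable features at the 8 surrounding lattice corners per level) and
#' the concatenated `L*F` features are decoded to a scalar by a small MLP.
#' Feature tables start near zero (uniform in +/- 1e-4); queries outside the
#' box clamp to the boundary.
#'
#' @param extent Physical box side in Angstrom (the field's domain is this
#'   box mapped to the unit cube).
#' @param config A [hash_grid_config()]; `finest_resolution = NULL` is
#'   resolved to `n_pixels/2` if `n_pixels` is given.
#' @param n_pixels Optional box size in pixels used to Nyquist-match the
#'   finest level.
#' @param seed Integer seed for parameter initialization.
#' @return A `cf_field` object (subclass `cf_field_hashgrid`).
#' @export
field_hashgrid <- function(extent, config = hash_grid_config(),
                           n_pixels = NULL, seed = 1) {
  if (is.null(config$finest_resolution) && !is.null(n_pixels))
    config$finest_resolution <- max(config$base_resolution,
                                    as.integer(n_pixels / 2))
  res <- hash_level_resolutions(config)
  tsize <- 2L^config$log2_hashmap_size
  set.seed(seed)
  tables <- lapply(res, function(N) {
    rows <- min(tsize, (N + 1L)^3)
    matrix(stats::runif(rows * config$F, -1e-4, 1e-4), rows, config$F)
  })
  mlp <- mlp_init(c(config$L * config$F,
                    rep(config$mlp_hidden, config$mlp_layers), 1))
  structure(list(kind = "hashgrid", extent = extent, config = config,
                 resolutions = res, tables = tables, mlp = mlp),
            class = c("cf_field_hashgrid", "cf_field"))
}

#' Create a voxel scalar field
#'
#' Real-space baseline: a trainable `n_voxels^3` array queried by trilinear
#' interpolation, zero outside the box (zero-padding contract).
#'
#' @param extent Physical box side in Angstrom.
#' @param n_voxels Per-axis voxel count.
#' @param data Optional initial array (defaults to zeros); dimensions must
#'   be `c(n_voxels, n_voxels, n_voxels)`.
#' @return A `cf_field` object (subclass `cf_field_voxel`).
#' @export
field_voxel <- function(extent, n_voxels, data = NULL) {
  if (is.null(data)) data <- array(0, dim = c(n_voxels, n_voxels, n_voxels))
  stopifnot(all(dim(data) == n_voxels))
  structure(list(kind = "voxel", extent = extent, n_voxels = n_voxels,
                 vol = data),
            class = c("cf_field_voxel", "cf_field"))
}

#' Create a frequency-encoded scalar field
#'
#' Sinusoidal-positional-encoding baseline: each coordinate axis is expanded
#' into `octaves` sin/cos pairs at geometrically growing frequencies and
#' decoded by an MLP.
#'
#' @param extent Physical box side in Angstrom.
#' @param octaves Frequency octaves per axis (default 8).
#' @param mlp_hidden,mlp_layers Decoder shape (defaults 128, 2).
#' @param seed Integer seed for initialization.
#' @return A `cf_field` object (subclass `cf_field_frequency`).
#' @export
field_frequency <- function(extent, octaves = 8, mlp_hidden = 128,
                            mlp_layers = 2, seed = 1) {
  mlp <- mlp_init(c(6 * octaves, rep(mlp_hidden, mlp_layers), 1), seed = seed)
  structure(list(kind = "frequency", extent = extent, octaves = octaves,
                 mlp = mlp),
            class = c("cf_field_frequency", "cf_field"))
}

#' Wrap an analytic function as a (non-trainable) field
#'
#' Convenience for oracles and references: `fn` receives a K x 3 matrix of
#' Angstrom coordinates and returns K scalars.
#'
#' @param fn Vectorized density function of Angstrom coordinates.
#' @param extent Physical box side in Angstrom.
#' @return A `cf_field` object (subclass `cf_field_function`).
#' @export
field_function <- function(fn, extent) {
  structure(list(kind = "function", extent = extent, fn = fn),
            class = c("cf_field_function", "cf_field"))
}

frequency_encode <- function(u, octaves) {
  K <- nrow(u)
  enc <- matrix(0, K, 6 * octaves)
  j <- 1
  for (o in 0:(octaves - 1)) {
    w <- 2^o * pi
    for (ax in 1:3) {
      enc[, j] <- sin(w * u[, ax]); enc[, j + 1] <- cos(w * u[, ax])
      j <- j + 2
    }
  }
  enc
}

# internal forward with cache; u is K x 3 normalized to [0,1]^3
field_forward <- function(field, u) UseMethod("field_forward")

field_forward.cf_field_hashgrid <- function(field, u) {
  if (any(!is.finite(u))) stop("non-finite query coordinates")
  feats <- cpp_hash_encode(u, field$resolutions, field$tables)
  fw <- mlp_forward(field$mlp, feats)
  list(y = as.numeric(fw$out), cache = list(u = u, feats = feats, mlp = fw))
}

field_forward.cf_field_voxel <- function(field, u) {
  d <- rep(field$n_voxels, 3)
  y <- cpp_trilinear(u, as.numeric(field$vol), as.integer(c(d, 1L)), 0L)
  list(y = as.numeric(y), cache = list(u = u))
}

field_forward.cf_field_frequency <- function(field, u) {
  uc <- pmin(pmax(u, 0), 1)
  enc <- frequency_encode(uc, field$octaves)
  fw <- mlp_forward(field$mlp, enc)
  list(y = as.numeric(fw$out), cache = list(u = u, uc = uc, enc = enc, mlp = fw))
}

field_forward.cf_field_function <- function(field, u) {
  pts <- (u - 0.5) * field$extent
  list(y = as.numeric(field$fn(pts)), cache = NULL)
}

# dy: numeric K. Returns list(grads = named list, du = K x 3 | NULL).
field_backward <- function(field, cache, dy, want_posgrad = FALSE)
  UseMethod("field_backward")

field_backward.cf_field_hashgrid <- function(field, cache, dy,
                                             want_posgrad = FALSE) {
  bw <- mlp_backward(field$mlp, cache$mlp, matrix(dy, ncol = 1))
  tg <- cpp_hash_encode_backward(cache$u, field$resolutions, field$tables,
                                 bw$dX)
  grads <- c(stats::setNames(tg, paste0("table", seq_along(tg))),
             stats::setNames(bw$dW, paste0("W", seq_along(bw$dW))),
             stats::setNames(bw$db, paste0("b", seq_along(bw$db))))
  du <- NULL
  if (want_posgrad)
    du <- cpp_hash_encode_posgrad(cache$u, field$resolutions, field$tables,
                                  bw$dX)
  list(grads = grads, du = du)
}

field_backward.cf_field_voxel <- function(field, cache, dy,
                                          want_posgrad = FALSE) {
  d <- as.integer(c(rep(field$n_voxels, 3), 1L))
  g <- cpp_trilinear_backward(cache$u, d, 0L, matrix(dy, ncol = 1))
  du <- NULL
  if (want_posgrad)
    du <- cpp_trilinear_posgrad(cache$u, as.numeric(field$vol), d, 0L,
                                matrix(dy, ncol = 1))
  list(grads = list(vol = array(g, rep(field$n_voxels, 3))), du = du)
}

field_backward.cf_field_frequency <- function(field, cache, dy,
                                              want_posgrad = FALSE) {
  bw <- mlp_backward(field$mlp, cache$mlp, matrix(dy, ncol = 1))
  grads <- c(stats::setNames(bw$dW, paste0("W", seq_along(bw$dW))),
             stats::setNames(bw$db, paste0("b", seq_along(bw$db))))
  du <- NULL
  if (want_posgrad) {
    du <- matrix(0, nrow(cache$u), 3)
    j <- 1
    for (o in 0:(field$octaves - 1)) {
      w <- 2^o * pi
      for (ax in 1:3) {
        du[, ax] <- du[, ax] +
          bw$dX[, j] * w * cos(w * cache$uc[, ax]) -
          bw$dX[, j + 1] * w * sin(w * cache$uc[, ax])
        j <- j + 2
      }
    }
    du <- du * (cache$u > 0 & cache$u < 1)  # clamp derivative
  }
  list(grads = grads, du = du)
}

# gradient w.r.t. the normalized query coordinates only (parameters
# frozen): the cheap path for per-image deformation refinement
field_posgrad <- function(field, cache, dy) UseMethod("field_posgrad")

field_posgrad.cf_field_hashgrid <- function(field, cache, dy) {
  dX <- mlp_input_grad(field$mlp, cache$mlp, matrix(dy, ncol = 1))
  cpp_hash_encode_posgrad(cache$u, field$resolutions, field$tables, dX)
}

field_posgrad.cf_field_voxel <- function(field, cache, dy) {
  d <- as.integer(c(rep(field$n_voxels, 3), 1L))
  cpp_trilinear_posgrad(cache$u, as.numeric(field$vol), d, 0L,
                        matrix(dy, ncol = 1))
}

field_posgrad.cf_field_frequency <- function(field, cache, dy) {
  field_backward(field, cache, dy, want_posgrad = TRUE)$du
}

# trainable parameters as a flat named list (arrays) --------------------------
field_params <- function(field) UseMethod("field_params")

field_params.cf_field_hashgrid <- function(field) {
  c(stats::setNames(field$tables, paste0("table", seq_along(field$tables))),
    stats::setNames(field$mlp$W, paste0("W", seq_along(field$mlp$W))),
    stats::setNames(field$mlp$b, paste0("b", seq_along(field$mlp$b))))
}

field_params.cf_field_voxel <- function(field) list(vol = field$vol)

field_params.cf_field_frequency <- function(field) {
  c(stats::setNames(field$mlp$W, paste0("W", seq_along(field$mlp$W))),
    stats::setNames(field$mlp$b, paste0("b", seq_along(field$mlp$b))))
}

field_set_params <- function(field, params) UseMethod("field_set_params")

field_set_params.cf_field_hashgrid <- function(field, params) {
  L <- length(field$tables)
  for (l in seq_len(L)) field$tables[[l]] <- params[[paste0("table", l)]]
  for (i in seq_along(field$mlp$W)) {
    field$mlp$W[[i]] <- params[[paste0("W", i)]]
    field$mlp$b[[i]] <- params[[paste0("b", i)]]
  }
  field
}

field_set_params.cf_field_voxel <- function(field, params) {
  field$vol <- params$vol
  field
}

field_set_params.cf_field_frequency <- function(field, params) {
  for (i in seq_along(field$mlp$W)) {
    field$mlp$W[[i]] <- params[[paste0("W", i)]]
    field$mlp$b[[i]] <- params[[paste0("b", i)]]
  }
  field
}

#' Number of trainable parameters of a field
#'
#' For a hash grid this is the per-level table rows times `F` plus the MLP
#' decoder count; with all levels capped at the table size it equals
#' `L * F * 2^log2_hashmap_size` plus the decoder.
#'
#' @param field A `cf_field`.
#' @return Integer parameter count.
#' @export
field_n_params <- function(field) {
  sum(vapply(field_params(field), length, 0))
}

#' Query a scalar field at physical coordinates
#'
#' @param field A `cf_field`.
#' @param points K x 3 matrix of Angstrom coordinates (box centered at the
#'   origin). Out-of-box points clamp to the boundary for the hash-grid and
#'   frequency parametrizations and evaluate to 0 for the voxel field.
#' @return Numeric vector of K density values.
#' @export
query_field <- function(field, points) {
  if (!inherits(field, "cf_field")) stop("unknown field parametrization")
  u <- normalize_points(points, field$extent)
  field_forward(field, u)$y
}

#' Render a field to a voxel volume
#'
#' Queries the field at the centers of an `n^3` lattice with the package's
#' coordinate conventions (pixel centers, box centered at the origin); the
#' result can be written out with [write_mrc()].
#'
#' @param field A `cf_field`.
#' @param n Per-axis voxel count (>= 2).
#' @param pixel_size Voxel size in Angstrom.
#' @return `n^3` numeric array.
#' @export
render_volume <- function(field, n, pixel_size) {
  stopifnot(n >= 2)
  ax <- (seq_len(n) - 1 - n / 2 + 0.5) * pixel_size
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  array(query_field(field, pts), dim = c(n, n, n))
}

#' Save / load a field checkpoint
#'
#' The full field object (configuration and trainable parameters) is
#' serialized to a single archive file.
#'
#' @param field A `cf_field`.
#' @param path File path.
#' @return `save_field` returns `path` invisibly; `load_field` the field.
#' @export
save_field <- function(field, path) {
  saveRDS(field, path)
  invisible(path)
}

#' @rdname save_field
#' @export
load_field <- function(path) {
  field <- readRDS(path)
  if (!inherits(field, "cf_field")) stop("not a field checkpoint")
  field
}

#' @export
print.cf_field <- function(x, ...) {
  cat(sprintf("<cf_field:%s> extent %.3g A, %d trainable parameters\n",
              x$kind, x$extent,
              if (x$kind == "function") 0L else field_n_params(x)))
  invisible(x)
}
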