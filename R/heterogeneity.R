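#' Amortized per-image deformation model
#'
#' Conformational heterogeneity is modelled by bending space: a shared
#' (amortized) network maps each particle image to a coarse canonical
#' vector field of shape `(n_F, n_F, n_F, 3)` (Angstrom displacements on a
#' regular lattice spanning the box), which is interpolated at the posed,
#' jittered grid points and added to them before the scalar-field query
#' (reverse mapping). The network is a fixed average-pooling front end
#' (the pooled image is standardized per image, matching the loss's
#' invariance to global image scale), a fully connected tanh trunk (tanh
#' units cannot die under aggressive optimization, unlike ReLUs) and a
#' zero-initialized linear head, so a freshly created model outputs
#' exactly the zero field and training starts at the homogeneous model.
#'
#' @param n_pixels Image side in pixels.
#' @param n_F Per-axis resolution of the canonical vector field
#'   (default 8; coarseness is the smoothness regularizer, since nearby
#'   coordinates share interpolated displacements).
#' @param pool Pooled image side fed to the trunk (default 8).
#' @param hidden,latent Trunk layer widths (defaults 128, 64).
#' @param max_disp Bound on per-component displacements in Angstrom
#'   (default 6): the head output is squashed through
#'   `max_disp * tanh(raw / max_disp)`, which is the identity near zero
#'   but keeps deformations on the physical scale of domain motions —
#'   without it the redundant direction shared with the density field
#'   (any image-independent deformation can be absorbed by the canonical
#'   map) lets the deformation norm drift without bound.
#' @param seed Integer seed for initialization.
#' @return A `cf_vfmodel` object.
#' @export
vector_field_model <- function(n_pixels, n_F = 8, pool = 8, hidden = 128,
                               latent = 64, max_disp = 6, seed = 1) {
  stopifnot(n_F >= 2, pool >= 2, pool <= n_pixels, max_disp > 0)
  net <- mlp_init(c(pool^2, hidden, latent, 3 * n_F^3), seed = seed,
                  zero_last = TRUE, act = "tanh")
  structure(list(n_pixels = n_pixels, n_F = as.integer(n_F),
                 pool = as.integer(pool), max_disp = max_disp, net = net),
            class = "cf_vfmodel")
}

# block average pooling of an n x n image to p x p (any n >= p)
pool_image <- function(image, p) {
  n <- nrow(image)
  bins <- floor((seq_len(n) - 1) * p / n) + 1
  byrow <- rowsum(image, bins) / as.numeric(table(bins))
  t(rowsum(t(byrow), bins) / as.numeric(table(bins)))
}

#' Predict the canonical vector field for an image
#'
#' Deterministic given the model parameters and the image (amortized
#' inference: the parameters are shared between all images).
#'
#' @param model A `cf_vfmodel`.
#' @param image n x n particle image.
#' @return `(n_F, n_F, n_F, 3)` array of displacements in Angstrom.
#' @export
predict_field <- function(model, image) {
  predict_field_forward(model, image)$vf
}

predict_field_forward <- function(model, image) {
  if (!is.matrix(image) || nrow(image) != model$n_pixels ||
      ncol(image) != model$n_pixels)
    stop(sprintf("image must be %d x %d", model$n_pixels, model$n_pixels))
  x <- as.numeric(pool_image(image, model$pool))
  s <- sqrt(mean((x - mean(x))^2))
  if (s > 0) x <- (x - mean(x)) / s  # per-image standardization
  fw <- mlp_forward(model$net, matrix(x, nrow = 1))
  nF <- model$n_F
  md <- model$max_disp
  raw <- array(fw$out, dim = c(nF, nF, nF, 3))
  list(vf = md * tanh(raw / md), cache = c(fw, list(raw = raw)))
}

# dvf: (nF, nF, nF, 3) gradient; returns named parameter gradients.
# The head bias gradient is dropped: the bias is a pure image-independent
# deformation direction, redundant with the canonical density.
predict_field_backward <- function(model, cache, dvf) {
  md <- model$max_disp
  draw <- dvf / cosh(cache$raw / md)^2  # d/draw of md * tanh(raw/md)
  bw <- mlp_backward(model$net, cache, matrix(as.numeric(draw), nrow = 1))
  grads <- c(stats::setNames(bw$dW, paste0("W", seq_along(bw$dW))),
             stats::setNames(bw$db, paste0("b", seq_along(bw$db))))
  grads[[paste0("b", length(bw$db))]] <- NULL
  grads
}

vfmodel_params <- function(model) {
  c(stats::setNames(model$net$W, paste0("W", seq_along(model$net$W))),
    stats::setNames(model$net$b, paste0("b", seq_along(model$net$b))))
}

vfmodel_set_params <- function(model, params) {
  for (i in seq_along(model$net$W)) {
    model$net$W[[i]] <- params[[paste0("W", i)]]
    model$net$b[[i]] <- params[[paste0("b", i)]]
  }
  model
}

#' Bend query points by a canonical vector field
#'
#' The canonical field (regular `n_F^3` lattice spanning the box) is
#' trilinearly interpolated at the points — displacements are queried at
#' the output coordinates (reverse mapping), not pushed from inputs — and
#' added to them. A zero field is the identity, reproducing the homogeneous
#' pipeline exactly.
#'
#' @param points K x 3 matrix of (posed, jittered) coordinates, Angstrom.
#' @param vf `(n_F, n_F, n_F, 3)` displacement array, Angstrom.
#' @param extent Physical box side in Angstrom.
#' @return K x 3 matrix of bent coordinates.
#' @export
bend_points <- function(points, vf, extent) {
  d <- dim(vf)
  stopifnot(length(d) == 4, d[4] == 3)
  u <- normalize_points(points, extent)
  disp <- cpp_trilinear(u, as.numeric(vf), as.integer(d), 1L)
  points + disp
}

# gradient of bend w.r.t. the canonical field voxels, given dL/d(disp)
bend_backward <- function(points, vf_dim, extent, ddisp) {
  u <- normalize_points(points, extent)
  array(cpp_trilinear_backward(u, as.integer(vf_dim), 1L, ddisp), vf_dim)
}

#' Refine per-image deformation fields by direct optimization
#'
#' Amortized inference shares one encoder across all images, which makes
#' its per-image fields only as sharp as the encoder's capacity and
#' training budget allow. This routine treats each image's canonical
#' vector field as a free latent and optimizes it directly against the
#' frozen scalar field (AdamW on the rendering loss plus an L2 ridge
#' toward the identity), warm-started from the amortized prediction when
#' a model is supplied. Images are processed in chunks so the field
#' queries batch efficiently.
#'
#' @param field Trained `cf_field` (kept fixed).
#' @param particles A `cf_particles`.
#' @param n_z Depth samples for the rendering grid (default 16: the
#'   depth sampling is a free hyperparameter and moderate counts render
#'   faithfully).
#' @param vfmodel Optional `cf_vfmodel` supplying warm starts (zero
#'   fields otherwise).
#' @param n_F Canonical lattice resolution when no model is given.
#' @param steps Optimization steps per image (default 20).
#' @param lr AdamW learning rate on the displacements, Angstrom-scaled
#'   (default 0.5).
#' @param penalty L2 penalty weight toward zero deformation
#'   (default 1e-3).
#' @param loss A [loss_spec()] (default cross-correlation, sigma 3).
#' @param chunk Images optimized simultaneously (default 25).
#' @return N x (3 n_F^3) matrix of flattened per-image fields.
#' @export
refine_fields <- function(field, particles, n_z = 16, vfmodel = NULL,
                          n_F = 8, steps = 20, lr = 0.5, penalty = 1e-3,
                          loss = loss_spec("cc", sigma = 3), chunk = 25) {
  n <- dim(particles$images)[1]
  N <- dim(particles$images)[3]
  if (!is.null(vfmodel)) n_F <- vfmodel$n_F
  d <- c(n_F, n_F, n_F, 3)
  grid <- build_grid(n, particles$config$pixel_size, n_z)
  proj <- build_projection_map(grid)
  extent <- field$extent
  Hs <- lapply(particles$ctfs, ctf_evaluate, n = n)
  K <- nrow(grid$points)
  out <- matrix(0, N, prod(d))

  for (start in seq(1, N, by = chunk)) {
    idx <- start:min(start + chunk - 1, N)
    nb <- length(idx)
    pts <- lapply(idx, function(i) pose_grid(grid, particles$poses[[i]]))
    VF <- matrix(0, nb, prod(d))
    if (!is.null(vfmodel))
      for (b in seq_len(nb))
        VF[b, ] <- as.numeric(predict_field(vfmodel,
                                            particles$images[, , idx[b]]))
    state <- adamw_init(list(VF = VF))
    for (s in seq_len(steps)) {
      U <- matrix(0, K * nb, 3)
      for (b in seq_len(nb)) {
        bent <- bend_points(pts[[b]], array(VF[b, ], d), extent)
        U[((b - 1) * K + 1):(b * K), ] <- normalize_points(bent, extent)
      }
      fw <- field_forward(field, U)
      dDens <- numeric(K * nb)
      for (b in seq_len(nb)) {
        rows <- ((b - 1) * K + 1):(b * K)
        pred <- apply_ctf(project_densities(fw$y[rows], proj),
                          Hs[[idx[b]]])
        lg <- loss_eval_grad(loss, particles$images[, , idx[b]], pred)
        dDens[rows] <- project_backward(apply_ctf(lg$grad, Hs[[idx[b]]]),
                                        proj)
      }
      du <- field_posgrad(field, fw$cache, dDens)
      G <- matrix(0, nb, prod(d))
      for (b in seq_len(nb)) {
        rows <- ((b - 1) * K + 1):(b * K)
        dvf <- bend_backward(pts[[b]], d, extent,
                             du[rows, , drop = FALSE] / extent)
        G[b, ] <- as.numeric(dvf) + 2 * penalty * VF[b, ]
      }
      upd <- adamw_step(state, list(VF = VF), list(VF = G),
                        function(nm) lr)
      state <- upd$state
      VF <- upd$params$VF
    }
    out[idx, ] <- VF
  }
  out
}

#' Cosine similarity matrix of per-image vector fields
#'
#' Entry (i, j) is the cosine of the angle between the flattened fields of
#' images i and j; the diagonal is 1 and the matrix is symmetric.
#'
#' @param fields N x d matrix whose rows are flattened per-image fields,
#'   or a list of arrays (flattened internally).
#' @return N x N symmetric matrix with unit diagonal.
#' @export
cosine_similarity_matrix <- function(fields) {
  if (is.list(fields))
    fields <- do.call(rbind, lapply(fields, as.numeric))
  if (nrow(fields) < 2) stop("need at least two fields")
  nrm <- sqrt(rowSums(fields^2))
  if (any(nrm == 0)) stop("zero-norm field at row ",
                          which(nrm == 0)[1])
  S <- tcrossprod(fields / nrm)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  pmin(pmax(S, -1), 1)
}

#' Cluster images into conformational states
#'
#' Spectral clustering of the cosine-similarity matrix: the similarity is
#' shifted to the affinity `(S + 1)/2`, the symmetric normalized graph
#' Laplacian's top-k eigenvector embedding is row-normalized, and k-means
#' (many restarts under a fixed seed) assigns the state labels.
#'
#' @param S N x N similarity matrix from [cosine_similarity_matrix()].
#' @param k Number of states (>= 2).
#' @param seed Integer seed for the k-means restarts.
#' @return Integer vector of labels in 0..k-1 (labelling is arbitrary up to
#'   permutation; see [match_labels()]).
#' @export
cluster_states <- function(S, k, seed = 1) {
  n <- nrow(S)
  if (k < 2) stop("`k` must be >= 2")
  if (k > n) stop("`k` exceeds the number of images")
  W <- (S + 1) / 2
  dsq <- 1 / sqrt(rowSums(W))
  Lsym <- W * tcrossprod(dsq)
  ev <- eigen(Lsym, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  set.seed(seed)
  km <- stats::kmeans(U, centers = k, nstart = 50, iter.max = 200)
  km$cluster - 1L
}

#' Match predicted labels to reference labels
#'
#' Resolves the label-permutation ambiguity of clustering by choosing the
#' permutation of predicted labels that maximizes agreement with the
#' reference.
#'
#' @param labels Integer vector of predicted labels (0-based).
#' @param truth Integer vector of reference labels (0-based), same length.
#' @return Integer vector of relabelled predictions.
#' @export
match_labels <- function(labels, truth) {
  ks <- sort(unique(c(labels, truth)))
  perms <- permutations_of(ks)
  best <- NULL
  best_acc <- -1
  for (p in perms) {
    mapped <- p[match(labels, ks)]
    acc <- mean(mapped == truth)
    if (acc > best_acc) {
      best_acc <- acc
      best <- mapped
    }
  }
  best
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out[[length(out) + 1]] <- c(x[i], rest)
  out
}
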