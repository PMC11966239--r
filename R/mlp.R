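# Minimal dense ReLU network with hand-written backprop. Used as the scalar
# decoder of the field parametrizations and as the heterogeneity encoder
# trunk. Parameters are plain R matrices so the optimizer can treat every
# trainable object uniformly.

mlp_init <- function(sizes, seed = NULL, zero_last = FALSE,
                     act = c("relu", "tanh")) {
  act <- match.arg(act)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  nl <- length(sizes) - 1
  W <- vector("list", nl)
  b <- vector("list", nl)
  for (i in seq_len(nl)) {
    sd <- sqrt(2 / sizes[i])  # He initialization for the ReLU layers
    W[[i]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1], 0, sd),
                     sizes[i], sizes[i + 1])
    b[[i]] <- numeric(sizes[i + 1])
  }
  if (zero_last) W[[nl]][] <- 0  # identity start (used by the hetero head)
  list(W = W, b = b, sizes = sizes, act = act)
}

# X: K x d_in. ReLU on all layers but the last (linear output).
# Thin wrappers over the compiled kernels; the cache holds only the input
# (the backward pass recomputes the activations in C++).
mlp_forward <- function(mlp, X) {
  a <- if (identical(mlp$act, "tanh")) 1L else 0L
  list(out = cpp_mlp_forward(X, mlp$W, mlp$b, a), X = X)
}

# dout: K x d_out. Returns parameter gradients and the input gradient.
mlp_backward <- function(mlp, cache, dout) {
  a <- if (identical(mlp$act, "tanh")) 1L else 0L
  cpp_mlp_backward(cache$X, mlp$W, mlp$b, dout, a)
}

# input gradient only, for frozen networks
mlp_input_grad <- function(mlp, cache, dout) {
  a <- if (identical(mlp$act, "tanh")) 1L else 0L
  cpp_mlp_input_grad(cache$X, mlp$W, mlp$b, dout, a)
}

mlp_n_params <- function(mlp) {
  sum(vapply(mlp$W, length, 0)) + sum(vapply(mlp$b, length, 0))
}
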