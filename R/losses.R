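# The three Gaussian-white-noise objectives. Each loss returns the scalar
# value; the *_grad variants also return the analytic gradient with respect
# to the predicted image, which the training loop consumes. Gradients are
# checked against finite differences in the test suite.

#' Mean-squared-error loss
#'
#' Negative log-likelihood of i.i.d. Gaussian pixel noise with known
#' standard deviation: `(1 / (2 sigma^2)) * sum((y - yhat)^2)`.
#'
#' @param y Observed image (matrix or vector).
#' @param yhat Predicted image, same shape.
#' @param sigma Noise standard deviation (> 0).
#' @return Scalar loss.
#' @export
loss_mse <- function(y, yhat, sigma = 1) {
  check_same_shape(y, yhat)
  if (sigma <= 0) stop("`sigma` must be positive")
  sum((y - yhat)^2) / (2 * sigma^2)
}

loss_mse_grad <- function(y, yhat, sigma = 1) {
  list(value = loss_mse(y, yhat, sigma), grad = (yhat - y) / sigma^2)
}

#' Cross-correlation loss
#'
#' Both images are standardized per image (`w(x) = (x - mean(x)) / std(x)`
#' with the population standard deviation) and compared in the MSE sense:
#' `(1 / (2 sigma^2)) * sum((w(y) - w(yhat))^2)`, which equals
#' `(n^2 / sigma^2) * (1 - r)` for the Pearson correlation `r` of the two
#' images. The loss is invariant to global multiplicative (positive) and
#' additive rescaling of either image; `sigma` only scales it by a
#' constant.
#'
#' @inheritParams loss_mse
#' @return Scalar loss, minimized (at 0) iff the images correlate
#'   perfectly.
#' @export
loss_cc <- function(y, yhat, sigma = 3) {
  check_same_shape(y, yhat)
  if (sigma <= 0) stop("`sigma` must be positive")
  wy <- whiten(y, "y")
  wh <- whiten(yhat, "yhat")
  sum((wy - wh)^2) / (2 * sigma^2)
}

loss_cc_grad <- function(y, yhat, sigma = 3) {
  check_same_shape(y, yhat)
  n2 <- length(y)
  wy <- whiten(y, "y")
  m <- mean(yhat)
  s <- sqrt(mean((yhat - m)^2))
  if (s == 0) stop("degenerate input: `yhat` is constant")
  wh <- (yhat - m) / s
  r <- sum(wy * wh) / n2
  grad <- -(wy - r * wh) / (sigma^2 * s)
  list(value = n2 * (1 - r) / sigma^2, grad = grad)
}

whiten <- function(x, label) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop(sprintf("degenerate input: `%s` is constant", label))
  (x - m) / s
}

#' Marginalized (BioEM-style) loss with a Gaussian prior
#'
#' Negative log of the Gaussian-noise likelihood of `y` given `yhat`,
#' analytically marginalized over a global multiplicative scale and
#' additive offset of `yhat` under a Gaussian prior (scale centered at 1,
#' offset at 0, both with standard deviation `prior_sd` relative to the
#' noise level), with the noise standard deviation integrated out by a
#' saddle-point (maximum) step. Up to constants:
#' `l = (n^2 / 2) log(Q + q0) + (1/2) log det(I + prior_sd^2 X'X)` where
#' `X = [yhat, 1]` and `Q` is the prior-regularized residual quadratic
#' form, computable from the sufficient statistics n^2, sum(y), sum(yhat),
#' sum(y^2), sum(yhat^2), sum(y yhat) alone. The Gaussian prior keeps the
#' loss bounded away from the degenerate minimum at `yhat -> 0` that the
#' flat-prior marginalization suffers from; the tiny floor `q0` keeps it
#' finite when the images agree exactly.
#'
#' @inheritParams loss_mse
#' @param prior_sd Prior standard deviation for scale and offset
#'   (default 10, a broad prior centered at the numerically stable
#'   scale 1 / offset 0).
#' @return Scalar loss (arbitrary additive constant).
#' @export
loss_bioem <- function(y, yhat, prior_sd = 10) {
  bioem_from_stats(bioem_stats(y, yhat), prior_sd)$value
}

bioem_stats <- function(y, yhat) {
  check_same_shape(y, yhat)
  s <- c(n2 = length(y), sy = sum(y), sh = sum(yhat), syy = sum(y^2),
         shh = sum(yhat^2), syh = sum(y * yhat))
  if (any(!is.finite(s))) stop("non-finite sufficient statistics")
  s
}

# loss and its partials w.r.t. (sh, shh, syh), by complex-step
# differentiation (machine-accurate, no finite-difference truncation).
bioem_from_stats <- function(s, prior_sd, grad = FALSE) {
  f <- function(sh, shh, syh) {
    n2 <- s[["n2"]]; sy <- s[["sy"]]; syy <- s[["syy"]]
    v <- prior_sd^2
    # A = I + v * X'X, X = [yhat, 1]; residual r = y - yhat (prior mean)
    a11 <- 1 + v * shh; a12 <- v * sh; a22 <- 1 + v * n2
    detA <- a11 * a22 - a12^2
    u1 <- syh - shh        # yhat . r
    u2 <- sy - sh          # 1 . r
    rr <- syy - 2 * syh + shh
    Q <- rr - v * (a22 * u1^2 - 2 * a12 * u1 * u2 + a11 * u2^2) / detA
    q0 <- 1e-9 * max(Re(syy), 1)
    n2 / 2 * log(Q + q0) + log(detA) / 2
  }
  val <- Re(f(s[["sh"]], s[["shh"]], s[["syh"]]))
  out <- list(value = val)
  if (grad) {
    h <- 1e-20
    out$d_sh <- Im(f(s[["sh"]] + h * 1i, s[["shh"]], s[["syh"]])) / h
    out$d_shh <- Im(f(s[["sh"]], s[["shh"]] + h * 1i, s[["syh"]])) / h
    out$d_syh <- Im(f(s[["sh"]], s[["shh"]], s[["syh"]] + h * 1i)) / h
  }
  out
}

loss_bioem_grad <- function(y, yhat, prior_sd = 10) {
  st <- bioem_stats(y, yhat)
  b <- bioem_from_stats(st, prior_sd, grad = TRUE)
  grad <- b$d_sh + 2 * yhat * b$d_shh + y * b$d_syh
  list(value = b$value, grad = grad)
}

check_same_shape <- function(y, yhat) {
  if (length(y) != length(yhat) ||
      !identical(dim(y) %||% length(y), dim(yhat) %||% length(yhat)))
    stop("`y` and `yhat` must have the same shape")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Loss specification
#'
#' Bundles the loss choice with its hyperparameters for the training loop.
#' The experimental default is the cross-correlation loss with `sigma = 3`.
#'
#' @param kind One of "mse", "cc", "bioem".
#' @param sigma Noise standard deviation for mse/cc.
#' @param prior_sd BioEM prior standard deviation.
#' @return A `cf_loss_spec`.
#' @export
loss_spec <- function(kind = c("cc", "mse", "bioem"), sigma = 3,
                      prior_sd = 10) {
  kind <- match.arg(kind)
  if (kind != "bioem" && sigma <= 0) stop("`sigma` must be positive")
  if (kind == "bioem" && prior_sd <= 0) stop("`prior_sd` must be positive")
  structure(list(kind = kind, sigma = sigma, prior_sd = prior_sd),
            class = "cf_loss_spec")
}

loss_eval_grad <- function(spec, y, yhat) {
  switch(spec$kind,
         mse = loss_mse_grad(y, yhat, spec$sigma),
         cc = loss_cc_grad(y, yhat, spec$sigma),
         bioem = loss_bioem_grad(y, yhat, spec$prior_sd))
}
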