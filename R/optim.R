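# AdamW over named lists of parameter arrays. Encoding-type parameters
# (hash tables, voxel arrays) and network weights take different learning
# rates, following common practice for hash-encoded fields.

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

adamw_step <- function(state, params, grads, lr_for, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    lr <- lr_for(nm)
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + weight_decay * params[[nm]])
  }
  list(state = state, params = params)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

accumulate_grads <- function(acc, grads) {
  for (nm in names(grads)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) grads[[nm]] else acc[[nm]] + grads[[nm]]
  }
  acc
}
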