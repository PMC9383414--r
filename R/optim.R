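# Adam optimizer over nested parameter lists (beta1 = 0.9, beta2 = 0.999,
# eps = 1e-8), plus the shared step-decay learning-rate schedule: the base
# rate is multiplied by 0.99 after every 10 completed epochs.

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_map(function(m) m / bc1, state$m)
  vhat <- tree_map(function(v) v / bc2, state$v)
  upd <- tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mhat, vhat)
  params <- tree_map2(`-`, params, upd)
  list(state = state, params = params)
}

#' Decayed learning rate at an epoch
#'
#' The base rate dropped by 1\% after every 10 completed epochs, so epochs
#' 1-10 run at `base`, 11-20 at `0.99 * base`, and after `10k` epochs the
#' effective rate is exactly `base * 0.99^k`.
#'
#' @param base Base learning rate.
#' @param epoch 1-based epoch index.
#' @param decay Multiplicative factor (default 0.99).
#' @param every Epochs between drops (default 10).
#' @return The effective learning rate.
#' @export
lr_at_epoch <- function(base, epoch, decay = 0.99, every = 10) {
  base * decay^((epoch - 1) %/% every)
}
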