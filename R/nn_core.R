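# Core pieces of the from-scratch network engine: parameter initialization,
# activations, softmax cross-entropy with per-sample weights, the Adam
# optimizer, dropout, and the generic minibatch training loop with early
# stopping. Architecture-specific forward/backward passes live in
# nn_models.R; conv/pool primitives are compiled (src/nnops.cpp).

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Weighted cross-entropy and its logit gradient. y is an integer class
# index (1-based), w per-sample weights (mean ~ 1).
softmax_xent <- function(logits, y, w) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  picked <- p[cbind(seq_len(n), y)]
  loss <- -sum(w * log(pmax(picked, 1e-12))) / n
  g <- p
  g[cbind(seq_len(n), y)] <- g[cbind(seq_len(n), y)] - 1
  list(loss = loss, grad = g * (w / n))
}

init_params <- function(shapes, sd, seed) {
  with_seed(seed, lapply(shapes, function(s) {
    array(rnorm(prod(s), 0, sd), dim = s)
  }))
}

n_params <- function(params) sum(vapply(params, length, 0L))

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / c1) / (sqrt(state$v[[k]] / c2) + eps)
  }
  list(params = params, state = state)
}

# Inverted dropout mask: scaling at train time keeps inference unscaled.
drop_mask <- function(dim_, rate) {
  if (rate <= 0) return(NULL)
  array(rbinom(prod(dim_), 1L, 1 - rate) / (1 - rate), dim = dim_)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

#' Optimization settings for network training
#'
#' Adam with the reference settings: learning rate 0.001, both momentum
#' terms at 0.9 (set `conventional_beta2 = TRUE` for the usual 0.999),
#' batch size 32, at most 600 epochs, cross-entropy loss on frames, early
#' stopping on the training loss (patience 25 epochs, minimum improvement
#' 1e-4; no validation set exists under leave-pair-out cross-validation).
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam momentum terms.
#' @param conventional_beta2 if `TRUE`, override `beta2` with 0.999.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience in epochs.
#' @param min_delta minimum loss improvement to reset patience.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, beta1 = 0.9, beta2 = 0.9,
                         conventional_beta2 = FALSE, batch_size = 32L,
                         max_epochs = 600L, patience = 25L, min_delta = 1e-4,
                         seed = NULL) {
  assert_positive(learning_rate, "learning_rate")
  assert_count(batch_size, "batch_size")
  assert_count(max_epochs, "max_epochs")
  if (conventional_beta2) beta2 <- 0.999
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "train_config")
}

# Per-cell standardization statistics from a training array (N, ...).
norm_stats <- function(x) {
  d <- dim(x)
  m <- apply(x, seq_along(d)[-1], mean)
  s <- apply(x, seq_along(d)[-1], stats::sd)
  s[!is.finite(s) | s < 1e-6] <- 1e-6
  list(mean = m, sd = s)
}

apply_norm <- function(x, norm) {
  d <- dim(x)
  n <- d[1]
  mu <- aperm(array(norm$mean, dim = c(d[-1], n)), c(length(d), seq_along(d[-1])))
  sd_ <- aperm(array(norm$sd, dim = c(d[-1], n)), c(length(d), seq_along(d[-1])))
  (x - mu) / sd_
}
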