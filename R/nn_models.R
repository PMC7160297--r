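#' CNN architecture configuration
#'
#' The four-layer convolutional classifier: two convolution + rectifier +
#' 2x2 max-pooling blocks for feature extraction, followed by dense layers
#' of 128 and 64 rectifier units and a 2-logit softmax head. The default
#' hyperparameters are the frozen result of an exhaustive search (see
#' [search_cnn_config()]) constrained to reach exactly 75106 trainable
#' parameters on the 22 x 20 x 7 input: 3x3 kernels, 63 then 20 filters,
#' valid padding in block 1 and same padding in block 2, floor-sized
#' pooling. Construction fails if the parameter count does not equal
#' `target_param_total`.
#'
#' @param input_shape input dimensions (freq bins, time bins, channels).
#' @param k1,k2 kernel sizes of the two conv blocks.
#' @param f1,f2 filter counts.
#' @param pad1,pad2 `"valid"` or `"same"` padding.
#' @param dense_units sizes of the two dense layers.
#' @param dropout_conv,dropout_dense dropout rates after each pooling /
#'   dense layer (training only).
#' @param init_sd SD of the zero-centred normal weight initialization.
#' @param target_param_total required trainable-parameter total; `NA`
#'   disables the check (used for reduced-channel ablation models).
#' @return an object of class `cnn_config`.
#' @export
cnn_config <- function(input_shape = c(22L, 20L, 7L),
                       k1 = 3L, f1 = 63L, pad1 = "valid",
                       k2 = 3L, f2 = 20L, pad2 = "same",
                       dense_units = c(128L, 64L),
                       dropout_conv = 0.25, dropout_dense = 0.5,
                       init_sd = 0.1,
                       target_param_total = if (identical(as.integer(input_shape),
                                                          c(22L, 20L, 7L)))
                         75106L else NA_integer_) {
  cfg <- structure(list(
    input_shape = as.integer(input_shape),
    k1 = as.integer(k1), f1 = as.integer(f1), pad1 = match.arg(pad1, c("valid", "same")),
    k2 = as.integer(k2), f2 = as.integer(f2), pad2 = match.arg(pad2, c("valid", "same")),
    dense_units = as.integer(dense_units),
    dropout_conv = dropout_conv, dropout_dense = dropout_dense,
    init_sd = init_sd, n_classes = 2L,
    target_param_total = target_param_total
  ), class = "cnn_config")
  n <- cnn_param_count(cfg)
  if (!is.na(cfg$target_param_total) && n != cfg$target_param_total) {
    stop(sprintf("CNN parameter count %d does not equal the required %d",
                 n, cfg$target_param_total), call. = FALSE)
  }
  cfg
}

conv_out_dim <- function(d, k, pad) if (pad == "same") d else d - k + 1L

cnn_dims <- function(cfg) {
  d1 <- vapply(cfg$input_shape[1:2], conv_out_dim, 0L, k = cfg$k1, pad = cfg$pad1)
  p1 <- d1 %/% 2L
  d2 <- vapply(p1, conv_out_dim, 0L, k = cfg$k2, pad = cfg$pad2)
  p2 <- d2 %/% 2L
  list(conv1 = d1, pool1 = p1, conv2 = d2, pool2 = p2,
       flat = p2[1] * p2[2] * cfg$f2)
}

#' Trainable-parameter count of a CNN configuration
#' @param cfg a [cnn_config()] (the check in the constructor uses this).
#' @return integer parameter total.
#' @export
cnn_param_count <- function(cfg) {
  dm <- cnn_dims(cfg)
  cin <- cfg$input_shape[3]
  as.integer(
    (cfg$k1^2 * cin + 1L) * cfg$f1 +
      (cfg$k2^2 * cfg$f1 + 1L) * cfg$f2 +
      (dm$flat + 1L) * cfg$dense_units[1] +
      (cfg$dense_units[1] + 1L) * cfg$dense_units[2] +
      (cfg$dense_units[2] + 1L) * 2L)
}

#' Exhaustive search for conv hyperparameters hitting a parameter total
#'
#' Enumerates kernel sizes \{3, 5\}, filter counts 4..64, same/valid
#' padding per block, and floor/ceil 2x2 stride-2 pooling, in a fixed
#' deterministic order, returning every combination whose trainable
#' parameter total equals `target` for the 2-conv-block + dense(128, 64) +
#' head template. The first hit is frozen as the package default. (Several
#' architectures hit the target; the frozen one is a reconstruction, not a
#' claim about the original.)
#'
#' @param target required parameter total.
#' @param first_only return only the first hit.
#' @return a data.frame of matching configurations.
#' @export
search_cnn_config <- function(target = 75106L, first_only = FALSE) {
  hits <- list()
  pdim <- function(d, mode) if (mode == "floor") d %/% 2L else (d + 1L) %/% 2L
  for (pool in c("floor", "ceil")) for (k1 in c(3L, 5L)) for (k2 in c(3L, 5L))
    for (pad1 in c("same", "valid")) for (pad2 in c("same", "valid"))
      for (f1 in 4:64) for (f2 in 4:64) {
        d1 <- vapply(c(22L, 20L), conv_out_dim, 0L, k = k1, pad = pad1)
        p1 <- pdim(d1, pool)
        d2 <- vapply(p1, conv_out_dim, 0L, k = k2, pad = pad2)
        p2 <- pdim(d2, pool)
        if (any(d1 < 1L) || any(d2 < 1L)) next
        n <- (k1^2 * 7L + 1L) * f1 + (k2^2 * f1 + 1L) * f2 +
          (p2[1] * p2[2] * f2 + 1L) * 128L + 129L * 64L + 65L * 2L
        if (n == target) {
          hits[[length(hits) + 1L]] <- data.frame(
            k1 = k1, k2 = k2, f1 = f1, f2 = f2, pad1 = pad1, pad2 = pad2,
            pool = pool, n_params = n, stringsAsFactors = FALSE)
          if (first_only) return(hits[[1L]])
        }
      }
  do.call(rbind, hits)
}

#' RNN (stacked LSTM) configuration
#'
#' Three stacked LSTM layers of 32 hidden units consuming the spectrogram
#' as a 20-step sequence of 22 x n_channels feature vectors (time bins as
#' the recurrent axis), with dropout between layers, and a softmax head on
#' the final step's top-layer state.
#'
#' @param input_shape input dimensions (freq, time, channels).
#' @param n_layers number of stacked LSTM layers.
#' @param hidden_units units per LSTM cell.
#' @param dropout inter-layer dropout rate.
#' @param init_sd weight-initialization SD.
#' @return an object of class `rnn_config`.
#' @export
rnn_config <- function(input_shape = c(22L, 20L, 7L), n_layers = 3L,
                       hidden_units = 32L, dropout = 0.25, init_sd = 0.1) {
  structure(list(input_shape = as.integer(input_shape),
                 n_layers = as.integer(n_layers),
                 hidden_units = as.integer(hidden_units),
                 n_steps = as.integer(input_shape[2]),
                 n_features = as.integer(input_shape[1] * input_shape[3]),
                 dropout = dropout, init_sd = init_sd, n_classes = 2L),
            class = "rnn_config")
}

#' Shallow network configuration
#'
#' Flatten, one 1024-unit rectifier layer, softmax head.
#'
#' @param input_shape input dimensions.
#' @param hidden_units hidden-layer size.
#' @param init_sd weight-initialization SD.
#' @return an object of class `snn_config`.
#' @export
snn_config <- function(input_shape = c(22L, 20L, 7L), hidden_units = 1024L,
                       init_sd = 0.1) {
  structure(list(input_shape = as.integer(input_shape),
                 hidden_units = as.integer(hidden_units),
                 init_sd = init_sd, n_classes = 2L),
            class = "snn_config")
}

new_model <- function(arch, config, params) {
  structure(list(arch = arch, config = config, params = params,
                 trained = FALSE, history = NULL, norm = NULL,
                 classes = c("HC", "ADHD")),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s, %d parameters, %s\n", toupper(x$arch),
              n_params(x$params),
              if (x$trained) sprintf("trained (%d epochs)", length(x$history$loss))
              else "untrained"))
  invisible(x)
}

#' Build the convolutional classifier
#'
#' @param config a [cnn_config()].
#' @param seed integer seed for the N(0, init_sd^2) initialization.
#' @return an untrained `trained_model`.
#' @export
#' @examples
#' m <- build_cnn(seed = 1)
#' n_model_params(m)   # 75106
build_cnn <- function(config = cnn_config(), seed = NULL) {
  stopifnot(inherits(config, "cnn_config"))
  dm <- cnn_dims(config)
  shapes <- list(
    W1 = c(config$k1, config$k1, config$input_shape[3], config$f1),
    b1 = config$f1,
    W2 = c(config$k2, config$k2, config$f1, config$f2),
    b2 = config$f2,
    Wd1 = c(dm$flat, config$dense_units[1]), bd1 = config$dense_units[1],
    Wd2 = c(config$dense_units[1], config$dense_units[2]),
    bd2 = config$dense_units[2],
    Wo = c(config$dense_units[2], 2L), bo = 2L)
  new_model("cnn", config, init_params(shapes, config$init_sd, seed))
}

#' Build the stacked-LSTM classifier
#' @param config an [rnn_config()].
#' @param seed initialization seed.
#' @return an untrained `trained_model`.
#' @export
build_rnn <- function(config = rnn_config(), seed = NULL) {
  stopifnot(inherits(config, "rnn_config"))
  h <- config$hidden_units
  shapes <- list()
  d <- config$n_features
  for (l in seq_len(config$n_layers)) {
    shapes[[paste0("Wx", l)]] <- c(d, 4L * h)
    shapes[[paste0("Wh", l)]] <- c(h, 4L * h)
    shapes[[paste0("b", l)]] <- 4L * h
    d <- h
  }
  shapes$Wo <- c(h, 2L)
  shapes$bo <- 2L
  new_model("rnn", config, init_params(shapes, config$init_sd, seed))
}

#' Build the shallow classifier
#' @param config an [snn_config()].
#' @param seed initialization seed.
#' @return an untrained `trained_model`.
#' @export
build_snn <- function(config = snn_config(), seed = NULL) {
  stopifnot(inherits(config, "snn_config"))
  d <- prod(config$input_shape)
  shapes <- list(W1 = c(d, config$hidden_units), b1 = config$hidden_units,
                 Wo = c(config$hidden_units, 2L), bo = 2L)
  new_model("snn", config, init_params(shapes, config$init_sd, seed))
}

#' Total trainable parameters of a model
#' @param model a `trained_model`.
#' @return integer count.
#' @export
n_model_params <- function(model) n_params(model$params)

pad_int <- function(pad) if (pad == "same") 1L else 0L

# ---- CNN forward / backward ------------------------------------------------

cnn_forward <- function(params, cfg, x, masks = NULL) {
  c1 <- cpp_conv2d_fwd(x, params$W1, params$b1, pad_int(cfg$pad1))
  r1 <- relu(c1)
  pl1 <- cpp_maxpool_fwd(r1)
  p1 <- apply_mask(pl1$y, masks$m1)
  c2 <- cpp_conv2d_fwd(p1, params$W2, params$b2, pad_int(cfg$pad2))
  r2 <- relu(c2)
  pl2 <- cpp_maxpool_fwd(r2)
  p2 <- apply_mask(pl2$y, masks$m2)
  n <- dim(x)[1]
  flat <- p2
  dim(flat) <- c(n, length(p2) / n)
  z1 <- sweep(flat %*% params$Wd1, 2, params$bd1, "+")
  a1 <- apply_mask(relu(z1), masks$m3)
  z2 <- sweep(a1 %*% params$Wd2, 2, params$bd2, "+")
  a2 <- apply_mask(relu(z2), masks$m4)
  logits <- sweep(a2 %*% params$Wo, 2, params$bo, "+")
  list(logits = logits, cache = list(x = x, c1 = c1, pl1 = pl1, p1 = p1,
                                     c2 = c2, pl2 = pl2, p2dim = dim(pl2$y),
                                     flat = flat, z1 = z1, a1 = a1,
                                     z2 = z2, a2 = a2))
}

cnn_backward <- function(params, cfg, cache, glogits, masks = NULL,
                         need_gx = FALSE) {
  g <- list()
  g$Wo <- crossprod(cache$a2, glogits)
  g$bo <- colSums(glogits)
  ga2 <- glogits %*% t(params$Wo)
  ga2 <- apply_mask(ga2, masks$m4)
  gz2 <- ga2 * (cache$z2 > 0)
  g$Wd2 <- crossprod(cache$a1, gz2)
  g$bd2 <- colSums(gz2)
  ga1 <- gz2 %*% t(params$Wd2)
  ga1 <- apply_mask(ga1, masks$m3)
  gz1 <- ga1 * (cache$z1 > 0)
  g$Wd1 <- crossprod(cache$flat, gz1)
  g$bd1 <- colSums(gz1)
  gflat <- gz1 %*% t(params$Wd1)
  gp2 <- gflat
  dim(gp2) <- cache$p2dim
  gp2 <- apply_mask(gp2, masks$m2)
  gr2 <- cpp_maxpool_bwd(cache$pl2$idx, gp2, dim(cache$c2))
  gc2 <- gr2 * (cache$c2 > 0)
  bw2 <- cpp_conv2d_bwd(cache$p1, params$W2, gc2, pad_int(cfg$pad2))
  g$W2 <- bw2$gw
  g$b2 <- bw2$gb
  gp1 <- apply_mask(bw2$gx, masks$m1)
  gr1 <- cpp_maxpool_bwd(cache$pl1$idx, gp1, dim(cache$c1))
  gc1 <- gr1 * (cache$c1 > 0)
  bw1 <- cpp_conv2d_bwd(cache$x, params$W1, gc1, pad_int(cfg$pad1))
  g$W1 <- bw1$gw
  g$b1 <- bw1$gb
  if (need_gx) attr(g, "gx") <- bw1$gx
  g
}

cnn_masks <- function(cfg, dims, n) {
  list(m1 = drop_mask(c(n, dims$pool1, cfg$f1), cfg$dropout_conv),
       m2 = drop_mask(c(n, dims$pool2, cfg$f2), cfg$dropout_conv),
       m3 = drop_mask(c(n, cfg$dense_units[1]), cfg$dropout_dense),
       m4 = drop_mask(c(n, cfg$dense_units[2]), cfg$dropout_dense))
}

# ---- SNN forward / backward ------------------------------------------------

snn_forward <- function(params, cfg, x, masks = NULL) {
  n <- dim(x)[1]
  flat <- x
  dim(flat) <- c(n, length(x) / n)
  z1 <- sweep(flat %*% params$W1, 2, params$b1, "+")
  a1 <- relu(z1)
  logits <- sweep(a1 %*% params$Wo, 2, params$bo, "+")
  list(logits = logits, cache = list(flat = flat, z1 = z1, a1 = a1,
                                     xdim = dim(x)))
}

snn_backward <- function(params, cfg, cache, glogits, masks = NULL,
                         need_gx = FALSE) {
  g <- list()
  g$Wo <- crossprod(cache$a1, glogits)
  g$bo <- colSums(glogits)
  ga1 <- glogits %*% t(params$Wo)
  gz1 <- ga1 * (cache$z1 > 0)
  g$W1 <- crossprod(cache$flat, gz1)
  g$b1 <- colSums(gz1)
  if (need_gx) {
    gx <- gz1 %*% t(params$W1)
    dim(gx) <- cache$xdim
    attr(g, "gx") <- gx
  }
  g
}

# ---- LSTM forward / backward (pure R BPTT) ---------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# x: (N, steps, features) sequence array.
rnn_forward <- function(params, cfg, x, masks = NULL) {
  n <- dim(x)[1]
  steps <- cfg$n_steps
  h_units <- cfg$hidden_units
  layers <- cfg$n_layers
  cache <- list()
  inp <- x
  for (l in seq_len(layers)) {
    Wx <- params[[paste0("Wx", l)]]
    Wh <- params[[paste0("Wh", l)]]
    b <- params[[paste0("b", l)]]
    h <- matrix(0, n, h_units)
    cc <- matrix(0, n, h_units)
    lc <- vector("list", steps)
    out <- array(0, dim = c(n, steps, h_units))
    for (t in seq_len(steps)) {
      xt <- matrix(inp[, t, ], n)
      z <- sweep(xt %*% Wx + h %*% Wh, 2, b, "+")
      i <- sigmoid(z[, 1:h_units, drop = FALSE])
      f <- sigmoid(z[, h_units + 1:h_units, drop = FALSE])
      o <- sigmoid(z[, 2 * h_units + 1:h_units, drop = FALSE])
      gg <- tanh(z[, 3 * h_units + 1:h_units, drop = FALSE])
      c_new <- f * cc + i * gg
      tc <- tanh(c_new)
      h_new <- o * tc
      lc[[t]] <- list(xt = xt, h_prev = h, c_prev = cc, i = i, f = f, o = o,
                      g = gg, c = c_new, tc = tc)
      h <- h_new
      cc <- c_new
      out[, t, ] <- h
    }
    mk <- masks[[paste0("m", l)]]
    if (!is.null(mk) && l < layers) out <- out * mk
    cache[[l]] <- list(steps = lc, out = out, inp = inp)
    inp <- out
  }
  h_last <- matrix(inp[, steps, ], n)
  logits <- sweep(h_last %*% params$Wo, 2, params$bo, "+")
  cache$h_last <- h_last
  list(logits = logits, cache = cache)
}

rnn_backward <- function(params, cfg, cache, glogits, masks = NULL,
                         need_gx = FALSE) {
  n <- nrow(glogits)
  steps <- cfg$n_steps
  h_units <- cfg$hidden_units
  layers <- cfg$n_layers
  g <- list()
  g$Wo <- crossprod(cache$h_last, glogits)
  g$bo <- colSums(glogits)
  # gradient wrt each layer's output sequence
  gout <- array(0, dim = c(n, steps, h_units))
  gout[, steps, ] <- glogits %*% t(params$Wo)
  for (l in rev(seq_len(layers))) {
    mk <- masks[[paste0("m", l)]]
    if (!is.null(mk) && l < layers) gout <- gout * mk
    lc <- cache[[l]]$steps
    Wx <- params[[paste0("Wx", l)]]
    Wh <- params[[paste0("Wh", l)]]
    gWx <- array(0, dim = dim(Wx))
    gWh <- array(0, dim = dim(Wh))
    gb <- numeric(4L * h_units)
    d_in <- nrow(Wx)
    ginp <- array(0, dim = c(n, steps, d_in))
    gh_next <- matrix(0, n, h_units)
    gc_next <- matrix(0, n, h_units)
    for (t in rev(seq_len(steps))) {
      s <- lc[[t]]
      gh <- gh_next + matrix(gout[, t, ], n)
      gc <- gc_next + gh * s$o * (1 - s$tc^2)
      gi <- gc * s$g * s$i * (1 - s$i)
      gf <- gc * s$c_prev * s$f * (1 - s$f)
      go <- gh * s$tc * s$o * (1 - s$o)
      gg <- gc * s$i * (1 - s$g^2)
      gz <- cbind(gi, gf, go, gg)
      gWx <- gWx + crossprod(s$xt, gz)
      gWh <- gWh + crossprod(s$h_prev, gz)
      gb <- gb + colSums(gz)
      ginp[, t, ] <- gz %*% t(Wx)
      gh_next <- gz %*% t(Wh)
      gc_next <- gc * s$f
    }
    g[[paste0("Wx", l)]] <- gWx
    g[[paste0("Wh", l)]] <- gWh
    g[[paste0("b", l)]] <- gb
    gout <- ginp
  }
  if (need_gx) attr(g, "gx") <- gout
  g
}

rnn_masks <- function(cfg, n) {
  ms <- list()
  for (l in seq_len(cfg$n_layers - 1L)) {
    ms[[paste0("m", l)]] <- drop_mask(c(n, cfg$n_steps, cfg$hidden_units),
                                      cfg$dropout)
  }
  ms
}

arch_funs <- function(arch) {
  switch(arch,
         cnn = list(fwd = cnn_forward, bwd = cnn_backward),
         snn = list(fwd = snn_forward, bwd = snn_backward),
         rnn = list(fwd = rnn_forward, bwd = rnn_backward),
         stop("unknown architecture: ", arch))
}

# Convert a frame array / frame_set to the input layout of an architecture.
model_input <- function(model, frames) {
  x <- if (inherits(frames, "frame_set")) frames$frames else frames
  assert_that(length(dim(x)) == 4L, "frames must be a 4-D array")
  if (model$arch == "rnn") {
    n <- dim(x)[1]
    x <- aperm(x, c(1, 3, 2, 4))            # time bins become the step axis
    dim(x) <- c(n, dim(x)[2], dim(x)[3] * dim(x)[4])
  }
  x
}

draw_masks <- function(model, n) {
  switch(model$arch,
         cnn = cnn_masks(model$config, cnn_dims(model$config), n),
         rnn = rnn_masks(model$config, n),
         snn = NULL)
}

#' Train a network on spectrogram frames
#'
#' Minimizes the (optionally per-sample weighted) softmax cross-entropy on
#' frames with Adam, dropout active during training only, and early
#' stopping on the training loss. Inputs are standardized cell-wise using
#' statistics of this training set only (stored in the model and re-applied
#' at prediction time, so no test statistics ever leak in).
#'
#' @param model an untrained model from [build_cnn()], [build_rnn()] or
#'   [build_snn()].
#' @param frames a `frame_set` or a `[n x freq x time x channel]` array.
#' @param labels per-frame class labels (2 levels; `ADHD` is the positive
#'   class when present).
#' @param sample_weights per-frame weights (default all 1).
#' @param config a [train_config()].
#' @return the trained model, with `$history$loss` per epoch.
#' @export
train <- function(model, frames, labels, sample_weights = NULL,
                  config = train_config()) {
  stopifnot(inherits(model, "trained_model"))
  x <- model_input(model, frames)
  n <- dim(x)[1]
  labels <- as.factor(labels)
  if (all(c("HC", "ADHD") %in% levels(labels))) {
    labels <- factor(as.character(labels), levels = c("HC", "ADHD"))
  }
  assert_that(nlevels(labels) == 2L && all(table(labels) > 0),
              "both classes must be present in the training labels")
  assert_that(length(labels) == n, "labels length must match frames")
  w <- sample_weights %||% rep(1, n)
  assert_that(length(w) == n, "sample_weights length must match frames")
  y <- as.integer(labels)
  model$classes <- levels(labels)

  # d14 standardization from training data only
  raw <- if (inherits(frames, "frame_set")) frames$frames else frames
  model$norm <- norm_stats(raw)
  x <- if (model$arch == "rnn") {
    model_input(model, apply_norm(raw, model$norm))
  } else {
    apply_norm(raw, model$norm)
  }

  funs <- arch_funs(model$arch)
  params <- model$params
  opt <- adam_init(params)
  losses <- numeric(0)
  best <- Inf
  wait <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      bl <- 0
      nb <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- if (model$arch == "rnn") {
          x[idx, , , drop = FALSE]
        } else {
          x[idx, , , , drop = FALSE]
        }
        masks <- draw_masks(model, length(idx))
        fw <- funs$fwd(params, model$config, xb, masks)
        sx <- softmax_xent(fw$logits, y[idx], w[idx])
        grads <- funs$bwd(params, model$config, fw$cache, sx$grad, masks)
        upd <- adam_step(params, grads, opt, config$learning_rate,
                         config$beta1, config$beta2)
        params <- upd$params
        opt <- upd$state
        bl <- bl + sx$loss
        nb <- nb + 1L
      }
      losses <- c(losses, bl / nb)
      if (losses[epoch] < best - config$min_delta) {
        best <- losses[epoch]
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  model$params <- params
  model$trained <- TRUE
  model$history <- list(loss = losses)
  model$train_config <- config
  model
}

#' Per-frame class probabilities
#'
#' Deterministic inference (dropout disabled): softmax probabilities for
#' each frame, columns named by class with `ADHD` the positive class.
#'
#' @param model a trained model.
#' @param frames a `frame_set` or 4-D array (same layout as training).
#' @param chunk frames per forward pass (memory control).
#' @return numeric matrix `[n x 2]` of probabilities summing to 1 per row.
#' @export
predict_frames <- function(model, frames, chunk = 512L) {
  stopifnot(inherits(model, "trained_model"))
  raw <- if (inherits(frames, "frame_set")) frames$frames else frames
  xs <- if (is.null(model$norm)) raw else apply_norm(raw, model$norm)
  x <- model_input(model, xs)
  n <- dim(x)[1]
  funs <- arch_funs(model$arch)
  out <- matrix(0, n, 2L, dimnames = list(NULL, model$classes))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    xb <- if (model$arch == "rnn") x[idx, , , drop = FALSE] else
      x[idx, , , , drop = FALSE]
    fw <- funs$fwd(model$params, model$config, xb, NULL)
    out[idx, ] <- softmax_rows(fw$logits)
  }
  out
}

# Gradient of a chosen logit w.r.t. the (standardized) input; used by the
# DeepDream module. x must already be in standardized units.
input_gradient <- function(model, x, target_class) {
  funs <- arch_funs(model$arch)
  xi <- if (model$arch == "rnn") model_input(model, x) else x
  fw <- funs$fwd(model$params, model$config, xi, NULL)
  g <- matrix(0, nrow(fw$logits), 2L)
  g[, target_class] <- 1
  grads <- funs$bwd(model$params, model$config, fw$cache, g, NULL,
                    need_gx = TRUE)
  gx <- attr(grads, "gx")
  if (model$arch == "rnn") {                     # back to (N, freq, time, ch)
    d <- dim(x)
    dim(gx) <- c(d[1], d[3], d[2], d[4])
    gx <- aperm(gx, c(1, 3, 2, 4))
  }
  list(logits = fw$logits, gx = gx)
}
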