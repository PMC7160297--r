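# Central-difference gradient checks of the network engine. Full tensors
# are checked for the compiled conv/pool primitives; the end-to-end CNN and
# LSTM losses are spot-checked on a random sample of coordinates per
# parameter tensor (and on the input, which the DeepDream stage relies on).

num_grad_at <- function(f, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, 0)
}

rel_err <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))

test_that("conv2d and maxpool backward match numerical gradients", {
  set.seed(42)
  x <- array(rnorm(2 * 5 * 6 * 3), c(2, 5, 6, 3))
  w <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  for (pad in 0:1) {
    y <- erspnet:::cpp_conv2d_fwd(x, w, b, pad)
    gy <- array(rnorm(length(y)), dim(y))
    bw <- erspnet:::cpp_conv2d_bwd(x, w, gy, pad)
    fx <- function(xx) sum(erspnet:::cpp_conv2d_fwd(xx, w, b, pad) * gy)
    fw <- function(ww) sum(erspnet:::cpp_conv2d_fwd(x, ww, b, pad) * gy)
    fb <- function(bb) sum(erspnet:::cpp_conv2d_fwd(x, w, bb, pad) * gy)
    expect_lt(rel_err(as.numeric(bw$gx), num_grad_at(fx, x, seq_along(x))), 1e-7)
    expect_lt(rel_err(as.numeric(bw$gw), num_grad_at(fw, w, seq_along(w))), 1e-7)
    expect_lt(rel_err(as.numeric(bw$gb), num_grad_at(fb, b, seq_along(b))), 1e-7)
  }
  pl <- erspnet:::cpp_maxpool_fwd(x)
  gy <- array(rnorm(length(pl$y)), dim(pl$y))
  gx <- erspnet:::cpp_maxpool_bwd(pl$idx, gy, dim(x))
  fp <- function(xx) sum(erspnet:::cpp_maxpool_fwd(xx)$y * gy)
  expect_lt(rel_err(as.numeric(gx), num_grad_at(fp, x, seq_along(x))), 1e-7)
})

test_that("CNN and LSTM loss gradients match numerical gradients", {
  set.seed(43)
  check_model <- function(m, fwd, x, y, w) {
    fw <- fwd(m$params, m$config, x, NULL)
    sx <- erspnet:::softmax_xent(fw$logits, y, w)
    bwd <- erspnet:::arch_funs(m$arch)$bwd
    gr <- bwd(m$params, m$config, fw$cache, sx$grad, NULL, need_gx = TRUE)
    loss_with <- function(params) {
      erspnet:::softmax_xent(fwd(params, m$config, x, NULL)$logits, y, w)$loss
    }
    for (k in names(m$params)) {
      idx <- sample(length(m$params[[k]]), min(15L, length(m$params[[k]])))
      f <- function(pp) { pr <- m$params; pr[[k]] <- pp; loss_with(pr) }
      expect_lt(rel_err(as.numeric(gr[[k]])[idx],
                        num_grad_at(f, m$params[[k]], idx)), 1e-5)
    }
    fx <- function(xx) {
      erspnet:::softmax_xent(fwd(m$params, m$config, xx, NULL)$logits, y, w)$loss
    }
    idx <- sample(length(x), 20L)
    expect_lt(rel_err(as.numeric(attr(gr, "gx"))[idx],
                      num_grad_at(fx, x, idx)), 1e-5)
  }

  cfg <- cnn_config(input_shape = c(8L, 8L, 2L), f1 = 4L, f2 = 3L,
                    target_param_total = NA)
  m <- build_cnn(cfg, seed = 1)
  check_model(m, erspnet:::cnn_forward,
              array(rnorm(3 * 8 * 8 * 2), c(3, 8, 8, 2)),
              c(1L, 2L, 1L), c(1, 1.5, 0.7))

  rcfg <- rnn_config(input_shape = c(4L, 5L, 2L), hidden_units = 6L,
                     dropout = 0)
  mr <- build_rnn(rcfg, seed = 2)
  check_model(mr, erspnet:::rnn_forward,
              array(rnorm(3 * 5 * 8), c(3, 5, 8)),
              c(2L, 1L, 2L), c(1, 1, 1))
})
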