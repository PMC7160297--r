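# A hand-built "shallow" model whose hidden layer is forced into its linear
# regime (large positive biases): the logit gradient is then the constant
# W1 %*% Wo[, target], giving a closed-form prediction for the dream output.
linear_probe_model <- function(seed = 1) {
  m <- build_snn(snn_config(input_shape = c(4L, 5L, 2L), hidden_units = 8L),
                 seed = seed)
  m$params$b1[] <- 100                     # keep every rectifier active
  m$trained <- TRUE
  m
}

test_that("dream follows the analytic gradient of a linearized model", {
  m <- linear_probe_model(seed = 3)
  g_const <- m$params$W1 %*% m$params$Wo[, 2]      # d logit_ADHD / d x
  step_dir <- g_const / mean(abs(g_const))
  p <- dream_params(n_iterations = 30L, step_size = 1, clamp = 1e6,
                    seed_mode = "null_image")
  out <- dream(m, p, target_class = "ADHD")
  want <- array(30 * step_dir, dim = c(4, 5, 2))
  expect_equal(as.numeric(out), as.numeric(want), tolerance = 1e-8)
  tr <- attr(out, "logit_trace")
  expect_length(tr, 31L)
  expect_true(all(diff(tr) > 0))                  # linear model: strictly up

  # n_iterations = 0 returns the seed unchanged
  p0 <- dream_params(n_iterations = 0L, seed_mode = "null_image")
  expect_true(all(dream(m, p0, "ADHD") == 0))
})

test_that("the target logit increases on a trained model", {
  tf <- toy_frames(12, shift = 1.5, seed = 4)
  m <- train(build_snn(seed = 5), tf$x, tf$y,
             config = train_config(max_epochs = 15L, seed = 6L))
  for (step in c(0.1, 1)) {
    out <- dream(m, dream_params(n_iterations = 30L, step_size = step,
                                 seed = 7L), "ADHD")
    tr <- attr(out, "logit_trace")
    expect_gte(tail(tr, 1), tr[1])
    if (step == 0.1) expect_true(all(diff(tr) > -1e-6))   # monotone at small step
  }
  # reproducibility
  o1 <- dream(m, dream_params(seed = 8L), "HC")
  o2 <- dream(m, dream_params(seed = 8L), "HC")
  expect_identical(o1, o2)
})

test_that("dream_over_folds averages per class and is order-invariant", {
  tf <- toy_frames(10, shift = 1.5, seed = 9)
  cfg <- train_config(max_epochs = 10L, seed = 10L)
  m1 <- train(build_snn(seed = 11), tf$x, tf$y, config = cfg)
  m2 <- train(build_snn(seed = 12), tf$x, tf$y, config = cfg)
  p <- dream_params(n_iterations = 10L, n_seeds = 2L, seed = 13L)

  single <- dream_over_folds(list(m1), dream_params(n_iterations = 10L,
                                                    n_seeds = 1L, seed = 13L))
  direct <- dream(m1, dream_params(n_iterations = 10L, n_seeds = 1L,
                                   seed = erspnet:::derive_seed(13L, 1L)),
                  "ADHD")
  expect_equal(single$class_stacks$ADHD, array(direct, dim = dim(direct)),
               tolerance = 1e-12, ignore_attr = TRUE)

  ab <- dream_over_folds(list(m1, m2), p)
  ba <- dream_over_folds(list(m2, m1), p)
  expect_equal(ab$difference, ba$difference, tolerance = 1e-12)
  expect_equal(ab$difference, ab$class_maps$ADHD - ab$class_maps$HC)
  expect_error(dream_over_folds(list(), p), "non-empty")
})

test_that("bandtime_summary selects the requested cells", {
  m <- matrix(seq_len(22 * 20), 22, 20)
  expect_equal(bandtime_summary(m, c(3, 20), c(0, 800)), mean(m))
  expect_error(bandtime_summary(m, c(25, 30), c(0, 800)), "no cells")
  # a single-cell window: frequency bin nearest 10 Hz, time bin centred 60 ms
  f <- log_spaced_freqs(ersp_params())
  fi <- which(f >= 9.5 & f <= 10.2)        # exactly the bin nearest 10 Hz
  expect_length(fi, 1L)
  expect_equal(bandtime_summary(m, c(9.5, 10.2), c(41, 79)),
               mean(m[fi, 2]))
})
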