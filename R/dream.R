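#' DeepDream parameters
#'
#' Activation-maximization settings: starting from a null (all-zero) or
#' random-noise image in standardized input units, the input is pushed
#' along the gradient of the target class logit for `n_iterations` steps of
#' `step_size`, the gradient being normalized by its mean absolute value at
#' each iteration (the standard DeepDream convention that makes "steps of
#' 1" meaningful), and the image clamped to `clamp` standardized units.
#'
#' @param n_iterations gradient-ascent iterations (default 30).
#' @param step_size step length after gradient normalization (default 1).
#' @param seed_mode `"null_image"` or `"random_noise"`.
#' @param n_seeds number of random initializations averaged per class.
#' @param clamp symmetric clamp on the synthesized image, standardized
#'   units.
#' @param seed integer RNG seed for the noise initializations.
#' @return an object of class `dream_params`.
#' @export
dream_params <- function(n_iterations = 30L, step_size = 1,
                         seed_mode = c("random_noise", "null_image"),
                         n_seeds = 8L, clamp = 6, seed = NULL) {
  assert_that(n_iterations >= 0, "`n_iterations` must be >= 0")
  assert_positive(step_size, "step_size")
  assert_count(n_seeds, "n_seeds")
  structure(list(n_iterations = as.integer(n_iterations),
                 step_size = step_size,
                 seed_mode = match.arg(seed_mode),
                 n_seeds = as.integer(n_seeds), clamp = clamp,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "dream_params")
}

#' Synthesize a class-maximizing input by gradient ascent
#'
#' @param model a trained model.
#' @param params a [dream_params()].
#' @param target_class class index (1 = HC, 2 = ADHD) or class name.
#' @param init optional explicit starting image (overrides `seed_mode`).
#' @return the synthesized input array `[freq x time x channels]` in
#'   standardized units, with attribute `logit_trace` (target logit per
#'   iteration, including the initial value).
#' @export
dream <- function(model, params = dream_params(), target_class = "ADHD",
                  init = NULL) {
  stopifnot(inherits(model, "trained_model"), model$trained)
  if (is.character(target_class)) {
    target_class <- match(target_class, model$classes)
  }
  assert_that(target_class %in% c(1L, 2L), "invalid target class")
  shape <- if (model$arch == "rnn") model$config$input_shape else
    model$config$input_shape
  x <- with_seed(params$seed, {
    if (!is.null(init)) {
      init
    } else if (params$seed_mode == "null_image") {
      array(0, dim = shape)
    } else {
      array(rnorm(prod(shape), 0, 0.1), dim = shape)
    }
  })
  xb <- array(x, dim = c(1L, shape))
  trace <- numeric(params$n_iterations + 1L)
  fell_back <- FALSE
  for (it in seq_len(params$n_iterations + 1L)) {
    ig <- input_gradient(model, xb, target_class)
    trace[it] <- ig$logits[1, target_class]
    if (it > params$n_iterations) break
    g <- ig$gx
    ma <- mean(abs(g))
    if (ma == 0) {
      if (!fell_back && params$seed_mode == "null_image") {
        warning("zero gradient at the null start; falling back to random noise")
        xb <- with_seed(params$seed,
                        array(rnorm(prod(shape), 0, 0.1), dim = c(1L, shape)))
        fell_back <- TRUE
        next
      }
      break                                    # dead gradient, stop early
    }
    xb <- xb + params$step_size * g / ma
    xb[xb > params$clamp] <- params$clamp
    xb[xb < -params$clamp] <- -params$clamp
  }
  out <- array(xb, dim = shape)
  attr(out, "logit_trace") <- trace
  out
}

#' Average DeepDream maps over fold models
#'
#' Runs [dream()] for both classes on every model (and `n_seeds` noise
#' seeds each), averages, and assembles per-class stacks, channel-averaged
#' maps, and the ADHD-minus-HC difference map.
#'
#' @param models list of trained fold models.
#' @param params a [dream_params()].
#' @return object of class `dream_map`: `class_stacks` (list of
#'   `[freq x time x ch]` arrays named HC/ADHD), `class_maps`
#'   (channel-averaged `[freq x time]`), `difference`
#'   (`ADHD - HC`, channel-averaged), `freqs`/`time_centres` if supplied by
#'   the caller later, `n_models`, `n_seeds`.
#' @export
dream_over_folds <- function(models, params = dream_params()) {
  assert_that(length(models) >= 1, "`models` must be non-empty")
  shape <- models[[1]]$config$input_shape
  acc <- list(HC = array(0, dim = shape), ADHD = array(0, dim = shape))
  total <- 0L
  for (mi in seq_along(models)) {
    for (s in seq_len(params$n_seeds)) {
      p_s <- params
      # the seed stream depends on the noise-seed index only, so the
      # average is invariant to the order of the models
      p_s$seed <- derive_seed(params$seed %||% 0L, s)
      for (cls in c("HC", "ADHD")) {
        d <- dream(models[[mi]], p_s, cls)
        attributes(d) <- list(dim = dim(d))
        acc[[cls]] <- acc[[cls]] + d
      }
      total <- total + 1L
    }
  }
  stacks <- lapply(acc, function(a) a / total)
  maps <- lapply(stacks, function(a) apply(a, c(1, 2), mean))
  structure(list(class_stacks = stacks, class_maps = maps,
                 difference = maps$ADHD - maps$HC,
                 n_models = length(models), n_seeds = params$n_seeds),
            class = "dream_map")
}

#' Mean of a difference map over a frequency band and time window
#'
#' @param map a `dream_map` (its `difference` is used) or a plain
#'   `[freq x time]` matrix.
#' @param band Hz interval.
#' @param window ms interval (bin centres inside it are selected).
#' @param freqs,time_centres axes; default to the canonical ERSP axes.
#' @return mean dB over the selected cells.
#' @export
bandtime_summary <- function(map, band, window,
                             freqs = log_spaced_freqs(ersp_params()),
                             time_centres = NULL) {
  m <- if (inherits(map, "dream_map")) map$difference else map
  if (is.null(time_centres)) {
    p <- ersp_params()
    edges <- seq(p$t_window[1], p$t_window[2], length.out = p$n_times + 1L)
    time_centres <- (edges[-1] + edges[-length(edges)]) / 2
  }
  fi <- which(freqs >= band[1] & freqs <= band[2])
  ti <- which(time_centres >= window[1] & time_centres <= window[2])
  assert_that(length(fi) > 0 && length(ti) > 0,
              "band/window selects no cells")
  mean(m[fi, ti])
}

#' Mean real-data spectrogram difference map (ADHD minus HC)
#'
#' Channel-averaged mean dB difference between the ADHD and HC frames of a
#' `frame_set` — the empirical counterpart the dream map is compared
#' against.
#'
#' @param frames a `frame_set`.
#' @return `[freq x time]` matrix of mean dB differences.
#' @export
ersp_group_difference <- function(frames) {
  stopifnot(inherits(frames, "frame_set"))
  adhd <- frames$frames[frames$group == "ADHD", , , , drop = FALSE]
  hc <- frames$frames[frames$group == "HC", , , , drop = FALSE]
  assert_that(dim(adhd)[1] > 0 && dim(hc)[1] > 0, "both groups required")
  apply(adhd, c(2, 3), mean) - apply(hc, c(2, 3), mean)
}
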