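#' @useDynLib erspnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rgamma rbinom glm binomial predict fft
#'   pt qnorm sd var coef quantile setNames nextn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous RNG state so that simulation functions are
#' deterministic given their `seed` argument without disturbing the session.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed (< 2^31) from a base seed and a stream index.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483587)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

assert_count <- function(x, name, min = 1L) {
  assert_that(is.numeric(x) && length(x) == 1L && !is.na(x) &&
                x == floor(x) && x >= min,
              sprintf("`%s` must be a single integer >= %d", name, min))
}

assert_positive <- function(x, name) {
  assert_that(is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0,
              sprintf("`%s` must be a single positive number", name))
}

#' EEG channel montage used throughout the pipeline
#'
#' Seven positions covering the fronto-parietal executive control network,
#' in the fixed stacking order used by every array in the package.
#'
#' @return character vector of channel names.
#' @export
#' @examples
#' eeg_channels()
eeg_channels <- function() c("Fp1", "Fp2", "F3", "Fz", "F4", "P3", "P4")
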