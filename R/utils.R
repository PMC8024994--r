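#' @importFrom rlang abort warn %||% .data
#' @importFrom stats rnorm runif sd fft approx t.test qnorm
#' @importFrom utils head tail
NULL

abort_invalid <- function(msg) {
  abort(msg, class = "tactileavatar_invalid_argument")
}

abort_estimation <- function(msg) {
  abort(msg, class = "tactileavatar_estimation_failure")
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    cmp <- if (strict) ">" else ">="
    abort_invalid(sprintf("`%s` must be a single finite number %s %s", name, cmp, min))
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    abort_invalid(sprintf("`%s` must be a positive integer", name))
  }
  invisible(as.integer(x))
}

#' Derive a stage-specific seed from a master seed
#'
#' Deterministically maps a master seed and a stage label to a new 31-bit
#' seed, so that every stochastic stage of an experiment (library, corpus,
#' cohort, network init, shuffling) draws from an independent stream while
#' the whole run remains reproducible from one integer.
#'
#' @param seed Master seed (single integer).
#' @param stage Character label of the stage.
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "corpus")
derive_seed <- function(seed, stage) {
  check_number(seed, "seed")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 69069 + h * 12345) %% (2^31 - 1))
}

# probability-vector check shared by decision/histogram code
check_prob <- function(p, name = "activation", tol = 1e-6) {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p)) {
    abort_invalid(sprintf("`%s` must be a numeric probability vector", name))
  }
  if (any(p < -tol) || abs(sum(p) - 1) > tol) {
    abort_invalid(sprintf("`%s` must be non-negative and sum to 1", name))
  }
  invisible(p)
}
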