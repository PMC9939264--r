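# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state so
#' package functions never disturb the session's random number stream.
#'
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a master seed and string labels
#'
#' Folds the labels into the master seed with a small polynomial hash so
#' every stochastic stage (census simulation, each bootstrap run, each
#' oversize re-run) draws from an independent, replayable stream.
#' Result is always in [1, 2^31 - 2].
#'
#' @noRd
derive_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% 2147483647
  as.integer(h) + 1L
}

stop_if_not_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

stop_if_not_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

first_of_month <- function(d) as.Date(format(d, "%Y-%m-01"))

add_months <- function(d, k) seq(d, by = paste(k, "months"), length.out = 2L)[2L]
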