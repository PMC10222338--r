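# internal helpers: argument checking and seed bookkeeping

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("invalid parameter: `%s` must be a single finite number", name)
  if (positive && x <= 0)
    stopf("invalid parameter: `%s` must be > 0 (got %g)", name, x)
  if (nonneg && x < 0)
    stopf("invalid parameter: `%s` must be >= 0 (got %g)", name, x)
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stopf("invalid parameter: `%s` must be an integer count", name)
  if (x < min)
    stopf("invalid parameter: `%s` must be >= %d (got %d)", name, min, as.integer(x))
  invisible(as.integer(x))
}

check_fraction <- function(x, name) {
  check_number(x, name)
  if (x < 0 || x > 1)
    stopf("invalid parameter: `%s` must lie in [0, 1] (got %g)", name, x)
  invisible(x)
}

#' Derive a child seed from a master seed
#'
#' Every source of randomness in the package is seeded deterministically from
#' a single master seed via this splittable scheme, so that whole workflows
#' are reproducible from one integer while replicates, switches and bootstrap
#' resamples remain statistically independent.  The result is always in
#' `[1, 2^31 - 2]`.
#'
#' @param seed Master seed (non-negative integer-valued number).
#' @param tag Character purpose tag (e.g. `"equilibrate"`, `"switch"`).
#' @param index Integer stream index (e.g. replicate or switch number).
#' @return A single integer-valued numeric seed.
#' @examples
#' child_seed(42, "equilibrate", 1)
#' @export
child_seed <- function(seed, tag, index = 0L) {
  check_number(seed, "seed", nonneg = TRUE)
  check_number(index, "index", nonneg = TRUE)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; all arithmetic exact in doubles
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 131 + ch) %% m
  x <- (seed %% m + 1) %% m
  x <- (x * 48271) %% m
  x <- (x + h) %% m
  x <- (x * 48271) %% m
  x <- (x + index %% m) %% m
  x <- (x * 69621) %% m
  x <- (x * 48271) %% m
  if (x == 0) x <- 1
  x
}
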