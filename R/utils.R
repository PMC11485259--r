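# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  }
  invisible(x)
}

assert_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("an explicit integer `seed` is required for stochastic operations", call. = FALSE)
  }
  invisible(as.integer(seed))
}

#' Derive a child seed from a global seed and a string key
#'
#' One global seed expands to per-operation child seeds by a fixed arithmetic
#' derivation, so pipeline stages are reproducible yet use independent streams.
#' The result is always in `[1, 2^31 - 2]`.
#'
#' @param seed integer master seed.
#' @param key character label of the consuming operation.
#' @return integer child seed.
#' @export
derive_seed <- function(seed, key) {
  assert_seed(seed)
  stopifnot(is.character(key), length(key) == 1L)
  cp <- utf8ToInt(key)
  h <- 0
  for (i in seq_along(cp)) h <- (h * 131 + cp[i]) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 2147483629 * 48271 + h) %% 2147483629 + 1)
}

# Draw n multivariate-normal rows with covariance `sigma` (optionally from a
# precomputed upper Cholesky factor).
rmvn <- function(n, sigma = NULL, chol_sigma = NULL) {
  R <- chol_sigma %||% chol(sigma)
  p <- ncol(R)
  matrix(stats::rnorm(n * p), n, p) %*% R
}

# stable hash of an R object for run provenance (no external digest dependency)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  cp <- utf8ToInt(as.character(s))
  h1 <- 5381; h2 <- 52711
  for (i in seq_along(cp)) {
    h1 <- (h1 * 33 + cp[i]) %% 4294967291
    h2 <- (h2 * 31 + cp[i]) %% 4294967279
  }
  sprintf("%08x%08x", as.integer(h1 %% 2147483647), as.integer(h2 %% 2147483647))
}

is_binary01 <- function(x) all(x %in% c(0, 1))
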