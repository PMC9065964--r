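#' @keywords internal
"_PACKAGE"

# Numerical tie tolerance for threshold comparisons (death / establishment /
# window-length rules).  Absolute, on environment units of magnitude ~1;
# large enough to absorb round-off in t = i*dt arithmetic, far below any
# ecologically meaningful difference.
.woo_tie_tol <- 1e-9

#' Evaluate an expression with a temporarily fixed RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so that seeded
#' generators do not disturb the global RNG stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive per-replicate child seeds from a master seed
#'
#' Counter-based: replicate r always receives the same child seed for a
#' given master seed, independent of how many replicates are requested or
#' in which order they run.
#'
#' @param master_seed single integer.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
child_seeds <- function(master_seed, n) {
  stopifnot(n >= 1)
  # splitmix-style integer hash of (master, counter), kept in 32-bit range
  m <- as.double(as.integer(master_seed)) %% 2147483647
  r <- seq_len(n)
  x <- (m * 48271 + r * 69621) %% 2147483647
  x <- (x * 16807) %% 2147483647
  as.integer(x %% 2147483645 + 1)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return named numeric vector `c(lower, upper)`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# internal: check a scalar numeric argument
.check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
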