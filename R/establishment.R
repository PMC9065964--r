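# Monte-Carlo establishment experiments on simulated trajectories.
#
# An establishment attempt places a young organism at the opening sample of
# a benign window and steps it forward: it dies at the first sample where
# its tolerance falls below the environment, and establishes once its
# tolerance reaches the maximum of the remaining series (beyond which death
# is impossible).  Comparisons carry a 1e-9 tie tolerance so that the
# marginal organism with lambda = lambda_crit establishes despite
# floating-point round-off in t = i*dt arithmetic.

# suffix running maximum of the environment, used for the early-success rule
.suffix_max <- function(values) rev(cummax(rev(values)))

#' Simulate a single establishment attempt
#'
#' The organism incepts at `inception_time` (which must fall on a sample
#' with `E < T0`: inception happens only in benign conditions) and develops
#' tolerance per `model`.  Walking forward sample by sample it
#'
#' * dies at the first sample where tolerance < environment (strict, with
#'   tie tolerance: survival at equality), or
#' * establishes once tolerance >= the maximum of the environment over all
#'   remaining samples (no later sample can kill it), or
#' * is censored if the series ends while it is alive but not yet
#'   established.
#'
#' @param traj a [signal_trajectory()].
#' @param model a [tolerance_model()].
#' @param inception_time time of the inception sample (must coincide with a
#'   sample time of `traj`).
#' @param suffix_max optional precomputed suffix maximum of `traj$values`
#'   (performance aid when attempting many inceptions on one trajectory).
#' @return an `establishment_outcome`: list with `established` (logical),
#'   `censored` (logical), `inception_time`, `failure_time` (`NA` unless
#'   death), `establishment_time` (`NA` unless established).  Exactly one
#'   of `established` / `failure_time` is set unless censored.
#' @examples
#' p <- regular_dichotomous_params(0, 1, tau_low = 10, tau_high = 10)
#' traj <- generate_regular_dichotomous(p, duration = 60, dt = 0.1)
#' m <- tolerance_model(T0 = 1/6, lambda = 0.1)
#' simulate_attempt(traj, m, inception_time = 0)
#' @export
simulate_attempt <- function(traj, model, inception_time, suffix_max = NULL) {
  stopifnot(inherits(traj, "signal_trajectory"),
            inherits(model, "tolerance_model"))
  n <- length(traj$values)
  i0 <- round((inception_time - traj$t0) / traj$dt) + 1
  if (i0 < 1 || i0 > n ||
      abs(traj$t0 + (i0 - 1) * traj$dt - inception_time) > 1e-6 * traj$dt) {
    stop("`inception_time` does not fall on a sample of the trajectory",
         call. = FALSE)
  }
  i0 <- as.integer(i0)
  if (traj$values[i0] >= model$T0) {
    stop("inception in hostile conditions: E(inception_time) >= T0",
         call. = FALSE)
  }
  if (is.null(suffix_max)) suffix_max <- .suffix_max(traj$values)
  tol_eps <- .woo_tie_tol
  chunk <- 1024L
  s <- i0
  while (s <= n) {
    e <- min(n, s + chunk - 1L)
    ii <- s:e
    tol <- tolerance_at(model, (ii - i0) * traj$dt)
    death <- which(tol < traj$values[ii] - tol_eps)
    # establishment requires clearing the maximum of the remaining series
    # at a sample that still has a future: reaching the final sample alive
    # without having established is censoring, not success
    estab <- which(tol >= suffix_max[ii] - tol_eps & ii < n)
    d <- if (length(death)) death[1L] else Inf
    g <- if (length(estab)) estab[1L] else Inf
    if (g <= d && is.finite(g)) {
      t_est <- traj$t0 + (ii[g] - 1L) * traj$dt
      return(structure(list(established = TRUE, censored = FALSE,
                            inception_time = inception_time,
                            failure_time = NA_real_,
                            establishment_time = t_est),
                       class = "establishment_outcome"))
    }
    if (is.finite(d)) {
      t_die <- traj$t0 + (ii[d] - 1L) * traj$dt
      return(structure(list(established = FALSE, censored = FALSE,
                            inception_time = inception_time,
                            failure_time = t_die,
                            establishment_time = NA_real_),
                       class = "establishment_outcome"))
    }
    s <- e + 1L
  }
  structure(list(established = FALSE, censored = TRUE,
                 inception_time = inception_time,
                 failure_time = NA_real_, establishment_time = NA_real_),
            class = "establishment_outcome")
}

#' @export
print.establishment_outcome <- function(x, ...) {
  status <- if (x$established) {
    sprintf("established at t = %g", x$establishment_time)
  } else if (x$censored) {
    "censored (alive at series end, not established)"
  } else {
    sprintf("died at t = %g", x$failure_time)
  }
  cat(sprintf("<establishment_outcome> inception t = %g: %s\n",
              x$inception_time, status))
  invisible(x)
}

#' Monte-Carlo estimate of the window-of-opportunity probability under DMN
#'
#' Generates DMN trajectories until `n_windows` completed (non-censored)
#' benign windows have been observed and reports the fraction whose
#' duration reaches the critical window `tau_crit` of the organism, with a
#' Wilson 95% confidence interval.  This is the simulation counterpart of
#' [p_woo_analytic()].
#'
#' @param dmn a [dmn_params()] object; its `n_steps` sets the chunk length
#'   of the generated trajectories.
#' @param model a [tolerance_model()].
#' @param n_windows number of completed windows to accumulate (>= 100).
#' @param seed integer master seed.
#' @return list with `estimate`, `ci` (Wilson 95%), `n_windows`,
#'   `n_established`, `tau_crit`.
#' @examples
#' dmn <- dmn_params(0, 1, 0.1, 0.2, dt = 0.05, n_steps = 20000)
#' m <- tolerance_model(1/6, 0.1)
#' monte_carlo_p_woo(dmn, m, n_windows = 500, seed = 1)
#' @export
monte_carlo_p_woo <- function(dmn, model, n_windows, seed) {
  stopifnot(inherits(dmn, "dmn_params"), inherits(model, "tolerance_model"))
  if (n_windows < 100) stop("`n_windows` must be >= 100", call. = FALSE)
  tau_crit <- required_window(model, dmn$E_high)
  if (is.infinite(tau_crit)) {
    return(list(estimate = 0, ci = c(lower = 0, upper = 0),
                n_windows = as.integer(n_windows), n_established = 0L,
                tau_crit = Inf))
  }
  durations <- numeric(0)
  chunk_seeds <- child_seeds(seed, 1000L)
  i <- 0L
  threshold <- (dmn$E_low + dmn$E_high) / 2
  while (length(durations) < n_windows) {
    i <- i + 1L
    if (i > length(chunk_seeds)) stop("window accumulation did not converge")
    traj <- generate_dmn(dmn, seed = chunk_seeds[i])
    w <- extract_benign_windows(traj, threshold)
    durations <- c(durations, w$duration[!w$censored])
  }
  durations <- durations[seq_len(n_windows)]
  n_est <- sum(durations >= tau_crit - .woo_tie_tol)
  list(estimate = n_est / n_windows,
       ci = wilson_interval(n_est, n_windows),
       n_windows = as.integer(n_windows), n_established = as.integer(n_est),
       tau_crit = tau_crit)
}

#' Fraction of attainable windows on correlated Gaussian signals
#'
#' For each replicate trajectory: benign windows (`E < T0`) are extracted,
#' an establishment attempt is run at each window's opening sample, and the
#' fraction of attempts that establish is recorded.  Replicates without any
#' window contribute no fraction and are counted separately (their absence
#' of opportunity is a different phenomenon from failed attempts).
#' Censored attempts (alive at series end but not established) count as not
#' attainable.
#'
#' @param oun an [oun_params()] object.
#' @param model a [tolerance_model()]; its `T0` defines the benign
#'   threshold.
#' @param n_replicates number of replicate trajectories (>= 2).
#' @param seed integer master seed; replicate r always receives the same
#'   child seed, so results are reproducible and extensible.
#' @return an object of class `fwoo_estimate`: list with `f_woo` (mean
#'   fraction across replicates with windows, `NA` if none had windows),
#'   `interdecile` (10th and 90th percentile of replicate fractions),
#'   `fractions`, `n_windows_total`, `n_censored_attempts`,
#'   `n_replicates`, `n_replicates_with_windows`.
#' @examples
#' p <- oun_params(1, tau_approx = 1, dt = 0.01, n_steps = 1000,
#'                 target_variance = 0.5, drift = "relaxation")
#' m <- tolerance_model(1/6, 1)
#' fraction_attainable_windows(p, m, n_replicates = 20, seed = 1)
#' @export
fraction_attainable_windows <- function(oun, model, n_replicates, seed) {
  stopifnot(inherits(oun, "oun_params"), inherits(model, "tolerance_model"))
  if (n_replicates < 2) stop("`n_replicates` must be >= 2", call. = FALSE)
  seeds <- child_seeds(seed, n_replicates)
  fractions <- rep(NA_real_, n_replicates)
  n_windows_total <- 0L
  n_censored <- 0L
  for (r in seq_len(n_replicates)) {
    traj <- generate_oun(oun, seed = seeds[r])
    res <- .attempt_all_windows(traj, model)
    n_windows_total <- n_windows_total + res$n_windows
    n_censored <- n_censored + res$n_censored
    if (res$n_windows > 0) fractions[r] <- res$n_established / res$n_windows
  }
  .fwoo_estimate(fractions, n_windows_total, n_censored, n_replicates)
}

# run one attempt per benign-window opening on a trajectory
.attempt_all_windows <- function(traj, model, suffix_max = NULL) {
  w <- extract_benign_windows(traj, model$T0)
  if (nrow(w) == 0) {
    return(list(n_windows = 0L, n_established = 0L, n_censored = 0L))
  }
  if (is.null(suffix_max)) suffix_max <- .suffix_max(traj$values)
  est <- 0L; cens <- 0L
  for (j in seq_len(nrow(w))) {
    out <- simulate_attempt(traj, model, w$start[j], suffix_max = suffix_max)
    if (out$established) est <- est + 1L
    if (out$censored) cens <- cens + 1L
  }
  list(n_windows = nrow(w), n_established = est, n_censored = cens)
}

.fwoo_estimate <- function(fractions, n_windows_total, n_censored,
                           n_replicates) {
  with_w <- sum(!is.na(fractions))
  if (with_w == 0) {
    f <- NA_real_; idr <- c(p10 = NA_real_, p90 = NA_real_)
  } else {
    obs <- fractions[!is.na(fractions)]
    f <- mean(obs)
    q <- stats::quantile(obs, c(0.1, 0.9), names = FALSE)
    idr <- c(p10 = q[1], p90 = q[2])
  }
  structure(list(f_woo = f, interdecile = idr, fractions = fractions,
                 n_windows_total = as.integer(n_windows_total),
                 n_censored_attempts = as.integer(n_censored),
                 n_replicates = as.integer(n_replicates),
                 n_replicates_with_windows = as.integer(with_w)),
            class = "fwoo_estimate")
}

#' @export
print.fwoo_estimate <- function(x, ...) {
  if (is.na(x$f_woo)) {
    cat(sprintf("<fwoo_estimate> no potential windows in any of %d replicates\n",
                x$n_replicates))
  } else {
    cat(sprintf(paste0("<fwoo_estimate> f_WoO = %.3f (interdecile %.3f-%.3f), ",
                       "%d windows over %d/%d replicates\n"),
                x$f_woo, x$interdecile[1], x$interdecile[2],
                x$n_windows_total, x$n_replicates_with_windows,
                x$n_replicates))
  }
  invisible(x)
}

#' f_WoO as a function of growth rate, with common random numbers
#'
#' Evaluates [fraction_attainable_windows()] over a grid of growth rates
#' while reusing the same replicate trajectories for every `lambda`
#' (common random numbers), so that differences along the grid reflect the
#' organism, not Monte-Carlo noise.
#'
#' @param oun an [oun_params()] object.
#' @param T0 initial tolerance (defines the benign threshold).
#' @param lambda_values vector of growth rates.
#' @param growth growth type.
#' @param n_replicates replicate trajectories per grid point.
#' @param seed integer master seed.
#' @return data frame with columns `lambda`, `f_woo`, `p10`, `p90`,
#'   `n_windows`, `n_replicates_with_windows`.
#' @export
fwoo_curve <- function(oun, T0, lambda_values,
                       growth = c("linear", "exponential"),
                       n_replicates, seed) {
  stopifnot(inherits(oun, "oun_params"))
  growth <- match.arg(growth)
  seeds <- child_seeds(seed, n_replicates)
  trajs <- lapply(seeds, function(s) generate_oun(oun, seed = s))
  sufmax <- lapply(trajs, function(tr) .suffix_max(tr$values))
  out <- lapply(lambda_values, function(lam) {
    model <- tolerance_model(T0, lam, growth)
    fractions <- rep(NA_real_, n_replicates)
    nw <- 0L; nc <- 0L
    for (r in seq_len(n_replicates)) {
      res <- .attempt_all_windows(trajs[[r]], model, suffix_max = sufmax[[r]])
      nw <- nw + res$n_windows
      nc <- nc + res$n_censored
      if (res$n_windows > 0) fractions[r] <- res$n_established / res$n_windows
    }
    est <- .fwoo_estimate(fractions, nw, nc, n_replicates)
    data.frame(lambda = lam, f_woo = est$f_woo,
               p10 = est$interdecile[1], p90 = est$interdecile[2],
               n_windows = est$n_windows_total,
               n_replicates_with_windows = est$n_replicates_with_windows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
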