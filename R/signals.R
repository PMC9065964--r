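# Environmental signal generators and window extraction.
#
# Three signal classes are supported: a regular dichotomous square wave, a
# two-state dichotomous Markov noise (DMN, the random telegraph process) and
# a discrete Ornstein-Uhlenbeck-type correlated Gaussian signal (red noise).

#' Parameters of a regular dichotomous environment
#'
#' A deterministic square wave alternating between a benign level `E_low`
#' (held for `tau_low`) and a harsh level `E_high` (held for `tau_high`).
#'
#' @param E_low benign environment level (stressor units).
#' @param E_high harsh environment level; must exceed `E_low`.
#' @param tau_low duration of the benign phase (time units), > 0.
#' @param tau_high duration of the harsh phase (time units), > 0.
#' @return an object of class `regular_dichotomous_params`.
#' @examples
#' regular_dichotomous_params(0, 1, tau_low = 2, tau_high = 1)
#' @export
regular_dichotomous_params <- function(E_low, E_high, tau_low, tau_high) {
  .check_scalar(E_low, "E_low"); .check_scalar(E_high, "E_high")
  .check_scalar(tau_low, "tau_low"); .check_scalar(tau_high, "tau_high")
  if (E_high <= E_low) stop("`E_high` must exceed `E_low`", call. = FALSE)
  if (tau_low <= 0 || tau_high <= 0) {
    stop("`tau_low` and `tau_high` must be positive", call. = FALSE)
  }
  structure(list(E_low = E_low, E_high = E_high,
                 tau_low = tau_low, tau_high = tau_high),
            class = "regular_dichotomous_params")
}

#' Parameters of dichotomous Markov noise (DMN)
#'
#' A two-state Markov signal: in the low state the probability of switching
#' within a step of length `dt` is `k_low * dt`, in the high state
#' `k_high * dt`.  Waiting times are therefore (discretized) exponential with
#' means `1/k_low` and `1/k_high`.
#'
#' @param E_low,E_high the two environment levels, `E_high > E_low`.
#' @param k_low transition rate out of the low state (1/time), > 0.
#' @param k_high transition rate out of the high state (1/time), > 0.
#' @param dt sampling step (time units), > 0.  `k * dt` must stay below 1;
#'   values above 0.1 trigger a warning because the discretized waiting-time
#'   distribution then departs visibly from the exponential.
#' @param n_steps series length in steps.
#' @return an object of class `dmn_params`.
#' @examples
#' dmn_params(0, 1, k_low = 0.1, k_high = 0.2, dt = 0.01, n_steps = 1e4)
#' @export
dmn_params <- function(E_low, E_high, k_low, k_high, dt, n_steps) {
  .check_scalar(E_low, "E_low"); .check_scalar(E_high, "E_high")
  .check_scalar(k_low, "k_low"); .check_scalar(k_high, "k_high")
  .check_scalar(dt, "dt"); .check_scalar(n_steps, "n_steps")
  if (E_high <= E_low) stop("`E_high` must exceed `E_low`", call. = FALSE)
  if (k_low <= 0 || k_high <= 0) stop("transition rates must be positive", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (n_steps < 2) stop("`n_steps` must be at least 2", call. = FALSE)
  if (max(k_low, k_high) * dt >= 1) {
    stop("k * dt >= 1: time step too coarse for the transition rate", call. = FALSE)
  }
  if (max(k_low, k_high) * dt >= 0.1) {
    warning("k * dt >= 0.1: waiting times depart noticeably from exponential",
            call. = FALSE)
  }
  structure(list(E_low = E_low, E_high = E_high, k_low = k_low,
                 k_high = k_high, dt = dt, n_steps = as.integer(n_steps)),
            class = "dmn_params")
}

#' Parameters of an Ornstein-Uhlenbeck-type environmental signal
#'
#' The discrete recursion
#' `E[t+dt] = E[t] + r * (mu - E[t]) * dt + epsilon * R`,
#' with `R` a standard-normal draw per step.  Two drift conventions are
#' available for the mean-reversion rate `r`:
#'
#' * `drift = "hasselmann"` (default): `r = 1 - 1/tau_approx`.  Stationary
#'   only for `tau_approx > 1` (and `r * dt < 2`); the correlation time is
#'   `1/r`, which approaches 1 as `tau_approx` grows.
#' * `drift = "relaxation"`: `r = 1/tau_approx`, the textbook OU rate, for
#'   which `tau_approx` *is* the correlation time; larger `tau_approx`
#'   reddens the signal.
#'
#' Exactly one of `target_variance` and `epsilon` must be supplied; the
#' other is derived via [scale_epsilon()].
#'
#' @param mu long-term mean environment level.
#' @param tau_approx approximate period of the signal (time units), > 0.
#' @param dt sampling step, > 0.
#' @param n_steps series length in steps.
#' @param target_variance desired stationary variance of the signal.
#' @param epsilon per-step noise amplitude (used directly if supplied).
#' @param drift drift convention, `"hasselmann"` or `"relaxation"`.
#' @return an object of class `oun_params` (with both `epsilon` and
#'   `target_variance` filled in where derivable).
#' @examples
#' oun_params(mu = 1, tau_approx = 10, dt = 0.01, n_steps = 1e4,
#'            target_variance = 0.5)
#' @export
oun_params <- function(mu, tau_approx, dt, n_steps,
                       target_variance = NULL, epsilon = NULL,
                       drift = c("hasselmann", "relaxation")) {
  drift <- match.arg(drift)
  .check_scalar(mu, "mu"); .check_scalar(tau_approx, "tau_approx")
  .check_scalar(dt, "dt"); .check_scalar(n_steps, "n_steps")
  if (tau_approx <= 0) stop("`tau_approx` must be positive", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (n_steps < 2) stop("`n_steps` must be at least 2", call. = FALSE)
  if (is.null(target_variance) == is.null(epsilon)) {
    stop("supply exactly one of `target_variance` and `epsilon`", call. = FALSE)
  }
  a <- .oun_ar_coef(tau_approx, dt, drift)
  if (!is.null(target_variance)) {
    .check_scalar(target_variance, "target_variance")
    if (target_variance < 0) stop("`target_variance` must be >= 0", call. = FALSE)
    epsilon <- scale_epsilon(target_variance, tau_approx, dt, drift)
  } else {
    .check_scalar(epsilon, "epsilon")
    if (epsilon < 0) stop("`epsilon` must be >= 0", call. = FALSE)
    target_variance <- if (abs(a) < 1) epsilon^2 / (1 - a^2) else NA_real_
  }
  structure(list(mu = mu, tau_approx = tau_approx, dt = dt,
                 n_steps = as.integer(n_steps),
                 target_variance = target_variance, epsilon = epsilon,
                 drift = drift),
            class = "oun_params")
}

# AR(1) coefficient of the discrete recursion
.oun_ar_coef <- function(tau_approx, dt, drift) {
  r <- switch(drift,
              hasselmann = 1 - 1 / tau_approx,
              relaxation = 1 / tau_approx)
  1 - r * dt
}

#' Noise amplitude that fixes the stationary variance of the OU recursion
#'
#' The recursion is an AR(1) process `E[n+1] = a E[n] + (1-a) mu + epsilon R`
#' with `a = 1 - r * dt`; its stationary variance is
#' `epsilon^2 / (1 - a^2)`.  This returns the `epsilon` that makes that
#' variance equal `target_variance`, so signals with different periods are
#' comparable in variance.
#'
#' @inheritParams oun_params
#' @return the per-step noise amplitude `epsilon`.
#' @examples
#' scale_epsilon(0.5, tau_approx = 2, dt = 0.01)  # ~0.0706
#' @export
scale_epsilon <- function(target_variance, tau_approx, dt,
                          drift = c("hasselmann", "relaxation")) {
  drift <- match.arg(drift)
  .check_scalar(target_variance, "target_variance")
  if (target_variance < 0) stop("`target_variance` must be >= 0", call. = FALSE)
  a <- .oun_ar_coef(tau_approx, dt, drift)
  if (abs(a) >= 1) {
    stop(sprintf(paste0("no stationary distribution: |1 - r*dt| = %.4g >= 1 ",
                        "for tau_approx = %g, dt = %g (%s drift); ",
                        "the recursion is a random walk or divergent"),
                 abs(a), tau_approx, dt, drift), call. = FALSE)
  }
  sqrt(target_variance * (1 - a^2))
}

#' Construct a sampled environmental trajectory
#'
#' @param values numeric vector of environment levels (length >= 2, finite).
#' @param dt constant sampling step, > 0.
#' @param t0 time of the first sample (default 0).
#' @param params optional generating parameter object, kept as an attribute
#'   for provenance.
#' @return an object of class `signal_trajectory`.
#' @export
signal_trajectory <- function(values, dt, t0 = 0, params = NULL) {
  if (!is.numeric(values) || length(values) < 2L) {
    stop("`values` must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("`values` must be finite", call. = FALSE)
  .check_scalar(dt, "dt"); .check_scalar(t0, "t0")
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  structure(list(t0 = t0, dt = dt, values = as.numeric(values),
                 params = params),
            class = "signal_trajectory")
}

#' @export
print.signal_trajectory <- function(x, ...) {
  cat(sprintf("<signal_trajectory> %d samples, dt = %g, t in [%g, %g]\n",
              length(x$values), x$dt, x$t0,
              x$t0 + (length(x$values) - 1) * x$dt))
  cat(sprintf("  mean %.4g, range [%.4g, %.4g]\n",
              mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.signal_trajectory <- function(x) length(x$values)

#' Sample times of a trajectory
#' @param traj a `signal_trajectory`.
#' @return numeric vector of sample times.
#' @export
trajectory_times <- function(traj) {
  traj$t0 + (seq_along(traj$values) - 1) * traj$dt
}

#' Generate a regular dichotomous square-wave environment
#'
#' The signal starts in the benign phase at `t0 = 0`: it equals `E_low` on
#' `[n P, n P + tau_low)` and `E_high` on `[n P + tau_low, (n+1) P)`, where
#' `P = tau_low + tau_high` is the period.
#'
#' @param params a [regular_dichotomous_params()] object.
#' @param duration total length of the series (time units), > 0.
#' @param dt sampling step, > 0.
#' @return a [signal_trajectory()].
#' @examples
#' p <- regular_dichotomous_params(0, 1, 1, 1)
#' generate_regular_dichotomous(p, duration = 4, dt = 0.5)$values
#' @export
generate_regular_dichotomous <- function(params, duration, dt) {
  stopifnot(inherits(params, "regular_dichotomous_params"))
  .check_scalar(duration, "duration"); .check_scalar(dt, "dt")
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  n <- floor(duration / dt + .woo_tie_tol)
  if (n < 2) stop("`duration`/`dt` must give at least 2 samples", call. = FALSE)
  t <- (seq_len(n) - 1) * dt
  period <- params$tau_low + params$tau_high
  phase <- t %% period
  # guard against round-off placing a sample infinitesimally before a switch
  low <- phase < params$tau_low - .woo_tie_tol
  values <- ifelse(low, params$E_low, params$E_high)
  signal_trajectory(values, dt = dt, t0 = 0, params = params)
}

#' Generate dichotomous Markov noise
#'
#' Two-state telegraph signal.  Per step of length `dt` the probability of
#' leaving the current state is `k * dt` (`k_low` in the low state, `k_high`
#' in the high state), so sojourn times are geometric in steps —
#' the discretization of exponential waiting times with means `1/k_low`,
#' `1/k_high`.  The initial state is drawn from the stationary distribution
#' (`P(low) = k_high / (k_low + k_high)`).  Identical `params` and `seed`
#' give bit-identical trajectories.
#'
#' @param params a [dmn_params()] object.
#' @param seed integer RNG seed (required; reproducibility contract).
#' @return a [signal_trajectory()].
#' @examples
#' p <- dmn_params(0, 1, 0.1, 0.2, dt = 0.05, n_steps = 2000)
#' traj <- generate_dmn(p, seed = 1)
#' mean(traj$values == 0)  # ~ k_high / (k_low + k_high)
#' @export
generate_dmn <- function(params, seed) {
  stopifnot(inherits(params, "dmn_params"))
  with_seed(seed, {
    n <- params$n_steps
    p_low <- params$k_low * params$dt
    p_high <- params$k_high * params$dt
    start_low <- stats::runif(1) < params$k_high / (params$k_low + params$k_high)
    # sojourn lengths in steps: 1 + Geometric(k*dt), alternating states;
    # identical in law to per-step Bernoulli switching, but vectorized
    vals <- numeric(0)
    state_low <- start_low
    while (length(vals) < n) {
      expected_run <- if (state_low) 1 / p_low else 1 / p_high
      batch <- max(16L, ceiling((n - length(vals)) / expected_run))
      # draw a batch of alternating sojourns starting from the current state
      runs_low <- stats::rgeom(batch, p_low) + 1
      runs_high <- stats::rgeom(batch, p_high) + 1
      # a sojourn longer than the whole series is indistinguishable from
      # one of exactly n steps (and vanishing rates produce huge draws)
      runs_low <- pmin(runs_low, n)
      runs_high <- pmin(runs_high, n)
      runs_low[is.na(runs_low)] <- n
      runs_high[is.na(runs_high)] <- n
      if (state_low) {
        runs <- as.vector(rbind(runs_low, runs_high))
        levels <- rep(c(params$E_low, params$E_high), batch)
      } else {
        runs <- as.vector(rbind(runs_high, runs_low))
        levels <- rep(c(params$E_high, params$E_low), batch)
      }
      vals <- c(vals, rep(levels, runs))
      # after an even number of sojourns the state is back where it started
    }
    signal_trajectory(vals[seq_len(n)], dt = params$dt, t0 = 0, params = params)
  })
}

#' Generate an Ornstein-Uhlenbeck-type environmental signal
#'
#' Iterates `E[t+dt] = E[t] + r (mu - E[t]) dt + epsilon R`, `R ~ N(0,1)`,
#' with the drift rate `r` set by the `drift` convention in `params` (see
#' [oun_params()]).  The series starts at `E0` (default `mu`); when `E0` is
#' not overridden, a burn-in of ten relaxation times is generated and
#' discarded so that the retained samples are (approximately) stationary.
#' Identical `params` and `seed` give bit-identical trajectories.
#'
#' @param params an [oun_params()] object.
#' @param seed integer RNG seed (required).
#' @param E0 optional initial value; supplying it disables the burn-in
#'   unless `burn_in` says otherwise.
#' @param burn_in logical; default `TRUE` when `E0` is `NULL`, else `FALSE`.
#' @return a [signal_trajectory()] of `params$n_steps` samples.
#' @examples
#' p <- oun_params(1, tau_approx = 10, dt = 0.01, n_steps = 1000,
#'                 target_variance = 0.5)
#' traj <- generate_oun(p, seed = 7)
#' @export
generate_oun <- function(params, seed, E0 = NULL, burn_in = NULL) {
  stopifnot(inherits(params, "oun_params"))
  a <- .oun_ar_coef(params$tau_approx, params$dt, params$drift)
  if (params$epsilon > 0 && abs(a) >= 1) {
    stop("non-stationary parameter combination: |1 - r*dt| >= 1 with noise; ",
         "use a different `tau_approx`/`dt` or the other drift convention",
         call. = FALSE)
  }
  if (is.null(burn_in)) burn_in <- is.null(E0)
  if (is.null(E0)) E0 <- params$mu
  r <- (1 - a) / params$dt
  n_burn <- if (burn_in && r > 0) ceiling(10 / (r * params$dt)) else 0L
  n_tot <- params$n_steps + n_burn
  with_seed(seed, {
    innov <- (1 - a) * params$mu + params$epsilon * stats::rnorm(n_tot)
    E <- as.numeric(stats::filter(innov, a, method = "recursive", init = E0))
    if (n_burn > 0) E <- E[-seq_len(n_burn)]
    signal_trajectory(E, dt = params$dt, t0 = 0, params = params)
  })
}

#' Extract benign windows from a trajectory
#'
#' A benign window is a maximal run of consecutive samples with
#' `E < threshold`.  Each sample `i` is taken to cover the half-open
#' interval `[t0 + i dt, t0 + (i+1) dt)`, so a run of `L` samples has
#' duration `L * dt`.  Windows touching the first or last sample are
#' flagged `censored`: their true length is truncated by the finite series.
#'
#' @param traj a [signal_trajectory()].
#' @param threshold the tolerance level defining benign conditions
#'   (typically the organism's initial tolerance `T0`).
#' @return a `window_set`: a data frame with columns `start`, `end`,
#'   `duration`, `censored`, and attributes `threshold`, `dt`, `n_steps`.
#'   Zero rows if the signal never drops below `threshold`.
#' @examples
#' traj <- signal_trajectory(c(1, 0, 0, 1, 0, 1), dt = 1)
#' extract_benign_windows(traj, 0.5)
#' @export
extract_benign_windows <- function(traj, threshold) {
  stopifnot(inherits(traj, "signal_trajectory"))
  .check_scalar(threshold, "threshold")
  below <- traj$values < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]; lens <- r$lengths[keep]
  n <- length(traj$values)
  out <- data.frame(
    start = traj$t0 + (starts - 1L) * traj$dt,
    end = traj$t0 + ends * traj$dt,
    duration = lens * traj$dt,
    censored = starts == 1L | ends == n
  )
  structure(out, class = c("window_set", "data.frame"),
            threshold = threshold, dt = traj$dt, n_steps = n)
}

#' Summary statistics of a trajectory
#'
#' Sample mean, sample variance (1/N normalization) and the correlation
#' time: the smallest lag `l * dt` at which the normalized autocorrelation
#' drops to `1/e` or below (biased 1/N estimator).  A white-noise series
#' thus reports a correlation time of one step, `dt`.  If the
#' autocorrelation never reaches `1/e`, the series length is returned; a
#' constant series reports variance 0 and correlation time 0 with a
#' warning.
#'
#' @param traj a [signal_trajectory()].
#' @return an object of class `signal_stats`: list with `mean`, `variance`,
#'   `correlation_time`.
#' @export
signal_statistics <- function(traj) {
  stopifnot(inherits(traj, "signal_trajectory"))
  x <- traj$values
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) {
    warning("constant series: variance 0, correlation time reported as 0",
            call. = FALSE)
    return(structure(list(mean = m, variance = 0, correlation_time = 0),
                     class = "signal_stats"))
  }
  # search for the 1/e crossing with a doubling lag window (acf is O(n*lag))
  target <- exp(-1)
  lag_max <- 64L
  ct <- NA_real_
  repeat {
    lag_max <- min(lag_max, n - 1L)
    ac <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[-1]
    hit <- which(ac <= target)
    if (length(hit) > 0) { ct <- hit[1] * traj$dt; break }
    if (lag_max >= n - 1L) { ct <- n * traj$dt; break }
    lag_max <- lag_max * 4L
  }
  structure(list(mean = m, variance = v, correlation_time = ct),
            class = "signal_stats")
}

#' @export
print.signal_stats <- function(x, ...) {
  cat(sprintf("<signal_stats> mean %.4g, variance %.4g, correlation time %.4g\n",
              x$mean, x$variance, x$correlation_time))
  invisible(x)
}

#' Analytic moments of a dichotomous signal
#'
#' For a two-level signal spending a fraction `p_low` of time in the low
#' state, the mean is `p_low E_low + p_high E_high` and the variance
#' `p_low p_high (E_high - E_low)^2` (two-point distribution moments).
#' `p_low = tau_low / (tau_low + tau_high)` for the regular signal and
#' `k_high / (k_low + k_high)` for DMN.
#'
#' @param params a [regular_dichotomous_params()] or [dmn_params()] object.
#' @return a `signal_stats` object; the correlation time is the analytic
#'   one where defined (`1/(k_low + k_high)` for DMN, `NA` for the regular
#'   wave, whose autocorrelation is periodic rather than decaying).
#' @examples
#' dichotomous_moments(dmn_params(0, 1, 0.1, 0.2, 0.01, 1000))
#' @export
dichotomous_moments <- function(params) UseMethod("dichotomous_moments")

#' @export
dichotomous_moments.regular_dichotomous_params <- function(params) {
  p_low <- params$tau_low / (params$tau_low + params$tau_high)
  .two_point_stats(params$E_low, params$E_high, p_low, NA_real_)
}

#' @export
dichotomous_moments.dmn_params <- function(params) {
  p_low <- params$k_high / (params$k_low + params$k_high)
  # telegraph-process autocorrelation decays as exp(-(k_low + k_high) t)
  .two_point_stats(params$E_low, params$E_high, p_low,
                   1 / (params$k_low + params$k_high))
}

.two_point_stats <- function(E_low, E_high, p_low, corr_time) {
  p_high <- 1 - p_low
  structure(list(
    mean = p_low * E_low + p_high * E_high,
    variance = p_low * p_high * (E_high - E_low)^2,
    correlation_time = corr_time
  ), class = "signal_stats")
}

#' Write / read a trajectory as CSV
#'
#' Columns `t,E`, preceded by a `# params: <json>` comment carrying the
#' generating parameters (when available), `t0` and `dt`.
#'
#' @param traj a [signal_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly (write); a [signal_trajectory()] (read).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "signal_trajectory"))
  meta <- list(t0 = traj$t0, dt = traj$dt)
  if (!is.null(traj$params)) {
    meta$params <- unclass(traj$params)
    meta$params_class <- class(traj$params)[1]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# params: ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                                   digits = NA)), con)
  utils::write.csv(data.frame(t = trajectory_times(traj), E = traj$values),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1L)
  d <- utils::read.csv(path, comment.char = "#")
  t0 <- d$t[1]
  dt <- if (nrow(d) > 1) d$t[2] - d$t[1] else 1
  params <- NULL
  if (grepl("^# params:", first)) {
    meta <- jsonlite::fromJSON(sub("^# params: *", "", first))
    if (!is.null(meta$t0)) t0 <- meta$t0
    if (!is.null(meta$dt)) dt <- meta$dt
    if (!is.null(meta$params)) {
      params <- structure(meta$params, class = meta$params_class)
    }
  }
  signal_trajectory(d$E, dt = dt, t0 = t0, params = params)
}

#' Write a window set as CSV
#'
#' Columns `start,end,duration,censored`.
#'
#' @param windows a `window_set` from [extract_benign_windows()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path) {
  stopifnot(inherits(windows, "window_set"))
  utils::write.csv(as.data.frame(windows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
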