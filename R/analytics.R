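# Closed-form windows-of-opportunity theory.
#
# For a dichotomous environment the organism must close the tolerance gap
# delta = E_high - T0 within one benign window.  Under dichotomous Markov
# noise, benign window lengths are exponential with rate k_low, so the
# probability that a window is long enough — a window of opportunity —
# has a closed form, and 2-D parameter diagrams can be evaluated directly.

#' Tolerance gap to be closed before establishment
#'
#' `delta = E_high - T0`, floored at 0: an organism whose initial tolerance
#' already exceeds the harsh level has no gap to close.
#'
#' @param T0 initial tolerance.
#' @param E_high harsh environment level.
#' @return the threshold `delta` >= 0 (vectorized).
#' @examples
#' tolerance_threshold(1/6, 1)  # 5/6
#' @export
tolerance_threshold <- function(T0, E_high) {
  pmax(E_high - T0, 0)
}

#' Critical tolerance growth rate for a given benign window
#'
#' The minimum linear growth rate that closes the gap `delta` within a
#' benign window of length `tau_low`: `lambda_crit = delta / tau_low`.
#'
#' @param delta tolerance gap, >= 0.
#' @param tau_low benign window length, > 0.
#' @return the critical growth rate (vectorized).
#' @examples
#' critical_growth_rate(5/6, 25/3)  # 0.1
#' @export
critical_growth_rate <- function(delta, tau_low) {
  if (any(tau_low <= 0)) stop("`tau_low` must be positive", call. = FALSE)
  if (any(delta < 0)) stop("`delta` must be >= 0", call. = FALSE)
  delta / tau_low
}

#' Probability density of benign window lengths under DMN
#'
#' Window lengths in the stationary dichotomous Markov signal are
#' exponentially distributed: `P(tau_low) = k_low exp(-k_low tau_low)`.
#'
#' @param tau window length(s), >= 0.
#' @param k_low transition rate out of the benign state, > 0.
#' @return density value(s).
#' @examples
#' window_length_density(10, 0.1)  # 0.1 * exp(-1)
#' @export
window_length_density <- function(tau, k_low) {
  if (any(tau < 0)) stop("`tau` must be >= 0", call. = FALSE)
  if (k_low <= 0) stop("`k_low` must be positive", call. = FALSE)
  stats::dexp(tau, rate = k_low)
}

#' Closed-form probability that a benign window is a window of opportunity
#'
#' The probability that an exponential window (rate `k_low`) is at least as
#' long as the critical window `tau_crit`:
#' `P_WoO = exp(-k_low tau_crit)`.  On the regular-dichotomous critical
#' boundary, where `tau_crit` equals the mean window `1/k_low`, this is
#' always `1/e` (about 0.368).  An infinite `tau_crit` gives exactly 0.
#'
#' @param k_low transition rate out of the benign state, > 0.
#' @param tau_crit critical window length, >= 0 (may be `Inf`).
#' @return probability in `[0, 1]` (vectorized).
#' @examples
#' p_woo_analytic(0.1, 10)  # 1/e
#' @export
p_woo_analytic <- function(k_low, tau_crit) {
  if (any(k_low <= 0)) stop("`k_low` must be positive", call. = FALSE)
  if (any(tau_crit < 0)) stop("`tau_crit` must be >= 0", call. = FALSE)
  exp(-k_low * tau_crit)
}

#' Classify the establishment regime of a configuration
#'
#' Four regimes, from the perspective of a young organism with initial
#' tolerance `T0` in an environment ranging over `[E_low, E_high]` with
#' average `E_avg`:
#'
#' * `i`  — benign: `T0 >= E_high`; establishment always possible.
#' * `ii` — benign on average: `E_high > T0 >= E_avg`; variability
#'   destroys opportunities.
#' * `iii` — harsh on average: `E_avg > T0 > E_low`; variability can open
#'   windows of opportunity.
#' * `iv` — harsh: `T0 <= E_low`; establishment never possible.
#'
#' Boundary ties follow the printed inequality pattern: `T0 = E_high` is
#' regime `i`, `T0 = E_avg` regime `ii`, `T0 = E_low` regime `iv`.
#'
#' @param T0 initial tolerance (vectorized).
#' @param E_low,E_avg,E_high environment minimum, average and maximum;
#'   must satisfy `E_low <= E_avg <= E_high` elementwise.
#' @return character vector of labels `"i"`, `"ii"`, `"iii"`, `"iv"`.
#' @examples
#' classify_regime(1/6, 0, 1/3, 1)  # "iii"
#' @export
classify_regime <- function(T0, E_low, E_avg, E_high) {
  n <- max(length(T0), length(E_low), length(E_avg), length(E_high))
  T0 <- rep_len(T0, n); E_low <- rep_len(E_low, n)
  E_avg <- rep_len(E_avg, n); E_high <- rep_len(E_high, n)
  if (any(E_low > E_avg) || any(E_avg > E_high)) {
    stop("require E_low <= E_avg <= E_high", call. = FALSE)
  }
  # assignment order resolves degenerate ties (collapsed variance):
  # T0 = E_high wins over everything (regime i), T0 = E_avg over T0 = E_low
  out <- rep("iii", n)
  out[T0 <= E_low] <- "iv"
  out[T0 >= E_avg & T0 > E_low] <- "ii"
  out[T0 >= E_high] <- "i"
  out
}

#' Establishment probability over a time horizon
#'
#' Compounds the per-window probability `p_woo` over the expected number of
#' benign windows within the horizon,
#' `N = horizon / (1/k_low + 1/k_high)` (one window per mean cycle):
#' `P_est = 1 - (1 - p_woo)^N`.  This expected-window-count compounding is
#' a deliberately minimal model of horizon-scale establishment; it ignores
#' the variance of the number of windows per horizon.
#'
#' @param p_woo per-window opportunity probability in `[0, 1]`.
#' @param horizon length of the observation horizon (time units), >= 0.
#' @param k_low,k_high DMN transition rates, > 0.
#' @return establishment probability in `[0, 1]`.
#' @examples
#' p_establishment(exp(-1), horizon = 45, k_low = 0.1, k_high = 0.2)
#' @export
p_establishment <- function(p_woo, horizon, k_low, k_high) {
  if (any(p_woo < 0 | p_woo > 1)) stop("`p_woo` must be in [0, 1]", call. = FALSE)
  if (any(horizon < 0)) stop("`horizon` must be >= 0", call. = FALSE)
  if (any(k_low <= 0) || any(k_high <= 0)) {
    stop("transition rates must be positive", call. = FALSE)
  }
  n_windows <- horizon / (1 / k_low + 1 / k_high)
  1 - (1 - p_woo)^n_windows
}

#' Construct a 2-D diagram grid
#' @keywords internal
#' @noRd
.diagram_grid <- function(x_name, x_values, y_name, y_values, cells, metadata) {
  stopifnot(all(diff(x_values) > 0), all(diff(y_values) > 0),
            all(cells$value >= 0 & cells$value <= 1))
  structure(list(x_name = x_name, x_values = x_values,
                 y_name = y_name, y_values = y_values,
                 cells = cells, metadata = metadata),
            class = "diagram_grid")
}

#' @export
print.diagram_grid <- function(x, ...) {
  cat(sprintf("<diagram_grid> %s (%d) x %s (%d), values in [%.3g, %.3g]\n",
              x$x_name, length(x$x_values), x$y_name, length(x$y_values),
              min(x$cells$value), max(x$cells$value)))
  invisible(x)
}

#' Establishment probability diagram over (T0, lambda) under DMN
#'
#' Evaluates `P_WoO` on a grid of initial tolerances and growth rates for a
#' fixed DMN environment: each cell composes
#' [tolerance_threshold()] -> [required_window()] -> [p_woo_analytic()].
#' Regime-`i` cells (no gap) evaluate to 1; regime-`iv` cells (benign
#' windows never drop below `T0`) are set to 0.  Also emitted is the
#' regular-dichotomous null-isocline `lambda_crit(T0)` computed with the
#' mean benign window `1/k_low`; along that line `P_WoO = 1/e`.
#'
#' @param dmn a [dmn_params()] object.
#' @param T0_values increasing grid of initial tolerances (x axis).
#' @param lambda_values increasing grid of growth rates (y axis).
#' @param growth tolerance growth type, `"linear"` or `"exponential"`.
#' @return a `diagram_grid` with long-format `cells` (`x`, `y`, `value`,
#'   `regime`) and an `isocline` data frame (`T0`, `lambda_crit`) in the
#'   metadata.
#' @export
probability_diagram <- function(dmn, T0_values, lambda_values,
                                growth = c("linear", "exponential")) {
  stopifnot(inherits(dmn, "dmn_params"))
  growth <- match.arg(growth)
  mom <- dichotomous_moments(dmn)
  grid <- expand.grid(x = T0_values, y = lambda_values,
                      KEEP.OUT.ATTRS = FALSE)
  regime <- classify_regime(grid$x, dmn$E_low, mom$mean, dmn$E_high)
  value <- mapply(function(T0, lambda) {
    m <- tolerance_model(T0, lambda, growth)
    p_woo_analytic(dmn$k_low, required_window(m, dmn$E_high))
  }, grid$x, grid$y)
  value[regime == "i"] <- 1
  value[regime == "iv"] <- 0
  cells <- data.frame(x = grid$x, y = grid$y, value = value, regime = regime)
  isocline <- data.frame(
    T0 = T0_values,
    lambda_crit = tolerance_threshold(T0_values, dmn$E_high) * dmn$k_low
  )
  .diagram_grid("T0", T0_values, "lambda", lambda_values, cells,
                metadata = list(type = "probability", growth = growth,
                                signal = unclass(dmn), isocline = isocline))
}

#' Occurrence diagram over environmental average and variance
#'
#' For each `(E_avg, sigma^2)` cell a symmetric two-point dichotomous
#' envelope is constructed (`E_low = E_avg - sigma`,
#' `E_high = E_avg + sigma`, equal time in both states, so
#' `sigma = (E_high - E_low)/2`), the regime is classified, and `P_WoO` is
#' evaluated with mean benign window `<tau_low> = tau_approx / 2`
#' (`k_low = 2 / tau_approx`).  Regime-`iv` cells are 0, regime-`i` cells 1.
#' The `(E_avg, sigma^2)` to envelope mapping is this package's convention
#' — the simplest dichotomous signal with the requested mean and variance.
#'
#' @param E_avg_values increasing grid of environmental averages (x axis).
#' @param variance_values increasing grid of environmental variances
#'   `sigma^2(E)`, >= 0 (y axis).
#' @param T0 fixed initial tolerance.
#' @param tau_approx approximate period of the signal (default 10).
#' @param lambda fixed tolerance growth rate (default 0.05).
#' @param growth growth type.
#' @return a `diagram_grid` with long-format `cells` (`x`, `y`, `value`,
#'   `regime`).
#' @export
occurrence_diagram <- function(E_avg_values, variance_values, T0,
                               tau_approx = 10, lambda = 0.05,
                               growth = c("linear", "exponential")) {
  growth <- match.arg(growth)
  if (any(variance_values < 0)) stop("variances must be >= 0", call. = FALSE)
  if (tau_approx <= 0) stop("`tau_approx` must be positive", call. = FALSE)
  grid <- expand.grid(x = E_avg_values, y = variance_values,
                      KEEP.OUT.ATTRS = FALSE)
  sigma <- sqrt(grid$y)
  E_low <- grid$x - sigma
  E_high <- grid$x + sigma
  regime <- classify_regime(T0, E_low, grid$x, E_high)
  k_low <- 2 / tau_approx
  value <- mapply(function(Eh) {
    m <- tolerance_model(T0, lambda, growth)
    p_woo_analytic(k_low, required_window(m, Eh))
  }, E_high)
  value[regime == "i"] <- 1
  value[regime == "iv"] <- 0
  cells <- data.frame(x = grid$x, y = grid$y, value = value, regime = regime)
  .diagram_grid("E_avg", E_avg_values, "variance", variance_values, cells,
                metadata = list(type = "occurrence", T0 = T0,
                                tau_approx = tau_approx, lambda = lambda,
                                growth = growth))
}

#' Write a diagram grid as long-format CSV plus JSON metadata
#'
#' The CSV has columns `x,y,value` (plus `regime` when present); the
#' sidecar `<path>.json` carries axis names and the fixed parameters.
#'
#' @param grid a `diagram_grid`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_diagram <- function(grid, path) {
  stopifnot(inherits(grid, "diagram_grid"))
  utils::write.csv(grid$cells, path, row.names = FALSE, quote = FALSE)
  meta <- list(x_name = grid$x_name, y_name = grid$y_name,
               metadata = grid$metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
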