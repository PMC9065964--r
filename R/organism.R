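# Stage-dependent tolerance of the developing organism.
#
# From inception (birth, germination, attachment, transplantation) the
# organism's tolerance T grows from an initial value T0 at rate lambda,
# either linearly or exponentially.  Tolerance is deterministic given
# (T0, lambda): all stochasticity in the framework lives in the
# environment, not in the organism.

#' Stage-dependent tolerance model
#'
#' @param T0 initial tolerance at inception (environment units); must be
#'   strictly positive for exponential growth.
#' @param lambda tolerance growth rate, >= 0.  Units: environment-units per
#'   time for linear growth, 1/time for exponential growth.
#' @param growth `"linear"` (`T(t) = T0 + lambda t`) or `"exponential"`
#'   (`T(t) = T0 exp(lambda t)`).
#' @return an object of class `tolerance_model`.
#' @examples
#' tolerance_model(T0 = 1/6, lambda = 0.1)
#' @export
tolerance_model <- function(T0, lambda, growth = c("linear", "exponential")) {
  growth <- match.arg(growth)
  .check_scalar(T0, "T0"); .check_scalar(lambda, "lambda")
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  if (growth == "exponential" && T0 <= 0) {
    stop("exponential growth requires `T0` > 0", call. = FALSE)
  }
  structure(list(T0 = T0, lambda = lambda, growth = growth),
            class = "tolerance_model")
}

#' @export
print.tolerance_model <- function(x, ...) {
  cat(sprintf("<tolerance_model> T0 = %g, lambda = %g, %s growth\n",
              x$T0, x$lambda, x$growth))
  invisible(x)
}

#' Tolerance at a given time since inception
#'
#' @param model a [tolerance_model()].
#' @param t time since inception, >= 0 (vectorized).
#' @return tolerance value(s); non-decreasing in `t`.
#' @examples
#' m <- tolerance_model(1/6, 0.1)
#' tolerance_at(m, 25/3)  # reaches 1
#' @export
tolerance_at <- function(model, t) {
  stopifnot(inherits(model, "tolerance_model"))
  if (any(t < 0)) stop("`t` must be >= 0 (time since inception)", call. = FALSE)
  switch(model$growth,
         linear = model$T0 + model$lambda * t,
         exponential = model$T0 * exp(model$lambda * t))
}

#' Shortest benign window permitting establishment
#'
#' The critical window length `tau_crit`: the smallest time since inception
#' at which the tolerance reaches the harsh level `E_high`.  For linear
#' growth `tau_crit = delta / lambda` with `delta = E_high - T0`; for
#' exponential growth `tau_crit = log(E_high / T0) / lambda`.  Returns 0
#' when `T0 >= E_high` (already tolerant) and `Inf` when `lambda = 0` with
#' a positive threshold (no growth, no establishment) — the infinite value
#' propagates cleanly to `P_WoO = exp(-k_low * Inf) = 0`.
#'
#' @param model a [tolerance_model()].
#' @param E_high harsh environment level to be overcome.
#' @return the critical window length `tau_crit` (time units), possibly
#'   `Inf`.
#' @examples
#' required_window(tolerance_model(1/6, 0.1), E_high = 1)  # 25/3
#' @export
required_window <- function(model, E_high) {
  stopifnot(inherits(model, "tolerance_model"))
  .check_scalar(E_high, "E_high")
  if (model$T0 >= E_high) return(0)
  if (model$lambda == 0) return(Inf)
  switch(model$growth,
         linear = (E_high - model$T0) / model$lambda,
         exponential = log(E_high / model$T0) / model$lambda)
}

#' Serialize / deserialize a tolerance model as JSON
#'
#' Keys `T0`, `lambda`, `growth_type`.
#'
#' @param model a [tolerance_model()].
#' @param json a JSON string as produced by `tolerance_model_to_json()`.
#' @return a JSON string / a [tolerance_model()].
#' @export
tolerance_model_to_json <- function(model) {
  stopifnot(inherits(model, "tolerance_model"))
  jsonlite::toJSON(list(T0 = model$T0, lambda = model$lambda,
                        growth_type = model$growth),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname tolerance_model_to_json
#' @export
tolerance_model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  tolerance_model(x$T0, x$lambda, x$growth_type)
}
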