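# Reproducible experiment runner.
#
# A run configuration bundles signal parameters, organism parameters, grid
# specifications, replicate counts and a mandatory master seed; presets
# regenerate the data behind the package's standard analyses (DMN window
# statistics and P_WoO curves, the (T0, lambda) probability diagram, f_WoO
# curves on correlated Gaussian signals, and the average-variance
# occurrence diagram).

#' Build a run configuration
#'
#' @param experiment experiment kind: one of `"dmn_windows"`,
#'   `"probability_diagram"`, `"fwoo_curves"`, `"occurrence_diagram"`.
#' @param signal signal parameter object ([dmn_params()] or
#'   [oun_params()]), or a list of named variants thereof for
#'   `"fwoo_curves"`.
#' @param organism a [tolerance_model()]; for grid experiments, `T0` and
#'   `lambda` may be overridden by `grid`.
#' @param grid named list of grid vectors (experiment-specific, e.g.
#'   `T0`, `lambda`, `delta`, `E_avg`, `variance`).
#' @param n_replicates replicate count for Monte-Carlo experiments.
#' @param seed mandatory master seed.
#' @param name optional experiment name used in file names.
#' @return an object of class `run_config`.
#' @export
run_config <- function(experiment, signal, organism = NULL, grid = list(),
                       n_replicates = 1L, seed, name = experiment) {
  experiment <- match.arg(experiment, c("dmn_windows", "probability_diagram",
                                        "fwoo_curves", "occurrence_diagram"))
  if (missing(seed)) stop("a master `seed` is mandatory", call. = FALSE)
  .check_scalar(seed, "seed")
  structure(list(experiment = experiment, signal = signal,
                 organism = organism, grid = grid,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), name = name),
            class = "run_config")
}

#' Named experiment presets
#'
#' Ready-made configurations for the package's standard experiments:
#'
#' * `"fig3"` — DMN window statistics and P_WoO(lambda) curves.  Signal:
#'   `E_low = 0`, `E_high = 1`, `k_low = 0.1`, `k_high = 0.2`, `dt = 0.01`,
#'   10000 steps; organism `T0 = 1/6` (gap `delta = 5/6`), linear growth.
#'   Curves are drawn for gaps `delta` in `{1/3, 5/6, 4/3}` over a
#'   logarithmic lambda grid.
#' * `"fig4"` — establishment probability diagram over `T0 x lambda` for
#'   the same DMN environment.
#' * `"fig5"` — f_WoO(lambda) curves on correlated Gaussian signals:
#'   `mu = 1`, variance 0.5, `dt = 0.01`, 1000 steps, defaults 1000
#'   replicates, `T0 = 1/6`; variants with the period scaled by 10 in both
#'   directions (`tau` in 0.1, 1, 10 at fixed variance) and the variance
#'   scaled by 2 (0.25, 0.5, 1 at fixed period).  Uses the `"relaxation"`
#'   drift, under which `tau_approx` is the correlation time of the signal.
#' * `"fig6"` — occurrence diagram over `E_avg x variance` with period 10
#'   and `lambda = 0.05`, `T0 = 0.5`.
#'
#' @param preset preset name.
#' @param seed master seed (default 1).
#' @param n_replicates optional override of the preset's replicate count.
#' @param n_steps optional override of the preset's series length.
#' @return a [run_config()].
#' @export
woo_preset <- function(preset = c("fig3", "fig4", "fig5", "fig6"),
                       seed = 1L, n_replicates = NULL, n_steps = NULL) {
  preset <- match.arg(preset)
  lambda_grid <- 10^seq(-2, 0.5, length.out = 26)
  switch(preset,
    fig3 = {
      dmn <- dmn_params(0, 1, k_low = 0.1, k_high = 0.2, dt = 0.01,
                        n_steps = n_steps %||% 10000L)
      run_config("dmn_windows", dmn,
                 organism = tolerance_model(1/6, 0.1),
                 grid = list(delta = c(1/3, 5/6, 4/3), lambda = lambda_grid),
                 n_replicates = n_replicates %||% 1L,
                 seed = seed, name = "fig3")
    },
    fig4 = {
      dmn <- dmn_params(0, 1, k_low = 0.1, k_high = 0.2, dt = 0.01,
                        n_steps = n_steps %||% 10000L)
      run_config("probability_diagram", dmn,
                 grid = list(T0 = seq(0.025, 0.975, by = 0.025),
                             lambda = seq(0.01, 0.5, by = 0.01)),
                 seed = seed, name = "fig4")
    },
    fig5 = {
      ns <- n_steps %||% 1000L
      mk <- function(tau, v) oun_params(mu = 1, tau_approx = tau, dt = 0.01,
                                        n_steps = ns, target_variance = v,
                                        drift = "relaxation")
      signals <- list(
        tau_0.1 = mk(0.1, 0.5), tau_1 = mk(1, 0.5), tau_10 = mk(10, 0.5),
        var_0.25 = mk(1, 0.25), var_1 = mk(1, 1)
      )
      run_config("fwoo_curves", signals,
                 organism = tolerance_model(1/6, 1),
                 grid = list(lambda = 2^seq(-3, 3, by = 1)),
                 n_replicates = n_replicates %||% 1000L,
                 seed = seed, name = "fig5")
    },
    fig6 = {
      run_config("occurrence_diagram",
                 signal = list(tau_approx = 10),
                 organism = tolerance_model(0.5, 0.05),
                 grid = list(E_avg = seq(0.05, 1, by = 0.05),
                             variance = seq(0, 0.5, by = 0.02)),
                 seed = seed, name = "fig6")
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an experiment and write its output bundle
#'
#' Writes experiment-specific CSV files plus a `metadata.json` sidecar
#' (full parameters, seed, package version, wall time, counts) into
#' `out_dir`.  Deterministic: the same configuration and seed produce
#' byte-identical CSV files.
#'
#' @param config a [run_config()], e.g. from [woo_preset()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the paths written and the in-memory
#'   results.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  paths <- character(0)
  counts <- list()
  results <- switch(config$experiment,
    dmn_windows = {
      dmn <- config$signal
      traj <- generate_dmn(dmn, seed = config$seed)
      thr <- (dmn$E_low + dmn$E_high) / 2
      w <- extract_benign_windows(traj, thr)
      p1 <- file.path(out_dir, paste0(config$name, "_windows.csv"))
      write_windows(w, p1)
      curves <- do.call(rbind, lapply(config$grid$delta, function(delta) {
        tau_crit <- delta / config$grid$lambda
        data.frame(delta = delta, lambda = config$grid$lambda,
                   p_woo = p_woo_analytic(dmn$k_low, tau_crit))
      }))
      p2 <- file.path(out_dir, paste0(config$name, "_pwoo_curves.csv"))
      utils::write.csv(curves, p2, row.names = FALSE, quote = FALSE)
      paths <- c(p1, p2)
      counts <- list(n_windows = nrow(w), n_censored = sum(w$censored))
      list(windows = w, curves = curves)
    },
    probability_diagram = {
      grid <- probability_diagram(config$signal, config$grid$T0,
                                  config$grid$lambda)
      p1 <- file.path(out_dir, paste0(config$name, "_diagram.csv"))
      write_diagram(grid, p1)
      paths <- c(p1, paste0(p1, ".json"))
      counts <- list(n_cells = nrow(grid$cells))
      list(diagram = grid)
    },
    fwoo_curves = {
      org <- config$organism
      curves <- do.call(rbind, lapply(names(config$signal), function(nm) {
        cu <- fwoo_curve(config$signal[[nm]], org$T0, config$grid$lambda,
                         growth = org$growth,
                         n_replicates = config$n_replicates,
                         seed = config$seed)
        cu$variant <- nm
        cu
      }))
      p1 <- file.path(out_dir, paste0(config$name, "_fwoo.csv"))
      utils::write.csv(curves, p1, row.names = FALSE, quote = FALSE)
      paths <- p1
      counts <- list(n_windows = sum(curves$n_windows))
      list(curves = curves)
    },
    occurrence_diagram = {
      org <- config$organism
      grid <- occurrence_diagram(config$grid$E_avg, config$grid$variance,
                                 T0 = org$T0,
                                 tau_approx = config$signal$tau_approx,
                                 lambda = org$lambda, growth = org$growth)
      p1 <- file.path(out_dir, paste0(config$name, "_diagram.csv"))
      write_diagram(grid, p1)
      paths <- c(p1, paste0(p1, ".json"))
      counts <- list(n_cells = nrow(grid$cells))
      list(diagram = grid)
    })
  meta <- list(
    experiment = config$experiment,
    name = config$name,
    seed = config$seed,
    n_replicates = config$n_replicates,
    grid = config$grid,
    signal = .serialize_params(config$signal),
    organism = if (!is.null(config$organism)) unclass(config$organism),
    counts = counts,
    package_version = as.character(utils::packageVersion("woo")),
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    files = basename(paths)
  )
  mpath <- file.path(out_dir, paste0(config$name, "_metadata.json"))
  jsonlite::write_json(meta, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(paths = c(paths, mpath), results = results, metadata = meta))
}

.serialize_params <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, c("dmn_params", "oun_params",
                    "regular_dichotomous_params"))) {
    out <- unclass(x)
    out$class <- class(x)[1]
    return(out)
  }
  if (is.list(x)) return(lapply(x, .serialize_params))
  x
}
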