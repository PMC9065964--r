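# Shared fixtures for the test suite.  All data is generated in code.

# DMN environment of the worked example: E in {0, 1}, k_low = 0.1,
# k_high = 0.2.  dt and length are per-test choices.
make_dmn <- function(dt = 0.05, n_steps = 60000L) {
  dmn_params(0, 1, k_low = 0.1, k_high = 0.2, dt = dt, n_steps = n_steps)
}

# worked-example organism: T0 = 1/6, linear growth at lambda = 0.1,
# so delta = 5/6 and tau_crit = 25/3
make_organism <- function() tolerance_model(T0 = 1/6, lambda = 0.1)

# correlated Gaussian environment in the relaxation convention, where
# tau_approx is the correlation time
make_oun <- function(tau = 1, variance = 0.5, dt = 0.01, n_steps = 1000L) {
  oun_params(mu = 1, tau_approx = tau, dt = dt, n_steps = n_steps,
             target_variance = variance, drift = "relaxation")
}

# completed (non-censored) benign windows of a DMN trajectory
completed_windows <- function(traj, threshold = 0.5) {
  w <- extract_benign_windows(traj, threshold)
  w[!w$censored, , drop = FALSE]
}
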