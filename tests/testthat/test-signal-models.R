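# Environmental signal generators: square wave, telegraph noise, red noise.

test_that("regular dichotomous wave has the stated phase structure and mean", {
  p <- regular_dichotomous_params(0, 1, tau_low = 1, tau_high = 1)
  traj <- generate_regular_dichotomous(p, duration = 4, dt = 0.5)
  expect_equal(traj$values, c(0, 0, 1, 1, 0, 0, 1, 1))
  expect_equal(mean(traj$values), 0.5)

  # closed-form time average (E_low tau_low + E_high tau_high) / period,
  # cross-checked against a long sample mean
  p2 <- regular_dichotomous_params(0, 1, tau_low = 2, tau_high = 1)
  long <- generate_regular_dichotomous(p2, duration = 3000, dt = 0.01)
  expect_equal(mean(long$values), 1 / 3, tolerance = 1e-3)
})

test_that("parameter constructors reject invalid configurations", {
  expect_error(regular_dichotomous_params(1, 0, 1, 1), "E_high")
  expect_error(regular_dichotomous_params(0, 1, -1, 1), "positive")
  expect_error(generate_regular_dichotomous(
    regular_dichotomous_params(0, 1, 1, 1), duration = -2, dt = 0.5),
    "positive")
  expect_error(dmn_params(0, 1, k_low = 20, k_high = 0.2, dt = 0.1,
                          n_steps = 100), "too coarse")
  expect_warning(dmn_params(0, 1, k_low = 5, k_high = 0.2, dt = 0.1,
                            n_steps = 100), "exponential")
  expect_error(oun_params(1, 1, 0.01, 100, target_variance = 0.5,
                          epsilon = 0.1), "exactly one")
})

test_that("DMN trajectories are seed-reproducible and two-valued", {
  d <- make_dmn(n_steps = 5000L)
  a <- generate_dmn(d, seed = 42)
  b <- generate_dmn(d, seed = 42)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, generate_dmn(d, seed = 43)$values))
  expect_setequal(unique(a$values), c(0, 1))
})

test_that("DMN occupancy matches the stationary two-state balance", {
  # expected fraction of time in the low state: k_high / (k_low + k_high);
  # tolerance = 3 standard errors of a time average of the telegraph
  # process, sd ~ sqrt(2 p q tau_c / T) with tau_c = 1/(k_low + k_high)
  d <- make_dmn(dt = 0.05, n_steps = 200000L)
  traj <- generate_dmn(d, seed = 1)
  p_low <- d$k_high / (d$k_low + d$k_high)
  total_time <- d$n_steps * d$dt
  se <- sqrt(2 * p_low * (1 - p_low) / (d$k_low + d$k_high) / total_time)
  expect_lt(abs(mean(traj$values == 0) - p_low), 3 * se)
})

test_that("DMN completed low windows are exponential with mean 1/k_low", {
  d <- make_dmn(dt = 0.05, n_steps = 400000L)
  w <- completed_windows(generate_dmn(d, seed = 7))
  expect_gt(nrow(w), 1000)
  expect_equal(mean(w$duration), 1 / d$k_low, tolerance = 0.05)
  cv <- stats::sd(w$duration) / mean(w$duration)
  expect_equal(cv, 1, tolerance = 0.1)
})

test_that("DMN in the absorbing limit stays in its starting state", {
  # k_low -> 0: once low, (almost) never leaves within the series
  d <- dmn_params(0, 1, k_low = 1e-12, k_high = 0.2, dt = 0.05,
                  n_steps = 5000L)
  traj <- generate_dmn(d, seed = 3)
  # stationary start is low with probability ~1, and it must stay there
  expect_true(all(traj$values == 0))
})

test_that("scale_epsilon fixes the stationary variance of the recursion", {
  expect_equal(scale_epsilon(0, tau_approx = 2, dt = 0.01), 0)
  a <- 1 - (1 - 1 / 2) * 0.01
  expect_equal(scale_epsilon(0.5, 2, 0.01), sqrt(0.5 * (1 - a^2)))
  expect_equal(scale_epsilon(0.5, 2, 0.01), 0.0706, tolerance = 1e-3)
  # non-stationary combinations are refused with an explicit message
  expect_error(scale_epsilon(0.5, 1, 0.01), "stationary")
  expect_error(scale_epsilon(0.5, 0.5, 0.01), "stationary")
  # simulation oracle: re-simulated sample variance within 10% of target,
  # in both drift conventions
  for (tau in c(2, 10)) {
    o <- oun_params(1, tau, dt = 0.05, n_steps = 1e5, target_variance = 0.5)
    v <- signal_statistics(generate_oun(o, seed = 101))$variance
    expect_equal(v, 0.5, tolerance = 0.1)
  }
  for (tau in c(0.1, 1, 10)) {
    o <- oun_params(1, tau, dt = 0.1, n_steps = 1e5, target_variance = 0.5,
                    drift = "relaxation")
    v <- signal_statistics(generate_oun(o, seed = 101))$variance
    expect_equal(v, 0.5, tolerance = 0.1)
  }
})

test_that("noise-free OU recursion decays geometrically toward the mean", {
  o <- oun_params(mu = 1, tau_approx = 2, dt = 0.01, n_steps = 100,
                  epsilon = 0)
  traj <- generate_oun(o, seed = 1, E0 = 2)
  # per-step factor a = 1 - (1 - 1/tau) dt = 0.995 on the deviation from mu
  expect_equal(traj$values, 1 + 0.995^(1:100), tolerance = 1e-12)
  # starting on the mean it stays there
  o2 <- oun_params(mu = 3, tau_approx = 2, dt = 0.01, n_steps = 50,
                   epsilon = 0)
  expect_true(all(generate_oun(o2, seed = 1, E0 = 3)$values == 3))
})

test_that("OU trajectories are seed-reproducible and near target moments", {
  o <- make_oun(tau = 1, n_steps = 1e5)
  a <- generate_oun(o, seed = 5)
  expect_identical(a$values, generate_oun(o, seed = 5)$values)
  # the time-average of an OU path has sd ~ sqrt(2 var tau / T) ~ 0.03
  # here; 0.1 is a 3-sigma band
  s <- signal_statistics(a)
  expect_equal(s$mean, 1, tolerance = 0.1)
  expect_equal(s$variance, 0.5, tolerance = 0.2)
})

test_that("benign windows are maximal runs with censoring flags", {
  traj <- signal_trajectory(rep(1, 10), dt = 1)
  w <- extract_benign_windows(traj, 0.5)
  expect_equal(nrow(w), 0)

  traj <- signal_trajectory(c(1, 0, 0, 1, 0, 1), dt = 1)
  w <- extract_benign_windows(traj, 0.5)
  expect_equal(w$duration, c(2, 1))
  expect_equal(w$start, c(1, 4))
  expect_equal(w$censored, c(FALSE, FALSE))

  # windows touching either boundary are censored
  traj2 <- signal_trajectory(c(0, 0, 1, 0), dt = 0.5)
  w2 <- extract_benign_windows(traj2, 0.5)
  expect_equal(w2$censored, c(TRUE, TRUE))
  expect_equal(w2$duration, c(1, 0.5))
})

test_that("DMN window durations recover the exponential law", {
  d <- make_dmn(dt = 0.05, n_steps = 200000L)
  w <- completed_windows(generate_dmn(d, seed = 11), threshold = 0.5)
  expect_equal(mean(w$duration), 10, tolerance = 0.05)
})

test_that("signal statistics report mean, variance and 1/e correlation time", {
  s <- signal_statistics(signal_trajectory(rep(c(0, 1), 50), dt = 1))
  expect_equal(s$mean, 0.5)
  expect_equal(s$variance, 0.25)

  # white noise (relaxation drift with tau = dt makes a = 0): one-step
  # correlation time
  o <- oun_params(0, 0.01, dt = 0.01, n_steps = 5000, target_variance = 1,
                  drift = "relaxation")
  s2 <- signal_statistics(generate_oun(o, seed = 3))
  expect_equal(s2$correlation_time, 0.01)

  # reddening: larger correlation time at larger tau, equal variance & seed
  ct <- sapply(c(0.5, 5), function(tau) {
    signal_statistics(generate_oun(make_oun(tau, n_steps = 2e4),
                                   seed = 9))$correlation_time
  })
  expect_lt(ct[1], ct[2])

  expect_warning(s3 <- signal_statistics(signal_trajectory(rep(2, 10), dt = 1)),
                 "constant")
  expect_equal(s3$variance, 0)
  expect_equal(s3$correlation_time, 0)
})

test_that("analytic dichotomous moments match the two-point distribution", {
  m <- dichotomous_moments(regular_dichotomous_params(0, 1, 2, 2))
  expect_equal(m$mean, 0.5)
  expect_equal(m$variance, 0.25)

  m2 <- dichotomous_moments(make_dmn())
  expect_equal(m2$mean, 1 / 3)
  expect_equal(m2$variance, 2 / 9)

  # degenerate two-point signal has zero variance
  m3 <- dichotomous_moments(regular_dichotomous_params(1, 1 + 1e-12, 1, 1))
  expect_equal(m3$variance, 0, tolerance = 1e-20)

  # oracle equivalence with sample moments of a long simulated series
  d <- make_dmn(dt = 0.05, n_steps = 200000L)
  s <- signal_statistics(generate_dmn(d, seed = 13))
  expect_equal(s$mean, m2$mean, tolerance = 0.05)
  expect_equal(s$variance, m2$variance, tolerance = 0.05)
})

test_that("trajectory CSV round-trips with parameter metadata", {
  d <- make_dmn(n_steps = 500L)
  traj <- generate_dmn(d, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$values, traj$values)
  expect_equal(back$dt, traj$dt)
  expect_s3_class(back$params, "dmn_params")
  expect_equal(back$params$k_low, 0.1)

  w <- extract_benign_windows(traj, 0.5)
  wpath <- withr::local_tempfile(fileext = ".csv")
  write_windows(w, wpath)
  expect_equal(names(utils::read.csv(wpath)),
               c("start", "end", "duration", "censored"))
})
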