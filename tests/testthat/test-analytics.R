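# Closed-form theory: thresholds, window law, P_WoO, regimes, diagrams.

test_that("tolerance gap is E_high - T0 floored at zero", {
  expect_equal(tolerance_threshold(1/6, 1), 5/6)
  expect_equal(tolerance_threshold(1, 1), 0)
  expect_equal(tolerance_threshold(2, 1), 0)
  expect_equal(tolerance_threshold(c(0, 0.5, 1.5), 1), c(1, 0.5, 0))
})

test_that("critical growth rate is gap over window length", {
  expect_equal(critical_growth_rate(1, 10), 0.1)
  expect_equal(critical_growth_rate(0, 7), 0)
  expect_equal(critical_growth_rate(5/6, 25/3), 0.1)
  expect_error(critical_growth_rate(1, 0), "positive")
})

test_that("window-length density is exponential and normalized", {
  expect_equal(window_length_density(0, 0.1), 0.1)
  expect_equal(window_length_density(10, 0.1), 0.1 * exp(-1))
  q <- stats::integrate(window_length_density, 0, 200, k_low = 0.1)
  expect_equal(q$value, 1, tolerance = 1e-6)
  expect_error(window_length_density(-1, 0.1), ">= 0")
})

test_that("P_WoO is the exponential tail and behaves monotonically", {
  expect_equal(p_woo_analytic(0.1, 10), exp(-1))
  expect_equal(round(p_woo_analytic(0.1, 10), 3), 0.368)
  expect_equal(p_woo_analytic(0.1, 0), 1)
  expect_equal(p_woo_analytic(0.1, Inf), 0)
  expect_equal(p_woo_analytic(0.1, 25/3 * (5/6) / (5/6)), exp(-5/6),
               tolerance = 1e-12)
  # strictly decreasing in both arguments, always in [0, 1]
  k <- seq(0.01, 1, length.out = 25)
  p_k <- p_woo_analytic(k, 5)
  expect_true(all(diff(p_k) < 0))
  tc <- seq(0, 50, length.out = 25)
  p_t <- p_woo_analytic(0.2, tc)
  expect_true(all(diff(p_t) < 0))
  expect_true(all(p_k >= 0 & p_k <= 1 & p_t >= 0 & p_t <= 1))
  expect_true(all((p_t == 1) == (tc == 0)))
})

test_that("regime classification covers the worked configurations", {
  # DMN worked example: E_avg = 1/3 from the two-point moments, T0 = 1/6
  mom <- dichotomous_moments(make_dmn())
  expect_equal(classify_regime(1/6, 0, mom$mean, 1), "iii")
  expect_equal(classify_regime(2, 0, 1/3, 1), "i")
  expect_equal(classify_regime(0, 0, 1/3, 1), "iv")
  # tie rules: T0 = E_high -> i; T0 = E_avg -> ii; T0 = E_low -> iv
  expect_equal(classify_regime(1, 0, 0.5, 1), "i")
  expect_equal(classify_regime(0.5, 0, 0.5, 1), "ii")
  expect_equal(classify_regime(0.2, 0.2, 0.5, 1), "iv")
  expect_error(classify_regime(0.5, 1, 0.5, 1), "E_low <= E_avg")
})

test_that("establishment probability compounds over expected windows", {
  expect_equal(p_establishment(0, 100, 0.1, 0.2), 0)
  expect_equal(p_establishment(1, 15, 0.1, 0.2), 1)
  # N = 3 mean cycles at horizon 45 with mean cycle 15
  expect_equal(p_establishment(0.368, 45, 0.1, 0.2), 1 - (1 - 0.368)^3)
  expect_error(p_establishment(0.5, -1, 0.1, 0.2), ">= 0")
  expect_error(p_establishment(1.5, 1, 0.1, 0.2), "0, 1")
})

test_that("probability diagram composes the pipeline, 1/e on the isocline", {
  d <- make_dmn()
  T0s <- seq(0.1, 0.9, by = 0.1)
  lams <- seq(0.02, 0.3, by = 0.04)
  grid <- probability_diagram(d, T0s, lams)
  expect_true(all(grid$cells$value >= 0 & grid$cells$value <= 1))
  # cell values equal the composed closed form
  i <- which(abs(grid$cells$x - 0.5) < 1e-9 & abs(grid$cells$y - 0.1) < 1e-9)
  expect_equal(grid$cells$value[i], exp(-0.1 * 0.5 / 0.1))
  # monotone non-decreasing along lambda at fixed T0, and along T0 at
  # fixed lambda (the gap shrinks as T0 rises)
  for (T0 in T0s) {
    col <- grid$cells[grid$cells$x == T0, ]
    expect_true(all(diff(col$value[order(col$y)]) >= 0))
  }
  for (lam in lams) {
    row <- grid$cells[abs(grid$cells$y - lam) < 1e-12, ]
    expect_true(all(diff(row$value[order(row$x)]) >= 0))
  }
  # the regular-dichotomous null-isocline: lambda_crit(T0) with the mean
  # window 1/k_low; evaluating P_WoO along it gives exactly 1/e
  iso <- grid$metadata$isocline
  expect_equal(iso$lambda_crit, tolerance_threshold(T0s, 1) * d$k_low)
  p_iso <- mapply(function(T0, lam) {
    p_woo_analytic(d$k_low, required_window(tolerance_model(T0, lam), 1))
  }, iso$T0, iso$lambda_crit)
  expect_equal(p_iso, rep(exp(-1), length(T0s)))
})

test_that("occurrence diagram reproduces the four-regime geometry", {
  E_avgs <- seq(0.1, 1, by = 0.1)
  vars <- seq(0, 0.4, by = 0.05)
  T0 <- 0.5
  grid <- occurrence_diagram(E_avgs, vars, T0 = T0)
  cells <- grid$cells
  # zero-variance column collapses to regimes i and iv:
  # 1 where T0 >= E_avg, 0 elsewhere
  col0 <- cells[cells$y == 0, ]
  expect_equal(col0$value, ifelse(T0 >= col0$x, 1, 0))
  expect_true(all(col0$regime %in% c("i", "iv")))
  # harsh average: increasing variance eventually opens windows
  harsh <- cells[cells$x == 0.8, ]
  harsh <- harsh[order(harsh$y), ]
  expect_equal(harsh$value[1], 0)
  opened <- harsh$y > (0.8 - T0)^2  # sigma large enough that E_low < T0
  expect_true(all(harsh$value[opened] > 0))
  expect_true(all(harsh$value[!opened] == 0))
  # within regime iii the occurrence falls as the average worsens
  band <- cells[cells$y == 0.4 & cells$regime == "iii", ]
  band <- band[order(band$x), ]
  expect_true(all(diff(band$value) < 0))
  # regime boundaries as variance varies at fixed E_avg: label switches
  # exactly where T0 crosses E_high, E_avg, E_low
  sweep <- cells[cells$x == 0.6, ]
  sweep <- sweep[order(sweep$y), ]
  sig <- sqrt(sweep$y)
  expected <- classify_regime(T0, 0.6 - sig, 0.6, 0.6 + sig)
  expect_equal(sweep$regime, expected)
  expect_error(occurrence_diagram(E_avgs, c(-0.1, 0.1), T0 = 0.5), ">= 0")
})

test_that("regime labels partition admissible parameter space", {
  set.seed(77)
  n <- 1e5
  T0 <- runif(n, -0.5, 2)
  e <- matrix(runif(3 * n, 0, 1.5), ncol = 3)
  e <- t(apply(e, 1, sort))
  lab <- classify_regime(T0, e[, 1], e[, 2], e[, 3])
  expect_true(all(lab %in% c("i", "ii", "iii", "iv")))
  # the four defining conditions (with the documented tie rules) are
  # mutually exclusive and exhaustive
  is_i <- T0 >= e[, 3]
  is_ii <- T0 < e[, 3] & T0 >= e[, 2] & T0 > e[, 1]
  is_iv <- T0 <= e[, 1]
  is_iii <- !is_i & !is_ii & !is_iv
  expect_true(all(is_i + is_ii + is_iii + is_iv == 1))
  expect_equal(lab, c("i", "ii", "iii", "iv")[
    1 * is_i + 2 * is_ii + 3 * is_iii + 4 * is_iv])
})

test_that("diagram grids write long-format CSV with JSON metadata", {
  grid <- occurrence_diagram(seq(0.2, 0.8, 0.2), c(0, 0.1, 0.2), T0 = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_diagram(grid, path)
  d <- utils::read.csv(path)
  expect_true(all(c("x", "y", "value") %in% names(d)))
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(meta$x_name, "E_avg")
  expect_equal(meta$metadata$lambda, 0.05)
})
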