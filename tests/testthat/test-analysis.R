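# Offline analysis: calibration regressions, growth-rate estimation,
# generation accounting, and box-whisker summaries.

test_that("the least-squares fit matches the normal-equations oracle", {
  x <- c(0, 1, 2, 3)
  f <- linear_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)

  flat <- linear_fit(x, rep(4, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)

  f2 <- linear_fit(c(0, 1, 2), c(0, 1, 1))
  expect_equal(f2$slope, 0.5)
  expect_equal(f2$intercept, 1 / 6)

  expect_error(linear_fit(rep(2, 5), rnorm(5)), "distinct")

  set.seed(51)
  for (i in 1:10) {
    n <- sample(3:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    f <- linear_fit(x, y)
    o <- ols_oracle(x, y)
    expect_equal(f$slope, o$slope)
    expect_equal(f$intercept, o$intercept)
    expect_equal(f$r, o$r)
    expect_equal(f$r2, o$r^2)
  }
})

test_that("the cell-density calibration excludes points outside the window", {
  # exact empirical line: T = 160 - 45 * log10(CFU)
  cfu <- 10^seq(2, 3, length.out = 8)
  T_pct <- 160 - 45 * log10(cfu)
  f <- fit_transmittance_vs_logcfu(T_pct, cfu, T_range = c(0, 100))
  expect_equal(f$n_excluded, 0)
  expect_equal(f$slope, -45)
  expect_equal(f$intercept, 160)
  expect_error(fit_transmittance_vs_logcfu(T_pct, cfu, T_range = c(0, 0)),
               "fewer than two")

  # Beer-Lambert forward data, restricted to the exponential window
  p <- optical_model_params(k_cell = 6e-9, path_length = 1)
  X <- 10^seq(6.5, 8.5, length.out = 40)
  T_bl <- transmittance_from_components(cell_absorbance(X, p), 0)
  f2 <- fit_transmittance_vs_logcfu(T_bl, X, T_range = c(25, 70))
  expect_gt(f2$r2, 0.98)
  expect_gt(f2$n_excluded, 0)
  expect_lt(f2$slope, 0)
})

test_that("the phenol-red calibration is linear inside the pH window", {
  p <- optical_model_params(k_cell = 0, phenolred_A_min = -log10(0.16),
                            phenolred_A_max = -log10(0.08),
                            pH_lo = 6, pH_hi = 7)
  pH <- seq(5.5, 7.5, by = 0.05)
  T_pct <- transmittance_from_components(0, phenolred_absorbance(pH, p))
  f <- fit_transmittance_vs_pH(T_pct, pH, window = c(6, 7))
  expect_equal(f$n_excluded, sum(pH < 6 | pH > 7))
  # the forward model is log-linear, so the line is a close but not perfect fit
  expect_gt(f$r2, 0.98)
  expect_lt(f$slope, 0)          # acidification raises transmittance
  # near the window midpoint the slope matches the linearized forward model
  mid <- abs(pH - 6.5) <= 0.15
  f_mid <- fit_transmittance_vs_pH(T_pct[mid], pH[mid], window = c(6, 7))
  A_span <- p$phenolred_A_max - p$phenolred_A_min
  T_bar <- mean(T_pct[mid])
  expect_equal(f_mid$slope, -log(10) * A_span * T_bar, tolerance = 0.05)
})

test_that("growth rate is recovered from a batch trace", {
  org <- tiny_org(mu_max = 1.3, Ks = 0.01, yield_Y = 1e10,
                  optics = tiny_optics(k_cell = 2e-9))
  cfg <- tiny_config(duration = 2, mode = mode_batch(), org = org,
                     med = tiny_medium(S0 = 5), inoculum = list(X = 2e7))
  log <- run_experiment(cfg)
  mu <- estimate_growth_rate(log, c(600, 6600))
  expect_equal(mu, 1.3, tolerance = 0.02)
  # halving the interval does not change the estimate
  mu_half <- estimate_growth_rate(log, c(600, 3600))
  expect_equal(mu_half, mu, tolerance = 0.01)
})

test_that("growth-rate estimation refuses misuse", {
  org <- tiny_org(mu_max = 2, Ks = 0.01, yield_Y = 1e9,
                  optics = tiny_optics(k_cell = 2e-9))
  cfg <- tiny_config(duration = 2, sample_period = 2,
                     mode = mode_realtime_feedback(50, 55, 10),
                     org = org, med = tiny_medium(S0 = 5),
                     inoculum = list(X = 1e8))
  log <- run_experiment(cfg)
  t_ref <- log$events$time_s[log$events$event == "refresh_cycle"][1]
  expect_error(estimate_growth_rate(log, c(t_ref - 60, t_ref + 60)),
               "refresh")
  # constant transmittance estimates zero growth
  flat <- log
  flat$samples$filtered_pct[] <- 42
  flat$events <- flat$events[0, ]
  expect_equal(estimate_growth_rate(flat, c(0, 600)), 0)
})

test_that("generations are the cumulative dilution doublings at steady state", {
  W <- 20
  fake_log <- structure(list(
    samples = data.frame(time_s = c(0, 43200), channel = 1L,
                         raw = c(1, 1), transmittance_pct = c(40, 40),
                         filtered_pct = c(40, 40.2),
                         phase = "idle"),
    events = data.frame(time_s = seq_len(25) * 1000, channel = 1L,
                        event = "refresh_cycle", pinch_time_s = 20,
                        volume_added_mL = 20, volume_removed_mL = 20,
                        transmittance_pct = 40,
                        cumulative_medium_mL = cumsum(rep(20, 25))),
    state = NULL,
    meta = list(working_volume_mL = W, polarity = "growth_decreases_T"),
    config = NULL), class = "experiment_log")
  g <- generations_from_log(fake_log)
  expect_equal(as.numeric(g), 25)          # 25 half-dilutions
  expect_true(attr(g, "steady"))

  # no refreshes but cell density exactly doubled: one doubling, flagged
  dbl <- fake_log
  dbl$events <- dbl$events[0, ]
  A0 <- 0.3
  T0 <- 100 * 10^-A0; T1 <- 100 * 10^-(2 * A0)
  dbl$samples$filtered_pct <- c(T0, T1)
  expect_warning(g2 <- generations_from_log(dbl), "steady")
  expect_equal(as.numeric(g2), 1)
  expect_false(attr(g2, "steady"))
})

test_that("a simulated turbidostat's generations match its growth integral", {
  org <- tiny_org(mu_max = 2, Ks = 0.01, yield_Y = 1e9,
                  optics = tiny_optics(k_cell = 2e-9))
  cfg <- tiny_config(duration = 6, sample_period = 2,
                     mode = mode_realtime_feedback(50, 55, 10),
                     org = org, med = tiny_medium(S0 = 5),
                     inoculum = list(X = 1.4e8))
  log <- run_experiment(cfg)
  g <- suppressWarnings(generations_from_log(log, tol = 0))
  oracle <- log$state$mu_integral[nrow(log$state)] / log(2)
  expect_equal(as.numeric(g), oracle, tolerance = 0.02)
})

test_that("steady-state summaries use interpolated quartiles and IQR whiskers", {
  s <- steady_state_summary(rep(7, 10))
  expect_equal(s$median, 7)
  expect_equal(s$q1, 7); expect_equal(s$q3, 7)
  expect_equal(s$whisker_low, 7); expect_equal(s$whisker_high, 7)

  s8 <- steady_state_summary(1:8)
  expect_equal(s8$median, 4.5)
  expect_equal(s8$q1, 2.75)
  expect_equal(s8$q3, 6.25)
  expect_equal(s8$n, 8)

  set.seed(61)
  x <- rnorm(40)
  a <- steady_state_summary(x)
  b <- steady_state_summary(sample(x))
  expect_equal(a, b)
  expect_equal(a$q1, quantile_oracle(x, 0.25))
  expect_equal(a$median, quantile_oracle(x, 0.5))
  expect_equal(a$q3, quantile_oracle(x, 0.75))
  # ordering invariant of the box
  with(a, {
    expect_lte(min, whisker_low); expect_lte(whisker_low, q1)
    expect_lte(q1, median); expect_lte(median, q3)
    expect_lte(q3, whisker_high); expect_lte(whisker_high, max)
  })
  # an outlier falls outside the whiskers
  y <- c(rnorm(30), 50)
  expect_lt(steady_state_summary(y)$whisker_high, 50)
  expect_error(steady_state_summary(c(1, 2, 3)), "at least four")
})
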