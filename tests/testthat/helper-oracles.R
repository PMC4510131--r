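# Independent brute-force oracles and small fixture builders shared across
# the suite. The oracles deliberately avoid the package's own code paths.

# trailing moving average by direct looping
boxcar_oracle <- function(v, n) {
  vapply(seq_along(v), function(k) mean(v[max(1, k - n + 1):k]), numeric(1))
}

# ordinary least squares via the normal equations, no lm()
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- sy / n - slope * sx / n
  r <- (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
  list(slope = slope, intercept = intercept, r = r)
}

# quantile by linear interpolation between order statistics, no quantile()
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

tiny_optics <- function(k_cell = 1e-9) {
  optical_model_params(k_cell = k_cell, path_length = 1,
                       phenolred_A_min = 0.2, phenolred_A_max = 0.8,
                       pH_lo = 6, pH_hi = 7)
}

tiny_org <- function(mu_max = 1, Ks = 0.1, yield_Y = 1e9, q_acid = 0,
                     optics = tiny_optics()) {
  organism_params(mu_max, Ks, yield_Y, q_acid, optics)
}

tiny_medium <- function(S0 = 2, ...) medium_spec(S0 = S0, ...)

tiny_calib <- function() calibration_record(0.1, 2.1)

# a compact closed-loop configuration for controller tests
tiny_config <- function(duration = 2, mode, polarity = "growth_decreases_T",
                        org = tiny_org(), med = tiny_medium(),
                        sample_period = 5, n_average = 1, noise_sd = 0,
                        inoculum = list(X = 1e7), seed = NULL, ...) {
  experiment_config(
    duration = duration,
    acquisition = acquisition_settings(sample_period, n_average, noise_sd),
    mode = mode, polarity = polarity, organism = org, medium = med,
    calibration = tiny_calib(), inoculum = inoculum, seed = seed, ...)
}
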