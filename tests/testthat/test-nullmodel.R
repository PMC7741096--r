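test_that("fit_exponential recovers exact and noisy exponentials", {
  g <- seq(4000, 9000, by = 1)
  truth <- 1 * exp(5e-4 * (9000 - g))
  spd <- density_model(g, truth, kind = "spd")
  fit <- fit_exponential(spd, c(9000, 4000))
  expect_equal(fit$rate, 5e-4, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)

  # constant SPD: rate ~ 0
  spd0 <- density_model(g, rep(2, length(g)), kind = "spd")
  fit0 <- fit_exponential(spd0, c(9000, 4000))
  expect_lt(abs(fit0$rate), 1e-10)

  # noisy exponential: recovered within a loose band (sigma = 1% of level)
  set.seed(31)
  rates <- replicate(20, {
    y <- truth * (1 + rnorm(length(g), 0, 0.01))
    fit_exponential(density_model(g, pmax(y, 0), kind = "spd"),
                    c(9000, 4000))$rate
  })
  expect_lt(abs(mean(rates) - 5e-4), 3 * sd(rates) / sqrt(20) + 1e-6)
  expect_error(fit_exponential(density_model(g, rep(0, length(g)), kind = "spd"),
                               c(9000, 4000)), "zero")
  expect_error(fit_exponential(spd, c(4000, 9000)), "old > young")
})

test_that("simulate_null conserves mass, reproduces under seed, and is flat for r=0", {
  tc <- toy_curves(c(2000, 9000))
  fit <- structure(list(amplitude = 1, rate = 0, window = c(8000, 4000)),
                   class = "exp_fit")
  null <- simulate_null(fit, n_dates = 40, error_pool = c(30, 50, 80),
                        atm = tc$atm, n_boot = 60, seed = 5)
  expect_s3_class(null, "density_model")
  expect_equal(null$kind, "null")
  # mass conservation: mean integrates to ~ n_dates (tail truncation aside)
  expect_equal(sum(null$mean), 40, tolerance = 0.01 * 40)
  # interior mean within 10% of the uniform expectation
  interior <- null$grid < 7600 & null$grid > 4400
  expect_lt(max(abs(null$mean[interior] - 0.01)) , 0.1 * 0.01 + 0.004)
  null2 <- simulate_null(fit, n_dates = 40, error_pool = c(30, 50, 80),
                         atm = tc$atm, n_boot = 60, seed = 5)
  expect_identical(null$replicates, null2$replicates)
})

test_that("detect_departures flags disjoint envelopes and scores exceedance", {
  g <- seq(5000, 6000, by = 10)
  n <- length(g)
  base <- rep(1, n)
  reps <- matrix(rep(base, 30), nrow = 30, byrow = TRUE) +
    matrix(rnorm(30 * n, 0, 0.01), 30)
  env <- apply(reps, 2, quantile, probs = c(0.023, 0.977))
  null <- density_model(g, colMeans(reps), pmin(env[1, ], colMeans(reps)),
                        pmax(env[2, ], colMeans(reps)),
                        n_boot = 30, kind = "null", replicates = reps)
  # obs identical to null envelopes: no intervals, statistic 0, p = 1
  obs_same <- density_model(g, colMeans(reps), null$lower, null$upper,
                            n_boot = 30, kind = "spd")
  rep0 <- detect_departures(obs_same, null)
  expect_equal(nrow(rep0$positive_intervals), 0L)
  expect_equal(nrow(rep0$negative_intervals), 0L)
  expect_equal(rep0$statistic, 0)
  expect_equal(rep0$global_p, 1)

  # obs shifted far above: one positive interval spanning the window
  obs_hi <- density_model(g, colMeans(reps) + 1, null$lower + 1, null$upper + 1,
                          n_boot = 30, kind = "spd")
  rep1 <- detect_departures(obs_hi, null)
  expect_equal(nrow(rep1$positive_intervals), 1L)
  expect_equal(rep1$positive_intervals$old, max(g))
  expect_equal(rep1$positive_intervals$young, min(g))
  expect_gt(rep1$statistic, 0)
  expect_equal(rep1$global_p, 1 / 31)            # Monte Carlo floor
  expect_lt(rep1$gaussian_p, 1e-6)               # sub-floor tail approximation
  expect_gte(rep1$global_p, 1 / (1 + null$n_boot))
})

test_that("a synthetic boom is flagged as a positive departure over its span", {
  tc <- toy_curves(c(2000, 10000))
  # truth: flat background with a boom at 6500-6000
  set.seed(17)
  years <- c(round(runif(60, 4000, 8000)), round(runif(60, 6000, 6500)))
  d <- toy_dates(rep(6000, length(years)), error = 40,
                 site_id = paste0("S", seq_along(years)))
  d$cra <- round(curve_at(tc$atm, years)$mu + rnorm(length(years), 0, 40))
  dens <- c14demog:::calibrate_dates(d, tc$atm)
  bins <- bin_phases(d, tc$atm, densities = dens, seed = 2)
  obs <- bootstrap_spd(bins, d, tc$atm, n_boot = 80, seed = 3,
                       densities = dens, correct_open_air = FALSE)
  fit <- fit_exponential(obs, c(8000, 4000))
  null <- simulate_null(fit, n_dates = length(bins), error_pool = d$error,
                        atm = tc$atm, n_boot = 80, seed = 4, grid = obs$grid)
  rept <- detect_departures(obs, null)
  expect_gt(nrow(rept$positive_intervals), 0L)
  # the flagged positive interval overlaps the injected boom span
  overlap <- any(rept$positive_intervals$old >= 6000 &
                   rept$positive_intervals$young <= 6500)
  expect_true(overlap)
  expect_lt(rept$global_p, 0.1)
})
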