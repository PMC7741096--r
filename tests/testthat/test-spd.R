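test_that("sum_densities accumulates mass like a brute-force loop", {
  g <- seq(100, 300, by = 1)
  d1 <- cal_density(150:160, rep(1, 11))
  expect_equal(sum(sum_densities(list(d1, d1), g)), 2)
  # one date: SPD equals the calibrated density
  s1 <- sum_densities(list(d1), g)
  expect_equal(s1[match(d1$grid, g)], d1$mass)
  # n random densities pointwise equal a brute-force accumulation
  set.seed(3)
  ds <- lapply(1:7, function(i) {
    start <- sample(100:250, 1)
    cal_density(start:(start + 30), runif(31))
  })
  brute <- numeric(length(g))
  for (d in ds) for (k in seq_along(d$grid)) {
    i <- match(d$grid[k], g); brute[i] <- brute[i] + d$mass[k]
  }
  expect_equal(sum_densities(ds, g), brute)
  expect_equal(sum_densities(list(), g), numeric(length(g)))
})

test_that("taphonomic survival follows the adopted power law", {
  expect_equal(taphonomic_survival(0), 5.726442e6 * 2176.4^(-1.3925309))
  t <- seq(0, 15000, by = 250)
  expect_true(all(diff(taphonomic_survival(t)) < 0))
  # log-space oracle for a ratio
  r <- taphonomic_survival(10000) / taphonomic_survival(1000)
  r_log <- exp(-1.3925309 * (log(10000 + 2176.4) - log(1000 + 2176.4)))
  expect_equal(r, r_log, tolerance = 1e-12)
  expect_error(taphonomic_survival(-3000), "undefined")
})

test_that("build_spd corrects open-air records and conserves mass", {
  cv <- identity_curve(c(0, 12000))
  # all closed: plain sum
  d <- toy_dates(c(5000, 6000, 7000), error = 40,
                 site_id = c("A", "B", "C"), site_type = "closed")
  bins <- bin_phases(d, cv, h = 30, seed = 1)
  dens <- c14demog:::calibrate_dates(d, cv)
  spd <- build_spd(bins, d, cv, densities = dens)
  plain <- sum_densities(dens, spd$grid)
  expect_equal(spd$mean, plain)
  expect_equal(sum(spd$mean), 3, tolerance = 1e-9)

  # correction off: same as plain sum even with open-air sites
  d2 <- d; d2$site_type <- c("open_air", "closed", "open_air")
  bins2 <- bin_phases(d2, cv, h = 30, seed = 1)
  spd2 <- build_spd(bins2, d2, cv, correct_open_air = FALSE, densities = dens)
  expect_equal(spd2$mean, plain)

  # correction on: open-air share reweighted by 1/n(t), mass conserved
  spd3 <- build_spd(bins2, d2, cv, correct_open_air = TRUE, densities = dens)
  expect_equal(sum(spd3$mean), 3, tolerance = 1e-9)
  open_plain <- sum_densities(dens[c(1, 3)], spd$grid)
  open_corr <- open_plain / taphonomic_survival(spd$grid)
  open_corr <- open_corr * 2 / sum(open_corr)
  expect_equal(spd3$mean, sum_densities(dens[2], spd$grid) + open_corr,
               tolerance = 1e-12)
  # hand check on a flat single open-air density: corrected SPD ~ 1/n(t)
  flat <- cal_density(1000:1002, rep(1 / 3, 3))
  w <- (1 / taphonomic_survival(1000:1002))
  expect_equal(open_corr_profile <- {
    x <- flat$mass / taphonomic_survival(flat$grid); x / sum(x)
  }, w / sum(w), tolerance = 1e-12)

  d_bad <- d; d_bad$site_type[2] <- "weird"
  expect_error(build_spd(bins, d_bad, cv, densities = dens), "site_type")
})

test_that("bootstrap_spd is reproducible, degenerate on one bin, and ordered", {
  cv <- identity_curve(c(0, 12000))
  set.seed(8)
  d <- toy_dates(round(runif(24, 5000, 7000)), error = 45,
                 site_id = sample(paste0("S", 1:5), 24, replace = TRUE))
  bins <- bin_phases(d, cv, h = 30, seed = 2)
  dens <- c14demog:::calibrate_dates(d, cv)
  b1 <- bootstrap_spd(bins, d, cv, n_boot = 40, seed = 7, densities = dens)
  b2 <- bootstrap_spd(bins, d, cv, n_boot = 40, seed = 7, densities = dens)
  expect_identical(b1$mean, b2$mean)
  expect_identical(b1$lower, b2$lower)
  expect_true(all(b1$lower <= b1$mean + 1e-12 & b1$mean <= b1$upper + 1e-12))

  # single unique bin with one member: resampling is degenerate
  d1 <- toy_dates(6000, error = 40)
  bin1 <- bin_phases(d1, cv, h = 30, seed = 1)
  bb <- bootstrap_spd(bin1, d1, cv, n_boot = 10, seed = 1)
  expect_equal(bb$lower, bb$upper)
  expect_equal(bb$lower, bb$mean)
  expect_error(bootstrap_spd(bins, d, cv, n_boot = 1, densities = dens), "n_boot")
})

test_that("bootstrap envelope covers a known truth and widens with fewer bins", {
  cv <- identity_curve(c(0, 12000))
  set.seed(12)
  width_for_n <- function(n) {
    d <- toy_dates(round(runif(n, 5000, 6000)), error = 40,
                   site_id = paste0("S", seq_len(n)))
    bins <- bin_phases(d, cv, h = 30, seed = 3)
    dens <- c14demog:::calibrate_dates(d, cv)
    b <- bootstrap_spd(bins, d, cv, n_boot = 60, seed = 4, densities = dens)
    mean(b$upper - b$lower) / n   # per-date envelope width
  }
  expect_gt(width_for_n(10), width_for_n(40))
})
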