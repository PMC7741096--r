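test_that("single-point KDE is the Gaussian kernel and integrates to one", {
  cv <- identity_curve(c(0, 12000), sigma = 0)
  # two sites, all calibrated mass at the same year: every draw is 6000
  d <- toy_dates(c(6000, 6000), error = 1, site_id = c("A", "B"))
  bins <- bin_phases(d, cv, seed = 1)
  dens <- list(T001 = cal_density(6000, 1), T002 = cal_density(6000, 1))
  kde <- kde_model(bins, d, cv, bandwidth = 150, n_boot = 5, seed = 2,
                   densities = dens, grid_step = 10)
  expect_equal(kde$mean, dnorm(kde$grid, 6000, 150), tolerance = 1e-9)
  expect_equal(sum(kde$mean) * 10, 1, tolerance = 1e-6)
  expect_true(all(abs(rowSums(kde$replicates) * 10 - 1) < 1e-6))
})

test_that("KDE equals a brute-force kernel sum and reproduces under seed", {
  cv <- identity_curve(c(0, 12000))
  set.seed(21)
  d <- toy_dates(round(runif(15, 5000, 7000)), error = 35,
                 site_id = paste0("S", 1:15))
  bins <- bin_phases(d, cv, seed = 1)
  dens <- c14demog:::calibrate_dates(d, cv)
  kde <- kde_model(bins, d, cv, bandwidth = 150, n_boot = 20, seed = 9,
                   densities = dens, grid_step = 10)
  kde2 <- kde_model(bins, d, cv, bandwidth = 150, n_boot = 20, seed = 9,
                    densities = dens, grid_step = 10)
  expect_identical(kde$replicates, kde2$replicates)
  # brute-force oracle for fixed draws on a 1-yr grid
  draws <- c(5200, 5800, 6400)
  g <- seq(4000, 8000, by = 1)
  brute <- sapply(g, function(t) mean(dnorm(t - draws, sd = 150)))
  mine <- c14demog:::kernel_density_grid(draws, g, 150, 1)
  expect_equal(mine, brute, tolerance = 1e-12)
})

test_that("growth of an exact exponential is its exponent, to 1e-6 relative", {
  g <- seq(4000, 9000, by = 10)   # K stays above the 1e-12 mask floor
  k <- exp(-0.004 * g); k <- k / (sum(k) * 10)
  reps <- rbind(k, k, k)
  kde <- density_model(g, k, kind = "kde", n_boot = 3, replicates = reps,
                       coverage = 0.954)
  gr <- growth_rate(kde)
  interior <- 2:(length(g) - 1)
  expect_lt(max(abs(gr$mean[interior] - 0.4)) / 0.4, 1e-6)
  expect_equal(gr$kind, "growth")
})

test_that("growth rate crosses zero at a Gaussian KDE's mode and matches a
           Richardson-checked finite-difference oracle", {
  g <- seq(2000, 10000, by = 10)
  k <- dnorm(g, 6000, 400)
  kde <- density_model(g, k, kind = "kde", n_boot = 2,
                       replicates = rbind(k, k), coverage = 0.954)
  gr <- growth_rate(kde)
  i0 <- which(g == 6000)
  expect_equal(gr$mean[i0], 0, tolerance = 1e-9)
  expect_true(all(gr$mean[g > 6100 & g < 7500] > 0))   # growth toward present
  expect_true(all(gr$mean[g < 5900 & g > 4500] < 0))
  # random smooth density: oracle at half the step agrees (Richardson)
  set.seed(5)
  f <- function(t) dnorm(t, 5500, 700) + 0.5 * dnorm(t, 7000, 500)
  k2 <- f(g)
  gr2 <- growth_rate(density_model(g, k2, kind = "kde", n_boot = 2,
                                   replicates = rbind(k2, k2)))
  gh <- seq(2000, 10000, by = 5)
  k2h <- f(gh)
  grh <- growth_rate(density_model(gh, k2h, kind = "kde", n_boot = 2,
                                   replicates = rbind(k2h, k2h)))
  at <- g > 3500 & g < 9000
  match_h <- match(g[at], gh)
  expect_equal(gr2$mean[at], grh$mean[match_h], tolerance = 1e-3)
  expect_error(growth_rate(density_model(c(1, 2, 4), 1:3, kind = "kde",
                                         n_boot = 2,
                                         replicates = rbind(1:3, 1:3))),
               "uniform")
})

test_that("extract_phases reads rectangular rate series correctly", {
  g <- seq(8000, 11000, by = 10)
  r <- ifelse(g <= 10000 & g >= 9000, 0.3, -0.1)
  gp <- density_model(g, r, kind = "growth", n_boot = 2,
                      replicates = rbind(r, r), coverage = 0.954)
  ph <- extract_phases(gp, min_phase_span = 200)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$start, 10000)
  expect_equal(ph$t_pop_max, 9000)
  expect_equal(ph$duration, 1000)
  expect_equal(ph$max_rate, 0.3)
  # all-negative series: no phases
  rneg <- rep(-0.05, length(g))
  ph0 <- extract_phases(density_model(g, rneg, kind = "growth", n_boot = 2,
                                      replicates = rbind(rneg, rneg)))
  expect_equal(nrow(ph0), 0L)
  # short positive blips below min_phase_span are ignored
  rblip <- ifelse(g <= 9550 & g >= 9450, 0.5, -0.1)
  phb <- extract_phases(density_model(g, rblip, kind = "growth", n_boot = 2,
                                      replicates = rbind(rblip, rblip)),
                        min_phase_span = 200)
  expect_equal(nrow(phb), 0L)
})

test_that("two injected booms are recovered in order on synthetic data", {
  # full-size scenario: the first boom sits behind a sparse lull and needs
  # the default date density to clear the reliability mask
  scn <- population_scenario(seed = 31)
  sim <- make_dataset(scn)
  dts <- screen_dates(sim$dates)
  dens <- c14demog:::calibrate_dates(dts, sim$atm, sim$mar)
  bins <- bin_phases(dts, sim$atm, sim$mar, densities = dens, seed = 31)
  kde <- kde_model(bins, dts, sim$atm, sim$mar, n_boot = 80, seed = 31,
                   densities = dens)
  ph <- extract_phases(growth_rate(kde))
  expect_gte(nrow(ph), 2L)
  truth <- sim$truth$phases
  starts_true <- vapply(truth, function(p) p$start, numeric(1))
  # for each true boom there is an extracted phase starting within 600 yr
  for (st in starts_true[vapply(truth, function(p) p$max_rate, 0) >= 0.2]) {
    expect_lt(min(abs(ph$start - st)), 600)
  }
})
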