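test_that("piecewise-exponential curves interpolate log-linearly", {
  bp <- data.frame(t = c(10000, 9000, 8000), level = c(1, 10, 5))
  pc <- piecewise_exp_curve(bp)
  expect_equal(pc$level[pc$grid == 10000], 1)
  expect_equal(pc$level[pc$grid == 9000], 10)
  # halfway in log space
  expect_equal(pc$level[pc$grid == 9500], sqrt(10), tolerance = 1e-12)
  # closed-form segment rates
  sr <- c14demog:::true_segment_rates(bp)
  expect_equal(sr$rate, c(100 * log(10) / 1000, 100 * log(0.5) / 1000))
})

test_that("default scenario encodes the stated booms with closed-form truth", {
  scn <- population_scenario()
  tp <- scn |> (\(s) c14demog:::true_phases(s$breakpoints))()
  starts <- vapply(tp, function(p) p$start, numeric(1))
  rates <- vapply(tp, function(p) p$max_rate, numeric(1))
  expect_true(any(abs(starts - 10300) < 1e-9 & abs(rates - 0.40) < 1e-9))
  expect_true(any(abs(starts - 8700) < 1e-9 & abs(rates - 0.25) < 1e-9))
  expect_error(population_scenario(breakpoints = data.frame(t = c(2, 1),
                                                            level = c(1, -1))),
               "positive")
})

test_that("flat curve with no taphonomy yields uniform event years", {
  scn <- population_scenario(
    breakpoints = data.frame(t = c(10000, 5000), level = c(1, 1)),
    n_dates = 5000L, open_air_fraction = 0, site_count = 30L,
    clustering_schedule = data.frame(t = c(10000, 5000), sd_km = c(100, 100)),
    seed = 19)
  ev <- sample_events(scn)
  expect_equal(nrow(ev), 5000L)
  expect_true(all(ev$site_type == "closed"))
  h <- hist(ev$year, breaks = seq(5000, 10000, by = 500), plot = FALSE)
  gof <- chisq.test(h$counts)
  expect_gt(gof$p.value, 0.01)
  # seed reproducibility
  ev2 <- sample_events(scn)
  expect_identical(ev, ev2)
})

test_that("a two-level step curve doubles event mass where the level triples", {
  scn <- population_scenario(
    breakpoints = data.frame(t = c(10000, 8001, 8000, 6000),
                             level = c(1, 1, 3, 3)),
    n_dates = 4000L, open_air_fraction = 0, site_count = 30L,
    clustering_schedule = data.frame(t = c(10000, 6000), sd_km = c(100, 100)),
    seed = 23)
  ev <- sample_events(scn)
  n_hi <- sum(ev$year < 8000)
  n_lo <- sum(ev$year > 8001)
  ratio <- n_hi / n_lo            # expect ~3 with multinomial noise
  expect_lt(abs(ratio - 3), 0.4)
})

test_that("uncalibrate inverts calibration within curve error", {
  cv <- identity_curve(c(0, 12000), sigma = 0)
  set.seed(29)
  u <- uncalibrate(6000, cv, lab_error = 1e-9)
  expect_equal(u$cra, 6000)
  # mean of many draws approaches mu(year)
  tc <- synth_cal_curve(c(0, 12000))
  mu <- curve_at(tc, 7000)$mu
  draws <- replicate(2000, uncalibrate(7000, tc, 30)$cra)
  se <- sqrt(curve_at(tc, 7000)$sigma^2 + 30^2) / sqrt(2000)
  expect_lt(abs(mean(draws) - mu), 4 * se + 0.5)
  expect_error(uncalibrate(20000, cv, 30), "outside")
})

test_that("calibrating generated dates recovers the true year (coverage)", {
  tc <- synth_cal_curve(c(2000, 12000))
  set.seed(37)
  hits <- 0; n <- 120
  for (i in seq_len(n)) {
    yr <- round(runif(1, 4000, 10000))
    u <- uncalibrate(yr, tc, 40)
    d <- c14demog:::calibrate_cra(u$cra, u$error, tc)
    o <- order(d$mass, decreasing = TRUE)
    hdi <- d$grid[o[seq_len(which(cumsum(d$mass[o]) >= 0.95)[1])]]
    if (yr >= min(hdi) && yr <= max(hdi)) hits <- hits + 1
  }
  expect_gte(hits / n, 0.90)
})

test_that("make_dataset emits schema-valid tables plus usable ground truth", {
  scn <- small_scenario(seed = 41)
  dir <- withr::local_tempdir()
  sim <- make_dataset(scn, dir = dir)
  # tables re-read through the pipeline's own readers
  dts <- read_c14_dates(sim$paths$dates)
  expect_equal(nrow(dts), scn$n_dates)
  iso <- read_isotopes(sim$paths$isotopes)
  expect_equal(nrow(iso), scn$n_iso)
  prox <- read_proxy(sim$paths$proxy)
  expect_s3_class(prox, "proxy_series")
  # ground truth round-trips through JSON
  truth <- jsonlite::read_json(sim$paths$truth, simplifyVector = TRUE)
  expect_equal(sort(truth$breakpoints$t), sort(scn$breakpoints$t))
  expect_equal(truth$diet_peak$t, 7800)
  # contamination present so screening has work
  expect_gt(sum(dts$context_flag == "insecure" | dts$error > 200), 0)
  expect_lt(nrow(screen_dates(dts)), nrow(dts))
  # isotope CRAs calibrate back near their true years on the mixed curve
  k <- which(iso$fraction_marine > 0)[1]
  expect_false(is.na(k))
})

test_that("the proxy series tracks the population curve by construction", {
  scn <- population_scenario(seed = 43,
                             proxy_link = c(gain = 1, noise_sd = 0.05, ar1 = 0.2))
  sim <- make_dataset(scn)
  pc <- piecewise_exp_curve(scn$breakpoints,
                            grid = sim$proxy$t_calBP)
  rho <- cor(sim$proxy$value, log(pc$level), method = "spearman")
  expect_gt(rho, 0.7)
})

test_that("zero-noise diet generation reproduces the injected ramp", {
  scn <- small_scenario(seed = 47,
                        diet_trend = c(peak_calBP = 7800, peak_d13c = -16,
                                       baseline_d13c = -20.5, noise_sd = 0,
                                       half_width = 700))
  sim <- make_dataset(scn)
  iso <- sim$isotopes
  ramp <- pmax(0, 1 - abs(iso$true_year - 7800) / 700)
  expect_equal(iso$d13c, round(-20.5 + 4.5 * ramp, 2), tolerance = 0.01)
})

test_that("scenarios round-trip through JSON config files", {
  path <- withr::local_tempfile(fileext = ".json")
  # exactly representable parameters: JSON keeps ~15 significant digits, so
  # irrational levels would shift the sampler by an ULP
  scn <- population_scenario(n_dates = 150L, seed = 9,
                             breakpoints = data.frame(
                               t = c(12000, 10000, 9000, 7000),
                               level = c(1, 0.5, 8, 2)),
                             diet_trend = c(peak_calBP = 7500, peak_d13c = -15,
                                            baseline_d13c = -20, noise_sd = 0.4,
                                            half_width = 600))
  write_scenario(scn, path)
  back <- read_scenario(path)
  expect_equal(back$n_dates, 150L)
  expect_equal(back$seed, 9L)
  expect_equal(back$breakpoints$level, scn$breakpoints$level)
  expect_equal(unname(back$diet_trend[["peak_calBP"]]), 7500)
  # identical datasets from original and round-tripped scenarios
  s1 <- sample_events(scn)
  s2 <- sample_events(back)
  expect_identical(s1, s2)
  expect_error(read_scenario("/nope/missing.json"), "not found")
})
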