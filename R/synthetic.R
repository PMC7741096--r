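# Synthetic dataset generator with known ground truth.
#
# Emits complete, schema-valid inputs for every pipeline stage: radiocarbon
# event dates drawn from a piecewise-exponential population curve (stadial
# crash + two Holocene booms), open-air vs closed site types with taphonomic
# loss, site coordinates with time-varying spatial clustering, lab errors,
# a d13C trend peaking then reversing, and an environmental proxy series
# correlated with the population curve. Piecewise-exponential truth curves
# make the growth rate an exact closed-form target per segment.

#' Define a synthetic population scenario
#'
#' Defaults state the package's reference world: a Late Glacial background,
#' a stadial crash over 12800-11700 cal BP, a first demographic boom at
#' sustained 0.40 %/yr from 10300 to a population maximum at 9400 cal BP, a
#' bust, a second boom at 0.25 %/yr from 8700 to 7750 cal BP, and decline
#' thereafter; a dietary d13C peak at 7800 cal BP; and fivefold spatial
#' clustering of sites across the Holocene. All values are scenario
#' parameters of a synthetic world, not estimates.
#'
#' @param breakpoints data.frame `t` (cal BP, decreasing toward present) and
#'   `level` (relative population, > 0); log-linear (i.e. exponential)
#'   interpolation between breakpoints.
#' @param n_dates number of radiocarbon dates to generate.
#' @param open_air_fraction proportion of sites that are open-air.
#' @param error_distribution `c(log_mean, log_sd)` of lognormal lab errors (yr).
#' @param site_count number of sites.
#' @param site_span temporal footprint of one site, yr (events cluster around
#'   a site's characteristic time on this scale).
#' @param clustering_schedule data.frame `t` (cal BP), `sd_km` (spatial SD of
#'   the site cluster at that time; linear interpolation between knots).
#' @param diet_trend list/vector with `peak_calBP`, `peak_d13c`,
#'   `baseline_d13c`, `noise_sd`, `half_width` (triangular ramp half-width, yr).
#' @param n_iso number of isotope individuals.
#' @param iso_range `c(old, young)` cal BP range with isotope coverage.
#' @param proxy_link `c(gain, noise_sd, ar1)` for the proxy series.
#' @param contaminated_fraction fraction of dates emitted with an insecure
#'   context or oversized error, exercising the screening step.
#' @param center lon/lat of the region's spatial centre.
#' @param seed scenario seed.
#' @return object of class `population_scenario`.
#' @export
population_scenario <- function(
    breakpoints = default_breakpoints(),
    n_dates = 300L,
    open_air_fraction = 0.5,
    error_distribution = c(log_mean = log(45), log_sd = 0.35),
    site_count = 62L,
    site_span = 400,
    clustering_schedule = data.frame(t = c(14000, 11000, 10500, 8200, 7000),
                                     sd_km = c(60, 250, 250, 50, 50)),
    diet_trend = c(peak_calBP = 7800, peak_d13c = -16, baseline_d13c = -20.5,
                   noise_sd = 0.6, half_width = 700),
    n_iso = 54L,
    iso_range = c(8500, 7000),
    proxy_link = c(gain = 1, noise_sd = 0.25, ar1 = 0.7),
    contaminated_fraction = 0.05,
    center = c(lon = -8.5, lat = 39.5),
    seed = 1L) {
  if (any(breakpoints$level <= 0)) stop("population levels must be positive")
  if (is.unsorted(rev(breakpoints$t), strictly = TRUE) &&
      is.unsorted(breakpoints$t, strictly = TRUE))
    stop("breakpoints must be monotone in time")
  stopifnot_scalar_prob(open_air_fraction, "open_air_fraction")
  stopifnot_scalar_prob(contaminated_fraction, "contaminated_fraction")
  structure(list(breakpoints = breakpoints[order(-breakpoints$t), ],
                 n_dates = as.integer(n_dates),
                 open_air_fraction = open_air_fraction,
                 error_distribution = error_distribution,
                 site_count = as.integer(site_count), site_span = site_span,
                 clustering_schedule = clustering_schedule,
                 diet_trend = diet_trend, n_iso = as.integer(n_iso),
                 iso_range = iso_range, proxy_link = proxy_link,
                 contaminated_fraction = contaminated_fraction,
                 center = center, seed = as.integer(seed)),
            class = "population_scenario")
}

#' Default truth-curve breakpoints
#'
#' Piecewise-exponential population curve whose segment rates encode the
#' reference narrative: mild Late Glacial growth, a crash through the
#' stadial, near-flat recovery, boom at 0.40 %/yr (10300-9400 cal BP),
#' bust at -0.20 %/yr, boom at 0.25 %/yr (8700-7750 cal BP), then decline.
#' Levels are computed from the stated per-segment rates.
#' @return data.frame `t`, `level`.
#' @export
default_breakpoints <- function() {
  t <- c(14000, 12800, 11700, 10300, 9400, 8700, 7750, 7000)
  # per-segment annualized rates (% per yr), toward the present
  rates <- c(0.034, -0.063, -0.006, 0.40, -0.20, 0.25, -0.30)
  level <- numeric(length(t))
  level[1] <- 0.8
  for (i in seq_along(rates))
    level[i + 1] <- level[i] * exp(rates[i] / 100 * (t[i] - t[i + 1]))
  data.frame(t = t, level = level)
}

#' Evaluate a piecewise-exponential population curve
#'
#' Log-linear interpolation of the breakpoint levels, on a 1-yr grid.
#' @param breakpoints data.frame `t`, `level`.
#' @param grid cal BP grid; defaults to 1-yr over the breakpoint range.
#' @return list `grid`, `level`.
#' @export
piecewise_exp_curve <- function(breakpoints, grid = NULL) {
  bp <- breakpoints[order(breakpoints$t), ]
  if (is.null(grid)) grid <- seq(min(bp$t), max(bp$t), by = 1)
  lv <- exp(stats::approx(bp$t, log(bp$level), xout = grid, rule = 2)$y)
  list(grid = grid, level = lv)
}

#' Sample dated events from a scenario
#'
#' Event calendar years are drawn i.i.d. with probability proportional to
#' curve(t), additionally thinned by [taphonomic_survival()] for events at
#' open-air sites (emulating preferential loss of older open-air deposits).
#' Sites get a characteristic time (drawn from the curve) and coordinates
#' from a Gaussian cluster whose SD follows the clustering schedule; each
#' event is attached to a site of its type with weight decaying over the
#' site's temporal footprint, so sites are time-coherent while the marginal
#' year distribution stays exact.
#'
#' @param scn a [population_scenario()].
#' @return data.frame `year`, `site_id`, `site_type`, `lon`, `lat`,
#'   `x_km`, `y_km`.
#' @export
sample_events <- function(scn) {
  pc <- piecewise_exp_curve(scn$breakpoints)
  if (all(pc$level <= 0)) stop("population curve has zero mass")
  with_seed(stream_seed(scn$seed, "sample-events"), {
    n_open_sites <- round(scn$site_count * scn$open_air_fraction)
    types <- rep(c("open_air", "closed"),
                 c(n_open_sites, scn$site_count - n_open_sites))
    char_t <- sample(pc$grid, scn$site_count, replace = TRUE, prob = pc$level)
    sd_km <- stats::approx(scn$clustering_schedule$t,
                           scn$clustering_schedule$sd_km,
                           xout = char_t, rule = 2)$y
    x_km <- stats::rnorm(scn$site_count, 0, sd_km)
    y_km <- stats::rnorm(scn$site_count, 0, sd_km)
    sites <- data.frame(
      site_id = sprintf("SYN%02d", seq_len(scn$site_count)),
      site_type = types, char_t = char_t, x_km = x_km, y_km = y_km,
      lon = scn$center["lon"] + x_km / (111.32 * cos(scn$center["lat"] * pi / 180)),
      lat = scn$center["lat"] + y_km / 110.57)
    # open-air share of events follows the open-air share of sites
    ev_open <- stats::runif(scn$n_dates) < n_open_sites / scn$site_count
    taph <- taphonomic_survival(pc$grid)
    years <- numeric(scn$n_dates)
    site_idx <- integer(scn$n_dates)
    w_open <- pc$level * taph
    for (k in seq_len(scn$n_dates)) {
      w <- if (ev_open[k]) w_open else pc$level
      years[k] <- sample(pc$grid, 1L, prob = w)
      cand <- which(sites$site_type == (if (ev_open[k]) "open_air" else "closed"))
      sw <- stats::dnorm(years[k] - sites$char_t[cand], sd = scn$site_span)
      if (sum(sw) <= 0) sw <- rep(1, length(cand))
      site_idx[k] <- cand[sample.int(length(cand), 1L, prob = sw)]
    }
    data.frame(year = years,
               site_id = sites$site_id[site_idx],
               site_type = sites$site_type[site_idx],
               lon = sites$lon[site_idx], lat = sites$lat[site_idx],
               x_km = sites$x_km[site_idx], y_km = sites$y_km[site_idx],
               row.names = NULL)
  })
}

#' Back-transform a calendar year to a simulated radiocarbon measurement
#'
#' The inverse of calibration: a CRA is drawn from
#' Normal(mu(year), sqrt(sigma(year)^2 + lab_error^2)) and rounded to the
#' nearest year. Uses the caller's RNG stream (seed where you need
#' reproducibility).
#'
#' @param year true calendar age, cal BP (inside the curve range).
#' @param curve a [cal_curve()].
#' @param lab_error 1-sigma lab error, yr.
#' @return list `cra`, `error`.
#' @export
uncalibrate <- function(year, curve, lab_error) {
  q <- curve_at(curve, year)
  cra <- round(stats::rnorm(1, q$mu, sqrt(q$sigma^2 + lab_error^2)))
  list(cra = cra, error = lab_error)
}

# triangular ramp in [0,1] peaking at `peak` with the given half-width
triangular_ramp <- function(t, peak, half_width) {
  pmax(0, 1 - abs(t - peak) / half_width)
}

#' Generate a complete synthetic dataset
#'
#' Emits the three pipeline input tables (radiocarbon dates, human isotopes,
#' environmental proxy) in the package's CSV schemas plus a ground-truth
#' record sufficient to score phase recovery, distance contraction, and the
#' diet peak. Radiocarbon dates are back-transformed through the supplied
#' (or synthetic) curves with lognormal lab errors; a small contaminated
#' fraction carries insecure contexts or oversized errors so the screening
#' stage has work to do. Isotope individuals get a triangular d13C ramp
#' peaking at the scenario's diet peak, with marine diet fractions mapped
#' from the noiseless ramp; the proxy is the standardized 400-yr-smoothed
#' log population curve times a gain, plus AR(1) noise on a 50-yr lattice.
#'
#' @param scn a [population_scenario()].
#' @param atm,mar calibration curves; default [synth_cal_curve()] pair
#'   covering the scenario range.
#' @param dir optional directory; when given, writes `dates.csv`,
#'   `isotopes.csv`, `proxy.csv`, `truth.json` there.
#' @return list `dates`, `isotopes`, `proxy` (data.frames), `truth` (list),
#'   and `paths` when `dir` was given.
#' @export
make_dataset <- function(scn, atm = NULL, mar = NULL, dir = NULL) {
  rng <- range(scn$breakpoints$t)
  if (is.null(atm))
    atm <- synth_cal_curve(c(max(0, rng[1] - 2000), rng[2] + 2000), "atmospheric")
  if (is.null(mar))
    mar <- synth_cal_curve(c(max(0, rng[1] - 2000), rng[2] + 2000), "marine")
  ev <- sample_events(scn)
  n <- nrow(ev)
  dates <- with_seed(stream_seed(scn$seed, "uncalibrate"), {
    err <- exp(stats::rnorm(n, scn$error_distribution[["log_mean"]],
                            scn$error_distribution[["log_sd"]]))
    err <- pmax(15, round(err))
    cra <- numeric(n)
    for (k in seq_len(n)) cra[k] <- uncalibrate(ev$year[k], atm, err[k])$cra
    context <- rep("secure", n)
    n_bad <- round(scn$contaminated_fraction * n)
    if (n_bad > 0) {
      bad <- sample.int(n, n_bad)
      half <- bad[seq_len(ceiling(n_bad / 2))]
      context[half] <- "insecure"
      err[setdiff(bad, half)] <- sample(201:400, length(setdiff(bad, half)),
                                        replace = TRUE)
    }
    data.frame(lab_id = sprintf("LAB-%04d", seq_len(n)),
               site_id = ev$site_id, site_name = ev$site_id,
               cra = cra, error = err, site_type = ev$site_type,
               lon = ev$lon, lat = ev$lat,
               fraction_marine = 0, delta_r = 0, delta_r_sigma = 0,
               context_flag = context,
               x_km = ev$x_km, y_km = ev$y_km,
               true_year = ev$year)
  })

  dt <- scn$diet_trend
  isotopes <- with_seed(stream_seed(scn$seed, "isotopes"), {
    pc <- piecewise_exp_curve(scn$breakpoints)
    sel <- pc$grid <= scn$iso_range[1] & pc$grid >= scn$iso_range[2]
    yrs <- sample(pc$grid[sel], scn$n_iso, replace = TRUE, prob = pc$level[sel])
    ramp <- triangular_ramp(yrs, dt[["peak_calBP"]], dt[["half_width"]])
    d13c_true <- dt[["baseline_d13c"]] +
      (dt[["peak_d13c"]] - dt[["baseline_d13c"]]) * ramp
    d13c <- d13c_true + stats::rnorm(scn$n_iso, 0, dt[["noise_sd"]])
    f_mar <- pmin(1, pmax(0, 0.5 * ramp))
    err <- pmax(20, round(exp(stats::rnorm(scn$n_iso,
                                           scn$error_distribution[["log_mean"]],
                                           scn$error_distribution[["log_sd"]]))))
    cra <- numeric(scn$n_iso)
    for (k in seq_len(scn$n_iso)) {
      curve <- if (f_mar[k] > 0)
        mix_curves(atm, mar, f_mar[k], reservoir_offset(95, 15)) else atm
      cra[k] <- uncalibrate(yrs[k], curve, err[k])$cra
    }
    data.frame(individual_id = sprintf("IND-%03d", seq_len(scn$n_iso)),
               site = sprintf("SYN-EST%1d", 1 + (seq_len(scn$n_iso) %% 2)),
               group = ifelse(seq_len(scn$n_iso) %% 2 == 0, "EstuaryA", "EstuaryB"),
               cra = cra, error = err, d13c = round(d13c, 2),
               d15n = round(8 + 6 * f_mar + stats::rnorm(scn$n_iso, 0, 0.8), 2),
               fraction_marine = round(f_mar, 3),
               delta_r = ifelse(f_mar > 0, 95, 0),
               delta_r_sigma = ifelse(f_mar > 0, 15, 0),
               true_year = yrs)
  })

  proxy <- with_seed(stream_seed(scn$seed, "proxy"), {
    pl <- scn$proxy_link
    tgrid <- seq(rng[1], rng[2], by = 50)
    pc <- piecewise_exp_curve(scn$breakpoints, grid = seq(rng[1], rng[2], by = 1))
    logl <- log(pc$level)
    sm <- vapply(tgrid, function(tt) mean(logl[abs(pc$grid - tt) <= 200]),
                 numeric(1))
    z <- (sm - mean(sm)) / stats::sd(sm)
    ar <- stats::filter(stats::rnorm(length(tgrid), 0, pl[["noise_sd"]]),
                        pl[["ar1"]], method = "recursive")
    data.frame(t_calBP = tgrid, value = pl[["gain"]] * z + as.numeric(ar))
  })

  truth <- list(
    breakpoints = scn$breakpoints,
    segment_rates = true_segment_rates(scn$breakpoints),
    phases = true_phases(scn$breakpoints, min_phase_span = 200),
    diet_peak = list(t = unname(dt[["peak_calBP"]]),
                     d13c = unname(dt[["peak_d13c"]])),
    clustering_schedule = scn$clustering_schedule,
    seed = scn$seed)

  out <- list(dates = dates, isotopes = isotopes, proxy = proxy, truth = truth,
              atm = atm, mar = mar)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(dates = file.path(dir, "dates.csv"),
                  isotopes = file.path(dir, "isotopes.csv"),
                  proxy = file.path(dir, "proxy.csv"),
                  truth = file.path(dir, "truth.json"))
    utils::write.csv(dates, paths$dates, row.names = FALSE)
    utils::write.csv(isotopes, paths$isotopes, row.names = FALSE)
    utils::write.csv(proxy, paths$proxy, row.names = FALSE)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    out$paths <- paths
  }
  out
}

#' Read a population scenario from a JSON config file
#'
#' Fields mirror [population_scenario()] arguments; `breakpoints` and
#' `clustering_schedule` are objects of parallel arrays (`t`, `level` /
#' `sd_km`), named vectors are plain objects. Absent fields keep their
#' defaults.
#'
#' @param path JSON file path.
#' @return a [population_scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("n_dates", "open_air_fraction", "site_count", "site_span",
               "n_iso", "contaminated_fraction", "seed"))
    if (!is.null(js[[nm]])) args[[nm]] <- js[[nm]]
  if (!is.null(js$breakpoints))
    args$breakpoints <- as.data.frame(js$breakpoints)
  if (!is.null(js$clustering_schedule))
    args$clustering_schedule <- as.data.frame(js$clustering_schedule)
  for (nm in c("error_distribution", "diet_trend", "proxy_link", "iso_range",
               "center"))
    if (!is.null(js[[nm]])) args[[nm]] <- unlist(js[[nm]])
  do.call(population_scenario, args)
}

#' Write a population scenario to a JSON config file
#' @param scn a [population_scenario()].
#' @param path output path.
#' @export
write_scenario <- function(scn, path) {
  x <- unclass(scn)
  # named numeric vectors lose their names as JSON arrays; emit objects
  for (nm in c("error_distribution", "diet_trend", "proxy_link", "center"))
    x[[nm]] <- as.list(x[[nm]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

# closed-form annualized growth rate (%/yr) of each truth segment
true_segment_rates <- function(breakpoints) {
  bp <- breakpoints[order(-breakpoints$t), ]
  n <- nrow(bp)
  data.frame(old = bp$t[-n], young = bp$t[-1],
             rate = 100 * log(bp$level[-1] / bp$level[-n]) /
               (bp$t[-n] - bp$t[-1]))
}

# ground-truth growth phases: maximal sustained positive-rate segment runs
true_phases <- function(breakpoints, min_phase_span = 200) {
  seg <- true_segment_rates(breakpoints)
  pos <- logical_runs(seg$rate > 0)
  out <- list()
  for (i in seq_len(nrow(pos))) {
    s <- pos[i, "start"]; e <- pos[i, "end"]
    span <- seg$old[s] - seg$young[e]
    if (span < min_phase_span) next
    sub <- seg[s:e, ]
    imax <- which.max(sub$rate)
    out[[length(out) + 1L]] <- list(start = seg$old[s], t_pop_max = seg$young[e],
                                    duration = span,
                                    max_rate = sub$rate[imax],
                                    max_rate_span = c(sub$old[imax], sub$young[imax]))
  }
  out
}
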