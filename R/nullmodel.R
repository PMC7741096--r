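# Exponential null model: fit, simulation, and departure detection.
#
# Long-run background population growth is modelled as exponential; the
# question is where the observed SPD departs from it. Departures are scored
# conservatively by requiring the two bootstrap envelopes to be disjoint,
# which is robust against calibration-curve artefacts.

#' Fit an exponential curve to an SPD
#'
#' Least-squares fit of \eqn{A \exp(r (t_0 - t))} to the SPD mean over a
#' calendar window, with \eqn{t_0} the old end of the window: positive `rate`
#' means growth toward the present. The amplitude is profiled out analytically
#' and the rate found by 1-D minimization, so the fit is deterministic.
#'
#' @param spd a [density_model()] (kind `"spd"`).
#' @param window `c(old, young)` cal BP bounds, old > young.
#' @param rate_bounds search interval for the rate, per year.
#' @return object of class `exp_fit`: `amplitude`, `rate`, `window`, plus the
#'   fitted values' grid.
#' @export
fit_exponential <- function(spd, window, rate_bounds = c(-0.05, 0.05)) {
  window <- as.numeric(window)
  if (window[1] <= window[2]) stop("window must be c(old, young) with old > young")
  sel <- spd$grid <= window[1] & spd$grid >= window[2]
  if (!any(sel)) stop("window lies outside the SPD grid")
  t <- spd$grid[sel]; y <- spd$mean[sel]
  if (all(y == 0)) stop("SPD is identically zero in the window")
  t0 <- window[1]
  sse <- function(r) {
    e <- exp(r * (t0 - t))
    a <- sum(y * e) / sum(e * e)
    sum((y - a * e)^2)
  }
  opt <- stats::optimize(sse, interval = rate_bounds, tol = 1e-12)
  r <- opt$minimum
  e <- exp(r * (t0 - t))
  a <- sum(y * e) / sum(e * e)
  if (a <= 0) stop("fitted amplitude is non-positive")
  structure(list(amplitude = a, rate = r, window = window),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit: rate %.4g /yr (%.3g%%/yr), amplitude %.4g, window %g-%g cal BP>\n",
              x$rate, 100 * x$rate, x$amplitude, x$window[1], x$window[2]))
  invisible(x)
}

# evaluate an exp_fit on a grid
predict_exp_fit <- function(fit, grid) {
  fit$amplitude * exp(fit$rate * (fit$window[1] - grid))
}

#' Simulate the sampling distribution of an exponential null model
#'
#' Each replicate draws `n_dates` calendar years from the fitted exponential
#' density over its window, back-transforms each through the atmospheric
#' curve to a simulated CRA ([uncalibrate()]) with a lab error drawn from
#' `error_pool`, recalibrates, and sums. The pointwise quantile envelope of
#' the replicates is the null band an observed SPD is compared against.
#'
#' @param fit an [fit_exponential()] result.
#' @param n_dates dates per replicate (>= 2).
#' @param error_pool pool of 1-sigma lab errors (yr) sampled with replacement.
#' @param atm atmospheric [cal_curve()].
#' @param mar unused (interface symmetry); simulated dates are terrestrial.
#' @param n_boot replicates (default 1000).
#' @param coverage envelope coverage (default 0.954).
#' @param seed integer seed.
#' @param grid optional output grid; defaults to the fit window.
#' @return a [density_model()] of kind `"null"`, replicates retained.
#' @export
simulate_null <- function(fit, n_dates, error_pool, atm, mar = NULL,
                          n_boot = 1000, coverage = 0.954, seed = 1L,
                          grid = NULL) {
  if (n_dates < 2) stop("n_dates must be at least 2")
  if (length(error_pool) == 0L) stop("error_pool must be non-empty")
  win <- fit$window
  if (win[1] > max(atm$grid) || win[2] < min(atm$grid))
    stop("fit window lies outside the calibration curve")
  years <- seq(win[2], win[1], by = 1)
  wts <- predict_exp_fit(fit, years)
  if (is.null(grid)) grid <- years
  reps <- matrix(0, nrow = n_boot, ncol = length(grid))
  with_seed(stream_seed(seed, "null-model"), {
    for (b in seq_len(n_boot)) {
      yr <- sample(years, n_dates, replace = TRUE, prob = wts)
      err <- sample(error_pool, n_dates, replace = TRUE)
      dens <- vector("list", n_dates)
      for (k in seq_len(n_dates)) {
        uc <- uncalibrate(yr[k], atm, err[k])
        dens[[k]] <- calibrate_cra(uc$cra, uc$error, atm)
      }
      reps[b, ] <- sum_densities(dens, grid)
    }
  })
  env <- envelope_quantiles(reps, coverage)
  m <- colMeans(reps)
  density_model(grid, m, pmin(env$lower, m), pmax(env$upper, m),
                coverage = coverage, n_boot = n_boot, kind = "null",
                replicates = reps)
}

# exceedance statistic of a curve against an envelope
exceedance_stat <- function(curve, lower, upper) {
  sum(pmax(0, curve - upper)) + sum(pmax(0, lower - curve))
}

#' Detect significant departures from the null model
#'
#' Intervals where the observed SPD's bootstrap envelope lies entirely above
#' (positive departure) or entirely below (negative) the null model's
#' envelope, plus a global exceedance statistic
#' \eqn{\sum_t \max(0, obs(t) - null_{hi}(t)) + \max(0, null_{lo}(t) - obs(t))}
#' of the observed mean against the null band. The global p-value is the
#' Monte Carlo rank of that statistic among the null replicates, each scored
#' against the envelope of the remaining replicates (leave-one-out), with the
#' usual (1 + k)/(1 + n) correction; because that p cannot fall below
#' 1/(1 + n_boot), a Gaussian tail approximation on the null statistics'
#' mean and SD is reported alongside.
#'
#' @param obs observed SPD [density_model()] with envelope.
#' @param null a [simulate_null()] result (replicates required).
#' @return object of class `departure_report`: `positive_intervals` and
#'   `negative_intervals` (data.frames with `old`/`young` cal BP), `statistic`,
#'   `global_p`, `gaussian_p`.
#' @export
detect_departures <- function(obs, null) {
  # compare on the common grid
  keep_o <- obs$grid %in% null$grid
  keep_n <- null$grid %in% obs$grid
  if (!any(keep_o)) stop("observed and null models share no grid cells")
  og <- obs$grid[keep_o]
  if (!isTRUE(all.equal(og, null$grid[keep_n])))
    stop("observed and null grids are misaligned")
  o_lo <- obs$lower[keep_o]; o_hi <- obs$upper[keep_o]; o_m <- obs$mean[keep_o]
  n_lo <- null$lower[keep_n]; n_hi <- null$upper[keep_n]
  pos <- logical_runs(o_lo > n_hi)
  neg <- logical_runs(o_hi < n_lo)
  runs_df <- function(runs) {
    if (nrow(runs) == 0L)
      return(data.frame(old = numeric(0), young = numeric(0)))
    data.frame(old = og[runs[, "end"]], young = og[runs[, "start"]])
  }
  statistic <- exceedance_stat(o_m, n_lo, n_hi)

  reps <- null$replicates
  if (is.null(reps)) stop("null model carries no replicates; rerun simulate_null()")
  reps <- reps[, keep_n, drop = FALSE]
  n_boot <- nrow(reps)
  alpha <- (1 - null$coverage) / 2
  # leave-one-out empirical quantiles per cell via order statistics:
  # with n-1 values, take the k'-th order statistic, skipping the held-out one
  k_lo <- max(1L, ceiling(alpha * (n_boot - 1)))
  k_hi <- min(n_boot - 1L, ceiling((1 - alpha) * (n_boot - 1)))
  null_stats <- numeric(n_boot)
  ord <- apply(reps, 2, sort)                   # (n_boot x ncells), sorted cols
  rk <- apply(reps, 2, rank, ties.method = "first")
  for (b in seq_len(n_boot)) {
    r <- rk[b, ]
    idx_lo <- ifelse(k_lo < r, k_lo, k_lo + 1L)
    idx_hi <- ifelse(k_hi < r, k_hi, k_hi + 1L)
    cells <- seq_along(r)
    lo_b <- ord[cbind(idx_lo, cells)]
    hi_b <- ord[cbind(idx_hi, cells)]
    null_stats[b] <- exceedance_stat(reps[b, ], lo_b, hi_b)
  }
  global_p <- (1 + sum(null_stats >= statistic)) / (1 + n_boot)
  sd_n <- stats::sd(null_stats)
  gaussian_p <- if (sd_n > 0)
    stats::pnorm(statistic, mean = mean(null_stats), sd = sd_n,
                 lower.tail = FALSE)
  else as.numeric(statistic <= mean(null_stats))
  structure(list(positive_intervals = runs_df(pos),
                 negative_intervals = runs_df(neg),
                 statistic = statistic, global_p = global_p,
                 gaussian_p = gaussian_p, coverage = null$coverage),
            class = "departure_report")
}

#' @export
print.departure_report <- function(x, ...) {
  fmt <- function(df) if (nrow(df) == 0L) "none" else
    paste(sprintf("%g-%g", df$old, df$young), collapse = ", ")
  cat("<departure_report>\n")
  cat("  positive (above null):", fmt(x$positive_intervals), "\n")
  cat("  negative (below null):", fmt(x$negative_intervals), "\n")
  cat(sprintf("  statistic %.4g; global p = %.3g (Monte Carlo), %.3g (Gaussian tail)\n",
              x$statistic, x$global_p, x$gaussian_p))
  invisible(x)
}

#' Write a departure report as JSON
#' @param report a [detect_departures()] result.
#' @param fit the [fit_exponential()] used for the null.
#' @param path output path.
#' @export
write_departure_report <- function(report, fit, path) {
  jsonlite::write_json(list(
    fit = list(amplitude = fit$amplitude, rate_per_yr = fit$rate,
               window = fit$window),
    positive_intervals = report$positive_intervals,
    negative_intervals = report$negative_intervals,
    statistic = report$statistic,
    global_p = report$global_p,
    gaussian_p = report$gaussian_p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
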