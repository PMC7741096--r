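# Summed probability densities with taphonomic correction and bootstrap
# confidence envelopes.

#' Construct a density model time series
#'
#' Container for an SPD, KDE, growth-rate, or null-model series: a mean track
#' with an optional lower/upper envelope at a stated coverage level, and
#' optionally the replicate matrix it was computed from.
#'
#' @param grid cal BP grid (uniform step, ascending).
#' @param mean value per grid cell.
#' @param lower,upper envelope bounds (or `NA`).
#' @param coverage envelope coverage level in (0, 1).
#' @param n_boot number of replicates behind the envelope.
#' @param kind one of `"spd"`, `"kde"`, `"growth"`, `"null"`.
#' @param replicates optional `n_boot x length(grid)` matrix.
#' @export
density_model <- function(grid, mean, lower = NULL, upper = NULL,
                          coverage = 0.954, n_boot = 0L,
                          kind = c("spd", "kde", "growth", "null"),
                          replicates = NULL) {
  kind <- match.arg(kind)
  if (coverage <= 0 || coverage >= 1) stop("coverage must lie in (0, 1)")
  n <- length(grid)
  if (is.null(lower)) lower <- rep(NA_real_, n)
  if (is.null(upper)) upper <- rep(NA_real_, n)
  if (length(mean) != n || length(lower) != n || length(upper) != n)
    stop("grid and series lengths differ")
  ok <- !is.na(lower) & !is.na(upper) & !is.na(mean)
  if (any(lower[ok] > mean[ok] + 1e-12) || any(mean[ok] > upper[ok] + 1e-12))
    stop("envelope must satisfy lower <= mean <= upper")
  structure(list(grid = as.numeric(grid), mean = as.numeric(mean),
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 coverage = coverage, n_boot = as.integer(n_boot),
                 kind = kind, replicates = replicates),
            class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("<density_model [%s]: %d cells, %g-%g cal BP, coverage %.3f, n_boot %d>\n",
              x$kind, length(x$grid), min(x$grid), max(x$grid),
              x$coverage, x$n_boot))
  invisible(x)
}

#' @export
plot.density_model <- function(x, main = NULL, ylab = NULL, ...) {
  if (is.null(ylab))
    ylab <- switch(x$kind, growth = "growth rate (% per annum)",
                   "summed probability density")
  if (is.null(main)) main <- paste(toupper(x$kind), "model")
  plot(x$grid, x$mean, type = "n", xlim = rev(range(x$grid)),
       xlab = "cal BP", ylab = ylab, main = main, ...)
  if (!all(is.na(x$lower))) {
    ok <- !is.na(x$lower)
    graphics::polygon(c(x$grid[ok], rev(x$grid[ok])),
                      c(x$lower[ok], rev(x$upper[ok])),
                      col = grDevices::adjustcolor("steelblue", 0.35), border = NA)
  }
  graphics::lines(x$grid, x$mean, lwd = 1.5)
  invisible(x)
}

#' Write a density model to CSV
#' @param x a [density_model()].
#' @param path output CSV path.
#' @export
write_density_model <- function(x, path) {
  utils::write.csv(data.frame(cal_BP = x$grid, mean = x$mean,
                              lower = x$lower, upper = x$upper,
                              n_boot = x$n_boot, coverage = x$coverage),
                   path, row.names = FALSE)
  invisible(path)
}

# common ascending 1-step-aligned grid spanning a list of cal_density objects
common_grid <- function(densities, step = 1) {
  lo <- min(vapply(densities, function(d) min(d$grid), numeric(1)))
  hi <- max(vapply(densities, function(d) max(d$grid), numeric(1)))
  seq(lo, hi, by = step)
}

#' Sum calibrated densities on a common grid
#'
#' Pointwise sum of per-date probability masses. Each input density carries
#' unit mass, so the total mass of the sum equals the number of dates.
#'
#' @param densities list of [cal_density()].
#' @param grid target cal BP grid (uniform, ascending); cells outside a
#'   density's support contribute zero.
#' @return numeric mass vector on `grid`.
#' @export
sum_densities <- function(densities, grid) {
  out <- numeric(length(grid))
  if (length(densities) == 0L) return(out)
  g0 <- grid[1]
  step <- if (length(grid) > 1) grid[2] - grid[1] else 1
  for (d in densities) {
    i0 <- as.integer(round((d$grid[1] - g0) / step))
    idx <- i0 + seq_along(d$mass)
    ok <- idx >= 1L & idx <= length(out)
    out[idx[ok]] <- out[idx[ok]] + d$mass[ok]
  }
  out
}

#' Taphonomic survival model
#'
#' Power-law survival of open-air depositional contexts,
#' \eqn{n(t) = a (t + b)^c} with the global-model constants
#' a = 5.726442e6, b = 2176.4, c = -1.3925309: older open-air deposits are
#' preferentially lost, so their date counts underestimate past activity.
#'
#' @param t calendar age, cal BP (non-negative).
#' @return survival weight n(t), strictly decreasing in t.
#' @export
taphonomic_survival <- function(t) {
  if (any(t + 2176.4 <= 0)) stop("taphonomic model undefined for t + 2176.4 <= 0")
  5.726442e6 * (t + 2176.4)^(-1.3925309)
}

# one SPD realization from bins: representative densities, open-air record
# divided by taphonomic survival then rescaled to conserve open-air mass
spd_realization <- function(rep_ids, dates, densities, grid, correct_open_air) {
  type <- dates$site_type[match(rep_ids, dates$lab_id)]
  dens <- densities[rep_ids]
  if (!correct_open_air) return(sum_densities(dens, grid))
  open <- type == "open_air"
  spd_closed <- sum_densities(dens[!open], grid)
  n_open <- sum(open)
  if (n_open == 0L) return(spd_closed)
  spd_open <- sum_densities(dens[open], grid) / taphonomic_survival(grid)
  spd_open <- spd_open * (n_open / sum(spd_open))
  spd_closed + spd_open
}

#' Build a summed probability density from site phases
#'
#' One calibrated density per phase (its representative date). Open-air
#' phases are summed separately, divided by the taphonomic survival curve
#' [taphonomic_survival()] and rescaled so their total mass still equals the
#' open-air phase count; closed-site (cave/rockshelter) phases are then added
#' without correction.
#'
#' @param bins a [bin_phases()] result.
#' @param dates the screened date table (site types looked up by lab_id).
#' @param atm,mar calibration curves.
#' @param correct_open_air apply the taphonomic correction? (default TRUE)
#' @param densities optional precomputed calibrated densities by lab_id.
#' @param grid optional target grid; defaults to the union support.
#' @return a [density_model()] of kind `"spd"` (mean only).
#' @export
build_spd <- function(bins, dates, atm, mar = NULL, correct_open_air = TRUE,
                      densities = NULL, grid = NULL) {
  if (length(bins) == 0L) stop("no phase bins supplied")
  bad <- !dates$site_type %in% c("open_air", "closed")
  if (any(bad)) stop("unknown site_type: ",
                     paste(unique(dates$site_type[bad]), collapse = ", "))
  rep_ids <- vapply(bins, `[[`, "", "representative_id")
  if (is.null(densities))
    densities <- calibrate_dates(dates[dates$lab_id %in% unlist(lapply(bins, `[[`, "member_ids")), ], atm, mar)
  if (is.null(grid)) grid <- common_grid(densities)
  mean <- spd_realization(rep_ids, dates, densities, grid, correct_open_air)
  density_model(grid, mean, kind = "spd")
}

#' Bootstrap confidence envelope for the SPD
#'
#' Each replicate resamples phases with replacement (same count), re-draws
#' each sampled phase's representative uniformly from its members (so
#' intra-phase choice uncertainty enters the envelope), and rebuilds the SPD.
#' The envelope is the pointwise empirical quantile band at the requested
#' coverage; the mean is the pointwise replicate mean.
#'
#' @inheritParams build_spd
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param coverage envelope coverage (default 0.954, i.e. 2-sigma).
#' @param seed integer seed (dedicated stream).
#' @param keep_replicates retain the replicate matrix in the result?
#' @return a [density_model()] of kind `"spd"` with envelope.
#' @export
bootstrap_spd <- function(bins, dates, atm, mar = NULL, n_boot = 1000,
                          coverage = 0.954, seed = 1L, correct_open_air = TRUE,
                          densities = NULL, grid = NULL,
                          keep_replicates = FALSE) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  if (length(bins) < 1L) stop("no phase bins supplied")
  if (is.null(densities)) densities <- calibrate_dates(dates, atm, mar)
  member_ids <- unique(unlist(lapply(bins, `[[`, "member_ids")))
  if (is.null(grid)) grid <- common_grid(densities[member_ids])
  nb <- length(bins)
  reps <- matrix(0, nrow = n_boot, ncol = length(grid))
  with_seed(stream_seed(seed, "spd-bootstrap"), {
    for (b in seq_len(n_boot)) {
      pick <- sample.int(nb, nb, replace = TRUE)
      rep_ids <- vapply(bins[pick], function(bin) {
        mem <- bin$member_ids
        if (length(mem) == 1L) mem else mem[sample.int(length(mem), 1L)]
      }, "")
      reps[b, ] <- spd_realization(rep_ids, dates, densities, grid,
                                   correct_open_air)
    }
  })
  env <- envelope_quantiles(reps, coverage)
  m <- colMeans(reps)
  density_model(grid, m, pmin(env$lower, m), pmax(env$upper, m),
                coverage = coverage, n_boot = n_boot, kind = "spd",
                replicates = if (keep_replicates) reps else NULL)
}
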