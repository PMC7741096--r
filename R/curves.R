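# Calibration curves: loading, resampling, reservoir-corrected mixing.
#
# A calibration curve maps calendar age (cal BP) to expected conventional
# radiocarbon age mu(t) with a 1-sigma curve error s(t). Curves are held on a
# uniform 1-year grid internally so calibrated densities are exact mass
# vectors and numerical differentiation downstream is stable.

#' Construct a calibration curve object
#'
#' @param grid calendar ages (cal BP). Must be strictly monotone with a
#'   uniform step; stored ascending.
#' @param mu expected radiocarbon age (14C yr BP) at each grid point.
#' @param sigma 1-sigma curve error (yr) at each grid point; non-negative.
#' @param label text identifier (e.g. `"atmospheric"`, `"marine"`).
#' @return an object of class `cal_curve` with elements `grid`, `mu`,
#'   `sigma`, `label`.
#' @export
cal_curve <- function(grid, mu, sigma, label = "curve") {
  grid <- as.numeric(grid); mu <- as.numeric(mu); sigma <- as.numeric(sigma)
  if (length(grid) < 2L) stop("curve needs at least two grid points")
  if (length(mu) != length(grid) || length(sigma) != length(grid))
    stop("grid, mu and sigma must have equal length")
  d <- diff(grid)
  if (any(d == 0) || (any(d > 0) && any(d < 0)))
    stop("grid must be strictly monotone")
  if (max(abs(abs(d) - abs(d[1]))) > 1e-8)
    stop("grid must have a uniform step")
  if (grid[1] > grid[2]) {  # store ascending
    grid <- rev(grid); mu <- rev(mu); sigma <- rev(sigma)
  }
  if (any(sigma < 0)) stop("sigma must be non-negative")
  structure(list(grid = grid, mu = mu, sigma = sigma, label = as.character(label)),
            class = "cal_curve")
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("<cal_curve '%s': %d points, %g-%g cal BP, step %g yr>\n",
              x$label, length(x$grid), min(x$grid), max(x$grid),
              abs(x$grid[2] - x$grid[1])))
  invisible(x)
}

curve_step <- function(curve) abs(curve$grid[2] - curve$grid[1])

#' Interpolate a calibration curve at arbitrary calendar ages
#'
#' Linear interpolation of both mu and sigma. Queries outside the tabulated
#' range are an error: the curve defines nothing there.
#'
#' @param curve a [cal_curve()].
#' @param t calendar ages (cal BP).
#' @return list with numeric vectors `mu` and `sigma`.
#' @export
curve_at <- function(curve, t) {
  rng <- range(curve$grid)
  if (any(t < rng[1] - 1e-9 | t > rng[2] + 1e-9))
    stop(sprintf("query outside curve range [%g, %g] cal BP", rng[1], rng[2]))
  list(mu = stats::approx(curve$grid, curve$mu, xout = t, rule = 1)$y,
       sigma = stats::approx(curve$grid, curve$sigma, xout = t, rule = 1)$y)
}

#' Read a calibration curve file
#'
#' Reads the standard `.14c` dialect: comma- or whitespace-separated columns
#' (cal BP, 14C age, 1-sigma error) read positionally, `#`-prefixed header or
#' comment lines skipped, extra columns ignored. The curve is resampled to a
#' uniform 1-year grid by linear interpolation.
#'
#' @param path path to the curve file.
#' @param label text identifier for the curve.
#' @return a [cal_curve()] on a 1-year grid.
#' @export
read_cal_curve <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- !(startsWith(lines, "#") | lines == "")
  body <- lines[keep]
  if (length(body) == 0L) stop("curve file is empty: ", path)
  lineno <- which(keep)
  rows <- lapply(seq_along(body), function(i) {
    fields <- strsplit(body[i], "[,[:space:]]+")[[1]]
    fields <- fields[fields != ""]
    v <- suppressWarnings(as.numeric(fields))
    if (length(v) < 3L || anyNA(v[1:3]))
      stop(sprintf("cannot parse curve file %s at line %d: '%s'",
                   path, lineno[i], body[i]), call. = FALSE)
    v[1:3]
  })
  m <- do.call(rbind, rows)
  m <- m[order(m[, 1]), , drop = FALSE]
  if (anyDuplicated(m[, 1])) m <- m[!duplicated(m[, 1]), , drop = FALSE]
  grid <- seq(min(m[, 1]), max(m[, 1]), by = 1)
  cal_curve(grid,
            stats::approx(m[, 1], m[, 2], xout = grid)$y,
            stats::approx(m[, 1], m[, 3], xout = grid)$y,
            label = label)
}

#' Construct a marine reservoir offset
#'
#' Local deviation (Delta-R) of the marine reservoir age from the global
#' marine curve, with its own 1-sigma uncertainty.
#'
#' @param delta_r offset in 14C yr.
#' @param delta_r_sigma 1-sigma of the offset (yr), non-negative.
#' @export
reservoir_offset <- function(delta_r = 0, delta_r_sigma = 0) {
  if (delta_r_sigma < 0) stop("delta_r_sigma must be non-negative")
  structure(list(delta_r = as.numeric(delta_r),
                 delta_r_sigma = as.numeric(delta_r_sigma)),
            class = "reservoir_offset")
}

#' Mix atmospheric and marine calibration curves
#'
#' For samples with a marine diet fraction F, the effective curve on the
#' intersection grid is
#' \deqn{\mu_{mix}(t) = (1-F)\,\mu_{atm}(t) + F\,(\mu_{mar}(t) + \Delta R)}
#' \deqn{\sigma_{mix}(t)^2 = ((1-F)\,s_{atm}(t))^2 +
#'   (F \sqrt{s_{mar}(t)^2 + \sigma_{\Delta R}^2})^2}
#' The reservoir offset applies only to the marine component (Delta-R is
#' defined relative to the marine curve), so the mixture degenerates to the
#' pure atmospheric curve at F = 0 and to marine + Delta-R at F = 1.
#'
#' @param atm,mar atmospheric and marine [cal_curve()] objects.
#' @param fraction_marine marine diet fraction F in \[0, 1\].
#' @param offset a [reservoir_offset()].
#' @return a [cal_curve()] on the intersection grid.
#' @export
mix_curves <- function(atm, mar, fraction_marine, offset = reservoir_offset()) {
  stopifnot_scalar_prob(fraction_marine, "fraction_marine")
  lo <- max(min(atm$grid), min(mar$grid))
  hi <- min(max(atm$grid), max(mar$grid))
  if (lo >= hi) stop("curve grids are disjoint: no overlap to mix on")
  grid <- seq(lo, hi, by = min(curve_step(atm), curve_step(mar)))
  a <- curve_at(atm, grid); m <- curve_at(mar, grid)
  f <- fraction_marine
  mu <- (1 - f) * a$mu + f * (m$mu + offset$delta_r)
  sig <- sqrt(((1 - f) * a$sigma)^2 +
                (f * sqrt(m$sigma^2 + offset$delta_r_sigma^2))^2)
  cal_curve(grid, mu, sig,
            label = sprintf("mix(%s,%s,F=%.3g)", atm$label, mar$label, f))
}

#' Synthetic calibration curves with known structure
#'
#' Generates a smooth, strictly increasing atmospheric-style curve (linear
#' trend plus centennial/millennial wiggles) and, for `kind = "marine"`, the
#' same shape shifted by a global ocean reservoir age with a larger curve
#' error. Clearly synthetic: the shape mimics the statistical character of
#' real curves (wiggles, slowly varying error) without reproducing any
#' published table.
#'
#' @param range calendar range covered, cal BP (ascending pair).
#' @param kind `"atmospheric"` or `"marine"`.
#' @param reservoir global reservoir age (14C yr) added for the marine kind.
#' @return a [cal_curve()] on a 1-year grid.
#' @export
synth_cal_curve <- function(range = c(0, 20000), kind = c("atmospheric", "marine"),
                            reservoir = 400) {
  kind <- match.arg(kind)
  grid <- seq(range[1], range[2], by = 1)
  mu <- 0.96 * grid + 150 +
    350 * sin(2 * pi * grid / 9000) +
    25 * sin(2 * pi * grid / 700) +
    8 * sin(2 * pi * grid / 180)
  sigma <- 14 + 6 * sin(2 * pi * grid / 3100)^2 + grid / 4000
  if (kind == "marine") {
    mu <- mu + reservoir + 15 * sin(2 * pi * grid / 1100)
    sigma <- sigma + 8
  }
  cal_curve(grid, mu, sigma, label = paste0("synthetic-", kind))
}
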