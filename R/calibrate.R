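# Calibration of radiocarbon determinations to calendar probability densities.

#' Construct a radiocarbon date record
#'
#' One conventional radiocarbon determination with the metadata the pipeline
#' uses: site membership, site type (open-air deposits suffer taphonomic
#' loss; caves and rockshelters do not), optional coordinates, marine diet
#' fraction with local reservoir offset, and a context-security flag.
#'
#' @param lab_id laboratory code (unique identifier).
#' @param cra conventional radiocarbon age, 14C yr BP (> 0).
#' @param error 1-sigma lab error, yr (> 0).
#' @param site_id site identifier.
#' @param site_type `"open_air"` or `"closed"`.
#' @param lon,lat decimal degrees (optional, `NA` allowed).
#' @param fraction_marine marine diet fraction in \[0, 1\]; 0 = terrestrial.
#' @param delta_r,delta_r_sigma local marine reservoir offset and its 1-sigma.
#' @param context_flag `"secure"` or `"insecure"` archaeological association.
#' @return one-row data.frame in the package's date-table schema.
#' @export
c14_date <- function(lab_id, cra, error, site_id = "S1",
                     site_type = c("closed", "open_air"),
                     lon = NA_real_, lat = NA_real_,
                     fraction_marine = 0, delta_r = 0, delta_r_sigma = 0,
                     context_flag = c("secure", "insecure")) {
  site_type <- match.arg(site_type)
  context_flag <- match.arg(context_flag)
  if (!is.finite(cra) || cra <= 0) stop("cra must be positive")
  if (!is.finite(error) || error <= 0) stop("error must be positive")
  stopifnot_scalar_prob(fraction_marine, "fraction_marine")
  data.frame(lab_id = as.character(lab_id), site_id = as.character(site_id),
             site_name = as.character(site_id), cra = cra, error = error,
             site_type = site_type, lon = lon, lat = lat,
             fraction_marine = fraction_marine, delta_r = delta_r,
             delta_r_sigma = delta_r_sigma, context_flag = context_flag,
             stringsAsFactors = FALSE)
}

DATE_COLS <- c("lab_id", "site_id", "site_name", "cra", "error", "site_type",
               "lon", "lat", "fraction_marine", "delta_r", "delta_r_sigma",
               "context_flag")

#' Read a radiocarbon date table
#'
#' CSV with columns `lab_id, site_id, site_name, cra, error, site_type, lon,
#' lat, fraction_marine, delta_r, delta_r_sigma, context_flag`. Missing
#' optional columns are filled with their defaults (terrestrial diet, zero
#' offset, secure context, no coordinates).
#'
#' @param path CSV path.
#' @return data.frame in the date-table schema.
#' @export
read_c14_dates <- function(path) {
  if (!file.exists(path)) stop("date table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("lab_id", "site_id", "cra", "error")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("date table missing required columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(df$site_name)) df$site_name <- df$site_id
  if (is.null(df$site_type)) df$site_type <- "closed"
  if (is.null(df$lon)) df$lon <- NA_real_
  if (is.null(df$lat)) df$lat <- NA_real_
  if (is.null(df$fraction_marine)) df$fraction_marine <- 0
  df$fraction_marine[is.na(df$fraction_marine)] <- 0
  if (is.null(df$delta_r)) df$delta_r <- 0
  df$delta_r[is.na(df$delta_r)] <- 0
  if (is.null(df$delta_r_sigma)) df$delta_r_sigma <- 0
  df$delta_r_sigma[is.na(df$delta_r_sigma)] <- 0
  if (is.null(df$context_flag)) df$context_flag <- "secure"
  df$context_flag[is.na(df$context_flag)] <- "secure"
  bad <- !df$site_type %in% c("open_air", "closed")
  if (any(bad)) stop("unknown site_type value(s): ",
                     paste(unique(df$site_type[bad]), collapse = ", "))
  if (any(!is.finite(df$error) | df$error <= 0)) stop("error must be positive")
  if (any(!is.finite(df$cra) | df$cra <= 0)) stop("cra must be positive")
  if (any(df$fraction_marine < 0 | df$fraction_marine > 1))
    stop("fraction_marine must lie in [0, 1]")
  df[, DATE_COLS]
}

#' Construct a calendar probability density
#'
#' Normalized probability mass over a uniform cal BP grid.
#'
#' @param grid cal BP grid (uniform step, stored ascending).
#' @param mass non-negative mass per grid cell; normalized to sum to 1.
#' @export
cal_density <- function(grid, mass) {
  grid <- as.numeric(grid); mass <- as.numeric(mass)
  if (length(grid) != length(mass)) stop("grid and mass lengths differ")
  if (length(grid) > 1) {
    d <- diff(grid)
    if (max(abs(abs(d) - abs(d[1]))) > 1e-8 || any(d == 0))
      stop("grid must be uniform and strictly monotone")
    if (grid[1] > grid[2]) { grid <- rev(grid); mass <- rev(mass) }
  }
  if (any(mass < 0)) stop("mass must be non-negative")
  tot <- sum(mass)
  if (tot <= 0 || !is.finite(tot)) stop("density has zero or non-finite total mass")
  structure(list(grid = grid, mass = mass / tot), class = "cal_density")
}

#' @export
print.cal_density <- function(x, ...) {
  cat(sprintf("<cal_density: %d cells, %g-%g cal BP, median %g>\n",
              length(x$grid), min(x$grid), max(x$grid), median_cal(x)))
  invisible(x)
}

#' Calibrate a radiocarbon determination
#'
#' Converts a 14C measurement (CRA +/- error) to a normalized probability
#' density over calendar age. For a sample with marine diet fraction F the
#' effective curve is the reservoir-corrected atmospheric/marine mixture
#' ([mix_curves()]). The posterior mass at calendar age t is proportional to
#' the curve-error-aware normal density
#' \deqn{m(t) \propto \frac{1}{\sqrt{\sigma^2 + s(t)^2}}
#'   \exp\left(-\frac{(\mathrm{CRA}-\mu(t))^2}{2(\sigma^2+s(t)^2)}\right)}
#' normalized to unit mass, with support truncated where the cumulative tail
#' mass falls below 1e-6 per side (bounded arrays; mass loss far below test
#' tolerance).
#'
#' @param date one-row date-table data.frame (see [c14_date()]).
#' @param atm atmospheric [cal_curve()].
#' @param mar marine [cal_curve()]; only consulted when `fraction_marine > 0`.
#' @return a [cal_density()].
#' @export
calibrate_date <- function(date, atm, mar = NULL) {
  f <- date$fraction_marine
  if (is.null(f) || is.na(f)) f <- 0
  curve <- if (f > 0) {
    if (is.null(mar)) stop("marine curve required for fraction_marine > 0")
    mix_curves(atm, mar, f, reservoir_offset(date$delta_r, date$delta_r_sigma))
  } else atm
  calibrate_cra(date$cra, date$error, curve)
}

# core calibration against one effective curve; vectorized over the grid
calibrate_cra <- function(cra, error, curve) {
  s2 <- error^2 + curve$sigma^2
  # cheap support pre-restriction: only cells within 10 combined sigmas matter
  keep <- abs(cra - curve$mu) <= 10 * sqrt(s2)
  if (!any(keep))
    stop(sprintf("date %g +/- %g BP lies outside the calibration curve range",
                 cra, error))
  idx <- range(which(keep))
  i <- idx[1]:idx[2]
  dens <- exp(-(cra - curve$mu[i])^2 / (2 * s2[i])) / sqrt(s2[i])
  tot <- sum(dens)
  if (tot <= 0 || !is.finite(tot)) stop("calibration produced zero total mass")
  mass <- dens / tot
  # truncate cumulative tails below 1e-6 per side
  lo <- findInterval(1e-6, cumsum(mass)) + 1L
  hi <- length(mass) - findInterval(1e-6, cumsum(rev(mass)))
  hi <- max(hi, lo)
  cal_density(curve$grid[i][lo:hi], mass[lo:hi])
}

#' Median calibrated age
#'
#' The grid age at which cumulative mass, accumulated from the older (larger
#' cal BP) end, first reaches 0.5.
#'
#' @param d a [cal_density()].
#' @return cal BP year.
#' @export
median_cal <- function(d) {
  cs <- cumsum(rev(d$mass))          # from older end (grid stored ascending)
  rev(d$grid)[which(cs >= 0.5 - 1e-12)[1]]
}

# calibrate a whole date table once; returns named list of cal_density by lab_id
calibrate_dates <- function(dates, atm, mar = NULL) {
  out <- vector("list", nrow(dates))
  names(out) <- dates$lab_id
  for (k in seq_len(nrow(dates))) out[[k]] <- calibrate_date(dates[k, ], atm, mar)
  out
}
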