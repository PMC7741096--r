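# Settlement-density proxy: mean pairwise inter-site distance in sliding
# time windows.

#' Haversine great-circle distance
#' @param lon1,lat1,lon2,lat2 decimal degrees (vectorized).
#' @return distance in km (Earth radius 6371.0088 km).
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * 6371.0088 * asin(pmin(1, sqrt(a)))
}

#' Sites occupied within a calendar window
#'
#' A site counts as occupied when at least one of its phases has a
#' representative whose median calibrated age falls in `[young, old]`.
#' Windows (500 yr) are wide relative to calibration uncertainty, so the
#' cheap deterministic median rule is adequate.
#'
#' @param bins a [bin_phases()] result (carries the medians).
#' @param window `c(old, young)` cal BP, old > young.
#' @return character vector of site ids.
#' @export
site_occupancy <- function(bins, window) {
  if (window[1] <= window[2]) stop("window must be c(old, young) with old > young")
  med <- phase_rep_medians(bins)
  inside <- med <= window[1] & med >= window[2]
  unique(vapply(bins[inside], `[[`, "", "site_id"))
}

#' Mean pairwise distance between sites
#'
#' Arithmetic mean over all unordered site pairs. With `metric =
#' "haversine"` coordinates are lon/lat degrees; with `"projected_euclidean"`
#' they are already planar km.
#'
#' @param coords data.frame with columns `site_id` and either `lon`/`lat`
#'   (haversine) or `x_km`/`y_km` (projected).
#' @param metric distance metric.
#' @return mean distance in km, or `NA` when fewer than 2 sites.
#' @export
mean_pairwise_distance <- function(coords,
                                   metric = c("haversine", "projected_euclidean")) {
  metric <- match.arg(metric)
  coords <- coords[!duplicated(coords$site_id), , drop = FALSE]
  n <- nrow(coords)
  if (n < 2L) return(NA_real_)
  if (metric == "projected_euclidean") {
    d <- stats::dist(cbind(coords$x_km, coords$y_km))
    return(mean(d))
  }
  pairs <- utils::combn(n, 2)
  mean(haversine_km(coords$lon[pairs[1, ]], coords$lat[pairs[1, ]],
                    coords$lon[pairs[2, ]], coords$lat[pairs[2, ]]))
}

#' Inter-site distance time series
#'
#' Mean pairwise distance among occupied sites in sliding windows
#' (default 500 yr) centered on a regular lattice (default 50-yr step),
#' with a LOESS (local linear) smooth over the defined centers. Undefined
#' (`NA`) wherever fewer than 2 sites are occupied.
#'
#' @param bins a [bin_phases()] result.
#' @param dates date table carrying site coordinates.
#' @param window_len window length, yr (default 500).
#' @param step lattice step, yr (default 50).
#' @param loess_span LOESS span (default 0.75).
#' @param metric see [mean_pairwise_distance()].
#' @return object of class `distance_series`: data.frame with `center`,
#'   `n_sites`, `mean_km`, `smoothed_km`.
#' @export
distance_series <- function(bins, dates, window_len = 500, step = 50,
                            loess_span = 0.75,
                            metric = c("haversine", "projected_euclidean")) {
  metric <- match.arg(metric)
  med <- phase_rep_medians(bins)
  if (length(med) == 0L) stop("no phase bins supplied")
  centers <- seq(floor(min(med) / step) * step,
                 ceiling(max(med) / step) * step, by = step)
  cols <- if (metric == "haversine") c("lon", "lat") else c("x_km", "y_km")
  site_xy <- dates[!duplicated(dates$site_id),
                   c("site_id", intersect(names(dates), cols)), drop = FALSE]
  if (!all(cols %in% names(site_xy)))
    stop("date table lacks coordinate columns: ", paste(cols, collapse = ", "))
  res <- data.frame(center = centers, n_sites = 0L,
                    mean_km = NA_real_, smoothed_km = NA_real_)
  for (i in seq_along(centers)) {
    win <- c(centers[i] + window_len / 2, centers[i] - window_len / 2)
    occ <- site_occupancy(bins, win)
    sel <- site_xy[site_xy$site_id %in% occ, , drop = FALSE]
    sel <- sel[stats::complete.cases(sel[, cols]), , drop = FALSE]
    res$n_sites[i] <- nrow(sel)
    if (nrow(sel) >= 2L) res$mean_km[i] <- mean_pairwise_distance(sel, metric)
  }
  ok <- !is.na(res$mean_km)
  if (sum(ok) >= 8L) {
    fit <- stats::loess(mean_km ~ center, data = res[ok, ], span = loess_span,
                        degree = 1, family = "gaussian")
    res$smoothed_km[ok] <- stats::predict(fit)
  } else res$smoothed_km <- res$mean_km
  structure(res, class = c("distance_series", "data.frame"))
}

#' @export
plot.distance_series <- function(x, ...) {
  plot(x$center, x$mean_km, xlim = rev(range(x$center)), pch = 16, cex = 0.6,
       col = "grey50", xlab = "cal BP", ylab = "mean inter-site distance (km)",
       main = "Settlement density proxy", ...)
  ok <- !is.na(x$smoothed_km)
  graphics::lines(x$center[ok], x$smoothed_km[ok], col = "firebrick", lwd = 2)
  invisible(x)
}
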