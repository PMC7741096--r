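# Rank correlation between the population proxy and environmental proxy
# series, overall and in sliding windows.

#' Construct an environmental proxy series
#' @param t cal BP (strictly monotone).
#' @param value proxy values (finite).
#' @param label text identifier.
#' @return object of class `proxy_series` (data.frame `t`, `value`).
#' @export
proxy_series <- function(t, value, label = "proxy") {
  if (length(t) != length(value)) stop("t and value lengths differ")
  if (length(t) == 0L) stop("empty proxy series")
  d <- diff(t)
  if (any(d == 0) || (any(d > 0) && any(d < 0)))
    stop("t must be strictly monotone")
  if (any(!is.finite(value))) stop("proxy values must be finite")
  o <- order(t)
  structure(data.frame(t = t[o], value = value[o]),
            class = c("proxy_series", "data.frame"), label = label)
}

#' Read a proxy series CSV (columns `t_calBP`, `value`)
#' @param path CSV path.
#' @param label series label.
#' @export
read_proxy <- function(path, label = basename(path)) {
  df <- utils::read.csv(path)
  nm <- names(df)
  tcol <- nm[grepl("^t", nm, ignore.case = TRUE)][1]
  if (is.na(tcol)) tcol <- nm[1]
  vcol <- setdiff(nm, tcol)[1]
  proxy_series(df[[tcol]], df[[vcol]], label = label)
}

#' Time-based centered running mean
#'
#' Mean of all observations within a `width`-year window centered on each
#' time point (window in time units, not sample counts; edge windows are
#' truncated), so irregularly spaced series are handled correctly.
#'
#' @param series a [proxy_series()].
#' @param width window width, yr (default 400).
#' @export
running_mean <- function(series, width = 400) {
  if (width <= 0) stop("width must be positive")
  t <- series$t; v <- series$value
  sm <- vapply(seq_along(t), function(i) {
    mean(v[abs(t - t[i]) <= width / 2])
  }, numeric(1))
  proxy_series(t, sm, label = paste0(attr(series, "label"), "-rm", width))
}

#' Windowed Spearman correlation of population and proxy series
#'
#' Both series are linearly interpolated onto a common lattice (default
#' 50-yr) over their overlap; Spearman's rho (average ranks for ties) is
#' computed in sliding windows (default 500 yr, 11 lattice points) and over
#' the full overlap. Windows with fewer than 3 points are `NA`.
#'
#' @param pop a [density_model()] (its mean track is used).
#' @param proxy a [proxy_series()].
#' @param window window length, yr (default 500).
#' @param step lattice step, yr (default 50).
#' @return list with `windows` (data.frame `center`, `rho`, `n`) and
#'   `overall_rho`.
#' @export
spearman_windowed <- function(pop, proxy, window = 500, step = 50) {
  lo <- max(min(pop$grid), min(proxy$t))
  hi <- min(max(pop$grid), max(proxy$t))
  if (lo >= hi) stop("population and proxy series do not overlap in time")
  lattice <- seq(ceiling(lo / step) * step, floor(hi / step) * step, by = step)
  if (length(lattice) < 3L) stop("overlap too short for the lattice")
  p <- stats::approx(pop$grid, pop$mean, xout = lattice)$y
  q <- stats::approx(proxy$t, proxy$value, xout = lattice)$y
  # a constant window has no ranking: rho is NA (the undefined marker),
  # not worth a warning
  cor_quiet <- function(a, b)
    suppressWarnings(stats::cor(a, b, method = "spearman"))
  overall <- cor_quiet(p, q)
  centers <- lattice
  res <- data.frame(center = centers, rho = NA_real_, n = 0L)
  half <- window / 2
  for (i in seq_along(centers)) {
    sel <- abs(lattice - centers[i]) <= half
    res$n[i] <- sum(sel)
    if (res$n[i] >= 3L) res$rho[i] <- cor_quiet(p[sel], q[sel])
  }
  list(windows = res, overall_rho = overall)
}
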