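# Shared fixtures, built in code at test time.

# flat toy curve: constant mu, constant sigma
flat_curve <- function(mu = 1000, sigma = 0, range = c(0, 2000), label = "flat") {
  grid <- seq(range[1], range[2], by = 1)
  cal_curve(grid, rep(mu, length(grid)), rep(sigma, length(grid)), label)
}

# identity toy curve: mu(t) = t
identity_curve <- function(range = c(0, 12000), sigma = 0, label = "identity") {
  grid <- seq(range[1], range[2], by = 1)
  cal_curve(grid, grid, rep(sigma, length(grid)), label)
}

# small wiggly curve pair for realistic-shape tests
toy_curves <- function(range = c(0, 12000)) {
  list(atm = synth_cal_curve(range, "atmospheric"),
       mar = synth_cal_curve(range, "marine"))
}

# date table with n dates at given medians-ish CRAs on the identity curve
toy_dates <- function(cra, error = 50, site_id = "S1", site_type = "closed",
                      ...) {
  do.call(rbind, lapply(seq_along(cra), function(i) {
    c14_date(sprintf("T%03d", i), cra[i],
             if (length(error) > 1) error[i] else error,
             site_id = if (length(site_id) > 1) site_id[i] else site_id,
             site_type = if (length(site_type) > 1) site_type[i] else site_type,
             ...)
  }))
}

# brute-force calibration oracle: Riemann evaluation of the same integrand
# on a fine grid (default 0.1 yr), aggregated back to the 1-yr cells
brute_force_calibrate <- function(cra, error, curve, fine = 0.1) {
  tt <- seq(min(curve$grid), max(curve$grid), by = fine)
  mu <- approx(curve$grid, curve$mu, xout = tt)$y
  sig <- approx(curve$grid, curve$sigma, xout = tt)$y
  s2 <- error^2 + sig^2
  f <- exp(-(cra - mu)^2 / (2 * s2)) / sqrt(s2)
  f / sum(f * fine)   # density per yr, normalized on the fine grid
}

# quick scenario scaled for unit tests
small_scenario <- function(seed = 11, ...) {
  population_scenario(n_dates = 120L, site_count = 24L, n_iso = 30L,
                      seed = seed, ...)
}
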