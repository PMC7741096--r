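# Pipeline orchestration: configuration, staged execution, artifacts,
# manifest. The R functions are the primary interface; scripts/pipeline.R in
# the source repository wraps run_pipeline() for shell use.

#' Default run configuration
#'
#' Parameter defaults are the analysis constants the pipeline is built
#' around: screening at 200 yr, 30-yr site phases, 1000 bootstrap
#' replicates at 95.4% coverage, 150-yr KDE bandwidth, 500-yr windows
#' stepped at 50 yr, 1000 Monte Carlo LOESS iterations, 10-yr KDE grid.
#'
#' @param paths named list: `curves_atm`, `curves_mar` (optional `.14c`
#'   files; synthetic curves are used when absent), `dates`, `isotopes`,
#'   `proxy`, `out_dir`.
#' @param seed master seed; fans out to per-stage streams via [stream_seed()].
#' @param ... overrides for any parameter listed above.
#' @return object of class `run_config`.
#' @export
run_config <- function(paths = list(), seed = 1L, ...) {
  params <- list(max_error = 200, phase_h = 30, n_boot = 1000,
                 coverage = 0.954, kde_bandwidth = 150, window = 500,
                 step = 50, loess_span = 0.75, n_mc = 1000, grid_step = 10,
                 metric = "haversine", min_phase_span = 200,
                 correct_open_air = TRUE)
  dots <- list(...)
  bad <- setdiff(names(dots), names(params))
  if (length(bad))
    stop("invalid config key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(names(params), collapse = ", "))
  params[names(dots)] <- dots
  structure(list(paths = paths, params = params, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with fields `paths`, `seed`, and any parameters.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  pars <- js[setdiff(names(js), c("paths", "seed"))]
  do.call(run_config, c(list(paths = as.list(js$paths),
                             seed = if (is.null(js$seed)) 1L else js$seed),
                        pars))
}

#' Run the palaeodemographic pipeline
#'
#' Executes the requested stage (or `"all"`) and writes stage artifacts
#' (CSV/JSON, plus figures for `"all"`) under `config$paths$out_dir`,
#' together with a run manifest (config echo, seed, package version, input
#' checksums). Stages: `simulate` (synthetic dataset), `calibrate`, `bin`,
#' `spd`, `testexp`, `kde`, `growth`, `spatial`, `corr`, `diet`, `all`.
#'
#' @param stage stage name.
#' @param config a [run_config()].
#' @param scenario optional [population_scenario()] for `simulate` (default
#'   scenario when omitted).
#' @return (invisibly) a list of in-memory stage results.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "calibrate", "bin",
                                   "spd", "testexp", "kde", "growth",
                                   "spatial", "corr", "diet"),
                         config = run_config(), scenario = NULL) {
  stage <- match.arg(stage)
  p <- config$params
  out_dir <- config$paths$out_dir
  if (is.null(out_dir)) stop("config$paths$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  res <- list()
  log_stage <- function(...) message(sprintf("[c14demog] %s", sprintf(...)))

  if (stage %in% c("simulate", "all") &&
      (is.null(config$paths$dates) || stage == "simulate")) {
    log_stage("simulate: generating synthetic dataset")
    scn <- if (!is.null(scenario)) scenario
    else if (!is.null(config$paths$scenario)) read_scenario(config$paths$scenario)
    else population_scenario(seed = seed)
    sim <- make_dataset(scn, dir = file.path(out_dir, "synthetic"))
    config$paths$dates <- sim$paths$dates
    config$paths$isotopes <- sim$paths$isotopes
    config$paths$proxy <- sim$paths$proxy
    res$simulate <- sim
    if (stage == "simulate") {
      write_manifest(config, out_dir)
      return(invisible(res))
    }
  }

  need <- function(key) {
    pth <- config$paths[[key]]
    if (is.null(pth) || !file.exists(pth))
      stop("missing input for stage: path '", key, "' (",
           if (is.null(pth)) "not set" else pth, ")")
    pth
  }
  atm <- if (!is.null(config$paths$curves_atm))
    read_cal_curve(need("curves_atm"), "atmospheric")
  else if (!is.null(res$simulate)) res$simulate$atm
  else synth_cal_curve(kind = "atmospheric")
  mar <- if (!is.null(config$paths$curves_mar))
    read_cal_curve(need("curves_mar"), "marine")
  else if (!is.null(res$simulate)) res$simulate$mar
  else synth_cal_curve(kind = "marine")

  dates_raw <- read_c14_dates(need("dates"))
  dates <- screen_dates(dates_raw, p$max_error)
  log_stage("screen: %d of %d dates retained", nrow(dates), nrow(dates_raw))
  dens <- calibrate_dates(dates, atm, mar)
  if (stage == "calibrate") {
    med <- vapply(dates$lab_id, function(id) median_cal(dens[[id]]), numeric(1))
    utils::write.csv(data.frame(lab_id = dates$lab_id, median_cal_BP = med),
                     file.path(out_dir, "calibrated_medians.csv"),
                     row.names = FALSE)
    write_manifest(config, out_dir)
    return(invisible(list(densities = dens)))
  }

  bins <- bin_phases(dates, atm, mar, h = p$phase_h,
                     seed = seed, densities = dens)
  log_stage("bin: %d site phases from %d dates", length(bins), nrow(dates))
  utils::write.csv(as.data.frame(bins), file.path(out_dir, "phase_bins.csv"),
                   row.names = FALSE)
  res$bins <- bins
  if (stage == "bin") { write_manifest(config, out_dir); return(invisible(res)) }

  if (stage %in% c("spd", "testexp", "corr", "all")) {
    log_stage("spd: bootstrapping %d replicates", p$n_boot)
    spd <- bootstrap_spd(bins, dates, atm, mar, n_boot = p$n_boot,
                         coverage = p$coverage, seed = seed,
                         correct_open_air = p$correct_open_air,
                         densities = dens)
    write_density_model(spd, file.path(out_dir, "spd.csv"))
    res$spd <- spd
  }

  if (stage %in% c("testexp", "all")) {
    log_stage("testexp: exponential null model")
    window <- c(max(res$spd$grid), min(res$spd$grid))
    fit <- fit_exponential(res$spd, window)
    null <- simulate_null(fit, n_dates = length(bins),
                          error_pool = dates$error, atm = atm,
                          n_boot = p$n_boot, coverage = p$coverage,
                          seed = seed, grid = res$spd$grid)
    rep_report <- detect_departures(res$spd, null)
    write_departure_report(rep_report, fit,
                           file.path(out_dir, "null_model_test.json"))
    res$null <- null; res$fit <- fit; res$departures <- rep_report
  }

  if (stage %in% c("kde", "growth", "all")) {
    log_stage("kde: %d replicates, bandwidth %g yr", p$n_boot, p$kde_bandwidth)
    kde <- kde_model(bins, dates, atm, mar, bandwidth = p$kde_bandwidth,
                     n_boot = p$n_boot, coverage = p$coverage, seed = seed,
                     densities = dens, grid_step = p$grid_step)
    write_density_model(kde, file.path(out_dir, "kde.csv"))
    res$kde <- kde
  }
  if (stage %in% c("growth", "all")) {
    log_stage("growth: annualized rates + phase descriptors")
    gr <- growth_rate(res$kde)
    write_density_model(gr, file.path(out_dir, "growth.csv"))
    phases <- extract_phases(gr, min_phase_span = p$min_phase_span)
    jsonlite::write_json(as.data.frame(unclass(phases)),
                         file.path(out_dir, "growth_phases.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    res$growth <- gr; res$phases <- phases
  }

  if (stage %in% c("spatial", "all")) {
    log_stage("spatial: inter-site distance series")
    ds <- distance_series(bins, dates, window_len = p$window, step = p$step,
                          loess_span = p$loess_span, metric = p$metric)
    utils::write.csv(as.data.frame(unclass(ds)),
                     file.path(out_dir, "distance_series.csv"),
                     row.names = FALSE)
    res$distance <- ds
  }

  if (stage %in% c("corr", "all") && !is.null(config$paths$proxy)) {
    log_stage("corr: windowed Spearman against proxy")
    proxy <- read_proxy(need("proxy"))
    sw <- spearman_windowed(res$spd, proxy, window = p$window, step = p$step)
    utils::write.csv(sw$windows, file.path(out_dir, "spearman_windows.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(overall_rho = sw$overall_rho),
                         file.path(out_dir, "spearman_overall.json"),
                         auto_unbox = TRUE, digits = NA)
    res$corr <- sw
  }

  if (stage %in% c("diet", "all") && !is.null(config$paths$isotopes)) {
    log_stage("diet: Monte Carlo LOESS (%d iterations)", p$n_mc)
    iso <- read_isotopes(need("isotopes"))
    trend <- mc_loess(iso, atm, mar, n_mc = p$n_mc, span = p$loess_span,
                      seed = seed, grid_step = p$grid_step)
    utils::write.csv(data.frame(cal_BP = trend$grid,
                                mean_d13c = trend$mean_d13c,
                                lower = trend$lower, upper = trend$upper),
                     file.path(out_dir, "diet_trend.csv"), row.names = FALSE)
    res$diet <- trend
  }

  if (stage == "all") write_figures(res, out_dir)
  write_manifest(config, out_dir)
  invisible(res)
}

write_figures <- function(res, out_dir) {
  fig <- function(name, expr) {
    grDevices::png(file.path(out_dir, name), width = 900, height = 560)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
  }
  if (!is.null(res$spd)) fig("spd.png", {
    plot(res$spd, main = "Population proxy (bootstrapped SPD)")
    if (!is.null(res$null)) {
      graphics::lines(res$null$grid, res$null$upper, lty = 2, col = "grey40")
      graphics::lines(res$null$grid, res$null$lower, lty = 2, col = "grey40")
    }
  })
  if (!is.null(res$growth)) fig("growth.png", plot(res$growth))
  if (!is.null(res$distance)) fig("distance.png", plot(res$distance))
  if (!is.null(res$diet)) fig("diet.png", plot(res$diet))
  invisible(NULL)
}

write_manifest <- function(config, out_dir) {
  inputs <- Filter(function(p) is.character(p) && file.exists(p) &&
                     !dir.exists(p), config$paths)
  manifest <- list(
    package = "c14demog",
    version = as.character(utils::packageVersion("c14demog")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    params = config$params,
    input_md5 = as.list(tools::md5sum(unlist(inputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
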