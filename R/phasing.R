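# Screening and site-phase binning.
#
# Heavily sampled sites would otherwise dominate the summed density, so per
# site the dates are reduced to one representative per "site phase": dates
# whose median calibrated ages fall within an intergenerational span (30 yr)
# are clustered together and one member is drawn at random.

#' Screen a radiocarbon date table
#'
#' Removes noisy determinations: dates with 1-sigma lab errors above
#' `max_error` (strictly greater than) and dates whose archaeological
#' association with human activity is not secure. Row order is preserved.
#'
#' @param dates date-table data.frame.
#' @param max_error largest admissible lab error, yr (default 200).
#' @return the retained subset (possibly empty).
#' @export
screen_dates <- function(dates, max_error = 200) {
  keep <- dates$error <= max_error & dates$context_flag == "secure"
  dates[keep, , drop = FALSE]
}

#' Bin dates into site phases by hierarchical clustering
#'
#' Per site, agglomerative clustering with complete linkage on the absolute
#' difference of median calibrated ages, cutting the tree at height `h`
#' (default 30 yr, an intergenerational period). Complete linkage guarantees
#' every phase has diameter at most `h`. One member per cluster is chosen
#' uniformly at random as the phase representative; the choice uses its own
#' seeded RNG stream so downstream bootstrap seeds never perturb binning, and
#' the number of bins is independent of the seed.
#'
#' @param dates screened date-table data.frame.
#' @param atm,mar calibration curves (see [calibrate_date()]).
#' @param h tree-cut height, yr.
#' @param seed integer seed for representative selection.
#' @param densities optional precomputed list of [cal_density()] keyed by
#'   `lab_id` (avoids recalibration).
#' @return object of class `phase_bins`: a list of bins, each with
#'   `site_id`, `member_ids`, `representative_id`, `phase_span_years`,
#'   plus a `medians` attribute (named vector of median cal BP by lab_id).
#' @export
bin_phases <- function(dates, atm, mar = NULL, h = 30, seed = 1L,
                       densities = NULL) {
  if (h < 0) stop("h must be non-negative")
  if (nrow(dates) == 0L) {
    return(structure(list(), class = "phase_bins", medians = numeric(0)))
  }
  if (is.null(densities)) densities <- calibrate_dates(dates, atm, mar)
  med <- vapply(dates$lab_id, function(id) median_cal(densities[[id]]),
                numeric(1))
  names(med) <- dates$lab_id
  bins <- list()
  for (site in unique(dates$site_id)) {
    ids <- dates$lab_id[dates$site_id == site]
    m <- med[ids]
    cl <- if (length(ids) == 1L) 1L else
      stats::cutree(stats::hclust(stats::dist(m), method = "complete"), h = h)
    for (g in sort(unique(cl))) {
      members <- ids[cl == g]
      bins[[length(bins) + 1L]] <- list(
        site_id = site,
        member_ids = members,
        representative_id = NA_character_,
        phase_span_years = diff(range(m[members])))
    }
  }
  # representative choice on a dedicated stream, after the partition is fixed
  with_seed(stream_seed(seed, "phasing"), {
    for (k in seq_along(bins)) {
      mem <- bins[[k]]$member_ids
      bins[[k]]$representative_id <- if (length(mem) == 1L) mem else
        mem[sample.int(length(mem), 1L)]
    }
  })
  structure(bins, class = "phase_bins", medians = med)
}

#' @export
print.phase_bins <- function(x, ...) {
  cat(sprintf("<phase_bins: %d phases across %d sites, %d dates>\n",
              length(x), length(unique(vapply(x, `[[`, "", "site_id"))),
              sum(lengths(lapply(x, `[[`, "member_ids")))))
  invisible(x)
}

#' @export
as.data.frame.phase_bins <- function(x, ...) {
  data.frame(
    site_id = vapply(x, `[[`, "", "site_id"),
    phase_index = stats::ave(seq_along(x), vapply(x, `[[`, "", "site_id"),
                             FUN = seq_along),
    representative_id = vapply(x, `[[`, "", "representative_id"),
    member_ids = vapply(x, function(b) paste(b$member_ids, collapse = ";"), ""),
    phase_span_years = vapply(x, `[[`, numeric(1), "phase_span_years"),
    stringsAsFactors = FALSE)
}

# medians of current representatives (named by bin index)
phase_rep_medians <- function(bins) {
  med <- attr(bins, "medians")
  vapply(bins, function(b) unname(med[b$representative_id]), numeric(1))
}
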