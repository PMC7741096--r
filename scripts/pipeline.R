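#!/usr/bin/env Rscript
# Thin shell wrapper over c14demog::run_pipeline().
#
# Usage:
#   Rscript scripts/pipeline.R <stage> --config <config.json>
#   Rscript scripts/pipeline.R <stage> --out <dir> [--seed <int>] \
#       [--dates <csv>] [--isotopes <csv>] [--proxy <csv>] \
#       [--curve-atm <file.14c>] [--curve-mar <file.14c>]
#
# Stages: all, simulate, calibrate, bin, spd, testexp, kde, growth,
#         spatial, corr, diet

suppressPackageStartupMessages(library(c14demog))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  message("usage: Rscript scripts/pipeline.R <stage> [--config cfg.json | --out dir ...]")
  quit(status = 2L)
}
stage <- args[1L]
rest <- args[-1L]
get_arg <- function(flag, default = NULL) {
  i <- which(rest == flag)
  if (length(i) == 1L && i < length(rest)) rest[i + 1L] else default
}

cfg_path <- get_arg("--config")
cfg <- if (!is.null(cfg_path)) {
  read_run_config(cfg_path)
} else {
  paths <- Filter(Negate(is.null),
                  list(out_dir = get_arg("--out"),
                       dates = get_arg("--dates"),
                       isotopes = get_arg("--isotopes"),
                       proxy = get_arg("--proxy"),
                       curves_atm = get_arg("--curve-atm"),
                       curves_mar = get_arg("--curve-mar")))
  run_config(paths = paths, seed = as.integer(get_arg("--seed", "1")))
}

status <- tryCatch({
  run_pipeline(stage, cfg)
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
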