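# c14demog

Palaeodemographic modelling from archaeological radiocarbon dates.

Regional radiocarbon databases are, in aggregate, a proxy for past human
population: more people leave more datable material. This package is for
archaeologists and palaeodemographers who want to go from a raw date table
— including marine and mixed-diet human samples that need
reservoir-corrected calibration — to defensible population-dynamics
statements, with every stage's uncertainty carried along.

The pipeline:

1. **Calibration** — per-date posterior over calendar age on a 1-yr grid,
   `m(t) ∝ exp(−(CRA−μ(t))²/2(σ²+s(t)²)) / √(σ²+s(t)²)`, with
   atmospheric/marine curve mixing `μ_mix = (1−F)μ_atm + F(μ_mar + ΔR)`
   for marine diet fraction F and local reservoir offset ΔR ± σ_ΔR.
2. **Screening and site-phase binning** — errors > 200 yr and insecure
   contexts dropped; per site, complete-linkage clustering of median
   calibrated ages cut at 30 yr (one intergenerational "site phase"), one
   random representative per phase.
3. **SPD with taphonomic correction** — summed probability density; the
   open-air record divided by the power-law survival curve
   `n(t) = a(t+b)^c` and mass-rescaled, closed sites added uncorrected;
   bootstrap envelope at 95.4% coverage.
4. **Exponential null model** — least-squares fit `A·e^{r(t₀−t)}`,
   null sampling distribution by uncalibrate–recalibrate simulation,
   departures flagged where the two envelopes are disjoint, global
   Monte Carlo p-value (plus Gaussian-tail approximation).
5. **KDE growth model** — bootstrapped 150-yr-bandwidth Gaussian KDE (one
   draw per site phase), annualized growth rate `r(t) = −d log K/dτ × 100`
   %/yr, growth-phase descriptors (start, duration, maximum rate,
   population maximum, each ± SD).
6. **Settlement density** — mean pairwise inter-site distance in 500-yr
   windows stepped at 50 yr, LOESS-smoothed.
7. **Proxy correlation** — windowed Spearman's rho against environmental
   series (e.g. sea-surface temperature, ice-core δ¹⁸O), on a common
   50-yr lattice.
8. **Palaeodiet** — Monte Carlo LOESS regression of human δ¹³C on
   calibrated age (1000 refits over calibration draws), with trend
   extremum ("most marine") extraction.
9. **Synthetic data** — a generator with a piecewise-exponential truth
   curve (stadial crash, two Holocene booms), taphonomic thinning,
   time-varying spatial clustering, a dietary δ¹³C ramp, and a linked
   proxy series, so the whole pipeline is testable offline with known
   ground truth.

## Worked example

Run the whole pipeline on the shipped synthetic scenario (truth: booms
starting 10300 and 8700 cal BP at 0.40 and 0.25 %/yr, diet peak at 7800
cal BP, proxy tied to the population curve):

```r
library(c14demog)
cfg <- run_config(paths = list(out_dir = "run1"), seed = 1,
                  n_boot = 200, n_mc = 300)
res <- run_pipeline("all", cfg)
print(res$phases)
#> <growth_phases: 2 phase(s)>
#>   phase 1: start 8633 ± 100 cal BP, duration 930 ± 128 yr, max 0.29 ± 0.07 %/yr at 8406 ± 103, pop max 7703 ± 87 (n=200)
#>   phase 2: start 10189 ± 675 cal BP, duration 1001 ± 549 yr, max 0.21 ± 0.11 %/yr at 9496 ± 241, pop max 9187 ± 293 (n=313)
res$departures$global_p
#> [1] 0.004975124
res$corr$overall_rho
#> [1] 0.7957783
trend_extremum(res$diet, "max")
#> cal_BP   d13c
#> 7810.00 -16.58
```

Reading the output: both injected booms are recovered — the later phase
(start 8633 ± 100 vs truth 8700) tightly, the earlier one (start 10189 ±
675 vs truth 10300) with the wide uncertainty that a sparse pre-boom record
honestly forces. The SPD departs from the fitted exponential null
(p ≈ 0.005, the boom structure), the population proxy correlates strongly
with the linked environmental series (ρ ≈ 0.80), and the injected marine
diet peak is localized to 7810 cal BP (truth 7800). Artifacts (CSV/JSON
series, figures, a manifest with config echo, seed and input checksums)
land in `run1/`.

Shell users can call the same stages via
`Rscript scripts/pipeline.R all --out run1 --seed 1`, or feed real data
with `--dates dates.csv --curve-atm intcal20.14c --curve-mar marine20.14c
--isotopes iso.csv --proxy sst.csv`.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch on the
default synthetic scenario — generation, screening, binning, bootstrap SPD,
null-model test, KDE growth and phase extraction, distance series, proxy
correlation, and the Monte Carlo LOESS diet trend — printing the headline
statistics it computes and writing the machine-readable report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/` — implementation (curves, calibrate, phasing, spd, nullmodel,
  kdegrowth, spatial, proxycorr, paleodiet, synthetic, pipeline).
- `tests/testthat/` — unit, property, and acceptance suites; all fixtures
  are generated in code (a small `.14c` parser fixture ships under
  `inst/extdata/`).
- `vignettes/radiocarbon-palaeodemography.Rmd` — the models, assumptions,
  parameters, numerical choices, and limitations, in detail.
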