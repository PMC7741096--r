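---
title: "Radiocarbon palaeodemography: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiocarbon palaeodemography: models, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c14demog)
```

## The problem

Archaeological radiocarbon dates are, in aggregate, a proxy for past human
activity: more people leave more datable material. `c14demog` turns a
regional database of radiocarbon determinations — including marine and
mixed-diet human samples that need reservoir-corrected calibration — into
population proxies (summed probability densities and kernel density
models), tests them against an exponential null model of background growth,
derives continuous annualized growth-rate curves with phase descriptors,
summarizes settlement density as an inter-site distance series, correlates
the population proxy with environmental records, and models palaeodietary
trends from human bone stable-isotope series. A synthetic-data generator
with known ground truth makes every stage testable offline.

This vignette documents the models, their assumptions, the tunable
parameters, and the numerical choices — including the places where the
design was genuinely open and what we decided.

## Calibration

A determination is a conventional radiocarbon age (CRA) with lab error
$\sigma$. A calibration curve supplies $\mu(t)$ and curve error $s(t)$ on a
calendar grid (cal BP, present = 1950 CE). The calibrated density at
calendar age $t$ is the curve-error-aware normal likelihood, normalized
over its support:

$$m(t) \propto \frac{1}{\sqrt{\sigma^2 + s(t)^2}}
  \exp\!\left(-\frac{(\mathrm{CRA}-\mu(t))^2}{2(\sigma^2+s(t)^2)}\right).$$

We include the $1/\sqrt{\sigma^2+s(t)^2}$ prefactor (mainstream calibration
practice) rather than the bare exponential; the difference is small but
testable. There is no uniform-prior reweighting and no bomb-peak handling.

*Mixed marine diets.* For a sample drawing a fraction $F$ of its carbon
from marine sources, the effective curve blends atmosphere and ocean:
$\mu_{mix} = (1-F)\mu_{atm} + F(\mu_{mar} + \Delta R)$, with errors
combined in quadrature, $\sigma_{mix}^2 = ((1-F)s_{atm})^2 +
(F\sqrt{s_{mar}^2+\sigma_{\Delta R}^2})^2$. The local reservoir offset
$\Delta R$ applies only to the marine component because it is defined
relative to the marine curve; the mixture degenerates correctly at
$F \in \{0, 1\}$. The underlying study states only that curves were mixed;
this error model is the standard one in calibration software and is our
design choice.

*Numerics.* Curves are resampled to a uniform 1-year grid (densities are
then exact mass vectors and later differentiation is stable). Support is
truncated where cumulative tail mass falls below $10^{-6}$ per side, then
renormalized to unit mass; tests compare against a 0.1-year brute-force
Riemann oracle conditioned on the same support, so the truncation itself is
never load-bearing. The median calibrated age is read by accumulating mass
from the older end, first cell reaching 0.5; plateau ties therefore resolve
toward the older end.

## Screening and site-phase binning

Dates with lab errors above 200 years, or with insecure archaeological
association, are screened out. To stop heavily sampled sites dominating the
sum, each site's dates are reduced to one per *site phase*: per site,
complete-linkage agglomerative clustering on absolute differences of median
calibrated ages, tree cut at `h = 30` years (an intergenerational span).
Complete linkage guarantees intra-phase diameter at most `h`. Whether the
original analysis clustered uncalibrated CRAs or calibrated medians is not
stated; we cluster medians, since the 30-year phase definition lives in
calendar time. One member per phase is chosen uniformly at random as
representative, on a dedicated RNG stream so that bootstrap seeds elsewhere
never perturb the binning; the number of bins is seed-invariant by
construction.

## SPD with taphonomic correction and bootstrap envelope

The summed probability density is the pointwise sum of the per-date
calibrated densities — "normalized" is read as each *date* carrying unit
mass before summation, not as SPD-wide renormalization, which is consistent
with the separate open-air scaling step. Open-air records are eroded
preferentially with age; their partial SPD is divided by the power-law
taphonomic survival curve $n(t) = a(t+b)^c$ (constants $a = 5.726442\times
10^6$, $b = 2176.4$, $c = -1.3925309$) and then rescaled so the corrected
open-air record keeps a total mass equal to the open-air phase count —
otherwise the correction would arbitrarily reweight open against closed
records. Closed-site (cave/rockshelter) phases are added uncorrected.

The envelope comes from bootstrap replicates: phases resampled with
replacement, each sampled phase's representative re-drawn from its members
(so intra-phase choice uncertainty enters the envelope), SPD rebuilt, and
pointwise empirical quantiles taken at coverage 0.954. Replicates are not
smoothed before the quantiles — whether the original envelope smoothed them
is unstated, and not smoothing is the more conservative reading.

## Exponential null model

Background growth is modelled as $A e^{r(t_0-t)}$ fitted to the SPD mean by
least squares (amplitude profiled analytically; the rate found by 1-D
deterministic minimization). The null sampling distribution is simulated by
drawing calendar years from the fitted law, back-transforming them through
the atmospheric curve ("uncalibration"), perturbing with lab errors drawn
from the observed error pool, recalibrating, and summing — so the null
envelope carries the same calibration artefacts as the data.

Departures are flagged only where the two *envelopes* are disjoint
(observed lower above null upper, or observed upper below null lower).
Envelope-versus-envelope comparison is deliberately conservative: it
resists calibration-wiggle false positives better than point-versus-band
rules. The global statistic is the summed exceedance of the observed mean
outside the null band; its Monte Carlo p-value ranks it among null
replicates, each scored against the leave-one-out envelope of the remaining
replicates, with the usual $(1+k)/(1+n)$ correction. Since that p cannot
fall below $1/(1+n_{boot})$, a Gaussian tail approximation on the null
statistics is reported alongside for sub-floor cases. The note on colours:
the flagged intervals are reported signed (positive/negative); any
colour-to-direction mapping is left to plotting.

## KDE population model and annualized growth

A smoother proxy: per bootstrap replicate, phases are resampled, ONE
calendar year is drawn per sampled phase from its representative's
calibrated density, and a fixed-bandwidth (150-year) Gaussian KDE of the
draws is formed — each replicate integrating to one by construction. The
continuous annualized growth rate is the negative logarithmic time
derivative per replicate,

$$r_b(t) = -\frac{d\log K_b}{d\tau} \times 100\ \%/\mathrm{yr},$$

positive when the density increases toward the present (decreasing cal BP),
so Holocene booms read as positive. We differentiate $\log K$ by central
differences rather than forming $K'/K$: the two are algebraically
identical, but on exponential segments the log-space form is exact to
machine precision while the ratio form carries $O((\rho h)^2/6)$
discretization error — the package's closed-form limit test (an exponential
density must return its exponent everywhere) relies on this.

*Reliability masking.* More than a couple of bandwidths away from the
nearest dated event, the KDE is pure Gaussian tail and its log-derivative
degenerates to the deterministic tail slope (distance/bandwidth², up to
about 2 %/yr) — an artefact of the kernel, not a population signal. At
moderately low density the one-dataset sampling error of the log-gradient
reaches several tenths of a percent per year. The growth model therefore
flags a cell *reliable* when the expected number of draws within one
bandwidth, $n \cdot K(t) \cdot 2\,\mathrm{bw}$, is at least 10 — capping
the KDE's relative sampling error near 20% — and this flag governs where
rate *values* may be read. This implements, as a per-cell rule, the
method's own restriction that growth can only be computed where the date
density is significant. A hard floor of $10^{-12}$ additionally guards the
logarithm.

*Phase descriptors.* A growth phase is a maximal span of positive rate
sustained at least 200 years (the threshold suppresses derivative noise
phases; it is configurable and was fixed before any acceptance run).
Boundary descriptors — start (upcrossing), population maximum
(downcrossing), duration — are level crossings, which are robust
statistics; they are measured on every replicate run matched to the
mean-curve phase by maximal temporal overlap, and reported as mean ± SD.
The rate magnitude is *not* the average of per-replicate span maxima: the
maximum of a noisy series is biased upward by extreme-value selection, and
at desk scale we measured that estimator reporting 1.24 %/yr for a true
0.40 %/yr boom. Instead `t_max_rate` is located where the *mean* rate curve
peaks within the phase (restricted to reliable cells), `max_rate` is the
replicate mean ± SD of the rate at that cell, and the location SD comes
from per-replicate argmax positions. Runs that never touch a reliable cell
are not claimed as phases. Whether the original ± values are SDs or CI
half-widths is unstated; we report SDs, and the full replicate matrix is
retained on the model object. All of this is the package's own design;
the source analysis does not state its descriptor recipe.

## Settlement density

For each 500-year window stepped at 50 years, the sites "occupied" are
those with at least one phase whose representative median falls in the
window — a deterministic rule that is adequate because windows are wide
relative to calibration uncertainty. The proxy is the arithmetic mean of
all pairwise inter-site distances (haversine on lon/lat by default, Earth
radius 6371.0088 km; planar Euclidean on projected kilometre coordinates by
flag), undefined where fewer than two sites are occupied, with a
local-linear LOESS track over the defined centers for display.

## Proxy correlation

Population mean and environmental series are linearly interpolated onto a
common 50-year lattice over their overlap; Spearman's rho (average ranks on
ties) is computed per 500-year window (11 lattice points) and overall.
Because interpolation precedes ranking, rank invariance under monotone
transforms holds exactly only for lattice-aligned series — an unavoidable
consequence of correlating series sampled on different supports. Windowed
p-values are deliberately not reported: strong autocorrelation makes naive
ones invalid. The environmental series helper includes a time-based
(not sample-count) 400-year centered running mean with truncated edges.

## Palaeodietary trend

Human bone collagen grows enriched in ¹³C with marine protein intake, so
the regression of δ¹³C on calendar age tracks marine reliance. Each
individual's age is a calibrated (possibly mixed-curve, multimodal)
density; per Monte Carlo iteration one year is drawn per individual, a
local-linear LOESS (span 0.75 — n is small, a wide local-linear smoother
avoids boundary blowup; neither value is stated by the source analysis) is
fitted, and predictions are taken on a 10-year grid restricted to cells
covered by at least 90% of iterations. The trend is the iteration mean;
the 2.5/97.5 percentile envelope conveys calibration uncertainty together
with smoother variability. Draw-level output is exchangeable rather than
literally invariant under sample reordering (reordering re-pairs draws with
RNG positions); the law of the estimate is unchanged. The trend extremum
("most marine") breaks plateau ties toward the older end. δ¹⁵N is carried
through I/O but not modelled.

## The synthetic world

The generator states one reference world and keeps it fixed:

* a piecewise-exponential population curve (log-linear between
  breakpoints), so every segment has a closed-form growth rate; the default
  encodes mild Late Glacial growth, a stadial crash over 12800–11700 cal
  BP, a boom at a sustained 0.40 %/yr from 10300 to 9400 cal BP, a bust at
  −0.20 %/yr, a second boom at 0.25 %/yr from 8700 to 7750 cal BP, and
  decline after;
* 300 dates across 62 sites, half open-air; open-air event years are
  thinned by the taphonomic survival curve, so the generator and the SPD
  correction are exact inverses;
* lognormal lab errors (median 45 yr), plus a 5% contaminated fraction
  (insecure contexts, oversized errors) so screening has real work;
* sites with Gaussian-cluster coordinates whose spatial SD follows a
  schedule (dispersal during the crash, fivefold contraction into the
  estuarine clustering of the late Holocene); events attach to sites of
  their type with temporal coherence (400-year site footprint) while the
  marginal year distribution stays exact;
* a δ¹³C triangular ramp peaking at 7800 cal BP (−20.5 to −16 ‰, noise SD
  0.6 ‰) across 54 individuals restricted to 8500–7000 cal BP, with marine
  fractions up to 0.5 mapped from the ramp and a +95 ± 15 reservoir offset
  on marine-influenced individuals;
* an environmental proxy equal to the standardized 400-year-smoothed log
  population curve plus AR(1) noise on a 50-year lattice.

Synthetic calibration curves mimic the statistical character of real ones —
strictly increasing trend, centennial and millennial wiggles, slowly
varying error — without reproducing any published table; everything they
feed is labelled synthetic.

What the generator does **not** emulate: research-intensity bias (sites
found where archaeologists dig), sea-level loss of coastal sites, curve
plateaus as sharp as real deglacial ones, inter-site dependence in lab
error, or spatially structured diets. A green test therefore establishes
that the estimators recover a known signal of realistic shape and size
through the full calibration-binning-bootstrap machinery — not that any
particular archaeological inference is right.

## Parameters at a glance

| parameter | default | unit | role |
|---|---|---|---|
| `max_error` | 200 | yr | screening threshold (strictly greater excluded) |
| `phase_h` | 30 | yr | site-phase tree cut (intergenerational span) |
| `n_boot` | 1000 | — | bootstrap replicates |
| `coverage` | 0.954 | — | envelope coverage (2σ) |
| `kde_bandwidth` | 150 | yr | Gaussian kernel SD |
| `grid_step` | 10 | yr | KDE/growth evaluation step |
| `min_phase_span` | 200 | yr | minimum sustained positive-rate span |
| `min_kernel_count` | 10 | draws | reliability mask for rate values |
| `window`, `step` | 500, 50 | yr | sliding windows (distance, correlation) |
| `loess_span` | 0.75 | — | LOESS span (distance smooth, diet trend) |
| `n_mc` | 1000 | — | Monte Carlo LOESS iterations |

A single pipeline seed fans out to named per-module streams
(`stream_seed()`), so stages are independently reproducible and
re-running one stage never shifts another's randomness.

## Known limitations

* No Bayesian sequence/phase modelling, no alternative null families
  (logistic etc.), no second-order spatial statistics, no lag optimization
  in the proxy correlation, and no isotope mixing models — all outside the
  package's scope.
* The growth-rate envelope is honest but wide wherever dates are sparse;
  descriptors are only claimed where the reliability mask passes, so
  poorly powered periods yield no phases rather than noisy ones. At a few
  hundred dates, a boom that emerges from a nearly empty lull is located
  to roughly ±200 years and its maximum rate to roughly ±0.1 %/yr — the
  package's simulation suite measures exactly this recovery, and users
  should expect descriptor SDs of that order, not decimals better.
* The Monte Carlo p-value floor is $1/(1+n_{boot})$; the Gaussian tail
  approximation reported alongside extrapolates beyond it and should be
  read as an approximation, not an exact tail probability.
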