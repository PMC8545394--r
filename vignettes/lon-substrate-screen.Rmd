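---
title: "Screening for Lon protease substrates from multiplexed proteomics"
author: "lonscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for Lon protease substrates from multiplexed proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lonscreen)
```

# The screening problem

An intracellular protease leaves two complementary signatures on its
substrates. Removing the protease stabilizes a substrate (slower loss
after translation shut-off) and raises its steady-state level; supplying
excess protease lowers it. A protein that shows the full pattern across
independent genetic perturbations is a strong substrate candidate, while
any single readout is easily confounded: steady-state shifts can be
transcriptional, and fast turnover alone may be due to another protease.

`lonscreen` operationalizes this logic for the Lon protease in
*Caulobacter crescentus*. The input is a protein-level abundance table
from TMT10 isobaric labeling: ten strain/condition channels
(`lonChannels()`) quantified together per biological replicate, two
replicates in the standard design. The pipeline makes no use of peptide-
or spectrum-level information and assumes channel intensities are already
normalized between samples upstream, as protein-level TMT exports
normally are.

# The four-criterion screen

Per replicate, five ratios are computed (`computeRatios()`); each exists
iff both of its channels were measured for that protein and replicate:

* `r_steady = DLON_T0 / WT_T0`
* `r_depl = DEPL_NO_VAN / DEPL_PLUS_VAN`
* `r_oe = OE_GLUC / OE_XYL1H`
* `r_wt_decay = WT_T0 / WT_T30`
* `r_dlon_decay = DLON_T0 / DLON_T30`

`aggregateReplicates()` averages each ratio arithmetically over the
replicates in which it is present. A protein detected in only one
replicate keeps that single value (provenance `single_replicate`);
missingness must not abort scoring, because real screens do score such
proteins. The stabilization ratio
`r_stabilization = r_wt_decay / r_dlon_decay` is then derived from the
averaged decay ratios.

`applyCriteria()` thresholds four criteria with inclusive comparisons,
reproducing the published defaults (`criteriaThresholds()`):

| criterion | test | default |
|---|---|---|
| steady | `r_steady >= theta_steady` | 1.1 |
| depl | `r_depl >= theta_depl` | 1.1 |
| oe | `r_oe >= theta_oe` | 1.05 |
| stab | `r_wt_decay >= theta_wt_decay_gate` and `r_stabilization >= theta_stab` | 1 and 1.05 |

The stabilization criterion is two-stage on purpose: a protein must first
show net decay in the wild type before its stabilization without Lon is
meaningful; without the gate, proteins that accumulate in both strains
could pass on a ratio artifact. A missing mean ratio makes its criterion
`FALSE` rather than erroring or imputing.

The thresholds are intentionally close to 1 — isobaric reporter ratios
are compressed toward unity by co-isolation interference, so even strong
substrates show modest fold changes. Specificity is recovered by the
combination rule: `selectCandidates()` calls a protein putative when it
meets at least `min_criteria = 3` of the four. `vennCounts()` reports the
complete set accounting (15 exclusive regions, tallies by number of
criteria met, and the zero-criteria count), which is the screen's
headline summary.

## Design choices where the procedure was open

* **Ratio-of-ratios from means** (`stab_mode = "from_means"`). With two
  replicates one can either average the per-replicate decay ratios and
  divide, or divide per replicate and average. The procedure text
  computes the stabilization ratio *after* replicate averaging, so that
  is the default; `"per_replicate_mean"` is implemented for comparison.
  The two agree exactly when replicates agree.
* **Universe = union of replicates.** Tallies and proportions are over
  proteins detected in at least one replicate; per-replicate detection
  counts (`countDetected()`) are reported separately. The union is the
  set of proteins the screen actually scored.
* **No significance testing.** The screen is a deterministic threshold
  filter; no p-values are attached to ratios, matching the original
  design. (`compareProportions(test = TRUE)` offers a hypergeometric
  enrichment test as an explicitly-beyond-the-procedure extra.)
* **Zeros are missing.** A zero or blank cell in the input is recorded
  as "not measured", never as abundance 0: every downstream quantity is
  a ratio and reporter intensities of truly detected proteins are
  positive.

# Chase kinetics

`normalizeTimecourse()` converts band intensities to relative levels:
divide by the loading control when one is supplied (e.g. Lon or creatine
kinase bands for in-vitro reactions), then anchor t = 0 at exactly 1.
`fitHalfLife()` estimates the decay constant by ordinary least squares of
`log(level)` on time with a free intercept, and reports
`t_half = log(2)/k`. Log-linear OLS is the standard, reproducible choice
for 3–4-point chase data; how the original approximate half-lives were
fitted is not documented, so this estimator is an explicit
interpretation, with a nonlinear single-exponential fit available via
`method = "nls"`. Numerical conventions:

* the intercept is free, so noise in the t = 0 anchor does not bias `k`;
* `k <= 0` (no net decay, or apparent accumulation) is reported as the
  "stable" sentinel (`halfLife()` is `Inf`, never a negative half-life);
* non-positive or missing levels are dropped before fitting; fewer than
  two usable points is an error, not a guess.

`summarizeReplicates()` reports per-time mean and sample SD (n − 1
denominator), the convention used for "mean ± SD of three independent
experiments" figures; a single course yields SD 0 with a warning.

# The synthetic world

`simulateScreenData()` exists so the screen and its evaluation are
exercisable without the original supplementary table. It plants three
classes whose noiseless channel means follow directly from the class
definition:

* **lon_substrate** — steady-state fold `f_steady = 1.5` in the deletion
  and `f_depl = 1.5` on depletion; overexpression multiplier
  `f_oe = 0.67` on the `OE_XYL1H` channel (so gluc/+xyl ≈ 1.5);
  wild-type decay `k_wt = log(2)/12` per min (a 12-minute half-life, the
  regime of validated substrates) and complete stabilization without Lon
  (`k_dlon = 0`).
* **stable_nonsubstrate** — flat across all channels.
* **nonlon_unstable** — decays at `k_nonlon` in *both* backgrounds with
  flat endpoint channels. Default `k_nonlon = log(2)/12`: the same
  turnover rate as the substrate class, making it a maximally confusable
  negative control that the stabilization ratio must cancel out.

Each channel value is multiplied by independent median-1 lognormal noise
(`noise_sigma = 0.1` on the natural-log scale). Multiplicative lognormal
noise is the natural model here because every screen quantity is a ratio
of positive intensities; 10% is a documented choice, not a measured
value — the original data's "low dynamic range" is qualitative. Whole
(protein, replicate) pairs drop out with probability `dropout_p = 0.05`,
reproducing proteins detected in only one replicate (per-channel dropout
is available as an option). Base abundances are log-uniform over
`[1e4, 1e7]`, a typical reporter-intensity span; since the screen is
scale-invariant per protein, this choice affects nothing downstream and
merely keeps fixtures realistic-looking. Default class sizes are 100
substrates, 900 stable and 100 Lon-independent unstable proteins.

What a green synthetic test does establish: the arithmetic of ratios,
averaging, fallback, thresholds and set accounting; the operating
characteristics of the combination rule under stated noise. What it does
not: anything about real TMT artifacts (co-isolation compression beyond
a global noise term, channel-correlated batch effects, abundance-
dependent missingness), biological co-regulation, or the true effect-size
distribution of Lon substrates. Recovery numbers on synthetic data are
statements about the stated world only.

# Evaluation

`scoreRecovery()` scores the candidate table against planted truth:
positive = the putative call, condition-positive = class
`lon_substrate`. Proteins dropped in every replicate are excluded from
the confusion matrix — the screen never saw them — and their count is
reported separately, so sensitivity stays interpretable as the
recoverable fraction. Undefined metrics (zero denominators) are `NA`,
never 0 or 1. `thresholdSweep()` reruns the screen over a threshold grid
on a fixed dataset; raising `min_criteria` can only shrink the called
set, so sensitivity is non-increasing and specificity non-decreasing
along that axis (asserted by the test suite, not assumed).

# Limitations

* The screen starts at the protein-level abundance table; peptide
  aggregation, normalization and any isotope-impurity correction are
  upstream concerns.
* Exactly one abundance per (protein, replicate, channel) is modeled;
  technical (injection) replicates must be pre-averaged.
* The half-life module fits a single exponential; multi-phase decay or
  synthesis delays are out of scope.
* Functional categories are taken entirely from a user-supplied mapping
  file; the package embeds no ontology.
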