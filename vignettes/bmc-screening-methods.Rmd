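---
title: "Benchmark-concentration statistics for neurosphere screening assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark-concentration statistics for neurosphere screening assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmcscreen)
library(dplyr)
```

## The problem

In vitro developmental neurotoxicity (DNT) screening with neurosphere
cultures measures how a test compound perturbs key neurodevelopmental
processes (KNDPs) in neural progenitor cells: proliferation (`NPC1`),
migration of radial glia, neurons and oligodendrocytes (`NPC2a-c`), neuronal
differentiation (`NPC3`), neurite outgrowth (`NPC4a/b`) and oligodendrocyte
differentiation (`NPC5`), alongside a viability channel (`CTB`) and a
membrane-integrity cytotoxicity channel (`LDH`). The statistical task is to
turn plate-level fluorescence readings into defensible potency estimates —
benchmark concentrations (BMCs) with confidence bounds — and into binary hit
calls that separate specific effects on neurodevelopment from noise and from
unspecific cytotoxicity. `bmcscreen` implements that chain end to end, plus
the two satellite analyses that accompany such screens: physiological
relevance of a BMC against cord-blood ligand concentrations, and
threshold-based filtering of differential-expression results with gene-set
overrepresentation.

## Data model and normalization

The unit of raw data is one well of one endpoint channel: compound,
endpoint, species, sex, donor, plate, well type (treated / solvent control /
positive control / blank), concentration in µM (0 for solvent), technical
replicate index, and a non-negative raw value. Three deterministic steps
produce the analysis scale:

1. **Background correction.** Wells with medium but no cells measure
   background fluorescence. The median blank value of each
   `(plate, endpoint)` group is subtracted; corrected values below zero are
   clipped to zero rather than rejected, since fluorescence noise below
   background is physically meaningless but routine. The median (not the
   mean) is used for blanks as well as solvent wells, for uniform robustness
   to single aberrant wells; the choice of median for blanks is this
   package's decision and is configurable only by preprocessing.
2. **Normalization.** Every well is expressed as percent of the median
   solvent-control value of its own plate and endpoint, so the solvent
   median maps to exactly 100 %. Normalization is strictly plate-local;
   pooling across plates happens only afterwards, because solvent controls
   are plate-local in this design.
3. **Technical aggregation.** The five technical replicate wells of a
   condition share one sphere preparation and one plate; they are not
   independent. Their median is the single value per biological replicate
   that all downstream statistics consume. A biological replicate is
   identified with a `(donor, plate)` pair — the simulator lays one
   biological replicate per plate.

## Benchmark response from historical variability

The benchmark response (BMR) — the % deviation from control that counts as a
biologically meaningful effect — is derived from assay noise rather than
chosen by hand: the coefficient of variation (CV) of normalized responses at
the lowest tested concentration across historical experiments, times 1.5,
rounded to the nearest multiple of 5 (half-up at exact midpoints), floored
at 5 %. The floor exists because a BMR of 0 is meaningless; the half-up
convention at midpoints such as 22.5 is this package's decision. A CV of
0.14 maps to a BMR of 20 %, a CV of 0.0707 to 10 %, a constant history to
the 5 % floor. One BMR is derived per endpoint; species can be used as an
optional extra stratifier by calling `derive_bmr()` on the stratified
history, since published designs leave the pooling level open.

## The model catalog

`fit_curves()` fits 13 concentration-response families spanning the linear,
sigmoidal, monotone and non-monotone classes: linear, quadratic, saturating
exponential, log-logistic with 2/3/4 parameters, Weibull types 1 and 2, a
Hill model with the control asymptote fixed at 100 %, a shifted
Michaelis–Menten hyperbola, Brain–Cousens and Cedergreen–Ritz–Streibig
hormesis models, and a Gaussian bell in log concentration. The exact catalog
is a package-level constant (`cr_families()`), chosen to mirror the standard
dose–response catalogs of the field's curve-fitting tools; it can be
subset per run. Each family evaluates the zero-concentration control
asymptote in closed form, so a solvent concentration of 0 never meets a
`log(0)`.

Fitting is bounded Levenberg–Marquardt least squares from a deterministic
multi-start grid (quartiles of the tested log-concentration range for
half-maximal parameters, data-driven asymptote starts). Bounds keep
asymptotes in [-50, 250] % of control, half-maximal concentrations within
[min tested / 100, max tested × 100] and slopes in [-20, 20], preventing
pathological extrapolation. Optimizer failure marks the fit non-converged
instead of raising, so one ill-posed family never blocks the catalog.

**Selection.** The "robust statistical criterion" is the small-sample
corrected AIC (AICc) on the least-squares fit, with `k` counting the
residual variance. Exact ties go to the family with fewer parameters, then
to fixed catalog order, making selection deterministic and
permutation-invariant. Families with no residual degrees of freedom get an
infinite score and are only selectable if nothing else converges.

**Confidence band.** Bands come from a nonparametric case-resampling
bootstrap: within each biological-replicate block, `(concentration,
response)` pairs are resampled with replacement and the selected family
refit (default B = 1000; the calibration studies below use B = 200 as their
problem-size choice). The default band is *simultaneous* (sup-t):
deviations from the pointwise bootstrap center are studentized by the
pointwise bootstrap SD, and the half-width is the smallest multiple under
which the entire curve stays inside for 95 % of resamples. Two reasons
drive this default: the hit rule below speaks of the *complete* confidence
interval of the curve, which is a statement about the whole band, and in
simulation the sup-t band gives well-calibrated BMC interval coverage
(~95 % at the 7×3 design) where a pointwise percentile band undercovers
(~88 %). A pointwise percentile band remains available via
`type = "pointwise"`.

## BMC, BMCL, BMCU and cytotoxicity gating

The BMC is the lowest concentration in the tested range at which the fitted
curve first departs from 100 % by at least the BMR, i.e. the first in-range
root of `fitted(c) = 100 ∓ BMR`, scanning upward from the lowest tested
concentration. Defining the BMC as the *first* crossing keeps it
well-defined for hormetic (non-monotone) fits. The confidence bounds BMCL
and BMCU are the analogous first crossings of the band edges — the edge
nearer the BMR line crosses earlier and gives BMCL. Bounds from band-edge
crossings (rather than a bootstrap distribution of BMCs) stay defined even
when some bootstrap replicates never cross. A curve that never reaches the
BMR line within the tested range is *censored* — a result state, not an
error. If the curve is already beyond the BMR at the lowest tested
concentration, the BMC is reported at that boundary so it stays inside the
tested range. The effect direction defaults to the sign of the fitted
effect at the highest allowed concentration and can be forced per endpoint.

Cytotoxicity gating precedes all endpoint analysis: the LDH channel is fit
the same way, its BMC10 in the increase direction is computed, and every
tested concentration above it is discarded for endpoint fitting and
testing. A censored cytotoxicity BMC leaves all concentrations in; an empty
allowed set is an explicit gating error (compound untestable).

## Hit classification

Significance testing uses the Dunnett–Tamhane step-down many-to-one
procedure on Welch (unequal-variance) t statistics, with the **lowest
tested concentration** — not the solvent control — as reference; the solvent
is used only for normalization and for the rescue t-test. Comparisons are
ordered by |t|; at each step the adjusted p-value is the tail probability
of the maximum of the remaining comparisons' joint null distribution,
estimated from seeded Monte-Carlo draws (default B = 10,000) that reproduce
the many-to-one correlation through a shared reference draw and propagate
variance-estimation uncertainty through chi-square draws per group. The
final remaining comparison uses the exact Welch p-value, so the two-group
case reduces exactly to the Welch t-test. Rejection stops at the first
non-rejection (step-down coherence); adjusted p-values are monotonized and
floored at the exact marginal Welch p. At the screening design (5 groups,
n = 5) the simulated family-wise error is about 4.1 % at a nominal 5 % —
the mild conservatism is inherited from the Welch t-test itself, whose
marginal type-I rate at n = 5 is about 4.4 %.

A stratum is a **hit** when at least one of two conditions holds:

- `stat_test`: the highest non-cytotoxic concentration differs
  significantly from the lowest tested concentration, and/or
- `ci_crossing`: at some allowed concentration the *entire* band lies
  beyond the BMR line (both edges past `100 ∓ BMR`). The weaker
  either-edge reading is available behind `ci_rule = "either_edge"`; the
  both-edges default follows from the "complete confidence interval"
  wording. Strata where only one of the two conditions fires keep that
  information in `basis` — no third class is invented between hit and
  no-hit.

The most sensitive endpoint (MSE) of a compound is the hit with the lowest
BMC; endpoints whose BMCs fall within each other's [BMCL, BMCU] are
reported as a tie set, mirroring screens where no clear MSE exists. Rescue
(antagonist co-exposure) experiments are assessed by a two-tailed Welch
t-test of the agonist-alone arm against solvent plus a step-down test of
the antagonist series against agonist-alone; "antagonized" requires both a
significant agonist effect and at least one antagonist dose significantly
shifted back toward the solvent level. Sex and species concordance
(`compare_strata()`) classifies each endpoint as concordant-hit,
concordant-no-hit or discordant and reports the BMC sensitivity ratio with
a flag when the confidence intervals do not overlap.

## Physiological relevance

Cord-blood ligand ranges are shipped as a reference CSV (mass
concentration, unit, molar mass) rather than hard-coded, since published
conversions imply slightly varying molar-mass choices; `mass_to_nM()`
converts via `nM = (ng/ml) × 1000 / (g/mol)`. A receptor's BMC is flagged
`yes` when it is at or below the upper bound of the pooled physiological
range of that receptor's ligands, `no` above it, and `questionable` when no
range is reported. "Within or below" is formalized as a comparison against
the upper bound only; the lower bound is reported but does not enter the
verdict.

## DEG filtering and overrepresentation

A gene is differentially expressed when `|log2 FC| > 0.486` (strict),
`FPKM >= 1` and `q < 0.05` (strict) — the inequalities are applied exactly
as printed, which the boundary tests pin down. Literature evidence
classification is input-driven (brain evidence takes precedence over
non-brain). Overrepresentation uses the hypergeometric upper tail per gene
set against the measured universe, reports raw p-values with a `p < 0.01`
flag and orders by overlap count (ties by p) — no multiple-testing
correction by default, matching the reporting rule the thresholds come
from; a correction switch exists. Up/down overlap counts are reported
separately when direction subsets are supplied, since either convention for
"DEG count" appears in practice.

## The synthetic-data generator

`simulate_assay()` reproduces the assay design: seven serial concentrations
at dilution factor 3, the top concentration a 1000-fold dilution of the
stock ("1 in 999" is read as one volume into 999, i.e. factor 1000; the
alternative factor-999 reading differs by 0.1 % and is immaterial), five
technical replicates, three or more biological replicates per sex, solvent
and blank wells on every plate, and a paired LDH channel. Raw values follow
`plate_scale × control_level × truth%/100 × (1 + bio_effect) + noise +
background`, with a lognormal plate scale (sdlog 0.05), a Gaussian
biological-replicate effect (sd 3 %), additive Gaussian well noise (default
sd 5 % of control — the noise level used throughout the calibration
studies) and a constant fluorescence background, clipped at zero. This
emulates the noise structure that motivates median-based correction and
normalization. It does **not** emulate spatial plate effects (edge wells),
per-cell image-derived measurements, or heavy-tailed outliers, so passing
calibrations demonstrate correctness of the statistical chain under a
realistic but idealized noise model, not robustness to every artifact of
real plates.

## Calibration results and problem sizes

The acceptance suite (reproduced by `scripts/acceptance.R`) computes, among
others: the closed-form 4PL benchmarks BMC20 = 0.25 µM and BMC25 = 1/3 µM
recovered to 1e-6 relative; brute-force first-crossing agreement across all
13 families; step-down family-wise error on 2000 null datasets (5 groups,
n = 5, Monte-Carlo B = 4000); a false-hit rate on 500 flat-truth campaigns
and the hit rate on 200 strong-effect campaigns (4PL dropping to 20 % of
control, BMR 20, 5 % noise) through the complete pipeline; and BMC20
recovery with interval coverage on 500 datasets at the 7×3 design. These
sizes — and bootstrap B = 200 inside the loops — are the package's choices
for the calibration studies; per-fit precision is unaffected, only the
Monte-Carlo resolution of the reported rates.

## Known limitations

- BMCL/BMCU inherit the band's bootstrap approximation; with very few
  biological replicates the within-block resampling underestimates
  between-donor variance.
- The step-down Monte-Carlo uses plug-in group variances; with 2 replicates
  per group its critical values are rough (the exact Welch p on the last
  step mitigates the two-group case).
- Hybrid (tail-probability) benchmark definitions, trend tests and
  measurement error in concentration are out of scope.
- Relevance verdicts compare nominal in vitro concentrations to cord-blood
  levels; no toxicokinetic extrapolation or protein-binding correction is
  attempted.
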