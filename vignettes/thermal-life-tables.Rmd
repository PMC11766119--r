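---
title: "Thermal life tables: models, fitting, and the synthetic cohort design"
author: "lifetherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal life tables: models, fitting, and the synthetic cohort design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifetherm)
```

## The problem

Constant-temperature life-table experiments follow every individual of
a cohort — here, spotted wing drosophila (*Drosophila suzukii*) eggs —
through its life stages under a fixed rearing temperature, recording at
each inspection the stage and whether the individual is alive. Two
kinds of quantity come out of such data:

* the *differential* life table: per-stage, per-temperature duration
  statistics and relative survival (completions over entrants), plus
  adult longevity and per-female fecundity summaries; and
* *thermal response functions*: parametric curves for development rate,
  mortality, longevity and fertility versus temperature, which are the
  raw material of physiologically based demographic models.

`lifetherm` implements both, plus a seeded generator of synthetic
cohorts with the same experimental structure, so that every step of the
pipeline can be validated end to end against known ground truth. The
package deliberately computes the differential representation only; the
cumulative cohort representation (`l_x m_x` schedules, net reproductive
rate, intrinsic rate of increase) is out of scope.

## From inspections to life tables

Durations are **first-observation differences**: the time a stage is
first seen to the time the next stage is first seen. Inspection
intervals shrink with temperature (24 h at 6–13 °C down to 2 h at
31–33 °C) precisely so that this grid resolution tracks the faster
development; the observed duration of a stage carries a discretization
bias of at most one interval. A midpoint-correction toggle exists in
`extract_stage_durations(midpoint =)` for sensitivity analysis; on a
uniform grid it only affects the first stage, whose entry time (egg
deposition) is known exactly.

Statistics follow the conventions the source tables use: SD with the
n − 1 denominator; adjusted Fisher–Pearson skewness (needs n ≥ 3) and
bias-adjusted *excess* kurtosis (needs n ≥ 4), both via `e1071` type 2 —
the excess convention is what makes near-normal cells print values near
zero, and the adjusted form is why the n = 3 cells are blank. The mode
is the most frequent grid value, reporting the smallest on ties and
missing when every value is unique. Survival is always recomputed from
the (entered, survived) counts; the displayed two-decimal proportion is
a formatting concern only. A handful of printed proportions in the
bundled study tables disagree with their own counts; the counts govern.

Malformed histories (non-monotone timestamps, skipped stages, alive
observations after death) are quarantined into a diagnostics table
rather than silently dropped: in a dataset where each row is a real
animal, a bookkeeping error should be visible.

Pre-oviposition is the day index of the first nonzero daily egg count,
with the **pairing day as time zero** (day 1 = first day after
pairing); females that never lay are excluded from the pre-oviposition
mean but contribute a zero lifetime total.

## The model catalogue

Development (and adult inverse-longevity) families: Logan, Brière,
Sharpe–De Michele, Lactin-1 and Lactin-2. Mortality: the quartic
"bathtub" polynomial and the Kim–Lee curve. Fertility: the
Gaussian-like curve. All are evaluated raw — no clipping inside the
model functions. The bathtub polynomial in particular can go negative
between its minima, and that behaviour is a diagnostic a user must see
(it is grounds for discarding the family for a stage), so any clipping
to [0, 1] is the consumer's explicit decision.

Three parses deserved a decision:

* **Sharpe–De Michele** is typeset ambiguously in much of the applied
  literature. We evaluate `T·exp(A − B/T) / (1 + exp(C − D/T) +
  exp(E − F/T))` with `T` in degrees Celsius: under this reading the
  published egg coefficients give ≈1.29 day⁻¹ at 26 °C, squarely
  bracketing the observed egg rate 1/0.8 d, whereas the Kelvin form
  does not. The original enzyme-kinetic derivation uses absolute
  temperature; `kelvin = TRUE` provides it.
* **Brière** is defined as 0 outside `[T_L, T_M]`: rates are
  biologically zero beyond the thresholds, and this avoids complex
  values of `(T_M − T)^{1/m}`.
* **Fertility** is grouped as `(λ² − (T − τ)² + δ²)^γ`, the only parse
  under which τ is the optimal temperature for egg production, as its
  role demands; a negative base with non-integer γ returns 0 (outside
  the reproductive window). Evaluation is in log space because
  `λ^{2γ+2}` overflows double precision long before the fitted
  parameter region is reached. The published parameter table for this
  curve appears to have its τ and δ labels swapped (τ printed as 4 °C
  while the text places the peak at 22.9 °C); we therefore treat the
  fitted-curve *peak*, not the printed parameter values, as the
  reproducible quantity.

Thermal traits are computed numerically: `thermal_optimum()` scans a
4001-point grid on [−5, 50] °C and polishes with golden-section search
(tolerance 0.01 °C); `thermal_thresholds()` brackets zero crossings on
either side of the optimum and refines by `uniroot`. Where a threshold
is a parameter (Brière; Lactin-1's upper root) it is returned exactly.
A side with no sign change — e.g. Logan at low temperature, which
decays to zero without crossing — is reported missing rather than
invented.

## Fitting

Estimation is ordinary (unweighted) nonlinear least squares. Every
family is nonconvex with threshold-type parameters, so a single start
is not defensible: `fit_model()` draws 64 Latin-hypercube starts inside
per-family box bounds (log-spaced along axes spanning more than three
decades), polishes each with Levenberg–Marquardt under the same bounds,
and keeps the best converged solution. The start layout is seeded, so
fits are bit-reproducible; noise-free self-generated data are recovered
to well below 0.1 % for every family except Sharpe–De Michele, whose
coefficients are structurally collinear — there the recovered *curve*
(RMSE < 1e−6) is the meaningful claim.

Default bounds anchor thresholds to the data span (`T_M` in
[max T − 2, 60] °C, `T_L` in [−10, min T + 2] °C, ΔT in (0, 20] °C) with
sign-appropriate boxes for scales and exponents; all are overridable
per fit. The source study does not state its bounds; these are
repository defaults.

Goodness of fit is the battery practitioners in this literature report:
`R² = 1 − SSres/SStot` (undefined for constant observations, and *not*
clamped — a fit worse than the mean shows as negative), `RMSE =
sqrt(SSres/n)` (denominator n, configurable reading; the literature
rarely states which it used), a Pearson-type `χ² = Σ(obs −
pred)²/|pred|` over points with |pred| > 1e−9 with the excluded count
reported, and `NDF = n − p`. The χ² definition is not fixed by the
sources this battery imitates; it is a package choice and no headline
result depends on it. Standard errors come from the residual-variance
scaled inverse Gauss–Newton curvature, with the condition judged on the
diagonally normalized matrix (so parameter-scale disparity is not
mistaken for collinearity); a near-singular curvature yields missing
SEs instead of misleading numbers.

Dataset granularity matters for degrees of freedom: development and
longevity fits use **one point per individual** (a 400-odd NDF for the
egg stage across 14 temperatures), while mortality fits use **one point
per temperature** (proportions have one value per cohort). The
fertility fit has nine temperature means against five parameters — it
proceeds, but that low-NDF degeneracy is why the individual parameters
are unstable while the peak location is robust.

## The synthetic generator

`generator_config()` defaults encode the study design itself: 14
temperatures (6–33 °C), 50 eggs per cohort, the temperature-dependent
inspection schedule, 10 couples for the egg-production trial, and
per-stage survival probabilities, duration means/SDs, adult longevity,
and fecundity targets taken directly from the bundled study tables.
Simulation proceeds per individual: Bernoulli survival per stage;
survivors draw a lognormal duration with the configured mean and SD
(positive support and mild right skew, matching the published shape
statistics; gamma is a config alternative); sex is assigned 1:1 at
pupal completion; adults draw a lognormal longevity. The continuous
history is then discretized onto the inspection grid, which is exactly
the censoring structure of the real datasheets.

Where the study gives no sub-model the generator uses declared
stand-ins: death occurs at a uniform fraction of the drawn stage
duration; the pre-oviposition delay is a rounded Gamma (shape 4) with
the configured mean; the between-female spread of lifetime egg totals
is a Gamma whose CV is implied by the published standard errors at
n = 10; daily counts are Poisson around a flat per-female intensity. A
stage that nobody completed at some temperature has no duration
statistics, so a death time there is placed using the nearest
temperature with data for that stage.

What passing tests therefore show: the pipeline recovers the exact
quantities the generator encodes (survival probabilities, duration
means up to grid discretization, fecundity targets) under the study's
sampling structure. What they do not show: robustness to features of
real data the generator does not emulate — inter-individual correlation,
temperature drift within a chamber, observer error in instar keys,
non-lognormal duration tails, or fecundity senescence schedules.

## Validation choices and problem sizes

The end-to-end recovery check simulates 500-egg cohorts at all 14
temperatures (≈7,000 individuals), rebuilds the life table, and
requires (i) every degenerate survival cell (probability 0 or 1)
reproduced exactly, (ii) every non-degenerate cell's generating
probability inside a familywise-95 % binomial region — Bonferroni
adjusted exact Clopper–Pearson intervals across the ~50 informative
cells, since testing each cell at an unadjusted 95 % would be expected
to fail a few cells by construction — and (iii) duration means within
one inspection interval of the configured mean. Parameter-recovery and
optimum/threshold brute-force checks run on 20-point noise-free curves
and 100 random parameter sets against a 10,000-point grid. These sizes
keep the full suite under a minute while leaving every statistical
check comfortably powered.

## Known limitations

* Mortality fits treat per-temperature proportions as homoscedastic
  observations (no logit transform, no binomial weighting), matching
  the practice the package reproduces; a weighted option would be a
  natural extension.
* The Pearson-type χ² divides by |pred|, which inflates the statistic
  when predictions approach zero; the explicit exclusion threshold and
  count make this visible but not ideal.
* The fertility fit's parameters should not be interpreted
  individually; only the fitted curve (and its peak) is stable.
* Sex-specific preimaginal mortality cannot be resolved: the design
  sexes individuals at adult emergence only.
* No support for fluctuating-temperature regimes, acclimation, or
  diapause; the curves describe constant-condition development from the
  egg stage on.
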