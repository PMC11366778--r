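---
title: "Methods: equipercentile RUDAS-MMSE crosswalks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equipercentile RUDAS-MMSE crosswalks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(equicross)
```

## Problem

The RUDAS and the MMSE are both 0–30 integer-scored cognitive screening
instruments, but their score distributions differ: the RUDAS was designed
to be less sensitive to education and language background, and its scores
in mixed clinical samples sit lower and spread wider than MMSE scores from
the same participants. A crosswalk — a table mapping each RUDAS score to
an MMSE equivalent — lets clinicians and researchers apply MMSE-based
cutoffs and pool cohorts measured with either instrument.

`equicross` estimates such crosswalks by equipercentile equating in a
single-group design: every participant contributes both a RUDAS and an
MMSE score, so the two marginal distributions come from the same sample
and no anchor test is needed.

## Equipercentile equating

### Percentile ranks and their inverse

For an integer score $x \in \{0, \dots, 30\}$ with sample relative
frequency $f(x)$ and cumulative distribution $F(x)$, the
continuity-corrected percentile rank is

$$P(x) = 100\,\bigl[F(x-1) + \tfrac{1}{2}f(x)\bigr].$$

This is the value at $x$ of the piecewise-linear continuized CDF $F^*$
with knots $F^*(x + 0.5) = F(x)$ and $F^*(-0.5) = 0$. The inverse used on
the target scale is the exact inverse of $F^*$: for $p^* = p/100$, find
the smallest integer $x_U$ with $F(x_U) > p^*$ and return

$$Q(p) = x_U - 0.5 + \frac{p^* - F(x_U - 1)}{f(x_U)}.$$

Two conventions handle the edge cases:

* **Flat regions.** If $p^*$ exactly equals a cumulative boundary (scores
  with zero mass make $F^*$ flat there), the inverse is set-valued; we
  return the midpoint of the flat interval. This keeps the raw-frequency
  equating symmetric and reproduces the standard convention for
  zero-frequency scores.
* **Extremes.** $p = 0$ maps to $-0.5$ and $p = 100$ to $30.5$, the ends
  of the continuized support.

The equipercentile equivalent of RUDAS score $x$ on the MMSE scale is
$e_Y(x) = Q_Y(P_X(x))$. Integer crosswalk entries round half-up
(`floor(e + 0.5)`) and clip to $[0, 30]$. Half-up rounding is used rather
than R's banker's rounding so that ties break deterministically in one
direction and the table is stable under tiny perturbations of $e$.

### Log-linear presmoothing

With $n \approx 300$, raw frequencies on 31 score points are noisy, and
scores below the observed minimum have undefined percentile ranks. Each
marginal is therefore presmoothed with the log-linear family

$$\log p(x) = \beta_0 + \sum_{k=1}^{C} \beta_k \,(x/30)^k,
\qquad x = 0, \dots, 30,$$

fit by maximum likelihood (via the Poisson surrogate in `stats::glm`,
whose maximum coincides with the multinomial MLE; convergence tolerance
$10^{-12}$, up to 200 iterations). Powers of $x/30$ rather than $x$ keep
the design numerically well conditioned at degree 6. Two properties of
the MLE matter here and are verified at fit time and in the tests:

* the fitted distribution **preserves the first $C$ raw sample moments**
  (checked to a relative tolerance of $10^{-6}$; violation raises a
  convergence error), and
* fitted probabilities are **strictly positive everywhere**, so the
  continuized CDF is strictly increasing and the crosswalk is defined on
  the full 0..30 range, including scores no participant attained.

The degree $C$ is selected per marginal by AIC
($-2\,\ell + 2C$, multinomial log-likelihood) over candidates
$C = 2, \dots, 6$; ties go to the smaller degree. Degree 2 is the
smallest model that can track both location and spread; degree 6 is
enough to capture the skew and ceiling compression seen in screening
data without chasing sampling noise. `select_degree()` exposes the full
candidate table, and `run_config(degree = )` pins a fixed degree when
comparability across runs matters more than fit.

## Validation metrics

A crosswalk is validated on a held-out cohort by converting each
participant's RUDAS score and comparing it with their observed MMSE:

* **ICC(2,1)** — two-way random-effects, absolute-agreement, single
  measure. Absolute agreement (not consistency) is the right form here
  because a crosswalk that is systematically shifted by two points is a
  worse crosswalk, even if perfectly correlated. Mean squares come from
  the standard two-way decomposition; the 95% interval is the F-based
  construction with Satterthwaite degrees of freedom. Qualitative bands:
  below .50 poor, .50–.75 moderate, .75–.90 good, above .90 excellent
  (boundaries at .75 and .90 count as the lower band; the package applies
  the band to the point estimate). A consistency-form ICC is available
  via `icc_agreement(type = "consistency")`.
* **Pearson's r** with a magnitude band on $|r|$ (very low below .30 up
  to very high at .90+) and $r^2$ as a percentage.
* **Within-±k agreement** — the percentage of participants whose
  converted score is within $k$ points of the observed MMSE, reported
  for $k = 1, 2$. This is the most clinically interpretable of the three.

`validate_crosswalk()` reports these overall and for subgroups (healthy
controls, people with Alzheimer's disease = GDS 3 plus GDS 4–5, and each
population label); subgroups with fewer than 3 participants are omitted
with a warning, since the ICC decomposition is not meaningful there. Note
that subgroup ICCs are expected to be much lower than the overall ICC:
restricting the score range removes most of the between-subject variance
that the ICC numerator measures.

Degenerate inputs raise typed errors: agreement is undefined when the
combined scores have essentially zero total variance. Zero
*between-subject* variance alone does not error — the ICC is then a
well-defined (typically negative) number, as in
`icc_agreement(c(1, 2, 3), c(3, 2, 1))`.

## Stratified splitting

`split_train_validation()` splits a cohort into training and validation
parts, stratified by clinical group (by default), targeting a 70%
training fraction. Per-stratum counts use largest-remainder
apportionment toward `round(fraction * n_total)`: each stratum first gets
the floor of its proportional share, and remaining slots go to the
strata with the largest fractional remainders. This keeps every stratum
within one participant of the target fraction and makes the overall
training size deterministic given the strata — e.g. strata of 214, 94
and 122 at fraction 0.7 give 150 + 66 + 85 = 301. Which participants
fill the slots is drawn from the supplied seed; the partition is exactly
reproducible. Strata with fewer than 2 members go entirely to training
with a warning.

## The synthetic cohort generator

`simulate_cohort()` draws paired scores from a mixture of per-stratum
latent bivariate Gaussians: each record is assigned a clinical component
(HC, GDS 3, GDS 4–5) by mixture weight, a latent $(RUDAS, MMSE)$ pair is
drawn with that component's means, SDs and correlation, and each
coordinate is rounded to the nearest integer and clipped to $[0, 30]$.

What this emulates:

* the bimodal-ish pooled distributions of a mixed memory-clinic sample
  (healthy controls near ceiling, dementia strata lower and wider);
* ceiling effects, produced mechanically by clipping — healthy-control
  latent means are allowed to exceed 30 so that probability mass piles up
  at the ceiling;
* the cross-test correlation within and across strata.

What it does not emulate: item-level structure, education or language
effects on individual items, test-retest error, floor effects in severe
dementia, or missing data. Scores are exchangeable within a component;
there is no covariate structure beyond the clinical stratum and the
population label.

### Calibration of the default presets

`default_configs()` ships three presets — `majority_training`
($n = 299$), `majority_validation` ($n = 131$) and `minority`
($n = 259$, healthy-control-dominated with strong ceiling compression).
The component-level latent parameters are calibration knobs of this
package: they were tuned once, by large-$n$ simulation, so that the
pooled post-rounding, post-clipping moments of each preset hit the
targets (majority: RUDAS $\approx 24.9 \pm 5.3$, MMSE
$\approx 26.3 \pm 4.4$, cross-test $r \approx .84$; minority: RUDAS
$\approx 28.5 \pm 3.1$, MMSE $\approx 29.0 \pm 2.6$, $r \approx .84$),
and then frozen. They are not estimates of any real stratum, and they
were not adjusted afterwards in response to test outcomes. The frozen
values:

| preset | component | weight | $\mu_R$ | $\sigma_R$ | $\mu_M$ | $\sigma_M$ | $\rho$ |
|---|---|---|---|---|---|---|---|
| majority | HC | 149/299 | 29.05 | 2.2 | 29.85 | 1.50 | .52 |
| majority | GDS3 | 65/299 | 24.65 | 3.4 | 26.15 | 2.80 | .52 |
| majority | GDS4_5 | 85/299 | 18.65 | 4.2 | 21.15 | 3.80 | .52 |
| minority | HC | 219/259 | 30.45 | 2.0 | 30.75 | 1.35 | .45 |
| minority | GDS3 | 20/259 | 25.60 | 3.0 | 27.00 | 2.40 | .55 |
| minority | GDS4_5 | 20/259 | 21.20 | 3.6 | 23.00 | 3.20 | .55 |

(The majority validation preset reuses the majority components with
weights 65/131, 29/131, 37/131.)

## The pipeline

`run_study(run_config(...))` chains the stages — data acquisition
(simulate or ingest + stratified split), per-marginal degree selection
and presmoothing, equating, crosswalk construction, and validation on
the majority validation arm and (optionally) the minority arm. Any stage
failure is re-raised as a pipeline error naming the stage. With
`output_dir` set, the crosswalk, cohorts, validation reports and a
settings file are written as CSV/JSON. All randomness flows from the
single `seed` in the config (training at `seed`, majority validation at
`seed + 1`, minority at `seed + 2`), and the pipeline preserves the
caller's RNG state.

```{r}
run <- run_study(run_config(seed = 11))
glance(run)
```

## The packaged published table

`published_crosswalk()` loads a published RUDAS→MMSE conversion table
(provenance `"published-rudas-mmse-v1"`, 31 rows, MD5-checksummed at
load). It is the recommended table for applying an established
conversion to new data via `apply_crosswalk()`. Re-estimated crosswalks
from the default simulated cohorts agree with it closely over RUDAS
10–30, the range on which the published conversion was observed;
below that, both tables are smoothed extrapolation and can differ.

## Problem sizes and tolerances

The package targets the scale it was built for: cohorts of roughly
100–1000 participants on two 0–30 scales. The test suite exercises
cohorts up to $n = 5000$ (for calibration checks), score supports down
to 3 points, and verifies the equating engine against an independent
bisection-based CDF-inversion oracle to $10^{-12}$, the smoothing MLE
against a coordinate-descent likelihood maximizer to $10^{-5}$, and the
ICC against an `lm()`-based ANOVA decomposition to $10^{-12}$. Moment
preservation is enforced at $10^{-6}$ relative; GLM convergence at
$10^{-12}$.

## Limitations

* Equipercentile equating assumes the two tests measure the same
  construct in the equated population; the crosswalk is
  population-dependent and should be re-estimated or at least
  re-validated before use in populations unlike the one it came from.
* The single-group design has no counterbalancing; order effects, if
  present in the data, fold into the crosswalk.
* Crosswalk entries below the observed score range rest on the
  log-linear extrapolation and carry no direct empirical support.
* The simulator is a moment-level emulation, not an item-level model;
  conclusions about item behavior are out of scope.
* Standard errors of the equated values themselves (e.g. by bootstrap)
  are not implemented; validation is via the held-out agreement metrics.
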