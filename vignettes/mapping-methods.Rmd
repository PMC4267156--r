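---
title: "Mapping FACT-B scores to EQ-5D-5L utilities: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping FACT-B scores to EQ-5D-5L utilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factbmap)
```

## The problem

Economic evaluation of cancer care needs preference-based utilities — a
single number per patient on a scale where 1 is full health and 0 is death —
but clinical studies often collect only profile instruments such as the
FACT-B, the 37-item breast-cancer module of the FACIT family. A *mapping*
(or cross-walk) algorithm predicts the EQ-5D-5L utility index from FACT-B
subscale scores, so that cost-utility and QALY analyses become possible when
only the FACT-B was administered. This package implements such a mapping
end to end: instrument scoring, utility computation from value-set tables,
the published mapping coefficients, the five-estimator framework the mapping
was derived with, and the goodness-of-fit and validation battery — plus a
synthetic-cohort generator so everything is testable without patient data.

## Instrument scoring

FACT-B items are rated 0–4; negatively worded items are reversed as
`4 - raw` (the 0–4 FACIT convention; reversal is an involution). Subscale
scores use the FACIT *half-rule*: a subscale is scored only when strictly
more than half of its items were answered, and missing items are imputed
with the mean of the answered ones — equivalently,
`score = sum(answered) * n_items / n_answered`. Prorated scores can be
non-integer and are kept at full precision for regression. Composites are
plain sums: FACT-G = PWB + SWB + EWB + FWB, TOI = PWB + FWB + BCS, and the
FACT-B total adds all five subscales. A composite is undefined whenever a
component is undefined, and subjects missing a covariate the chosen model
needs are dropped from fitting.

The item manifest (which item belongs to which subscale, and which items
are negatively worded) is configurable: item-level content is licensed, so
the default manifest ships placeholder identifiers (`PWB1`…`BCS10`) with no
reversals, and real analyses supply their own manifest CSV.

## Utilities and value sets

EQ-5D-5L responses (five dimensions, levels 1–5) convert to utilities
through a country-specific value set with 5^5 = 3125 entries, full health
mapping to exactly 1. The interim crosswalk value sets used in the
development study (Japanese floor −0.111, UK floor −0.594) are licensed
artifacts and not bundled; the package loads any user-supplied value-set
CSV (either the full 3125-row table or an additive-decrement schema) and
generates clearly-labelled *synthetic* stub sets — monotone in every
dimension, correct range — for tests and examples only.

## The five estimators

The utility index is bounded above at 1 with a large point mass there
(24.8% of the development sample), which strains the assumptions of
ordinary least squares. The framework therefore fits, under each of five
preset covariate sets (Model 1 = all five subscales … Model 4 = PWB, EWB,
FWB, BCS, the recommended one):

* **OLS** — minimizes squared error; on training data the mean prediction
  equals the mean observation.
* **Tobit** — treats utilities as a latent normal censored above at 1;
  maximum likelihood over (β, σ) with density terms below the ceiling and
  survival terms at it. *Prediction uses the latent linear index*, which
  may exceed 1 — deliberately mirroring the published distribution tables,
  where Tobit predictions exceed the admissible range in a small share of
  the sample.
* **Median (quantile) regression** — minimizes absolute deviations; makes
  no censoring assumption.
* **CLAD** — Powell's censored least absolute deviations: median
  regression acknowledging the ceiling via iterative trimming (drop
  observations whose fitted value reaches the censor point, refit, repeat).
  When trimming never activates it coincides exactly with median
  regression.
* **Logistic quantile regression** — transforms the bounded outcome with
  `h(y) = log((y - y_min) / (y_max - y))` and runs median regression on the
  transformed scale; back-transformed predictions are guaranteed strictly
  inside `(y_min, y_max)`.

The transform bounds follow the conventional rule — `y_min` half of the
value set's smallest increment below the smallest observed utility,
`y_max = 1.001` — with the development study's constants available as
presets (`y_min = 0.17885` Japanese, `−0.28265` UK). One wrinkle: the
printed UK minimum utility (−0.283) sits marginally *below* the printed UK
`y_min`, which can only be a rounding artifact of the displayed minimum;
`derive_bounds()` therefore enforces `y_min < observed_min` for
user-supplied data while the presets store the published constants
verbatim.

### Numerical choices

*LAD solver.* No linear-programming backend is assumed: the quantile
fitter is iteratively reweighted least squares on a smoothed check loss
(smoothing floor lowered over three stages, weighted solves by normal
equations with a QR fallback), refined by a basic-solution search — an
optimal quantile fit interpolates as many observations as design columns,
so exact fits through subsets of the smallest-residual observations are
enumerated and the best objective kept. The solver is deterministic; on
degenerate data with non-unique LAD solutions the attained objective, not
the coefficient vector, is the meaningful quantity. In the test suite its
objective agrees with an independent quantile-regression implementation to
10^-8 at n = 10^4 and to machine precision at small n.

*Tobit.* BFGS on (β, log σ) with analytic gradients, started at OLS,
finished with damped Newton steps to a gradient sup-norm of 1e-8 (the
convergence flag reports whether 1e-6 was reached). Standard errors come
from the inverse observed information. With no censored observations the
MLE coincides with OLS (asserted to 1e-4 at a censor point of 10).

*CLAD iteration.* The kept set only ever shrinks (observations trimmed at
one iteration are never re-admitted), so the iteration terminates without
oscillation, capped at 50 rounds; fitted values exactly at the censor point
are trimmed. The development study does not describe its CLAD scheme, so
coefficient-level agreement with other software is not claimed — on
Japanese-value-set-like data trimming rarely activates and CLAD equals
median regression exactly, matching the published observation that the two
had identical point estimates in all models.

*Standard errors.* OLS classical; Tobit from the observed information;
CLAD, quantile and logistic-quantile by seeded nonparametric bootstrap
(default 200 resamples), since the development study does not state its
method.

## Goodness of fit and validation

Across methods, fit is compared by the squared Pearson correlation between
observed and predicted values (equal to R² under OLS), penalized as
`adjusted r² = 1 − (n − 1)/(n − p − 1)(1 − r²)` with `p` the number of
covariates excluding the intercept — the convention verified by the fact
that all 25 published adjusted values reproduce from the published r²
values only under this counting. MSE and MAD are both reported because MSE
structurally favors least-squares and MAD least-absolute-deviation fits.

The validation battery groups subjects by self-assessed performance status
(0, 1, 2, and 3–4 merged, scored 3 in the trend test), compares observed
and predicted means within groups by the Wilcoxon signed-rank test (zeros
dropped; exact permutation null via dynamic programming for ≤ 25 nonzero
pairs, which handles midranks exactly, otherwise a tie- and
continuity-corrected normal approximation; p = 1 by convention when all
differences vanish), and tests each mapping's predictions for trend across
status with Cuzick's rank statistic, standardized by its exact permutation
mean and variance so that the two-group case reduces to the tie-corrected
rank-sum test. Group-mean discrepancies are flagged against the minimally
important difference of the EQ-5D for cancer patients (0.08 UK, 0.06 US).
Whether the original signed-rank tests were exact or asymptotic is not
stated; the exact branch is the small-sample default here.

## The synthetic-cohort generator

The generator emulates the development sample's *marginal* structure, which
is all the published tables identify:

* Subscale scores: exchangeably correlated Gaussian latents with the
  published baseline means (21.1, 22.2, 18.0, 20.0, 21.7) and SDs
  (6.0, 6.1, 4.7, 6.7, 6.1), rounded half-up and clamped to each
  instrument range. The published tables give no correlation matrix; the
  exchangeable correlation defaults to 0.4, chosen so the default r² on
  synthetic fits lands in the ≈ 0.5 regime of the published models, and is
  configurable.
* Latent utility: the published OLS Model 4 mapping plus Gaussian noise
  (SD 0.08 by default).
* Ceiling: real EQ-5D-5L value sets have a discrete gap between full
  health and the best impaired state, so observed utility distributions
  show a point mass at exactly 1 sitting above a continuum. The default
  rule reproduces this by collapsing the top `target_ceiling_fraction`
  (default 24.8%, the published ceiling mass) of the latent distribution
  to 1, with the threshold calibrated on the realized latent quantiles
  (rounding and clamping make the latent slightly non-normal, so analytic
  normal quantiles would drift off target). Under the defaults a large
  cohort shows ≈ 24.8% at ceiling and mean utility ≈ 0.785, close to the
  published 0.777. Setting `target_ceiling_fraction = NULL` censors at
  exactly 1 — the canonical Tobit data-generating process used for the
  censored-estimator recovery experiments — and `ceiling_rule = "clip"`
  plainly clips.
* Performance status: cut from the latent utility at its quantiles
  matching the published mix (40.8/48.3/7.1/3.8%), which makes group mean
  utilities strictly decreasing in status by construction; the merged
  worst group is split evenly between labels 3 and 4.
* Follow-up wave: subjects retained with probability 0.93 (238 → ≈ 221,
  the published retention), latent utilities drifted by N(0, 0.05) and
  re-censored at the *baseline* threshold, subscales drifted by a small
  integer perturbation (SD 20 × drift, i.e. one point at the default).

What passing tests on these cohorts do **not** show: the generator has
Gaussian subscale latents and additive noise, no item-level response
structure (items are only generated uniformly conditional on a subscale
score for scoring tests), no language/ethnicity effects, and marginals
calibrated to published summaries only — so agreement on synthetic data
demonstrates the estimators' correctness under their own assumptions, not
the clinical accuracy of the mapping in new populations.

A note on one deliberate deviation: a plain Gaussian latent censored at 1
cannot simultaneously reproduce the published mean (0.777), SD (0.163) and
ceiling mass (24.8%) — with the published mapping and noise SD 0.08 the
latent is approximately N(0.776, 0.137²), putting only ≈ 5% above 1, while
shifting the intercept to force 24.8% pushes the mean to ≈ 0.89. The
gap-collapse rule above is the package's resolution: it matches the
ceiling mass and the mean at once and mirrors the actual mechanism (the
value-set gap below full health). Consequently OLS on *default* synthetic
cohorts is mildly biased upward — as it should be on ceiling-heavy data;
parameter-recovery experiments therefore pair each estimator with data
from its own generating process (ceiling-free for OLS and median
regression, censoring at exactly 1 for Tobit and CLAD, the
transformed-scale Laplace model for logistic quantile regression).

## Problem sizes used in the shipped experiments

Recovery experiments run at n = 10^4 with 200 bootstrap resamples for the
LAD-family standard errors; distribution checks use n = 10^4 (±2
percentage points on the ceiling mass) and n = 238 development-sized
cohorts (±6 points); brute-force oracles run at n ≤ 12 (signed-rank
enumeration) and n ≤ 8 with p ≤ 2 (LAD subset enumeration); the Cuzick
permutation oracle uses 10^5 permutations on nine observations. These
sizes keep every Monte-Carlo tolerance a small multiple of its binomial or
bootstrap standard error.

## Known limitations

* The development data are not deposited, so the published coefficients
  are transcribed at 4-decimal precision and cannot be re-estimated;
  registry entries are fixtures, not fits.
* Tobit σ is not published; published Tobit entries predict via the latent
  index but cannot simulate.
* The CLAD/median-regression divergence reported under the UK value set
  depends on the original (unstated) solver and is not reproduced.
* Stub value sets share only the range and monotonicity of real crosswalk
  tables; real analyses must supply licensed tables.
* Sensitivity analyses from the development study (language interactions,
  quadratic terms, item-level stepwise selection) are out of scope, though
  extra covariates can enter any design linearly.
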