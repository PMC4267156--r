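# factbmap

Map FACT-B breast-cancer quality-of-life scores to EQ-5D-5L health
utilities.

Cost-utility and QALY analyses need a preference-based utility index (1 =
full health, 0 = death, negative = worse than death), but many breast-cancer
studies collect only the FACT-B, a 37-item profile instrument with five
subscales: physical (PWB), social/family (SWB), emotional (EWB), functional
well-being (FWB) and breast-cancer concerns (BCS). `factbmap` implements a
published mapping algorithm between the two, together with the machinery it
was built from:

* **Scoring** — FACIT half-rule subscale scoring (a subscale counts only
  when strictly more than half its items are answered; missing items are
  imputed at the observed mean), polarity recoding, and the FACT-G
  (PWB+SWB+EWB+FWB), TOI (PWB+FWB+BCS) and FACT-B total composites.
* **Utilities** — EQ-5D-5L utility computation from pluggable value-set
  tables (full 3125-state tables or additive-decrement schemas), with
  synthetic stub sets for testing.
* **Estimation** — the recommended mapping is OLS under "Model 4":

      utility = 0.2846 + 0.0121 PWB + 0.0041 EWB + 0.0044 FWB + 0.0034 BCS

  The full published registry (5 methods x 5 models, development sample
  n = 238) ships with the package, and all five estimators can be refitted
  on new cohorts: OLS, upper-censored Tobit (MLE on the latent normal),
  median quantile regression, Powell's CLAD (iterative trimming), and
  logistic quantile regression on h(y) = log((y − y_min)/(y_max − y)),
  whose back-transformed predictions always stay inside the bounds.
* **Evaluation** — squared observed-predicted correlation with the
  complexity penalty adjusted r² = 1 − (n−1)/(n−p−1)(1−r²), MSE, MAD,
  distribution summaries with floor/ceiling fractions, Wilcoxon
  signed-rank tests (exact null for small samples), Cuzick's trend test
  across performance-status groups, and minimally-important-difference
  flags (0.08 UK / 0.06 US).
* **Simulation** — a synthetic-cohort generator emulating the development
  sample's subscale distributions, ceiling mass (24.8% at utility 1) and
  performance-status mix, for testing and parameter-recovery experiments.

## Worked example

```r
library(factbmap)

# published mapping: predict a utility from subscale scores
m <- published_mapping("ols", 4)
predict(m, c(PWB = 21.1, EWB = 18.0, FWB = 20.0, BCS = 21.7))
#> [1] 0.77549

# simulate a development-sized cohort and refit all five estimators
cohort <- generate_cohort(synth_config(n = 238, seed = 1))
mean(cohort$utility == 1)
#> [1] 0.2478992          # ceiling mass near the published 24.8%

fit <- fit_mapping(cohort, model = 4, method = "ols")
print(fit)
#> FACT-B -> EQ-5D-5L mapping: ordinary least squares
#>   model spec: Model 4
#>   fitted on n = 238 subjects
#> (Intercept)         PWB         EWB         FWB         BCS
#>      0.2435      0.0129      0.0049      0.0034      0.0058

gof(cohort$utility, fitted(fit), p = 4)
#> goodness of fit (n = 238, p = 4):
#>   r2 0.5964  adjusted r2 0.5895  MSE 0.0088  MAD 0.0764

# validate against a follow-up wave by performance status
fu <- generate_followup(cohort)
v <- validate_by_status(fu, m)
v$max_discrepancy
#> [1] 0.1232356
```

The first call evaluates the published equation at the development sample's
mean subscale profile: 0.7755, essentially the observed mean utility
(0.777; the residual gap is rounding of the printed coefficients).
The refitted coefficients differ from the published ones because the
synthetic cohort is generated with a ceiling mechanism, on which OLS — by
design — is mildly biased; the goodness-of-fit magnitudes sit in the same
r² ≈ 0.5–0.6 regime as the published models.

A thin command-line interface wraps the same functions
(`exec/factbmap score|map|fit|evaluate|simulate|validate`).

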