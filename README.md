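# twinpillars

Twin models and regression trees for studying how meeting multiple
lifestyle "pillars" — ≥8h sleep, ≥5 daily fruit/vegetable servings, ≤2h
daily sedentary time, ≥150 min/week of moderate-to-vigorous physical
activity (MVPA), and not smoking — relates to body mass index (BMI) and
depressive symptoms (PHQ-2) in same-sex twin pairs.

The package is aimed at behavior-genetic and epidemiological analysts who
want the full co-twin analysis chain in one place:

* **Survey coding** of the five dichotomous pillar indicators, the 0–5
  pillar count (missing unless all five indicators are observed), BMI from
  US-customary units (`703·lb/in²`, modeled as log BMI) and the PHQ-2 total
  (modeled as √PHQ).
* **Univariate ACE decomposition** by maximum likelihood for continuous and
  ordinal (liability-threshold) twin traits, with FIML handling of
  incomplete pairs: shares `a²`, `c²`, `e²` with implied twin correlations
  `r_MZ = a² + c²`, `r_DZ = a²/2 + c²`.
* **Quasi-causal bivariate co-twin models.** The count gets its own ACE
  structure and the outcome loads on it and on its familial components:

  ```
  X_ij = μx + a_x A_ij + c_x C_i + e_x E_ij
  Y_ij = μy + b_P X_ij + b_A A_ij + b_C C_i + residual ACE + covariates
  ```

  Model 1 fixes `b_A = b_C = 0` (phenotypic association); Model 2 estimates
  a single between-family confound path `b_F = b_A = b_C`; Model 3 equates
  the phenotypic path `b_P` across male and female pair groups, with a Wald
  test of that equality. On the log-BMI scale `100·(1−exp(b_P))` is the
  percent change in BMI per additional pillar met.
* **Regression trees** over the binary pillars (SSE improvement, surrogate
  splits for missing data, 10-fold cost-complexity pruning, summed-
  improvement variable importance scaled to 100).
* **Within-pair difference descriptives** (more-pillars twin minus co-twin,
  by count gap and zygosity) and between-individual category contrasts.
* **A synthetic twin-registry generator** emulating the analysis's
  assumptions (MZ/DZ liability structure, published pillar prevalences and
  missingness rates, raw survey back-conversion), so every stage is
  testable without restricted registry data.

## Worked example

```r
library(twinpillars)

cfg <- registry_config(n_mz_pairs = 1000, n_dz_pairs = 1000)
raw <- generate_registry(cfg, seed = 2024)   # raw survey rows, 2 per family
dat <- code_pillars(raw)                     # pillars, count, outcomes

table(dat$n_pillars)
#>    0    1    2    3    4    5
#>   31  453 1174 1406  671  112

fit_ace_continuous(dat, "log_bmi")
#> Univariate ACE fit (continuous): log_bmi
#>   a2 = 0.563  c2 = 0.192  e2 = 0.245
#>   mean = 3.2363  total variance = 0.0506
#>   -2LL = -1645.20  pairs: MZ 1000, DZ 1000

m1 <- fit_quasicausal(dat, "sqrt_phq", model = 1,
                      predictor_mode = "observed_count")
m2 <- fit_quasicausal(dat, "sqrt_phq", model = 2,
                      predictor_mode = "observed_count")
m1
#> Quasi-causal bivariate twin model (Model 1, observed_count)
#>   outcome: sqrt_phq  predictor: count of sleep_met, fv_met, ...
#>   [male]  b_P = -0.1475 (SE 0.0167, p = 8.94e-19)
#>   [female]  b_P = -0.1585 (SE 0.0122, p = 1.49e-38)
m2
#> Quasi-causal bivariate twin model (Model 2, observed_count)
#>   [male]  b_P = -0.0643 (SE 0.0251, p = 0.0105)  b_F = -0.2586 (SE 0.0176)
#>   [female]  b_P = -0.0981 (SE 0.0201, p = 1.01e-06)  b_F = -0.0841 (SE 0.0221)

wald_test(m2, "b_P_equal")$p
#> [1] 0.2927907
```

Read: the population-level (Model 1) association between the pillar count
and depressive symptoms attenuates once between-family confounds are
controlled (Model 2) but remains negative and significant, and the
cross-sex Wald test does not reject equal `b_P` for men and women — the
justification for the pooled Model 3. A slope of −0.026 on the log-BMI
scale corresponds to `percent_change_per_pillar(-0.026)` = 2.57 ≈ a 2.6%
decrease in BMI per additional pillar met (factor `exp(-0.026)` = 0.97).

`run_pipeline()` chains all stages (descriptives, ACE, Models 1–3 for both
outcomes and both "top-2" pillar presets, trees, difference summaries) on a
generated or supplied registry and writes CSV/JSON outputs plus a seeded
run log.

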