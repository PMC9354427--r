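---
title: "Methods: twin models and trees for multiple lifestyle behaviors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin models and trees for multiple lifestyle behaviors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Five widely promoted lifestyle "pillars" — at least 8 hours of sleep per
night, at least 5 daily servings of fruits and vegetables, at most 2 hours of
daily sedentary screen time, at least 150 weekly minutes of
moderate-to-vigorous physical activity (MVPA), and not smoking — are all
associated with body mass index (BMI) and depressive symptoms in ordinary
population samples. Such phenotypic associations are ambiguous: people who
meet more pillars differ from people who meet fewer in genetic background
and in the family environment they were reared in, and those differences
also shape BMI and mood. Same-sex twin pairs let us split the association:
monozygotic (MZ) co-twins share all additive genetic influences and their
rearing environment, dizygotic (DZ) co-twins share half the additive
genetic influences on average, so the contrast between the two pair types
identifies how much of a predictor-outcome association is carried by
between-family confounds and how much survives within pairs
("quasi-causal").

`twinpillars` implements the full analysis chain for this design: survey
coding of the pillar indicators and the 0--5 pillar count, univariate ACE
variance decomposition, the bivariate quasi-causal co-twin model with its
constraint sequence and Wald tests, CART-style regression trees with
surrogate splits and variable importance, within-pair difference
descriptives, and a synthetic registry generator that makes every stage
testable without access to restricted registry data.

## Coding rules

BMI is computed from self-reported height (inches) and weight (pounds) as
`703 * lb / in^2` and modeled as its natural logarithm; the two-item PHQ-2
depression screener (items 0--3) is summed to 0--6 and modeled as its
square root. Each pillar is a dichotomous met/not-met indicator; the pillar
count is the number met, and it is treated as missing whenever any
indicator is missing — a count computed from a partial profile would be a
lower bound rather than a sum, which is also why the count has higher
missingness than any single item.

Two coding options deserve comment.

* **Sleep standard.** The main standard is 8 hours; 7 hours is exposed as a
  sensitivity setting (`sleep_standard = "7h"`), reflecting the consensus
  range of 7--9 hours whose midpoint motivates the default.
* **Fruits and vegetables.** The published clause list for this pillar is
  asymmetric in fruits versus vegetables and contains a duplicated clause.
  The default implementation is the literal rule — met when fruits are at
  least "3--4" servings with vegetables at least "1--2", or vegetables are
  "5+" with fruits at least "1--2". Because the printed list looks like a
  transcription slip of a symmetric rule, the mirrored clause is available
  behind `symmetric_fv = TRUE`; we deliberately do not guess further.

## The univariate ACE model

For a trait value of twin *j* in a pair, the classical biometric
decomposition is

$$y_j = \mu + a A_j + c C + e E_j,$$

with unit-variance latent factors, $\mathrm{corr}(A_1, A_2) = 1$ for MZ and
$0.5$ for DZ pairs, and $C$ shared. The implied twin correlations are
$r_{MZ} = a^2 + c^2$ and $r_{DZ} = a^2/2 + c^2$. We optimize unconstrained
path coefficients and report their squares as standardized shares, which
keeps shares nonnegative by construction and makes boundary solutions
(e.g. $\hat c^2 = 0$) visible as a pile-up at zero rather than a negative
estimate; boundary fits are flagged as SE-unreliable. Incomplete pairs
contribute their univariate marginal density, so the fit is
full-information maximum likelihood (FIML) rather than complete-case.
Standard errors come from the central-difference Hessian of the
$-2\log L$ surface, mapped to shares by the delta method.

Ordinal traits (the binary pillars; the 0--5 count) use the
liability-threshold model: a standard-normal latent liability cut at
ordered thresholds. Pair contributions are bivariate-normal rectangle
probabilities at latent correlation $a^2 \bar r + c^2$, computed with a
deterministic bivariate-normal CDF (Drezner-Wesolowsky Gauss-Legendre
form, with an adaptive fallback near $|\rho| = 1$), never by simulation, so
likelihood values are exactly reproducible. The count spans six categories
(0--5); we model all six.

## The bivariate quasi-causal model

The pillar count $X$ receives its own ACE structure, and the outcome loads
both on $X$ and directly on $X$'s familial components:

$$X_{ij} = \mu_x + a_x A_{x,ij} + c_x C_{x,i} + e_x E_{x,ij},$$
$$Y_{ij} = \mu_y + b_P X_{ij} + b_A A_{x,ij} + b_C C_{x,i}
  + a_u A_{u,ij} + c_u C_{u,i} + e_u E_{u,ij}.$$

$b_P$ is the phenotypic (within-person) association; $b_A$ and $b_C$ carry
whatever part of the association is due to genes and rearing environment
shared within families. The constraint sequence mirrors the standard
co-twin analysis:

1. **Model 1** (phenotypic): $b_A = b_C = 0$, $b_P$ free per sex group.
2. **Model 2** (quasi-causal): a single between-family path
   $b_F = b_A = b_C$ is estimated. The equality is imposed a priori: with
   only MZ/DZ contrast to separate them, $b_A$ and $b_C$ are so weakly
   identified that unconstrained fits produce unstable estimates with large
   standard errors.
3. **Model 3**: Model 2 with $b_P$ additionally equated across the male-
   and female-pair groups, justified when a Wald test of the cross-sex
   equality is non-significant. Only $b_P$ is constrained; variance
   components remain sex-specific.

$b_A$ and $b_C$ multiply the *standardized* latent components (variance
1), i.e. they are path coefficients; descriptions of these parameters as
"amounts of variance" are loose shorthand and we adopt the path-coefficient
semantics explicitly. Covariates (age, race as a White/non-White contrast,
income and education as integer scores) enter the outcome mean only; a
predictor-side adjustment is not part of the model.

Model 1 deliberately retains the ACE structure on the outcome residual: it
is the same twin SEM with two paths fixed at zero, not an
independent-observations regression, so the Model 1 to Model 2 comparison
is a nested likelihood comparison on identical data. Note the nesting
direction: Model 1 ($b_F = 0$) and Model 3 (shared $b_P$) are both
restrictions *of* Model 2, so $-2\log L$ can only decrease from Model 1 or
Model 3 to Model 2.

Two predictor treatments are provided. The default,
`predictor_mode = "liability_ordinal"`, is the liability-threshold
treatment of the count: the outcome pair is conditionally bivariate normal
given the latent liabilities, and each pair's likelihood integrates the
latent pair over its threshold rectangle by Gauss-Legendre quadrature. The
quadrature is deterministic; the per-axis order (default 8) grows
automatically with interval width so that tail categories remain accurate,
and doubling the order moves $-2\log L$ by well under $10^{-6}$ on our
fixtures. `predictor_mode = "observed_count"` treats the integer count as
a continuous ACE phenotype; it is an order of magnitude faster, recovers
the same associations on simulated registries (the two modes are
cross-checked in the test suite), and is the default for the
registry-scale `run_pipeline()` wrapper for that reason. On the log-BMI
scale, a slope $b_P$ converts to a percent change per additional pillar as
$100(1 - e^{b_P})$.

FIML is used throughout: any subset of the pair 4-vector
$(X_1, Y_1, X_2, Y_2)$ may be missing, and the observed subvector
contributes its marginal density (in liability mode, a missing category
integrates its liability over the whole line, and a pair missing both
outcomes reduces to an exact rectangle probability). Non-positive-definite
implied covariances during optimization are penalized, not crashed on.
When the model level shares no parameters across sex groups the two groups
are fitted separately and the covariance assembled block-diagonally —
algebraically identical to the joint fit, and faster.

## Regression trees

Trees predict the raw-scale outcome (kg/m^2, PHQ-2 units) from the five
binary indicators. The splitting criterion is the ANOVA improvement
$SSE(\text{parent}) - SSE(\text{left}) - SSE(\text{right})$, computed over
the cases observed on the candidate. The originating description of this
procedure names the Gini index, which is the classification criterion of
the same tool; for a continuous outcome the regression default of that
tool is the SSE reduction implemented here. Defaults follow the CART
conventions: minimum 20 cases in a parent node, complexity threshold
`cp = 0.01` of the root SSE, ties broken by the canonical pillar order
(sleep, fruit/vegetables, sedentary, MVPA, smoking).

Missing values are routed by surrogate splits: every other variable is
oriented to maximize agreement with the primary split among cases observed
on both, retained only when it beats the go-with-majority baseline, and
applied in agreement order, with the majority side as last resort.
Variable importance sums each variable's improvements as a primary
splitter plus adjusted-agreement-weighted improvements as a surrogate
(adjusted agreement is the excess over the majority baseline rescaled to
$[0, 1]$), normalized to total 100. Importance is computed on the pruned
tree by default; whether to use the pruned or full tree is genuinely open,
and the pruned tree is the one whose structure is reported.

Pruning is cost-complexity: the nested weakest-link sequence of the grown
tree is evaluated by 10-fold cross-validation (folds assigned by family so
co-twins never straddle a fold; the assignment is seeded), and the penalty
minimizing cross-validated error is chosen. The one-standard-error rule is
available (`rule = "1se"`); it is the variant that reliably collapses
pure-noise trees to the root (100% of our replicates, versus roughly 90%
for the minimum-error rule), while minimum-error remains the default.

## Within-pair descriptives

For a pillar-count gap $d$, the between-individual summary averages the
contrasts $\bar y_{k+d} - \bar y_k$ over all populated category pairs
(unweighted by default; an n-weighted option exists) and propagates the
standard error through the coefficients of the resulting linear
combination of category means — adjacent contrasts share categories, so
the coefficients telescope and the SE is not the naive independent sum.
The within-pair summary takes, for each discordant complete pair, the
outcome of the twin meeting more pillars minus the co-twin's, grouped by
absolute count difference and zygosity; strata with no pairs are simply
absent (at realistic prevalences no pair differs by all five pillars), and
an SE is reported only when a stratum has at least two pairs. These
descriptives intentionally use raw outcome scales, matching how such
figures are drawn, while the models use transformed scales.

## The synthetic registry generator

`generate_registry()` emulates the study conditions the analysis assumes:

* same-sex MZ and DZ pairs, about two-thirds female;
* pillar endorsement prevalences 38.7, 50.3, 48.3, 41.2, 89.8 percent
  (sleep, fruit/vegetables, sedentary, MVPA, non-smoking), realized by
  thresholding ACE-structured standard-normal liabilities at
  `qnorm(1 - p)`;
* pillar liabilities independent across pillars by default (no dependence
  structure is documented for the real data); a shared-factor loading is
  available for stress tests;
* outcomes linked to the standardized pillar count by $b_P$ and to the
  count's additive-genetic and shared-environmental composites by $b_A$,
  $b_C$, plus covariate effects and an ACE-structured residual. The count
  is standardized by its analytic population SD
  ($\sqrt{\sum_p p(1-p)} \approx 1.03$ at the default prevalences), so
  slope units are stable across configurations and nearly coincide with
  per-count units;
* default slopes taken from the constrained quasi-causal estimates
  reported for the real registry (log-BMI: $b_P = -0.006$,
  $b_F = -0.054$; sqrt-PHQ: $b_P = -0.098$, $b_F = -0.109$), with age
  effects per decade; pillar-liability ACE shares (0.4/0.2/0.4) and
  outcome residual shares are testing placeholders, not empirical claims —
  the real registry's intraclass correlations are not published in the
  material we reproduce;
* item-level MCAR missingness calibrated so that BMI is missing for 1.2%,
  PHQ-2 for 1.1%, and the five-pillar count for 3.8% of individuals (the
  per-item pillar rate solves $1-(1-q)^5 = 0.038$). MCAR is an assumption
  of convenience: the real mechanism is undocumented, and FIML is valid
  under the weaker MAR condition anyway.

Liabilities are back-converted to raw survey responses so the coding rules
are exercised end to end: sleep hours are drawn uniformly within the
met/not-met region (with the not-met region split so the 7-hour
sensitivity standard reproduces its own published prevalence of 73.9%),
fruit/vegetable and sedentary categories are drawn uniformly within the
category sets consistent with the indicator, activity day-pairs are drawn
on the full grid and projected by minimal L1 change onto the consistent
set, heights are drawn from sex-specific normals and weights solved from
the generated BMI, and the PHQ-2 total is split across its two items.
Rounding (quarter-hour sleep, integer height/weight) is clamped so it
never crosses a coding cutoff.

What the generator does *not* emulate: assortative mating, age- or
sex-dependent variance components, dependence between pillars, non-normal
liabilities, informative missingness, and measurement error beyond
rounding. Passing parameter-recovery tests on this generator therefore
shows the estimators are correct for the assumed data-generating process —
it does not validate the substantive findings on real registry data,
which are not reproducible without access to them.

## Numerical choices

* Bivariate normal CDF: 32-node Gauss-Legendre on the Drezner-Wesolowsky
  correlation integral for $|\rho| \le 0.95$, adaptive conditional-CDF
  integration above, exact limits at $|\rho| = 1$; rectangle probabilities
  are clipped at zero and floored at $10^{-300}$ inside logs.
* Optimization: `nlminb` over unconstrained parameterizations
  (paths squared into shares; thresholds as a first value plus
  log-increments), with one jittered restart if convergence is not
  reported. Degenerate implied covariances return a large penalty.
* Standard errors: central-difference Hessians of $-2\log L$ with step
  $10^{-4}(1+|\theta|)$; parameter covariance $2 H^{-1}$; boundary
  estimates flagged rather than silently reported.
* Liability-mode quadrature: latent integrals truncated at $\pm 7.5$
  (tail mass below $10^{-12}$), per-axis node count
  $\max(\text{order}, 3 \times \text{width})$ capped at 40.

## Problem sizes

The package's own validation suite runs at sizes chosen to make
Monte-Carlo error small relative to the tolerances being asserted: ACE
recovery at 5,000 pairs per zygosity (estimates within $\pm 0.05$ of
truth, about three empirical standard errors), the confounding-attenuation
experiment at 3,000 + 3,000 pairs, Wald-test size calibration over 500
replicates of 150 + 150 pairs per sex group, moment checks against
$10^6$-pair simulation, and exhaustive split-oracle checks on all fixtures
up to 50 cases and 6 predictors.

## Known limitations

* No ADE or sex-limitation variance models, no sibling or other-kinship
  extensions, no opposite-sex pairs, no direction-of-causation or
  longitudinal models.
* The bivariate model's supplementary presentation in the source material
  is not public; the structural equations here are reconstructed from the
  main-text description and table footnotes, and exact standard-error
  conventions of commercial SEM software are not replicated.
* $b_A$ and $b_C$ are near-collinear even after the equality constraint;
  with modest samples the between-family path can sit on a likelihood
  ridge against the shared-environmental residual, and its SE should be
  read with that in mind (the phenotypic path $b_P$ is well identified in
  all our experiments).
* Trees treat predictors as binary only — that is the design of this
  analysis, not a general CART implementation.
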