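---
title: "Intervention-derived multilipid scores: models, conventions and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intervention-derived multilipid scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidscore)
```

## The problem and the model

Dietary guidance to replace saturated (SFA) with unsaturated (UFA) fat is
hard to evaluate against hard endpoints directly: feeding trials are
short, cohorts are confounded. The strategy implemented here bridges the
two. A randomized feeding trial defines, per lipid variable $x_j$ (log
concentration), the causal diet effect $\beta_j$ via ordinary least
squares of the post-intervention value on the arm indicator, adjusting
for the baseline value, age, BMI and sex. Effects surviving
Benjamini–Hochberg control at FDR 5% are carried, unchanged, as weights
of a multilipid score

$$\mathrm{MLS}_i = \tfrac{1}{s}\textstyle\sum_j \beta_j x_{ij},$$

and $s$ is set to the estimated arm effect on the unscaled score (same
adjusted model applied to the score), so that a one-unit MLS difference
reads as "the lipidome shift produced by the trial's fat-quality
contrast". In an independent cohort the score is then treated as an
ordinary exposure: Prentice-weighted Cox regression under a case-cohort
design, conditional logistic regression under 1:1 matching, linear
substitution models against macronutrient densities, and
effect-modification analysis of an intervention by the pre-intervention
score.

Key modelling assumptions, stated once:

- lipid effects are additive on the natural-log scale, which is why
  weights combine linearly and why aggregation (sums of concentrations)
  must happen **before** the log transform;
- the trial's arms are exchangeable at baseline (randomization), so the
  baseline-adjusted arm coefficient is a consistent effect estimate;
- proportional hazards on the age time scale for cohort outcomes;
- the score's association transports across populations — a working
  assumption the package can probe (reduction fidelity, cluster scores,
  mutual adjustment) but not prove.

## Sign convention

Selected diet effects are concentration *reductions* ($\beta_j < 0$).
Because lowered lipid levels multiply negative weights, the weighted sum
*rises* under the intervention diet: a higher score means a more
UFA-like lipidome, and protective hazard ratios are below 1. If a score
is standardized against a contrast with a negative arm effect (possible
for single-biomarker analogues such as non-HDL cholesterol, which the
intervention lowers), `standardize_to_contrast()` warns that scaling
flips the sign rather than silently changing directionality.

## Tunable parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| FDR level | 0.05 | — | the selection rule of the methodology |
| missingness filter | > 0.70 | fraction | strict inequality: exactly 70% missing is retained |
| dilution factor | 1/0.9 | — | 10% citrate volume in plasma |
| CI-test alpha (PC) | 0.01 | — | conservative edges for sparse lipid graphs |
| NetCoupler threshold | 0.05 | — | per-submodel significance, sign-consistency required |
| degree cap (NetCoupler) | 12 | neighbors | bounds the $2^{\mathrm{degree}}$ submodel loop |
| substitution scale | 8 | % energy | coefficients read per 8%E substituted for SFA |
| Cox ties | Efron | — | default; Breslow switchable |

## The synthetic world

There is no public lipidomics + outcome dataset for this methodology, so
the generator *is* part of the artifact. It states one world and stays
there:

- **Dependence structure.** A random spanning tree plus extra random
  edges (target density 0.05 at $p = 111$) gives a connected, sparse
  conditional-independence graph; edge weights U(0.2, 0.4) with random
  sign enter a precision matrix, diagonal-loaded to positive
  definiteness and rescaled to unit marginal variances so effects are in
  s.d. units. The zero pattern of the precision is exactly the graph,
  which is what makes PC-skeleton recovery testable.
- **Trial.** 65 control / 130 intervention subjects (the pooled-arm
  layout), within-subject autocorrelation $\rho_{time} = 0.6$ between
  visits, and an additive shift $\delta_j$ on 45 of 111 lipids for the
  intervention arm only. Effect magnitudes are
  $-0.5 \times U(0.75, 1.25)$ log units: the trial this emulates
  produced many strong, uniformly negative selected effects (its
  standardized score effect was about +1 s.d.), and 0.5 log units
  (≈ 40% concentration reduction) at these arm sizes yields the
  high-power regime the selection-recovery criterion describes. Chosen
  a priori from a design calculation, not tuned to tests.
- **Covariates.** age U(35, 65) years, sex Bernoulli(0.5), BMI
  N(26, 4²) kg/m²; the methodology's source specifies none of these.
- **Outcomes.** Exponential event times with hazard
  $\lambda_0 e^{\gamma \cdot \mathrm{score}}$, $\gamma = \log 0.68$ per
  score s.d. by default and administrative censoring at follow-up end;
  entry age is the time origin, matching the age-scale Cox analysis.
- **Left censoring.** Values below a per-lipid 5% quantile are deleted,
  emulating a lower limit of quantification.
- **Second platform.** Isobaric aggregation of molecular species — the
  actual resolution loss between the two real platforms — rather than a
  noise model.
- **Macronutrients.** %E intakes with realistic ranges; `coupling` is
  defined as *the substitution estimand itself*: the true score shifts
  by `coupling × UFA/8` with SFA neutral, so the leave-one-out model's
  UFA coefficient equals `coupling` exactly in the noiseless limit. (A
  formulation shifting the score by the UFA−SFA contrast would make the
  estimand twice the coupling; the chosen semantics keeps recovery
  checks interpretable.)
- **Effect modification.** The stated scenario gives the intervention a
  benefit confined to the below-median pre-intervention-score stratum
  (stratum log-hazard ratios ≈ −0.55 vs 0), expressed through arm,
  arm × pre and arm × pre × year-1 terms (−0.035, 0.344, −0.4) so that
  the three-way Wald test the analysis model uses has a genuine signal.
  A scenario with a pure arm × threshold effect would load on the
  two-way term and leave the three-way test near its null — a property
  of the analysis model, not a defect of the test.

What the generator does **not** emulate: instrument batch effects
(beyond nothing), platform-specific measurement error, non-proportional
hazards, informative censoring, correlated covariates, or diet
measurement error. A green test therefore establishes internal
statistical correctness (estimators recover their estimands in a
well-specified world), not robustness to those violations.

## Numerical conventions and edge cases

- **BH selection boundary.** q-values are `min` cummulated step-up
  values; selection is `q < level` (strict), coinciding with the classic
  step-up rule everywhere except exact equality `q == level`.
- **Prentice risk sets.** Non-subcohort cases enter the risk set
  `1e-4` years (≈ 53 minutes) before their event age — large enough to
  survive `coxph`'s relative tie tolerance on an age scale of ~40–80
  years, small enough to be epidemiologically nil. Robust variance is
  clustered on subject.
- **Conditional logistic.** Fit as an exact-method Cox model per
  matched stratum (the standard construction); |log OR| > 15 is treated
  as separation and refused. Exposures are standardized to the control
  s.d. by default (per-s.d. odds ratios).
- **Double-chain multiplicity.** A fatty acid occurring on k chains of
  one species contributes k times its concentration to the class-FA sum.
  The alternative (count once) breaks additivity of class totals; the
  chosen rule keeps "sum of FA sums = chains × class total" exact and is
  asserted in tests. The original methodology's convention is not
  recoverable from its text; this one is documented prominently.
- **Left-censored imputation.** `qrilc_like` regresses observed log
  order statistics on normal quantiles offset by the censored mass, then
  draws from the fitted normal truncated at the observed minimum. It is
  a deliberate, simplified reimplementation of the quantile-regression
  imputation idea — not a port — and falls back to half-minimum below 4
  observed values.
- **LCD strata ties.** Equal-count 11-bin strata use `rank(ties =
  "min")`, so identical intakes always share a stratum (and identical
  populations get identical scores); with ≥ 11 distinct values the top
  stratum is reachable and the 0–30 range is attained.
- **aMed medians** are pooled, not sex-specific (unstated in the source
  methodology; pooled is the simpler reproducible choice).
- **AHEI cut-offs** ship as a preset of published AHEI-2010 anchors,
  explicitly external to the derivation study; the moderate-alcohol
  window is 5–15 g/day with 2.5 abstainer points, and the
  "without alcohol points" variant (0–100) is available for use as a
  diet-quality covariate.
- **PC stability.** Conditioning sets are drawn from adjacency sets
  frozen at the start of each level, making the skeleton invariant to
  column order; surviving edges record the smallest |partial
  correlation| met along the way.
- **Louvain determinism.** Clustering is seeded; an edgeless graph
  returns singletons with modularity 0 by convention (the modularity
  functional is undefined without edges).
- **rMLS predictor mapping.** Candidate predictors for an unavailable
  class-FA sum are isobaric species of the same class whose total
  carbons/double bonds can contain the target fatty acid. The original
  per-variable predictor lists live in inaccessible supplementary
  material; this rule is a documented reconstruction, and the
  `ReducedScoreMap` records every predictor and weight for audit.
- **Seeds.** All stochastic operations demand explicit seeds; one master
  seed expands to per-stage child seeds by a fixed hash, so pipeline
  reruns are bit-identical while stages stay independent.

## Design choices where the design was open

- Per-arm versus pooled intervention analysis: pooled is the default
  (the derivation trial pooled its two UFA arms after consistency
  checks); per-arm remains possible by subsetting the trial object.
- Variance standardization uses a caller-chosen reference sample
  (typically the subcohort), mirroring cohort-based per-s.d. reporting.
- Imputation regressions in `reduce_score()` are unpenalized by
  default, with an optional ridge for p > n reference panels.
- Covariate single-imputation in the source analysis is replaced by an
  explicit complete-case contract: model columns with missing values are
  a hard error, never silently dropped.
- NetCoupler reports raw classifications plus BH-adjusted flags across
  nodes; the source methodology is silent on cross-node multiplicity.

## Limitations

- The Prentice "just before the event" entry offset is a convention;
  other case-cohort weightings (Self–Prentice, Barlow) are not
  implemented.
- No competing risks, time-varying covariates, or multiple imputation.
- The PC skeleton assumes approximately Gaussian log-lipids and faithful
  sparse structure; the d-separation-oracle tests verify the algorithm,
  not the Gaussianity of real data.
- AHEI sodium scoring uses fixed mg/day anchors rather than
  sample-decile scoring.
- Matching calipers for continuous factors are configuration, not
  inference; unmatched cases are dropped and counted, never reused.
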