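# lipidscore

Dietary fat quality — replacing saturated fatty acids (SFA) with
unsaturated fatty acids (UFA) — leaves a broad fingerprint on the plasma
lipidome. `lipidscore` packages the statistical machinery to turn that
fingerprint into a transportable biomarker and to interrogate it
epidemiologically. It is aimed at nutritional and molecular
epidemiologists who have (a) a two-arm feeding trial with pre/post
lipidomics and (b) one or more observational cohorts with overlapping
lipidomics panels.

## What it computes

The core object is an intervention-derived **multilipid score (MLS)**.
For lipid variables $x_1, \dots, x_p$ (natural-log concentrations), the
trial yields per-lipid intervention effects $\beta_j$ from the
baseline-adjusted model

$$x_{ij}^{post} = \alpha_j + \beta_j \cdot \mathrm{arm}_i + \gamma_j x_{ij}^{base} + \boldsymbol{\delta}_j' \mathbf{z}_i + \varepsilon_{ij},$$

with Benjamini–Hochberg selection at FDR 5%. The selected effects become
the score weights, and the score is standardized to the trial contrast:

$$\mathrm{MLS}_i = \frac{1}{s} \sum_{j \in \mathrm{selected}} \beta_j \, x_{ij},$$

where $s$ is the estimated arm effect on the unscaled score, so one MLS
unit equals the diet-intervention contrast. Around this sit:

- **Lipid data model** — LIPIDMAPS-style name parsing, within-class
  fatty-acid sums, isobaric species sums, a strict >70% missingness
  filter, left-censored imputation (quantile-regression-style or
  half-minimum), scalar dilution correction and a log-once contract.
- **Cohort association** — Prentice-weighted Cox regression for
  case-cohort designs on the age time scale (robust variance),
  conditional logistic regression for 1:1 matched designs, 10-year
  change analysis, and effect-modification analysis (three-way
  interaction plus median-stratified hazard ratios).
- **Cross-platform reduction (rMLS)** — score components not measured
  on a lower-resolution platform are regression-imputed from isobaric
  species using weights learned in a reference cohort, or skipped.
- **Substitution & diet scores** — isocaloric leave-one-out
  macronutrient substitution models scaled per 8% of energy, and
  LCD (0–30), aMed (0–9) and AHEI (0–110) diet-quality indices.
- **Network analysis** — order-independent PC-skeleton estimation with
  Fisher-z partial-correlation tests, Louvain clustering, cluster
  scores that sum exactly to the full score, and a NetCoupler-style
  all-neighbor-subset "direct effect" classification.
- **Synthetic data** — a first-class generator (sparse Gaussian
  conditional-dependence structure, additive trial effects, left
  censoring, proportional-hazards outcomes, case-cohort/matched
  sampling, repeated measures, a second platform by isobaric
  aggregation, coupled macronutrient intakes) with known ground truth,
  so every claim the package makes is testable end to end.

## Worked example

```r
library(lipidscore)

gt     <- generate_ground_truth(p = 111, n_affected = 45,
                                graph_density = 0.05, seed = 1)
trial  <- simulate_trial(gt, n_per_arm = c(65, 130), seed = 2)
effects <- estimate_diet_effects(trial, fdr_level = 0.05)
sum(effects$selected)                     # 41 of 111 lipids selected
def    <- standardize_to_contrast(select_components(effects), trial)
def                                       # <score_definition:MLS> 41 variables, s = 11.2138

cohort <- simulate_cohort(gt, n = 4000, score_def = def, seed = 3)
cohort$subjects$score <- compute_score(cohort$lipids, def)
cc     <- draw_case_cohort(cohort, subcohort_fraction = 0.3, seed = 4)
fit_prentice_cox(cc, exposure = "score", covariates = c("age", "sex", "bmi"))
#> <hazard_result> HR = 0.323 (95% CI 0.212-0.493); reduction 67.7% (50.7% to 78.8%); n=1396, events=280

sub <- cc$id[cc$subcohort]
g   <- pc_skeleton(cohort$lipids$values[sub, def$variables], alpha = 0.01)
g                                         # <network_graph> 41 nodes, 84 edges
louvain_clusters(g, seed = 5)$modularity  # 0.39 over 6 clusters
```

Reading the output: 41 of the 111 simulated lipid variables pass the FDR
filter (45 were truly shifted by the simulated diet); the score scaled to
the trial contrast is then associated with incident disease in a
case-cohort sample of 1,396 subjects (280 cases) — here one
contrast-unit higher MLS corresponds to an estimated 67.7% lower hazard,
because the simulated hazard gradient is steep. The conditional-
independence skeleton over the score lipids splits into 6 Louvain
clusters.

## Documentation

`vignettes/multilipid-scores.Rmd` describes the model, the synthetic
world and its assumptions, numerical conventions and known limitations.
A command-line entry point ships in `inst/cli/lipidscore.R`
(`simulate`, `score`, `pipeline` subcommands).
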