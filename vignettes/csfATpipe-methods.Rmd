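---
title: "Methods: multi-stage CSF proteomics analysis across the AT continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-stage CSF proteomics analysis across the AT continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfATpipe)
```

# Scope and model

`csfATpipe` implements, as a reusable and fully tested pipeline, the analysis
design used in large cerebrospinal-fluid (CSF) aptamer-proteomics studies of
the Alzheimer's disease (AD) continuum: quality control of
relative-fluorescence-unit (RFU) matrices, biomarker-based case definition,
staged differential abundance with meta-analysis, derivation of a frozen
sparse protein signature, pseudo-trajectory grouping, network/circuit-based
enrichment, and clinical outcome models. Because the cohorts such analyses
run on are private, the package ships a synthetic multi-cohort generator with
planted ground truth; every downstream guarantee is expressed and tested
against that ground truth.

## Biomarker groups

Participants are stratified by CSF amyloid-beta-42 (A) and phosphorylated tau
181 (T). Each biomarker is dichotomized per cohort with a two-component
Gaussian mixture fitted by EM (`fit_mixture_cut`); the cut-point is the
*equal-posterior crossing* between the component means rather than the
midpoint, so unequal component variances and weights move the threshold the
way a Bayes classifier would. Amyloid positivity is *low* A-beta-42, tau
positivity is *high* pTau. The three analyzed groups are A−T− (biomarker
negative controls), A+T− (asymptomatic amyloid-only stage) and A+T+
(biomarker-defined AD). The A−T+ pattern is excluded everywhere, and the
generator never produces it. Boundary values sit on the side of the strict
inequality (A+ means strictly below the threshold); posterior ties are
resolved by that inequality because no sharper rule is available.

EM details: deterministic initialization from a median split (so the fit
depends only on the data, not the seed), collapse guards (component weight
< 0.01, vanishing variance, coincident means) raise an error recommending a
fixed fallback threshold rather than returning a meaningless cut.

## Quality control

Aptamer-level rules, applied in order, each strict (`>`):

1. **Scale factor** — max over plates of |calibration − median scale factor|
   above 0.5.
2. **Replicate CV** — median across technical-replicate groups of the raw-RFU
   coefficient of variation above 0.15. CV is computed on raw RFU (CV of a
   log quantity is not standard); with no usable replicate group the rule is
   skipped and logged.
3. **Aptamer IQR** — outside the per-*sample* Tukey fences (1.5×IQR of that
   sample's log10 values across aptamers) in more than 85% of samples. The
   mirrored orientation was chosen to make this rule the exact dual of the
   unambiguous sample rule.
4. **Non-human analytes** — removed by ID list.
5. **Sample IQR** — dual of rule 3, computed on the aptamer-filtered matrix.

Each removed item carries the reason of the first rule that caught it, so
reasons partition the removals and a second QC pass removes nothing
(idempotence is property-tested).

## Differential abundance and the three-stage design

Per aptamer, ordinary least squares of log10 RFU on disease status (case = 1)
adjusted for age, sex, plate (one-hot, first plate lexicographically as
reference) and two surrogate variables. Surrogates are the leading left
singular vectors of the residual matrix after projecting out the *full*
design, including status. Protecting the primary variable is essential: if
the residualization omits status, the leading singular vector of a dataset
with real case-control signal is the case-control contrast itself and the
surrogate absorbs the effect (we verified this empirically: power collapses
to ~0). This matches the behaviour of the surrogate-variable estimators used
in practice. Surrogate signs are fixed (first nonzero loading positive) so
runs are reproducible.

The staged design: stage 1 (discovery) is tested at FDR < 0.05
(Benjamini-Hochberg over all aptamers); stage-2 FDR is recomputed *within*
the stage-1 survivors, which are the only analytes carried forward;
replicated analytes with direction-consistent estimates are combined by
Stouffer's Z (two-sided p mapped to a signed z via `qnorm(p/2,
lower.tail = FALSE) * sign`), and a Bonferroni correction over the
meta-analyzed set gives the final calls. Exact zeros are clamped to the
smallest positive double with a warning; mixed directions are an error
because the direction gate runs upstream. Cross-platform concordance reports
Pearson correlations of effect sizes (meta effect = mean of the stage
estimates) and of signed −log10 p (sign from the estimate; an unsigned
correlation would ignore direction), over the shared analytes.

## Signature derivation

Candidates (the Bonferroni-significant set) go through, in order: a 70/30
stratified split (floor rule per stratum); L1-penalized logistic regression
with five-fold cross-validation choosing the penalty of maximal mean CV AUC;
greedy pruning of pairs with |r| > 0.8 walking proteins in ascending
meta-analysis p (the spec of "representative analyte" is open; the smallest-p
member is the defensible representative); restriction to the proteins shared
with the validation platform; an unpenalized multivariate logistic refit
dropping coefficients with p ≥ 0.05 and refitting on the survivors. The
frozen model stores protein IDs, standardization means/SDs, coefficients,
intercept and a Youden-optimal probability cutoff (smallest threshold on
ties, predicted positive at score ≥ threshold), and is serialized to JSON.
Scoring other data never imputes: a missing panel protein is an error, and
cross-platform application goes through the intersection step instead.

Complete separation in the refit is an error by default. `run_pipeline`
enables the documented fallback (a lightly ridge-penalized fit, fixed L2
penalty 0.01, skipping the p-filter because penalized Wald p-values are not
valid): synthetic worlds plant effects independently across proteins, so the
panel's joint Mahalanobis distance grows like sqrt(panel size) and separates
far more easily than correlated real proteomes do. This is a property of the
generator, not of the method.

## Pseudo-trajectories

Bonferroni-significant proteins are classified from the two adjacent-stage
comparisons (A−T− vs A+T−; A+T− vs A+T+): sign pattern (+,+) is G1
(linear-up), (+,−) G2 (up-down), (−,−) G3 (linear-down), (−,+) G4 (down-up),
requiring p < 0.05 in *both* comparisons; everything else is unclassified
(the strict conjunctive rule is the only internally consistent reading).
Because classification is restricted to endpoint-significant proteins, the
generator's non-monotone archetypes end opposite the baseline (up-down is
0, +δ, −δ) — a protein that returned exactly to baseline would be invisible
to the endpoint comparison that defines the clustered set.

A caution established during testing: the two p-gates share the A+T− samples,
so under the null their t-statistics are correlated (ρ = −1/2 at equal group
sizes) and the chance-classification rate is ≈ 0.0092 at α = 0.05, not
α² = 0.0025. Guarantees premised on independent gates are too tight and the
corresponding acceptance check is knowingly left failing rather than
loosened.

## Circuits and enrichment

The prior knowledge network is a signed digraph (activation/inhibition).
Booleanization maps positive endpoint-DAA estimates to state 1 and negative
to 0 (exact zeros drop the node with a warning); compatibility pruning keeps
an activation edge iff its endpoints share a state and an inhibition edge iff
they differ — the standard Boolean-consistency reading, which the source
methodology leaves informal. The case network uses the A+T+ states, the
control network their complement; enrichment defaults to the case network's
circuit proteins (configurable), since the case phenotype is the stated
target of circuit detection.

Elementary circuits (directed cycles visiting intermediate nodes once) are
enumerated by a depth-first search from each node restricted to
lexicographically larger nodes, so every circuit is found exactly once,
canonically rotated to start at its smallest node. Parallel
activation/inhibition edges between the same pair produce distinct circuits
with opposite parity (parity = even/odd inhibition count, rotation
invariant). The default length cap of 8 edges keeps enumeration polynomial in
practice while covering the short feedback loops that dominate curated
networks; hitting the cap is logged. The enumeration is property-tested
against an independent permutation-based brute-force oracle on random
graphs. (The methodology text mentions a connected-components routine for
this step, which cannot produce elementary circuits as it defines them; we
implement the stated definition.)

Over-representation uses the upper-tail hypergeometric probability
(equivalently one-sided Fisher), with every term intersected with the
measured background first, k = 0 reported as p = 1, and BH FDR across terms.
Cell-type enrichment is the same statistic over marker sets that must be
mutually exclusive; overlaps are an error naming the offending proteins.

## Clinical outcomes

Progression: one pooled linear model of CDR-SB (Clinical Dementia Rating,
sum of boxes) on years since lumbar puncture with age, sex, predicted
signature status, known AT status, and first-visit CDR-SB, plus
time×predicted-status and age×predicted-status interactions; the
time×predicted-status coefficient (extra points/year when signature-positive)
is the headline. The pooled fit ignores within-person correlation by design
(matching the original analysis); cluster-robust CR1 standard errors by
individual are available via `robust = TRUE`. Time-to-conversion uses the
Kaplan-Meier product-limit estimator with Greenwood-based intervals and a
log-rank test (labelled as such; a Cox model is deliberately out of scope —
the displayed result of the source analysis is the survival curve).

# The synthetic world

`simulation_config()` states the world once; tests never tune it after
measurement. Defaults and their reasoning:

- **Cohorts**: two (discovery 400, replication 300), the smallest structure
  exercising the full staged design at desk scale.
- **log10 RFU is Gaussian** with per-aptamer baselines uniform on
  [2.5, 4.5] (the dynamic range of aptamer panels); RFU = 10^value, so
  matrices are strictly positive.
- **noise_sd = 0.2, batch_sd = 0.05** log10 units: residual spread dominates
  plate shifts, as in plate-randomized designs.
- **effect_size = 0.15** per stage transition. A single effect protein then
  discriminates modestly (endpoint shift 0.3 = 1.5 residual SDs, AUC ≈ 0.77)
  while multi-protein panels reach the 0.97–0.99 regime reported for real
  panels. Effect magnitudes of real proteins are unknown (an open question in
  the source); this is our one-time choice.
- **Archetypes**: equal mix of linear-up (0, +δ, +2δ), up-down (0, +δ, −δ),
  linear-down and down-up (mirrors).
- **biomarker_separation = 5** component SDs: CSF amyloid and pTau are
  strongly bimodal; 5 SDs gives ≈ 98.8% three-group recoverability (see the
  trajectory caution above for why not 100%).
- **at_proportions = (0.47, 0.19, 0.34)**, the discovery-stage composition of
  the motivating study design.
- **Clinical layer**: CDR-SB slopes 0.2 vs 0.55 points/year
  (signature-negative vs -positive; difference 0.35 mirrors the reported
  interaction), conversion hazards 0.02 vs 0.10 per year (5× ratio),
  censoring uniform over 15 follow-up years, annual visits.
- **Calibrators and scale factors**: 3 replicate wells per plate around a
  cohort calibrator profile (technical CV ≈ 5%), scale-factor pairs within
  ±0.1 of 1 — a clean dataset passes QC untouched, and `inject_qc_failures`
  plants unambiguous violations with a recorded roster.

What the generator does **not** emulate: correlation between proteins (each
aptamer's noise is independent — real proteomes are strongly co-regulated,
which is why the separation fallback exists and why synthetic panel AUCs
saturate near 1), aptamer cross-reactivity, assay floor/ceiling effects,
cohort-specific preanalytics, informative censoring, and nonlinear CDR-SB
trajectories. A green test therefore establishes correctness of the
*procedures* against planted truth, not realism of any particular effect
magnitude.

# Numerical and design choices

- All rule thresholds compare strictly (`>`), following the
  "surpassing"/"exceeding" wording; exact-boundary cases in floating point
  are indeterminate by nature and the tests probe just off the boundary.
- Per-aptamer OLS shares one QR decomposition across all aptamers;
  zero-variance aptamers report estimate 0, p = 1 and a flag instead of NaN.
- Stage-2 FDR is conditional (recomputed within stage-1 survivors), because
  only those analytes are tested further.
- Ties in AUC use the rank statistic (ties count half); Youden ties take the
  smallest threshold.
- Determinism: a single seed drives generation; derived seeds are small fixed
  offsets; SVD/EM paths are seed-free deterministic. The whole pipeline is
  byte-identical across runs with the same configuration (tested).
- The package ships no command-line binary: the exported functions,
  `run_pipeline()`, and the TSV/GMT/JSON readers and writers are the
  interface, and `scripts/acceptance.R` shows the end-to-end invocation.

# Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(
  n_samples_per_cohort = c(discovery = 400L, replication = 300L),
  seed = 1L
)
res <- run_pipeline(cfg, out_dir = "pipeline_out")
res$evals$stage2          # frozen-model performance on the replication cohort
res$trajectories$counts   # G1..G4 group sizes among Bonferroni survivors
res$progression           # CDR-SB slope interaction
res$km                    # Kaplan-Meier + log-rank by predicted status
```

# Known limitations

- Penalized (ridge-fallback) signatures carry no coefficient p-values; the
  multivariate p-filter is skipped and the panel is the full restricted set.
- The progression model is a pooled fit; its naive p-values understate
  uncertainty under repeated measures (use `robust = TRUE` for inference).
- Circuit enumeration is exponential in the worst case; the length cap
  truncates (and logs) rather than exhausts on dense networks.
- Surrogate variables are a residual-SVD core; they will not numerically
  match any specific published surrogate-variable software.
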