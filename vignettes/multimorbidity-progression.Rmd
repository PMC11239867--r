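---
title: "Mapping multimorbidity progression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping multimorbidity progression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbidmap)
```

# The problem

Multimorbidity — the co-occurrence of two or more long-term conditions — is
usually described by clustering diseases that are frequently diagnosed
together. Association-based clusters are dominated by prevalent diagnoses and
cannot distinguish "A leads to B" from "A and B share causes", nor can they
represent bi-directional trajectories. `morbidmap` instead maps progression
from estimated *directional causal effects*: for every ordered disease pair
(a, b), the change in the risk of developing b caused by having a, adjusted
for measured confounders. Everything downstream — rankings, effect-profile
clusters, chapter-level flows, and progression constellations — is built on
this pairwise effect matrix.

# The estimand and the TMLE estimator

For a pair (a, b), participants free of b at baseline form the analysis set.
With exposure A (having disease a), binary outcome Y (incident b during the
outcome window), and baseline covariates W (sociodemographic and behavioural
covariates plus baseline indicators of every other study disease), the target
is the average treatment effect on the risk-difference scale,

$$\psi = E_W\left[\,E[Y \mid A = 1, W] - E[Y \mid A = 0, W]\,\right].$$

The estimator is targeted maximum likelihood estimation (TMLE):

1. fit an initial outcome regression $\bar Q(A, W)$ and a propensity score
   $g(W) = P(A = 1 \mid W)$ (main-terms logistic regressions by default; any
   probabilistic classifier can be plugged in through the learner interface);
2. fluctuate $\bar Q$ along the clever covariate
   $H(A, W) = A/g(W) - (1-A)/(1-g(W))$ by a one-parameter logistic regression
   of Y on H with offset $\mathrm{logit}\,\bar Q(A, W)$;
3. report the plug-in contrast of the fluctuated fit,
   $\psi = \tfrac1n\sum_i [\bar Q^*(1, W_i) - \bar Q^*(0, W_i)]$.

The fluctuation makes the empirical mean of the efficient influence curve
$IC_i = H(A_i, W_i)(Y_i - \bar Q^*(A_i, W_i)) + \bar Q^*(1, W_i) - \bar
Q^*(0, W_i) - \psi$ exactly zero, which gives TMLE its double robustness
( consistency when either $\bar Q$ or $g$ is correctly specified) and its
standard error $\widehat{se} = sd(IC)/\sqrt n$. Pairs are classed
`increasing` when the 95% CI lies above zero, `decreasing` when below, `null`
otherwise; no multiplicity correction is applied by default (a
Benjamini–Hochberg option exists) because the raw CI classification is what
the downstream network stages consume.

## Exposure designs and their trade-offs

The risk-set construction for "having disease a before b" is genuinely open,
so both defensible designs are implemented and the choice is an explicit
argument:

* **ever-before** (default): A = 1 when a's onset strictly precedes both b's
  onset and the end of follow-up. This matches how onset intervals are
  measured, but conditions on post-baseline information, so it carries
  immortal-time and collider risk; the point-treatment TMLE with
  baseline-only covariates is not strictly valid for it. We keep it as the
  default because it uses all exposure information, and we document rather
  than silently correct its bias.
* **landmark**: A = 1 when a is prevalent at baseline. This is the design
  under which the point-treatment estimand is cleanly defined, and it is the
  design used by all validation runs against the simulator's do-intervention
  oracle, and the default of the end-to-end pipeline: on synthetic cohorts
  the ever-before estimator is dominated by its selection bias (it calls
  large numbers of truly-null pairs "decreasing"), while landmark estimates
  track the oracle. Its cost is a smaller exposed group (only
  baseline-prevalent carriers), which makes positivity the binding
  constraint for rare diseases.

Same-day onsets of a and b are treated as "a does not precede b", so
simultaneous coding is never counted as exposure.

## Positivity policy

Positivity is handled by an explicit, auditable policy rather than
case-by-case judgement: propensity values are truncated to [0.01, 0.99]
(configurable) with the clipped fraction reported per pair, and pairs with
fewer than 10 exposed or 10 unexposed participants are skipped with a recorded
reason. Validation shows the residual cost of this policy: for exposures
whose baseline prevalence is well below 1%, influence-curve CIs undercover
(the IC variance understates the extrapolation uncertainty of ~100-exposed
contrasts), which pulls overall CI coverage on hard synthetic cohorts to just
below the nominal band while estimates remain within 3 SEs of the truth for
over 95% of pairs. The per-pair `clipped_frac` diagnostic identifies exactly
these pairs.

## One-year sensitivity

To measure how quickly effects act, the full pipeline can be re-run with the
outcome window limited to 365 days from time zero (a's onset for the exposed,
baseline for the unexposed — the unexposed have no onset to anchor on, which
is the one open choice in this analysis). The per-disease fraction of pairs
whose one-year effect magnitude exceeds the full-window magnitude summarizes
rapidity.

# The synthetic cohort generator

Because the motivating cohort data are access-restricted, the package ships a
generator whose defaults define the validation conditions, together with a
Monte-Carlo oracle for the true effects.

* **Model.** Discrete-time hazards on a 91-day (quarterly) grid: at each
  step, each not-yet-onset disease d onsets with probability
  $\mathrm{expit}(\alpha_d + \beta_d^\top L_i + \sum_{d'\ \mathrm{onset}}
  \gamma_{d'd})$. The covariates $L_i$ (4 standard normals by default) load on
  all diseases (measured confounding, loading SD 0.3 on the log-odds scale);
  $\gamma$ is the planted sparse effect graph. A hidden-covariate switch
  drops one covariate from the emitted table while it keeps driving onsets,
  for studying unmeasured confounding.
* **Calibration.** $\alpha_d$ solves, by root-finding over the realized
  covariate sample, for the target marginal ever-diagnosed prevalence under
  $\gamma = 0$; defaults span 2–20%, mirroring a prevalence-filtered disease
  panel.
* **Timing.** Follow-up defaults to 12.7 years; a 5-year pre-baseline
  burn-in generates baseline-prevalent diagnoses (onset day ≤ 0). Quarterly
  steps keep desk-scale runs fast while resolving the <1 / 1–5 / >5-year
  interval bands. Sex is a stratum label; each stratum is generated by its
  own run.
* **Oracle.** `true_effect_profile()` simulates paired counterfactual arms —
  do(a onsets at baseline) vs do(a never onsets) — with common random
  numbers, suppressing a's natural onsets in both arms so burn-in histories
  coincide; the effect on each b is the difference in cumulative incidence
  among participants b-free at baseline. Because the oracle overrides the
  exposure mechanism, confounder loadings on the exposure cannot move it
  (verified exactly in the tests); loadings on the *outcome* legitimately
  change the marginal risk difference through the nonlinearity of the
  hazards, so "the" true effect is always defined relative to a full
  generator configuration.

What the generator does *not* emulate: competing risks and death,
time-varying covariates, diagnosis-code noise, and calendar-time effects.
Passing validation on it demonstrates estimator correctness under confounded
sparse-graph dynamics, not robustness to those additional real-data features.

# Effect-spectrum summaries

A disease's row of the effect matrix is its *consequential spectrum ray*
(how it affects all others); its column is its *causal spectrum ring* (how
all others affect it). Rankings of influential / influenced / preventive /
prevented diseases use the proportion of a disease's non-skipped pairs that
are significant beyond an effect-size threshold of 0.01 absolute risk
difference — the single strong-effect convention reused by every network
stage, and configurable everywhere. Ties break by
mean |effect|, then code order. Onset intervals per significant increasing
pair use the lower median (determinism under even counts) of the day gaps
among participants diagnosed with both diseases in order, expressed in years
(365.25 days), excluding pairs with fewer than 5 qualifying participants.

# Ray/ring clustering with AU support

Rays (and rings) form a D × (D−1) signed-effect profile matrix with null and
skipped cells imputed to 0, clustered by Ward linkage on Euclidean distances
(`hclust`, `ward.D2`). Cluster support uses the multiscale bootstrap: at each
scale r in {0.5, …, 1.4}, resample round(r·m) profile columns with
replacement, recluster, and record per dendrogram edge the fraction of
replicates containing the same leaf set (BP\_r). The approximately unbiased
p-value fits $z_r = \Phi^{-1}(1 - BP_r) = v\sqrt r + c/\sqrt r$ by weighted
least squares (weights $B\,\phi(z_r)^2 / (BP_r(1 - BP_r))$) and reports
$AU = 1 - \Phi(v - c)$. Boundary BP values are clamped to
$[1/(2B),\,1 - 1/(2B)]$ before the probit transform; if every BP is exactly
0 or 1 the AU is set to that constant and flagged. Trees can be cut at a
fixed k or into the maximal (root-excluded) clades with AU above a threshold
(default 0.87); uncovered leaves become flagged singletons with AU 1 by
convention. The dissimilarity metric, replicate count and cutting rule are
all configuration because no single convention is canonical here.

# Chapter flows and the permutation null

Unordered pairs with both directions significant and above the 0.01
threshold are *bi-directional* progression; exactly one qualifying direction
is *uni-directional*. Flows aggregate into 16-chapter tables (uni counts
directed, bi counts once per pair) using the standard ICD-10 chapter ranges
(the metabolic chapter is E00–E90). Enrichment of a chapter pair is tested
against a null that permutes the disease-to-chapter assignment while
preserving chapter sizes and the entire edge structure — this isolates
chapter-level organization from the graph's degree structure, which is held
fixed. One-sided p-values use the add-one rule, $p = (1 + \#\{null \ge
obs\})/(B + 1)$, so the minimum attainable p at the default B = 10,000 is
1/10,001 ≈ 0.0001.

# Constellations

The progression graph keeps increasing effects above the threshold as
directed weighted edges. For clustering, weights are symmetrized by the
maximum of the two directions, dissimilarity is the shortest-path length
with edge length 1/weight, and the affinity uses local scaling,
$a_{ij} = \exp(-d_{ij}^2/(\sigma_i\sigma_j))$ with $\sigma_i$ the distance
to the 7th nearest neighbour — the construction that makes "self-tuning"
k-means well-defined while leaving "self-tuning spectral clustering" (with
rotation-based k selection) available as an independent comparator. Nodes
are embedded by the top eigenvectors of the normalized affinity, k is chosen
per connected component by the largest eigengap (components are clustered
independently and the condition is flagged), and k-means with multiple
restarts under a fixed seed produces the partition. Hubs maximize
within-constellation weighted strength (quality and quantity of links); ties
break by degree then code. The rotation-based selector caps candidate k well
below the component size because a full eigenbasis is orthogonal and hence
trivially axis-alignable, which would make the alignment cost uninformative.

Layouts minimize the Kamada-Kawai spring energy
$E = \sum_{i<j} k_{ij}(\lVert p_i - p_j\rVert - l_{ij})^2/2$ with ideal
lengths $l_{ij}$ = shortest-path distances and $k_{ij} = 1/l_{ij}^2$, by
node-wise 2×2 Newton updates with step halving, starting from a
deterministic circle; accepted steps never increase the energy, and
disconnected graphs are laid out per component on a grid.

Stability compares the reference partition, via the adjusted Rand index
(computed from the contingency-table formula), against k-means
reinitializations on the same embedding, the rotation-selected spectral
alternative, and a cross-method set (Ward on the dissimilarity, Louvain on
the affinity graph).

# Numerical choices and degenerate inputs

* Logistic nuisance fits fall back to ridge-penalized regression
  (λ = 10⁻³) under separation or singularity; constant outcomes short-circuit
  to the empirical mean.
* Fluctuation non-convergence, empty eligibility sets and constant exposures
  all produce recorded `skipped` results rather than errors, so an all-pairs
  run always returns D(D−1) rows.
* The pipeline derives every stage seed from one master seed by fixed
  offsets (`master * 1000 + stage`), and its manifest records seeds and MD5
  digests of every output, making reruns byte-identical and resumable.

# Problem sizes used in validation

The shipped validation suite exercises: three confounded cohorts with D = 10
diseases and n = 20,000 participants (270 directional pairs against a
Monte-Carlo oracle at 50,000 counterfactual pairs each); a global-null cohort
at n = 10,000; 200 random graphs for permutation-null uniformity; 20 planted
4-block, 40-node progression graphs; and an end-to-end demo at D = 12,
n = 5,000. These sizes were chosen so a complete validation runs on a single
desktop core in well under half an hour while keeping Monte-Carlo error a
small fraction of the estimator standard errors.

# Known limitations

* The ever-before design's immortal-time bias is documented, not corrected;
  longitudinal (time-varying treatment) TMLE is out of scope.
* CI coverage degrades for exposures with baseline prevalence well below 1%
  under the landmark design (see the positivity section), and the same
  pairs produce a mild excess of false-positive classifications under a
  global null; the `clipped_frac` diagnostic flags affected pairs.
* The D × (D−1) profile rows drop each disease's own column, so profile
  columns are not a common coordinate system across rows; with D in the
  hundreds the one-column shift is immaterial, at very small D it is not.
* Cluster counts from AU-threshold cutting depend on the bootstrap replicate
  count through BP resolution; B ≥ 500 is recommended before interpreting
  cluster counts.
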