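# morbidmap

Mapping multimorbidity progression from longitudinal diagnosis records.

`morbidmap` is for epidemiologists and biostatisticians who want to go beyond
co-occurrence clustering of chronic disease: it estimates, for every ordered
pair of diseases (a, b) in a cohort, the *directional* effect of having a on
the subsequent development of b, and then assembles those effects into the
progression structures that matter clinically — which diseases drive
multimorbidity, which are driven, how progression flows between ICD-10
chapters, and which groups of diseases form tightly connected progression
constellations.

## The statistical core

For each ordered pair, among participants free of b at baseline, the package
estimates the average treatment effect on the risk-difference scale

ψ = E_W[ E(Y | A = 1, W) − E(Y | A = 0, W) ],

with A = exposure to disease a, Y = incident b during the outcome window, and
W = baseline covariates plus baseline indicators of all other study diseases.
The estimator is targeted maximum likelihood estimation (TMLE): initial
logistic fits of the outcome regression Q̄(A, W) and propensity g(W) are
fluctuated along the clever covariate H(A, W) = A/g − (1−A)/(1−g), which
makes the estimator doubly robust and gives influence-curve standard errors,
SE = sd(IC)/√n. Each pair is classed increasing / decreasing / null by its
95% CI. Downstream stages:

* **Rankings** of influential / influenced / preventive / prevented diseases
  (proportion of a disease's pairs significant beyond an effect threshold of
  0.01), plus onset-interval timing bands (<1, 1–5, >5 years).
* **Ray/ring clustering**: Ward clustering of each disease's effect profile,
  with multiscale-bootstrap approximately-unbiased (AU) cluster support,
  AU = 1 − Φ(v − c) from the weighted fit z_r = v√r + c/√r.
* **Chapter flows**: bi-/uni-directional progression between the 16 ICD-10
  chapters, tested against a size-preserving permutation of the
  disease-to-chapter assignment, p = (1 + #{null ≥ obs})/(B + 1).
* **Constellations**: self-tuning (locally scaled) spectral clustering of
  the thresholded progression graph, hub diseases by within-constellation
  weighted strength, Kamada-Kawai layout, and adjusted-Rand-index stability.
* **Synthetic cohorts**: a discrete-time hazard simulator with a planted
  effect graph and a Monte-Carlo do-intervention oracle, so every stage is
  validated against known ground truth without access-restricted data.

## A worked example

```r
library(morbidmap)

cfg    <- sim_config(n = 8000, D = 8, seed = 3,
                     target_prevalence = seq(0.05, 0.25, length.out = 8))
gamma  <- make_planted_graph(8, density = 0.2, seed = 9)
cohort <- simulate_cohort(cfg, gamma)

diseases <- prevalence_filter(cohort$diag, cohort$cov, threshold = 0.01)
em <- run_all_pairs(cohort$diag, cohort$cov, diseases, design = "landmark",
                    onset = cohort$onset_day,
                    follow_up_end = cohort$follow_up_end)
head(as.data.frame(em)[c("a", "b", "psi", "se", "ci_low", "ci_high", "class")], 5)
#>     a   b      psi     se  ci_low ci_high      class
#> 1 A10 C10  0.01733 0.0253 -0.0322  0.0668       null
#> 2 A10 D10 -0.01930 0.0207 -0.0599  0.0213       null
#> 3 A10 E10  0.07629 0.0350  0.0076  0.1450 increasing
#> 4 A10 F10  0.01538 0.0314 -0.0461  0.0768       null
#> 5 A10 G10  0.00306 0.0327 -0.0610  0.0671       null
```

Row 3 reads: having disease A10 raises the absolute risk of developing E10
during follow-up by about 7.6 percentage points (95% CI 0.8–14.5), so the
pair is classed `increasing`. Summaries and network stages:

```r
classify_counts(em)
#> increasing 4 (7.1%), decreasing 4 (7.1%), null 48, skipped 0

head(rank_influential(em), 3)
#>   disease proportion mean_abs_effect rank
#> 1     A10      0.143          0.0325    1
#> 2     D10      0.143          0.0319    2
#> 3     F10      0.143          0.0243    3

pg <- build_progress_graph(em)        # edges: increasing pairs with psi > 0.01
cs <- self_tuning_cluster(pg, seed = 1)
identify_hubs(pg, cs)
#>   constellation hub chapter strength size
#> 1             1 E10 E00-E90   0.1409    3
#> 2             2 C10 C00-D48   0.0909    3

stability_report(pg, cs, n_seeds = 20, seed = 1)$mean_ari
#> [1] 1
```

Here the thresholded progression graph splits into two constellations of
three diseases; the hub of each is the member with the largest total edge
weight to the others, and the partition is perfectly stable (mean ARI = 1)
across k-means reinitializations and alternative clustering methods.

The whole framework — simulate, estimate, spectrum, cluster rays/rings,
chapter flows, constellations, stability — runs end to end with

```r
run_pipeline(pipeline_config(out_dir = "demo", sex = "female",
                             n = 5000, D = 12, seed = 7))
```

which writes per-stage CSV/JSON outputs and a manifest with seeds and MD5
digests under `demo/female/`.

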