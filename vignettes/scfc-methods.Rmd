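---
title: "Node-level structural-functional coupling: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Node-level structural-functional coupling: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfcoupling)
```

## The question the package addresses

Structural connectivity (SC, white-matter streamline counts between brain
regions) and functional connectivity (FC, correlated BOLD fluctuations) are
related but not interchangeable descriptions of the same network.  How
tightly function tracks structure varies across the brain, and diseases that
reorganise brain networks — temporal lobe epilepsy being the motivating
example — appear to weaken that correspondence preferentially in regions
where it is normally strongest.  `scfcoupling` implements a node-level
analysis of this correspondence:

1. **FC construction.** From a T × N region-level BOLD matrix, the N × N
   Pearson correlation matrix is computed, Fisher-Z transformed
   (`atanh`, variance-stabilising), and proportionally thresholded so that
   only the strongest 10% of the N(N−1)/2 unique edges survive.  Equal
   density across subjects removes a gross confound from between-subject
   comparisons.
2. **Regional coupling.** For every node *i*, the coupling is the
   tie-corrected Spearman rank correlation between row *i* of the SC matrix
   and row *i* of the FC matrix over the N−1 off-diagonal entries; the
   self-connection is always excluded.  A rank statistic is the right choice
   because streamline counts are heavy-tailed and zero-inflated, and because
   it is invariant to any monotone rescaling of either modality.
3. **Node clustering.** Whole-brain nodes are partitioned by k-means on
   their coupling profiles across healthy-control (HC) subjects, with the
   number of clusters chosen by an explicit elbow rule, and clusters
   relabelled so that mean coupling increases with the cluster index.
   Patients are assigned to the HC-derived clusters; clusters are never
   refit per group.
4. **Cluster indices.** ASFC (cluster-averaged coupling: the mean of member
   nodes' coupling) and CSFC (within-cluster coupling: the Spearman
   correlation between the SC and FC values of all edges internal to the
   cluster).
5. **Statistics.** Omnibus three-group tests (ANOVA/ANCOVA with sex,
   education and age as covariates), permutation-based pairwise contrasts,
   a post-hoc battery with Benjamini–Hochberg correction, and partial
   correlations between node coupling and clinical variables (seizure
   duration) on covariate residuals.

## The synthetic cohort generator

No patient imaging data are distributed, so every downstream stage is
validated against a generator with planted ground truth
(`sim_config()` / `generate_cohort()`).  The defaults are the study
conditions the package is tested under: 246 nodes in 8 functional networks
(seven canonical resting-state networks plus a subcortical network), five
coupling strata of sizes 27/71/55/64/29 with HC target couplings 0.103,
0.150, 0.176, 0.201, 0.247; groups of 48 controls, 34 left-sided and 31
right-sided patients; SC density 10.2%; and patient decoupling planted in
strata 3–5 (defaults per group: left 0.013/0.010/0.019, right
0.011/0.011/0.028).

**Structural matrices** are uniformly random edge sets at the configured
density with log-normal integer weights (heavy-tailed, like streamline
counts).  A node left without edges is repaired by rewiring (or rejected,
per `isolated_policy`).

**Functional matrices with planted coupling.**  Because Spearman coupling
depends only on ranks, the generator mixes a rank-preserving transform of
SC with independent noise:

FC*ᵢⱼ* = *wᵢⱼ* · *gᵢⱼ* + (1 − *wᵢⱼ*) · *εᵢⱼ*,

where *g* is the normal-score transform of the SC entries (computed over
all unique pairs, so ties — the zero mass of a sparse SC — stay tied) and
*ε* is symmetric Gaussian noise with standard deviation `noise_sd`.  The
map from mixing weight to expected Spearman correlation has no closed form
under ties, so it is estimated once per configuration by Monte Carlo on
rows drawn from an actual generated SC (`mixing_curve()`), monotonised, and
inverted by interpolation; `calibrate_mixing()` exposes the same
calibration as a bisection for a single target.  Two design points matter:

* *Symmetry.* Entry (i, j) belongs to the profiles of both nodes, so
  per-node weights cannot be set independently.  The generator targets
  entry-level association (cᵢ + cⱼ)/2 with cᵢ = 2·tᵢ − mean(t); each row's
  average association then equals its own target tᵢ.  At 246 nodes and 48
  controls the planted stratum means are recovered to within about 0.003.
* *Calibration noise is shared.*  All entries read the same estimated
  curve, so the curve's Monte-Carlo error acts as a common bias, not
  independent noise.  The default of 500 calibration rows keeps that shared
  error near ±0.003; validation that asserts ±0.01 bands uses 1000 rows.

**Time-series mode** additionally emits a T × N Gaussian series whose
population correlation is a monotone (`tanh`) squashing of the generated
FC, repaired to positive-definiteness by eigenvalue clipping; the sample
Pearson matrix of the series then approximates the target, and rank-based
quantities are preserved.  Matrix mode is the default for speed.

**Clinical correlations.**  Designated top-stratum nodes (two negative, one
positive by default) have their per-patient targets shifted by
`beta` · sign · standardised seizure duration, planting recoverable
coupling–duration correlations.  Demographics are drawn group-matched
(age ≈ 30 ± 9 y, education ≈ 11 ± 3 y, similar sex ratios); a
`confound_age_shift` switch exists to exercise covariate adjustment.

**What the generator does not emulate:** spatial autocorrelation of real
parcellations, distance-dependent connection probability, scanner/motion
artefacts, tractography biases (gyral bias, crossing fibres), or
network-structured FC beyond what the SC mixing induces.  Passing tests
demonstrate that the statistical machinery recovers planted effects of
realistic size — not that real data meet the generator's assumptions.

## Irreducible coupling noise and what "low noise" means

The sampling error of a Spearman coefficient over N − 1 = 245 row entries
is ≈ 0.06 regardless of `noise_sd` (the mixing noise changes the *target*
a weight achieves, not the estimator's variance).  Averaged over 48
controls the per-node noise in mean-coupling space is ≈ 0.009.  Against the
default stratum targets — whose middle gaps are only ≈ 0.026 — the
within-cluster-sum-of-distances curve bends almost equally at k = 4 and
k = 5: in the zero-noise limit the chord-distance rule separates the two by
less than 0.01 normalised units.  The cluster-number recovery validation
therefore uses strata spread evenly over the generator's controllable
coupling range (targets 0.05–0.45), where the elbow selects k = 5
essentially always.  With the closely spaced default targets, a fixed
k = 5 (`cluster_nodes(..., k = 5)`) reproduces the intended partition with
over 90% node agreement even though the elbow rule alone may prefer k = 4.

## Numerical and procedural choices

* **Thresholding** keeps the `ceiling(s·E)` largest edges by signed value
  (strongest positive correlations); `mode = "absolute"` ranks by
  magnitude.  Ties at the cutoff are broken by stable node order and
  reported.  The Fisher-Z transform precedes thresholding; both orders are
  defensible and the operations are exposed separately.
* **Coupling** uses all N − 1 off-diagonal entries, including zeros of
  either matrix; `sc_nonzero_only = TRUE` restricts to structurally
  connected pairs for sensitivity analysis.  Degenerate (constant) rows
  yield `NA`, are excluded pairwise from ASFC means, and are mean-imputed
  (with a warning) for clustering only.
* **k-means** runs 50 restarts per candidate k under a fixed seed
  (Hartigan–Wong, Euclidean); empty-cluster failures are retried up to 10
  times.  Features are per-HC-subject coupling vectors by default
  (`features = "subject"`); `"mean"` uses the scalar HC mean, which is
  faster and effectively equivalent for well-separated strata.  Features
  are not standardised by default (both embeddings are in coupling units).
* **Elbow rule**: normalise the (k, WSS) curve to the unit square and pick
  the k at maximal perpendicular distance below the endpoint chord —
  deterministic, affine-invariant, and exactly the informal
  "where the decrease flattens" criterion made operational.  Non-monotone
  curves (possible under restarts) are repaired by running minimum; a
  near-straight curve is flagged `no_clear_elbow`.
* **"Nonparametric t-test"** is implemented as a seeded permutation test of
  the group-mean difference (9,999 permutations by default), with
  Wilcoxon rank-sum as an alternative; covariate-adjusted contrasts
  permute covariate residuals.  Permutation p-values use the add-one
  estimator (1 + #extreme)/(B + 1).
* **Partial correlation** residualises both variables on the covariates by
  OLS and correlates the residuals with Spearman (consistent with the
  coupling statistic); Pearson is available, under which a covariate equal
  to the clinical variable gives an exactly zero partial correlation.
* **Multiplicity**: Benjamini–Hochberg across the reported family by
  default; `correct = "none"` mimics analyses that report uncorrected
  p-values.
* **Covariate coding**: sex as a binary indicator, continuous covariates
  mean-centred.

## A selection effect worth knowing about

Fitting clusters on the controls and then comparing controls with patients
*within the top cluster* is circular in a specific, quantifiable way: the
top cluster collects nodes whose HC coupling is high partly by sampling
noise, so the HC group mean in that cluster is biased upward relative to
groups that did not participate in the selection.  On null cohorts
(no planted decoupling) with few nodes this inflates the type-I error of
HC-versus-patient contrasts several-fold, while patient-versus-patient
contrasts stay calibrated.  The package's statistical calibration tests
therefore evaluate the group machinery on the planted strata; analyses of
real data with this design should interpret control-versus-patient
contrasts in selected clusters with that bias in mind (split-half selection
or permutation of the whole pipeline would remove it).

## Validation scale

The shipped validation uses problem sizes chosen to exercise the exact
study conditions where they are cheap (246 nodes, 48 controls for
calibration recovery; 100 replicate cohorts for cluster-number recovery)
and reduced node counts for replicate-heavy calibration checks (500 null
cohorts at 30 nodes; 200 decoupling cohorts at 100 nodes with the planted
per-group reductions equalised, matching the study's finding of no
left-right difference).  All stochastic validation is seeded and
reproducible.

## Known limitations

* The generator plants stratum-constant coupling; real coupling varies
  continuously, so planted-partition recovery is an upper bound on what
  clustering achieves in practice.
* CSFC is computed per subject and cluster from all within-cluster pairs;
  clusters smaller than 3 nodes have too few edges and return `NA`.
* The pipeline is single-machine and in-memory; a 246-node, 113-subject
  cohort occupies well under 1 GB.
* Volume discarding is the only time-series preprocessing step included;
  slice-timing, motion, normalisation and nuisance regression are assumed
  to have produced the region-level series upstream.
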