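# scfcoupling

Node-level **structural–functional connectome coupling** analysis for brain
networks, with a synthetic cohort generator for end-to-end validation.

Structural connectivity (SC; streamline counts between the 246 regions of a
whole-brain parcellation) and functional connectivity (FC; Pearson
correlation of regional BOLD time series) describe the same network in
different currencies. How closely function tracks structure differs across
the brain, and network diseases such as temporal lobe epilepsy appear to
weaken the correspondence preferentially where it is normally strongest.
This package implements that analysis for region-level inputs:

* **FC construction** — Pearson correlation of regional time series,
  Fisher-Z transform, proportional sparsity thresholding (default: keep the
  top 10% of edges): `fc_from_timeseries()`, `fisher_z()`,
  `proportional_threshold()`, `discard_initial_volumes()`.
* **Regional coupling** — for each node *i*, the tie-corrected Spearman
  rank correlation ρᵢ = ρ(SCᵢ·, FCᵢ·) over the N−1 off-diagonal row
  entries (self-connection excluded): `regional_coupling()`,
  `cohort_coupling()`.
* **Node clustering** — k-means on coupling profiles across healthy
  controls, cluster count by an explicit elbow (chord-distance) rule,
  clusters relabelled in ascending mean coupling; patients are assigned to
  the control-derived clusters: `cluster_nodes()`, `select_k_elbow()`,
  `enrichment_table()`.
* **Cluster indices** — ASFC (mean member-node coupling per cluster) and
  CSFC (Spearman correlation between SC and FC over all within-cluster
  edges): `asfc()`, `csfc()`, `cluster_metrics_table()`.
* **Group statistics** — ANOVA/ANCOVA omnibus tests, seeded permutation
  pairwise contrasts with BH correction, and partial correlations of node
  coupling with clinical variables on covariate residuals:
  `omnibus_test()`, `pairwise_test()`, `posthoc_battery()`,
  `partial_correlation()`.
* **Synthetic cohorts** — paired SC/FC per subject with planted per-node
  coupling strata, planted patient decoupling, and planted
  coupling–duration correlations: `sim_config()`, `generate_cohort()`,
  `generate_sc()`, `generate_fc_with_target_coupling()`,
  `calibrate_mixing()`.
* **Pipeline** — one configured run from simulation (or TSV inputs) to the
  statistics tables, with a reproducible manifest: `run_pipeline()`; a thin
  CLI lives at `inst/cli/scfc.R`.

See `vignettes/scfc-methods.Rmd` for the models, parameter meanings and
design decisions.

## Worked example

Simulate the default cohort (48 controls, 34 + 31 patients, 246 nodes, five
coupling strata), compute coupling, cluster the nodes on controls, and test
the top cluster:

```r
library(scfcoupling)

cfg    <- sim_config(seed = 7)
cohort <- generate_cohort(cfg)
#> <scfc_cohort> 113 subjects (HC=48 LTLE=34 RTLE=31), 246 nodes, 5 strata

coupling <- cohort_coupling(cohort)
hc       <- coupling[cohort$table$group == "HC", ]
model    <- cluster_nodes(hc, k_range = 2:10, seed = 7,
                          features = "mean", k = 5)
#> <scfc_cluster_model> k = 5 (mean features), sizes: 27, 71, 53, 66, 29
round(model$cluster_mean_coupling, 3)
#> [1] 0.099 0.144 0.169 0.199 0.245

metrics <- cluster_metrics_table(cohort, model, coupling = coupling)
wide    <- cohort_stats_table(cohort$table, metrics)
omnibus_test(wide, "asfc_5", covariates = c("age", "sex", "education"))
#>       contrast statistic  p_value   method        n
#> 1 HC/LTLE/RTLE      54.8 4.13e-17 ancova_F 48/34/31

post <- posthoc_battery(wide, c("asfc_5", "csfc_5"), n_perm = 999, seed = 7)
post[, c("outcome", "contrast", "statistic", "p_value", "adjusted_p")]
#>   outcome     contrast statistic p_value adjusted_p
#> 1  asfc_5   LTLE vs HC   -0.0211   0.001     0.0015
#> 2  asfc_5   RTLE vs HC   -0.0258   0.001     0.0015
#> 3  asfc_5 RTLE vs LTLE   -0.0047   0.177     0.2124
#> 4  csfc_5   LTLE vs HC   -0.0378   0.001     0.0015
#> 5  csfc_5   RTLE vs HC   -0.0467   0.001     0.0015
#> 6  csfc_5 RTLE vs LTLE   -0.0090   0.383     0.3830
```

Reading the output: the recovered cluster mean couplings (0.099 … 0.245)
match the planted stratum targets (0.103 … 0.247) to within sampling error;
both patient groups show significantly reduced coupling in the
highest-coupling cluster relative to controls (the planted decoupling of
≈ 0.019–0.028), while the two patient groups do not differ from each other.

The same analysis as one configured run, with TSV outputs and a manifest:

```r
run_pipeline(list(simulate = list(), k = 5, seed = 7, out_dir = "run1"))
```

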