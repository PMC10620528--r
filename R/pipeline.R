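#' Run the full coupling pipeline
#'
#' Orchestrates the whole analysis as one configured run:
#' simulate (or load) a cohort, build functional connectivity from time
#' series where applicable (volume discard, Pearson correlation, Fisher-Z,
#' proportional threshold), compute per-node coupling, fit the node
#' clustering on healthy controls, derive per-subject cluster indices
#' (ASFC/CSFC), and run the group-contrast battery and clinical partial
#' correlations.  All stage outputs are written as labelled TSV files plus a
#' JSON manifest with the configuration and file hashes; a rerun with the
#' same configuration reproduces every stochastic output bitwise.
#'
#' @param config a named list (or path to a YAML file) with any of:
#'   \describe{
#'     \item{simulate}{list of [sim_config()] arguments (used when no
#'       `input_dir` is given).}
#'     \item{input_dir}{directory of cohort files in [write_cohort()]
#'       layout, used instead of simulation.}
#'     \item{n_discard}{initial volumes to drop in time-series mode
#'       (default 0).}
#'     \item{sparsity, threshold_mode}{proportional-threshold settings for
#'       FC built from time series (defaults 0.10, `"signed"`).}
#'     \item{sc_nonzero_only}{coupling restricted to SC-nonzero positions
#'       (default `FALSE`).}
#'     \item{k_range, k, features, standardize}{clustering controls
#'       (defaults `2:10`, elbow-selected k, `"subject"` features).}
#'     \item{control_group}{label of the control group (default first
#'       group present, `"HC"` when available).}
#'     \item{covariates}{covariate columns for adjusted statistics
#'       (default `c("age", "sex", "education")`).}
#'     \item{n_perm}{permutations for the pairwise contrasts (default
#'       9999).}
#'     \item{correct}{multiplicity correction, `"BH"` or `"none"`.}
#'     \item{seed}{master seed (default 1).}
#'     \item{out_dir}{output directory; if `NULL`, nothing is written.}
#'   }
#' @return (invisibly) a list with the cohort, coupling matrix, cluster
#'   model, metrics table, stats tables and the manifest.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    simulate = list(), input_dir = NULL, n_discard = 0,
    sparsity = 0.10, threshold_mode = "signed", sc_nonzero_only = FALSE,
    k_range = 2:10, k = NULL, features = "subject", standardize = FALSE,
    control_group = NULL, covariates = c("age", "sex", "education"),
    n_perm = 9999, correct = "BH", seed = 1, out_dir = NULL
  ), config, keep.null = TRUE)
  cfg$k_range <- parse_k_range(cfg$k_range)

  cohort <- run_stage("input", {
    if (!is.null(cfg$input_dir)) {
      read_cohort(cfg$input_dir)
    } else {
      sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$simulate)
      generate_cohort(do.call(sim_config, sim_args))
    }
  })
  subjects <- cohort$subjects
  table <- cohort$table

  # time-series subjects: rebuild FC through the standard chain
  subjects <- run_stage("build_fc", {
    lapply(subjects, function(sub) {
      if (!is.null(sub$ts)) {
        ts <- discard_initial_volumes(sub$ts, cfg$n_discard)
        fc <- proportional_threshold(fisher_z(fc_from_timeseries(ts)),
                                     sparsity = cfg$sparsity,
                                     mode = cfg$threshold_mode)
        sub$fc <- fc
      }
      sub
    })
  })
  cohort$subjects <- subjects

  coupling <- run_stage("coupling", {
    cohort_coupling(subjects, sc_nonzero_only = cfg$sc_nonzero_only)
  })

  control <- cfg$control_group %||%
    (if ("HC" %in% table$group) "HC" else table$group[1])
  hc_rows <- which(table$group == control)
  if (length(hc_rows) < 2) stop(sprintf("control group '%s' has < 2 subjects", control))

  model <- run_stage("clustering", {
    cluster_nodes(coupling[hc_rows, , drop = FALSE], k_range = cfg$k_range,
                  seed = cfg$seed, features = cfg$features,
                  standardize = cfg$standardize, k = cfg$k,
                  na_action = "impute_mean")
  })

  metrics <- run_stage("cluster_metrics", {
    cluster_metrics_table(subjects, model, coupling = coupling)
  })

  wide <- run_stage("stats_table", {
    cohort_stats_table(table, metrics)
  })

  groups <- unique(table$group)
  stats_out <- run_stage("group_stats", {
    outcomes <- c(sprintf("asfc_%d", seq_len(model$k)),
                  sprintf("csfc_%d", seq_len(model$k)))
    outcomes <- outcomes[outcomes %in% names(wide)]
    # an index must be defined for at least 3 subjects of every group to be
    # testable (CSFC can be missing for degenerate tiny clusters)
    testable <- vapply(outcomes, function(oc) {
      ok <- !is.na(wide[[oc]])
      all(tapply(ok, wide$group, sum) >= 3)
    }, logical(1))
    if (any(!testable)) {
      message(sprintf("skipping undertested outcome(s): %s",
                      paste(outcomes[!testable], collapse = ", ")))
      outcomes <- outcomes[testable]
    }
    omni <- do.call(rbind, lapply(outcomes, function(oc) {
      r <- omnibus_test(wide, oc, covariates = cfg$covariates)
      r$outcome <- oc
      r
    }))
    post <- if (length(groups) == 3) {
      posthoc_battery(wide, outcomes,
                      group_levels = c(control, setdiff(groups, control)),
                      covariates = cfg$covariates,
                      correct = cfg$correct, n_perm = cfg$n_perm,
                      seed = cfg$seed)
    } else NULL
    list(omnibus = omni, posthoc = post)
  })

  partial <- run_stage("clinical_correlation", {
    if (!"seizure_duration" %in% names(table)) NULL else {
      patients <- wide[wide$group != control & !is.na(wide$seizure_duration), ,
                       drop = FALSE]
      top_nodes <- names(model$assignment)[model$assignment == model$k]
      if (nrow(patients) < 5) NULL else {
        pd <- cbind(patients,
                    as.data.frame(coupling[match(patients$subject_id,
                                                 rownames(coupling)),
                                           top_nodes, drop = FALSE]))
        partial_correlation_battery(pd, top_nodes, "seizure_duration",
                                    covariates = cfg$covariates,
                                    correct = cfg$correct)
      }
    }
  })

  enrich <- enrichment_table(model, cohort$atlas %||% synthetic_atlas_for(model))

  result <- list(config = cfg, cohort = cohort, coupling = coupling,
                 model = model, metrics = metrics, stats_table = wide,
                 omnibus = stats_out$omnibus, posthoc = stats_out$posthoc,
                 partial_correlations = partial, enrichment = enrich)

  if (!is.null(cfg$out_dir)) {
    result$manifest <- run_stage("write_outputs", write_outputs(result, cfg))
  }
  invisible(result)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

parse_k_range <- function(k_range) {
  if (is.character(k_range)) {           # "2:10" from YAML/CLI
    parts <- as.integer(strsplit(k_range, ":", fixed = TRUE)[[1]])
    k_range <- parts[1]:parts[2]
  }
  as.integer(k_range)
}

# fallback atlas when a loaded cohort ships no label table
synthetic_atlas_for <- function(model) {
  nodes <- names(model$assignment)
  atlas_labels(nodes, nodes, rep("unassigned", length(nodes)),
               rep_len(c("L", "R"), length(nodes)))
}

#' Join subject metadata to per-subject cluster indices (wide layout)
#'
#' Produces one row per subject with `asfc_<c>` and `csfc_<c>` columns,
#' the substrate for all group statistics.
#'
#' @param table subject metadata data.frame (with `subject_id`, `group`,
#'   covariates).
#' @param metrics a [cluster_metrics_table()] result.
#' @return a data.frame.
#' @export
cohort_stats_table <- function(table, metrics) {
  k <- max(metrics$cluster)
  wide <- table
  for (c in seq_len(k)) {
    sel <- metrics[metrics$cluster == c, ]
    wide[[sprintf("asfc_%d", c)]] <- sel$asfc[match(table$subject_id,
                                                    sel$subject_id)]
    wide[[sprintf("csfc_%d", c)]] <- sel$csfc[match(table$subject_id,
                                                    sel$subject_id)]
  }
  wide
}

write_outputs <- function(result, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(cfg$out_dir, name)

  cp <- as.data.frame(result$coupling)
  cp <- cbind(subject_id = rownames(result$coupling), cp)
  utils::write.table(cp, out("coupling.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(node = names(result$model$assignment),
               cluster = as.integer(result$model$assignment)),
    out("clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(k = result$model$k_range, wss = as.numeric(result$model$wss_curve)),
    out("elbow.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$enrichment, out("enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$metrics, out("cluster_metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$cohort$table %||% result$stats_table,
                     out("subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stats_all <- result$omnibus
  if (!is.null(result$posthoc)) {
    stats_all <- merge_stat_frames(result$omnibus, result$posthoc)
  }
  utils::write.table(stats_all, out("stats.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(result$partial_correlations)) {
    utils::write.table(result$partial_correlations,
                       out("partial_correlations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  files <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  manifest <- list(
    package = "scfcoupling",
    version = as.character(utils::packageVersion("scfcoupling")),
    seed = cfg$seed,
    selected_k = result$model$k,
    config = cfg[setdiff(names(cfg), "out_dir")],
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(cfg$out_dir, files))), files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}

merge_stat_frames <- function(a, b) {
  cols <- union(names(a), names(b))
  for (cl in setdiff(cols, names(a))) a[[cl]] <- NA
  for (cl in setdiff(cols, names(b))) b[[cl]] <- NA
  rbind(a[cols], b[cols])
}
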