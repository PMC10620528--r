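#' Cluster-averaged coupling index (ASFC)
#'
#' The ASFC of a cluster is the arithmetic mean of its member nodes'
#' regional coupling values: it directly measures the average coupling
#' strength of all regions in the cluster.  Nodes with missing coupling are
#' excluded pairwise and the number used is reported.
#'
#' @param coupling a [regional_coupling()] result (`coupling_vector`) or a
#'   plain named numeric vector of per-node coupling values.
#' @param model an `scfc_cluster_model` sharing the node set.
#' @return a list with `asfc` (named length-k vector), `n_used` (nodes
#'   entering each mean).
#' @export
asfc <- function(coupling, model) {
  stopifnot(inherits(model, "scfc_cluster_model"))
  rho <- if (inherits(coupling, "coupling_vector")) coupling$rho else coupling
  rho <- align_to_model(rho, model)
  k <- model$k
  out <- rep(NA_real_, k)
  n_used <- integer(k)
  for (c in seq_len(k)) {
    vals <- rho[model$assignment == c]
    n_used[c] <- sum(!is.na(vals))
    if (n_used[c] > 0) out[c] <- mean(vals, na.rm = TRUE)
  }
  names(out) <- seq_len(k)
  list(asfc = out, n_used = n_used)
}

#' Within-cluster coupling index (CSFC)
#'
#' For each cluster, collects all unique within-cluster node pairs, forms
#' the vector of structural edge weights and the matched vector of
#' functional edge weights, and returns their tie-corrected Spearman
#' correlation.  All within-cluster pairs enter, including zero entries of
#' either matrix, unless `sc_nonzero_only` restricts to structurally
#' connected pairs.  Clusters with fewer than 3 edges (size < 3) are
#' returned as `NA`.
#'
#' @param sc,fc `conn_matrix` objects on the model's node set and order.
#' @param model an `scfc_cluster_model`.
#' @param sc_nonzero_only restrict to pairs with nonzero SC weight.
#' @return a list with `csfc` (named length-k vector) and `n_edges_within`
#'   (per-cluster pair counts used).
#' @export
csfc <- function(sc, fc, model, sc_nonzero_only = FALSE) {
  stopifnot(inherits(sc, "conn_matrix"), inherits(fc, "conn_matrix"),
            inherits(model, "scfc_cluster_model"))
  if (!identical(sc$node_labels, fc$node_labels)) {
    stop("SC and FC node labels disagree")
  }
  assign <- model$assignment[sc$node_labels]
  if (anyNA(assign)) stop("cluster model does not cover all matrix nodes")
  k <- model$k
  out <- rep(NA_real_, k)
  n_edges <- integer(k)
  for (c in seq_len(k)) {
    members <- which(assign == c)
    if (length(members) >= 2) {
      sub_sc <- sc$values[members, members]
      sub_fc <- fc$values[members, members]
      ut <- upper.tri(sub_sc)
      x <- sub_sc[ut]
      y <- sub_fc[ut]
      if (sc_nonzero_only) {
        keep <- x != 0
        x <- x[keep]; y <- y[keep]
      }
      n_edges[c] <- length(x)
      if (length(x) >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0) {
        out[c] <- stats::cor(x, y, method = "spearman")
      }
    }
  }
  names(out) <- seq_len(k)
  list(csfc = out, n_edges_within = n_edges)
}

#' Per-subject cluster coupling table for a cohort
#'
#' Convenience wrapper computing ASFC and CSFC for every subject under one
#' cluster model, returning a tidy table ready for group statistics.
#'
#' @param subjects an `scfc_cohort` or list of subject records with `sc`,
#'   `fc` and optionally `subject_id`.
#' @param model an `scfc_cluster_model`.
#' @param coupling optional precomputed subjects x nodes coupling matrix
#'   (rows in subject order); computed via [cohort_coupling()] if missing.
#' @return a data.frame with columns `subject_id`, `cluster`, `asfc`,
#'   `csfc`, `n_nodes`, `n_edges`.
#' @export
cluster_metrics_table <- function(subjects, model, coupling = NULL) {
  if (inherits(subjects, "scfc_cohort")) subjects <- subjects$subjects
  if (is.null(coupling)) coupling <- cohort_coupling(subjects)
  k <- model$k
  rows <- vector("list", length(subjects))
  for (s in seq_along(subjects)) {
    sub <- subjects[[s]]
    a <- asfc(coupling[s, ], model)
    cs <- csfc(sub$sc, sub$fc, model)
    rows[[s]] <- data.frame(
      subject_id = if (!is.null(sub$subject_id)) sub$subject_id else sprintf("S%03d", s),
      cluster = seq_len(k),
      asfc = as.numeric(a$asfc),
      csfc = as.numeric(cs$csfc),
      n_nodes = a$n_used,
      n_edges = cs$n_edges_within,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

align_to_model <- function(rho, model) {
  nodes <- names(model$assignment)
  if (!is.null(names(rho))) {
    idx <- match(nodes, names(rho))
    if (anyNA(idx)) stop("coupling vector does not cover the model's nodes")
    rho <- rho[idx]
  } else if (length(rho) != length(nodes)) {
    stop("coupling vector length does not match the cluster model")
  }
  rho
}
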