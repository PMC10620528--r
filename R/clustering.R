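#' Cluster whole-brain nodes by their coupling profiles
#'
#' Partitions nodes into coupling-homogeneous clusters with k-means.  Each
#' node is embedded either as the vector of its coupling values across the
#' healthy-control subjects (`features = "subject"`, the default, matching a
#' subjects-by-nodes coupling heatmap) or as its scalar mean coupling
#' (`features = "mean"`).  k-means is run for every k in `k_range` with
#' multiple restarts under a fixed seed; the number of clusters is chosen by
#' the elbow rule on the within-cluster sum of distances curve (see
#' [select_k_elbow()]), and clusters are relabelled so that mean coupling is
#' strictly increasing in the cluster index (cluster k = highest coupling).
#'
#' @param hc_coupling subjects x nodes coupling matrix for the
#'   healthy-control group (see [cohort_coupling()]).
#' @param k_range integer candidate cluster counts (default 2:10).
#' @param seed integer RNG seed controlling the k-means restarts.
#' @param features `"subject"` or `"mean"` node embedding.
#' @param standardize if `TRUE`, scale feature columns to unit variance
#'   before clustering (default `FALSE`).
#' @param nstart number of k-means restarts per k.
#' @param k optional fixed cluster count, bypassing elbow selection.
#' @param max_retry bounded retries when k-means fails (e.g. an empty
#'   cluster under a degenerate restart).
#' @param na_action `"error"` (default) rejects missing coupling values;
#'   `"impute_mean"` fills a node's missing entries with its mean over the
#'   other subjects (its overall mean when fully missing) and warns.
#' @return an `scfc_cluster_model`: list with `k`, `assignment` (named
#'   integer vector, node -> cluster), `centroids`, `wss_curve`, `k_range`,
#'   `cluster_mean_coupling`, `features`, `seed`, `no_clear_elbow`.
#' @export
cluster_nodes <- function(hc_coupling, k_range = 2:10, seed = 1,
                          features = c("subject", "mean"),
                          standardize = FALSE, nstart = 50, k = NULL,
                          max_retry = 10, na_action = c("error", "impute_mean")) {
  features <- match.arg(features)
  na_action <- match.arg(na_action)
  hc_coupling <- as.matrix(hc_coupling)
  if (nrow(hc_coupling) < 2 && features == "subject") {
    stop("need at least 2 HC subjects for per-subject features")
  }
  if (anyNA(hc_coupling)) {
    if (na_action == "error") {
      stop("coupling matrix contains missing values; impute or drop nodes first")
    }
    warning(sprintf("imputing %d missing coupling value(s) with node means",
                    sum(is.na(hc_coupling))))
    grand <- mean(hc_coupling, na.rm = TRUE)
    for (j in which(colSums(is.na(hc_coupling)) > 0)) {
      cm <- mean(hc_coupling[, j], na.rm = TRUE)
      hc_coupling[is.na(hc_coupling[, j]), j] <- if (is.nan(cm)) grand else cm
    }
  }
  node_labels <- colnames(hc_coupling)
  if (is.null(node_labels)) node_labels <- default_node_labels(ncol(hc_coupling))
  X <- if (features == "subject") t(hc_coupling) else
    matrix(colMeans(hc_coupling), ncol = 1)
  if (standardize) X <- scale(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > nrow(X) - 1)) {
    stop("k_range must lie within [2, n_nodes - 1]")
  }

  set.seed(seed)
  if (is.null(k)) {
    fits <- vector("list", length(k_range))
    wss <- numeric(length(k_range))
    for (j in seq_along(k_range)) {
      fits[[j]] <- kmeans_retry(X, k_range[j], nstart, max_retry)
      wss[j] <- fits[[j]]$tot.withinss
    }
    names(wss) <- k_range
    sel <- select_k_elbow(wss, k_range)
    k <- as.integer(sel)
    no_elbow <- isTRUE(attr(sel, "no_clear_elbow"))
    fit <- fits[[match(k, k_range)]]
  } else {
    # fixed k: fit only the requested partition
    k <- as.integer(k)
    if (!k %in% k_range) stop("fixed k must be an element of k_range")
    fit <- kmeans_retry(X, k, nstart, max_retry)
    wss <- stats::setNames(fit$tot.withinss, k)
    no_elbow <- FALSE
  }

  # relabel clusters in ascending order of mean HC coupling
  node_mean <- colMeans(hc_coupling)
  cl_mean <- tapply(node_mean, fit$cluster, mean)
  ord <- order(cl_mean)                      # old label -> rank
  relabel <- integer(k)
  relabel[as.integer(names(cl_mean))[ord]] <- seq_len(k)
  assignment <- relabel[fit$cluster]
  names(assignment) <- node_labels
  centroids <- fit$centers[as.integer(names(cl_mean))[ord], , drop = FALSE]
  rownames(centroids) <- seq_len(k)

  structure(list(
    k = k,
    assignment = assignment,
    centroids = centroids,
    wss_curve = wss,
    k_range = k_range,
    cluster_mean_coupling = as.numeric(sort(cl_mean)),
    features = features,
    standardize = standardize,
    seed = seed,
    no_clear_elbow = no_elbow
  ), class = "scfc_cluster_model")
}

kmeans_retry <- function(X, k, nstart, max_retry) {
  for (attempt in seq_len(max_retry + 1)) {
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers = k, nstart = nstart,
                                     iter.max = 100)),
      error = function(e) NULL)
    if (!is.null(fit) && length(unique(fit$cluster)) == k) return(fit)
  }
  stop(sprintf("k-means failed to produce %d nonempty clusters after %d retries",
               k, max_retry))
}

#' @export
print.scfc_cluster_model <- function(x, ...) {
  cat(sprintf("<scfc_cluster_model> k = %d (%s features), sizes: %s\n",
              x$k, x$features,
              paste(tabulate(x$assignment, x$k), collapse = ", ")))
  if (x$no_clear_elbow) cat("  note: no clear elbow in the WSS curve\n")
  invisible(x)
}

#' Elbow (knee) selection of the number of clusters
#'
#' Operationalises the elbow rule geometrically: after normalising the
#' (k, WSS) curve to the unit square, returns the k whose point lies at
#' maximal perpendicular distance below the chord joining the curve's
#' endpoints.  This is deterministic given the curve and invariant to affine
#' rescaling of either axis.  A non-monotone curve (possible with stochastic
#' restarts) is first repaired to its running minimum with a warning.  If the
#' curve is essentially straight, the smallest interior k is returned and the
#' result is flagged via `attr(, "no_clear_elbow")`.
#'
#' @param wss_curve numeric within-cluster sum-of-distances values, one per
#'   candidate k.
#' @param k_range the candidate k values, same length as `wss_curve`.
#' @return the selected k (integer) with attributes `distances` (per-k chord
#'   distance, in normalised units) and `no_clear_elbow` (logical).
#' @export
select_k_elbow <- function(wss_curve, k_range) {
  wss_curve <- as.numeric(wss_curve)
  k_range <- as.integer(k_range)
  stopifnot(length(wss_curve) == length(k_range), length(k_range) >= 3)
  if (is.unsorted(k_range, strictly = TRUE)) stop("k_range must be increasing")
  if (any(diff(wss_curve) > 0)) {
    warning("WSS curve is not nonincreasing; repaired by running minimum")
    wss_curve <- cummin(wss_curve)
  }
  x <- (k_range - k_range[1]) / (k_range[length(k_range)] - k_range[1])
  span <- wss_curve[1] - wss_curve[length(wss_curve)]
  if (span <= 0) {
    # flat curve: no structure at all
    out <- k_range[2]
    attr(out, "distances") <- rep(0, length(k_range))
    attr(out, "no_clear_elbow") <- TRUE
    return(out)
  }
  y <- (wss_curve - wss_curve[length(wss_curve)]) / span
  # chord from (0, 1) to (1, 0); signed distance below it is (1 - x - y)/sqrt(2)
  d <- (1 - x - y) / sqrt(2)
  best <- which.max(d)
  no_elbow <- FALSE
  if (d[best] < 1e-3) {           # essentially straight line
    best <- 2L
    no_elbow <- TRUE
  }
  out <- k_range[best]
  attr(out, "distances") <- d
  attr(out, "no_clear_elbow") <- no_elbow
  out
}

#' Per-cluster network enrichment table
#'
#' Tabulates, for each cluster, how many member nodes fall in each atlas
#' network, reported as counts together with the cluster size (the "n of
#' cluster_size" convention).  Column sums reproduce the cluster sizes and
#' the grand total equals the number of nodes.
#'
#' @param model an `scfc_cluster_model`.
#' @param atlas an [atlas_labels()] table covering the model's nodes.
#' @return a data.frame with columns `cluster`, `network`, `n`,
#'   `cluster_size`, `label` (e.g. `"9/27"`), one row per cluster x network
#'   with a nonzero count plus zero rows for completeness.
#' @export
enrichment_table <- function(model, atlas) {
  stopifnot(inherits(model, "scfc_cluster_model"))
  nodes <- names(model$assignment)
  idx <- match(nodes, atlas$node_id)
  if (anyNA(idx)) {
    stop(sprintf("atlas is missing node(s): %s",
                 paste(nodes[is.na(idx)], collapse = ", ")))
  }
  network <- atlas$network[idx]
  tab <- table(cluster = model$assignment, network = network)
  sizes <- tabulate(model$assignment, model$k)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[names(out) == "Freq"] <- "n"
  out$cluster <- as.integer(out$cluster)
  out$cluster_size <- sizes[out$cluster]
  out$label <- sprintf("%d/%d", out$n, out$cluster_size)
  out <- out[order(out$cluster, -out$n, out$network), ]
  rownames(out) <- NULL
  out
}
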