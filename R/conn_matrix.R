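#' Connectivity matrix container
#'
#' A `conn_matrix` wraps an N x N symmetric weighted matrix (functional or
#' structural connectivity) together with node labels and a modality tag.
#' By convention the diagonal (self-connection) is stored as zero and ignored
#' by every downstream operation.
#'
#' @param values numeric N x N matrix, symmetric within `tol`.
#' @param node_labels character vector of length N; defaults to the matrix
#'   dimnames or to `N001..N<NN>`.
#' @param modality one of `"FC_raw"`, `"FC_z"`, `"FC_thresholded"`, `"SC"`.
#'   `SC` matrices must be nonnegative.
#' @param tol numeric tolerance for the symmetry check.
#'
#' @return An object of class `conn_matrix`: a list with elements `values`
#'   (matrix with dimnames), `node_labels`, `modality`.
#' @export
conn_matrix <- function(values,
                        node_labels = NULL,
                        modality = c("FC_raw", "FC_z", "FC_thresholded", "SC"),
                        tol = 1e-8) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("connectivity values must be numeric")
  n <- nrow(values)
  if (ncol(values) != n) {
    stop(sprintf("connectivity matrix must be square, got %d x %d",
                 n, ncol(values)))
  }
  if (is.null(node_labels)) {
    node_labels <- rownames(values)
    if (is.null(node_labels)) node_labels <- default_node_labels(n)
  }
  node_labels <- as.character(node_labels)
  if (length(node_labels) != n) {
    stop("node_labels length does not match matrix dimension")
  }
  if (anyDuplicated(node_labels)) stop("node labels must be unique")
  if (anyNA(values)) stop("connectivity matrix contains missing values")

  asym <- abs(values - t(values))
  if (max(asym) > tol) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "matrix is asymmetric beyond tolerance at nodes %s / %s (|delta| = %g)",
      node_labels[bad[1]], node_labels[bad[2]], max(asym)))
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0

  if (modality == "SC" && any(values < 0)) {
    bad <- which(rowSums(values < 0) > 0)
    stop(sprintf("SC matrix has negative entries at node(s): %s",
                 paste(node_labels[bad], collapse = ", ")))
  }
  dimnames(values) <- list(node_labels, node_labels)
  structure(list(values = values, node_labels = node_labels,
                 modality = modality),
            class = "conn_matrix")
}

default_node_labels <- function(n) sprintf("N%03d", seq_len(n))

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %s, %d nodes, density %.3f\n",
              x$modality, length(x$node_labels), conn_density(x)))
  invisible(x)
}

#' Off-diagonal density of a connectivity matrix
#'
#' Fraction of nonzero entries among the N(N-1)/2 unique node pairs.
#'
#' @param x a `conn_matrix`.
#' @return a number in \[0, 1\].
#' @export
conn_density <- function(x) {
  stopifnot(inherits(x, "conn_matrix"))
  ut <- x$values[upper.tri(x$values)]
  mean(ut != 0)
}

#' Number of nodes of a connectivity object
#' @param x a `conn_matrix`.
#' @return integer node count.
#' @export
n_nodes <- function(x) {
  stopifnot(inherits(x, "conn_matrix"))
  length(x$node_labels)
}

#' Region-level BOLD time-series container
#'
#' @param values numeric T x N matrix (timepoints by regions).
#' @param node_labels length-N region identifiers (default: column names).
#' @param subject_id optional subject identifier.
#'
#' @return an object of class `timeseries_matrix`.
#' @export
timeseries_matrix <- function(values, node_labels = NULL, subject_id = NA_character_) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("time series must be numeric")
  if (nrow(values) < 3) stop("need at least 3 timepoints")
  if (is.null(node_labels)) {
    node_labels <- colnames(values)
    if (is.null(node_labels)) node_labels <- default_node_labels(ncol(values))
  }
  node_labels <- as.character(node_labels)
  if (length(node_labels) != ncol(values)) {
    stop("node_labels length does not match number of columns")
  }
  if (anyNA(values)) stop("time series contains missing values")
  colnames(values) <- node_labels
  v <- apply(values, 2, stats::var)
  flat <- node_labels[v == 0]
  if (length(flat)) {
    warning(sprintf("zero-variance time series at node(s): %s",
                    paste(flat, collapse = ", ")))
  }
  structure(list(values = values, node_labels = node_labels,
                 subject_id = subject_id),
            class = "timeseries_matrix")
}

#' @export
print.timeseries_matrix <- function(x, ...) {
  cat(sprintf("<timeseries_matrix> subject %s: %d timepoints x %d regions\n",
              x$subject_id, nrow(x$values), length(x$node_labels)))
  invisible(x)
}

# ---- delimited-text I/O ----------------------------------------------------

#' Read / write connectivity matrices as labelled TSV
#'
#' Matrices are stored as dense tab-delimited text with node labels as the
#' header row and first column, so a write/read round trip is exact.
#'
#' @param path file path.
#' @param modality modality tag passed to [conn_matrix()].
#' @param expect_labels optional character vector; if supplied, the file's
#'   node labels must match (after reordering) or an error naming the
#'   offending nodes is raised.
#' @return [read_conn_matrix()] returns a `conn_matrix`.
#' @export
read_conn_matrix <- function(path, modality = "SC", expect_labels = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("file %s is not a square labelled matrix (%d x %d)",
                 path, nrow(m), ncol(m)))
  }
  if (!identical(rownames(m), colnames(m))) {
    stop(sprintf("row and column labels disagree in %s", path))
  }
  if (!is.null(expect_labels)) {
    m <- reconcile_labels(m, expect_labels, path)
  }
  conn_matrix(m, modality = modality)
}

reconcile_labels <- function(m, expect_labels, path) {
  missing <- setdiff(expect_labels, rownames(m))
  extra <- setdiff(rownames(m), expect_labels)
  if (length(missing) || length(extra)) {
    stop(sprintf("node labels in %s do not match: missing [%s], unexpected [%s]",
                 path,
                 paste(missing, collapse = ", "),
                 paste(extra, collapse = ", ")))
  }
  m[expect_labels, expect_labels, drop = FALSE]
}

#' @param x a `conn_matrix` (for [write_conn_matrix()]) or
#'   `timeseries_matrix` (for [write_timeseries()]).
#' @rdname read_conn_matrix
#' @export
write_conn_matrix <- function(x, path) {
  stopifnot(inherits(x, "conn_matrix"))
  write_labelled_table(x$values, path, row_labels = TRUE)
  invisible(path)
}

#' @rdname read_conn_matrix
#' @export
read_timeseries <- function(path, subject_id = NA_character_) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  timeseries_matrix(as.matrix(tab), subject_id = subject_id)
}

#' @param subject_id subject identifier attached to the loaded series.
#' @rdname read_conn_matrix
#' @export
write_timeseries <- function(x, path) {
  stopifnot(inherits(x, "timeseries_matrix"))
  write_labelled_table(x$values, path, row_labels = FALSE)
  invisible(path)
}

# full-precision text serialisation: %.17g survives a write/read round trip
# bitwise for doubles and prints integers plainly
write_labelled_table <- function(m, path, row_labels) {
  ch <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  df <- as.data.frame(ch, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_labels,
                     col.names = if (row_labels) NA else TRUE)
}

# ---- atlas -----------------------------------------------------------------

#' Atlas label table
#'
#' Maps each node to a region name, one of the functional networks (the seven
#' canonical resting-state networks plus a subcortical network) and a
#' hemisphere.
#'
#' @param node_id,region,network,hemisphere equal-length vectors.
#' @return a data.frame of class `atlas_labels`.
#' @export
atlas_labels <- function(node_id, region, network, hemisphere) {
  node_id <- as.character(node_id)
  if (anyDuplicated(node_id)) stop("duplicate node ids in atlas")
  df <- data.frame(node_id = node_id, region = as.character(region),
                   network = as.character(network),
                   hemisphere = as.character(hemisphere),
                   stringsAsFactors = FALSE)
  if (anyNA(df)) stop("atlas table contains missing values")
  class(df) <- c("atlas_labels", "data.frame")
  df
}

#' Read an atlas table (TSV: node_id, region, network, hemisphere)
#'
#' @param path file path.
#' @param expect_nodes optional node labels that must all be present;
#'   missing nodes are reported by name.
#' @return an `atlas_labels` data.frame.
#' @export
read_atlas <- function(path, expect_nodes = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("node_id", "region", "network", "hemisphere")
  if (!all(need %in% names(tab))) {
    stop(sprintf("atlas file %s must have columns: %s",
                 path, paste(need, collapse = ", ")))
  }
  atl <- atlas_labels(tab$node_id, tab$region, tab$network, tab$hemisphere)
  if (!is.null(expect_nodes)) {
    missing <- setdiff(expect_nodes, atl$node_id)
    if (length(missing)) {
      stop(sprintf("atlas is missing node(s): %s",
                   paste(missing, collapse = ", ")))
    }
    atl <- atl[match(expect_nodes, atl$node_id), , drop = FALSE]
    rownames(atl) <- NULL
    class(atl) <- c("atlas_labels", "data.frame")
  }
  atl
}

#' @param x an `atlas_labels` table.
#' @rdname read_atlas
#' @export
write_atlas <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
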