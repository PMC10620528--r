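#' Functional connectivity from region-level time series
#'
#' Computes the sample Pearson correlation between every pair of regional
#' time series.  The diagonal is stored as zero (self-connections are ignored
#' throughout).  Regions with zero temporal variance yield zero correlations
#' and a warning, so degenerate synthetic inputs do not abort a cohort run.
#'
#' @param ts a [timeseries_matrix()].
#' @return a `conn_matrix` with modality `FC_raw`.
#' @export
fc_from_timeseries <- function(ts) {
  stopifnot(inherits(ts, "timeseries_matrix"))
  v <- apply(ts$values, 2, stats::var)
  flat <- which(v == 0)
  r <- suppressWarnings(stats::cor(ts$values))
  if (length(flat)) {
    warning(sprintf("zero-variance node(s) set to zero correlation: %s",
                    paste(ts$node_labels[flat], collapse = ", ")))
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  conn_matrix(r, node_labels = ts$node_labels, modality = "FC_raw")
}

#' Fisher-Z (variance stabilising) transform of a correlation matrix
#'
#' Applies `atanh` elementwise to the off-diagonal entries.  Correlations
#' with `|r| >= 1` are clipped to `1 - 1e-7` in magnitude (with a warning)
#' so the transform stays finite.  The transform is monotone and
#' sign-preserving, so edge rankings are unchanged.
#'
#' @param fc a `conn_matrix` with modality `FC_raw`.
#' @param clip magnitude at which correlations are clipped before `atanh`.
#' @return a `conn_matrix` with modality `FC_z`.
#' @export
fisher_z <- function(fc, clip = 1 - 1e-7) {
  stopifnot(inherits(fc, "conn_matrix"))
  m <- fc$values
  over <- abs(m) >= 1
  diag(over) <- FALSE
  if (any(over)) {
    warning(sprintf("%d correlation(s) with |r| >= 1 clipped to %g before atanh",
                    sum(over) / 2, clip))
    m[over] <- sign(m[over]) * clip
  }
  z <- atanh(m)
  diag(z) <- 0
  conn_matrix(z, node_labels = fc$node_labels, modality = "FC_z")
}

#' Proportional sparsity thresholding
#'
#' Keeps the strongest `ceiling(sparsity * E)` of the `E = N(N-1)/2` unique
#' off-diagonal entries and zeroes the rest, preserving symmetry, so that all
#' subjects' graphs end up with the same edge density.  By default edges are
#' ranked by signed value (strongest positive correlations survive); set
#' `mode = "absolute"` to rank by magnitude.  Ties at the cutoff are broken
#' by stable node-index order and reported via a message.
#'
#' @param fc a `conn_matrix` (typically modality `FC_z`).
#' @param sparsity fraction of edges to retain, in (0, 1\].
#' @param mode `"signed"` (default) or `"absolute"` edge ranking.
#' @return a `conn_matrix` with modality `FC_thresholded`.
#' @export
proportional_threshold <- function(fc, sparsity = 0.10,
                                   mode = c("signed", "absolute")) {
  stopifnot(inherits(fc, "conn_matrix"))
  mode <- match.arg(mode)
  if (!(sparsity > 0 && sparsity <= 1)) stop("sparsity must be in (0, 1]")
  m <- fc$values
  n <- nrow(m)
  ut <- which(upper.tri(m))
  vals <- m[ut]
  key <- if (mode == "signed") vals else abs(vals)
  keep_n <- ceiling(sparsity * length(ut))
  ord <- order(-key, ut)              # stable: value, then node-index order
  kept <- ord[seq_len(keep_n)]
  if (keep_n < length(ut) && key[ord[keep_n]] == key[ord[keep_n + 1]]) {
    message(sprintf(
      "proportional_threshold: tie at the cutoff value %g broken by node order",
      key[ord[keep_n]]))
  }
  out <- matrix(0, n, n)
  out[ut[kept]] <- vals[kept]
  out <- out + t(out)
  conn_matrix(out, node_labels = fc$node_labels, modality = "FC_thresholded")
}

#' Drop initial volumes from a BOLD time series
#'
#' Removes the first `n_discard` timepoints (scanner equilibration /
#' magnetisation-saturation volumes) from a region-level series.
#'
#' @param ts a [timeseries_matrix()].
#' @param n_discard nonnegative count of initial timepoints to drop; must be
#'   strictly less than the number of available timepoints.
#' @return a `timeseries_matrix` with `T - n_discard` timepoints.
#' @export
discard_initial_volumes <- function(ts, n_discard) {
  stopifnot(inherits(ts, "timeseries_matrix"))
  n_discard <- as.integer(n_discard)
  if (n_discard < 0) stop("n_discard must be nonnegative")
  if (n_discard == 0) return(ts)
  T <- nrow(ts$values)
  if (T <= n_discard) {
    stop(sprintf("cannot discard %d volumes from a series of length %d",
                 n_discard, T))
  }
  timeseries_matrix(ts$values[-seq_len(n_discard), , drop = FALSE],
                    node_labels = ts$node_labels,
                    subject_id = ts$subject_id)
}
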