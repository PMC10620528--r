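#' Per-node structural-functional coupling
#'
#' For every node i, computes the Spearman rank correlation between row i of
#' the structural connectivity matrix and row i of the functional
#' connectivity matrix over the N-1 off-diagonal positions (the
#' self-connection is excluded).  Ties are handled with average ranks, i.e.
#' the standard tie-corrected coefficient.  A node whose SC or FC row is
#' constant has undefined coupling and is returned as `NA` with a warning.
#'
#' @param sc a `conn_matrix` with modality `SC`.
#' @param fc a `conn_matrix` (any FC modality) on the same node set and order.
#' @param sc_nonzero_only if `TRUE`, restrict each row correlation to the
#'   positions where the SC row is nonzero (sensitivity analysis); the
#'   default uses all N-1 entries.
#' @return an object of class `coupling_vector`: list with `rho` (named
#'   length-N vector), `n_pairs_used`, `subject_id`.
#' @export
regional_coupling <- function(sc, fc, sc_nonzero_only = FALSE) {
  stopifnot(inherits(sc, "conn_matrix"), inherits(fc, "conn_matrix"))
  if (!identical(sc$node_labels, fc$node_labels)) {
    stop("SC and FC node labels disagree; reconcile ordering first")
  }
  n <- length(sc$node_labels)
  if (sc_nonzero_only) {
    rho <- rep(NA_real_, n)
    npairs <- integer(n)
    for (i in seq_len(n)) {
      x <- sc$values[i, -i]
      y <- fc$values[i, -i]
      keep <- x != 0
      npairs[i] <- sum(keep)
      if (npairs[i] >= 3 && stats::sd(x[keep]) > 0 && stats::sd(y[keep]) > 0) {
        rho[i] <- stats::cor(x[keep], y[keep], method = "spearman")
      }
    }
  } else {
    rho <- row_spearman_nodiag(sc$values, fc$values)
    npairs <- rep.int(n - 1L, n)
  }
  if (anyNA(rho)) {
    warning(sprintf("coupling undefined (degenerate row) at node(s): %s",
                    paste(sc$node_labels[is.na(rho)], collapse = ", ")))
  }
  names(rho) <- sc$node_labels
  structure(list(rho = rho, n_pairs_used = npairs,
                 subject_id = NA_character_),
            class = "coupling_vector")
}

# Row-wise tie-corrected Spearman between matched rows of two square
# matrices, excluding the diagonal position of each row.  Vectorised:
# average-rank each row, then Pearson on ranks via row sums.
row_spearman_nodiag <- function(A, B) {
  n <- nrow(A)
  m <- n - 1L
  RA <- matrix(NA_real_, n, m)
  RB <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    RA[i, ] <- rank(A[i, -i])
    RB[i, ] <- rank(B[i, -i])
  }
  ca <- RA - rowMeans(RA)
  cb <- RB - rowMeans(RB)
  sa <- rowSums(ca^2)
  sb <- rowSums(cb^2)
  rho <- rowSums(ca * cb) / sqrt(sa * sb)
  rho[sa == 0 | sb == 0] <- NA_real_
  rho
}

#' @export
print.coupling_vector <- function(x, ...) {
  ok <- !is.na(x$rho)
  cat(sprintf("<coupling_vector> %d nodes (%d defined), mean rho %.3f\n",
              length(x$rho), sum(ok), mean(x$rho[ok])))
  invisible(x)
}

#' Stack per-subject coupling vectors into a cohort matrix
#'
#' @param subjects either an `scfc_cohort` (see [generate_cohort()]) or a
#'   list whose elements each contain `sc` and `fc` `conn_matrix` objects
#'   (optionally a `subject_id`).
#' @param sc_nonzero_only passed to [regional_coupling()].
#' @return a subjects x nodes numeric matrix of coupling values, with
#'   subject ids as row names and node labels as column names.
#' @export
cohort_coupling <- function(subjects, sc_nonzero_only = FALSE) {
  if (inherits(subjects, "scfc_cohort")) subjects <- subjects$subjects
  stopifnot(length(subjects) >= 1)
  labels <- subjects[[1]]$sc$node_labels
  out <- matrix(NA_real_, length(subjects), length(labels),
                dimnames = list(NULL, labels))
  ids <- character(length(subjects))
  for (s in seq_along(subjects)) {
    sub <- subjects[[s]]
    if (!identical(sub$sc$node_labels, labels)) {
      stop(sprintf("subject %d does not share the cohort atlas", s))
    }
    cv <- regional_coupling(sub$sc, sub$fc, sc_nonzero_only = sc_nonzero_only)
    out[s, ] <- cv$rho
    ids[s] <- if (!is.null(sub$subject_id)) sub$subject_id else sprintf("S%03d", s)
  }
  rownames(out) <- ids
  out
}
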