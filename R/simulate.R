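#' Generate a synthetic structural connectivity matrix
#'
#' Samples a symmetric, zero-diagonal streamline-count matrix: a uniformly
#' random edge set at the configured off-diagonal density, with heavy-tailed
#' integer weights (log-normal draws rounded to integers >= 1).  If the
#' sampled edge set leaves a node with no connections, the matrix is either
#' repaired by rewiring (default) or rejected, per
#' `config$isolated_policy`.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (as inside [generate_cohort()]).
#' @return a `conn_matrix` with modality `SC`.
#' @export
generate_sc <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_nodes
  E <- n * (n - 1L) / 2L
  m <- max(1L, round(config$sc_density * E))
  pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  idx <- sample.int(E, m)

  deg <- tabulate(c(pair_i[idx], pair_j[idx]), n)
  if (any(deg == 0)) {
    if (config$isolated_policy == "error") {
      stop(sprintf("density %.3f left node(s) with no edges: %s",
                   config$sc_density,
                   paste(default_node_labels(n)[deg == 0], collapse = ", ")))
    }
    in_set <- logical(E)
    in_set[idx] <- TRUE
    for (v in which(deg == 0)) {
      if (deg[v] > 0) next    # may have been fixed by an earlier rewire
      u <- sample(setdiff(seq_len(n), v), 1)
      e_new <- pair_index(min(u, v), max(u, v), n)
      if (in_set[e_new]) next
      # drop a random edge whose endpoints both keep degree >= 2
      cur <- which(in_set)
      ok <- cur[deg[pair_i[cur]] >= 2 & deg[pair_j[cur]] >= 2]
      drop <- if (length(ok)) sample(ok, 1) else NA_integer_
      if (!is.na(drop)) {
        in_set[drop] <- FALSE
        deg[pair_i[drop]] <- deg[pair_i[drop]] - 1L
        deg[pair_j[drop]] <- deg[pair_j[drop]] - 1L
      }
      in_set[e_new] <- TRUE
      deg[u] <- deg[u] + 1L
      deg[v] <- deg[v] + 1L
    }
    idx <- which(in_set)
    m <- length(idx)
  }

  w <- pmax(1, round(stats::rlnorm(m, config$sc_weight_meanlog,
                                   config$sc_weight_sdlog)))
  sc <- matrix(0, n, n)
  sc[cbind(pair_i[idx], pair_j[idx])] <- w
  sc <- sc + t(sc)
  conn_matrix(sc, node_labels = default_node_labels(n), modality = "SC")
}

# linear index of pair (i, j), i < j, in the row-major upper-triangle
# enumeration used above
pair_index <- function(i, j, n) {
  (i - 1L) * n - i * (i - 1L) / 2L + (j - i)
}

# Normal scores of the upper-triangle entries of a symmetric matrix:
# average ranks mapped through the standard normal quantile function.
# Ties (notably the zero mass of a sparse SC) share one score, so the
# transform is exactly rank-preserving within every row.
sc_normal_scores <- function(values) {
  n <- nrow(values)
  ut <- which(upper.tri(values))
  r <- rank(values[ut], ties.method = "average")
  g <- matrix(0, n, n)
  g[ut] <- stats::qnorm(r / (length(ut) + 1))
  g + t(g)
}

#' Monte-Carlo calibration curve for the FC mixing weight
#'
#' Estimates, over a grid of mixing weights w, the expected tie-corrected
#' Spearman correlation between `w * g + (1 - w) * noise` and the underlying
#' SC row, where g is the rank-preserving normal-score transform of the row.
#' The rows are drawn from an actual SC matrix so the calibration reflects
#' the tie structure (the zero mass) of sparse streamline-count profiles.
#' The estimated curve is monotonised and returned with forward and inverse
#' interpolators.
#'
#' @param sc a `conn_matrix` (modality `SC`) supplying representative rows.
#' @param noise_sd standard deviation of the Gaussian noise term.
#' @param n_rows Monte-Carlo replicate rows per grid point.
#' @param w_grid mixing-weight grid.
#' @return a list of class `mixing_curve` with `w`, `rho`, `fun` (w -> rho)
#'   and `inverse` (rho -> w).
#' @export
mixing_curve <- function(sc, noise_sd = 1, n_rows = 500,
                         w_grid = seq(-0.5, 1, by = 0.025)) {
  stopifnot(inherits(sc, "conn_matrix"))
  n <- length(sc$node_labels)
  g <- sc_normal_scores(sc$values)
  rows <- sample.int(n, n_rows, replace = TRUE)
  m <- n - 1L
  X <- G <- EPS <- matrix(NA_real_, n_rows, m)
  for (r in seq_len(n_rows)) {
    i <- rows[r]
    X[r, ] <- rank(sc$values[i, -i])     # pre-ranked SC row
    G[r, ] <- g[i, -i]
    EPS[r, ] <- stats::rnorm(m, 0, noise_sd)
  }
  cx <- X - rowMeans(X)
  sx <- rowSums(cx^2)
  rho <- vapply(w_grid, function(w) {
    Y <- w * G + (1 - w) * EPS
    RY <- t(apply(Y, 1, rank))
    cy <- RY - rowMeans(RY)
    mean(rowSums(cx * cy) / sqrt(sx * rowSums(cy^2)))
  }, numeric(1))
  rho <- cummax(rho)                      # enforce monotonicity (MC noise)
  keep <- !duplicated(rho)
  structure(list(
    w = w_grid, rho = rho, noise_sd = noise_sd,
    fun = stats::approxfun(w_grid, rho, rule = 2),
    inverse = stats::approxfun(rho[keep], w_grid[keep], rule = 2)
  ), class = "mixing_curve")
}

#' Calibrate a single mixing weight by monotone bisection
#'
#' Finds the weight w such that the Monte-Carlo mean Spearman correlation
#' between `w * g + (1 - w) * noise` and the underlying row equals
#' `target_rho` within `tol`.  The measured mean is monotone nondecreasing
#' in w, and common random numbers (rows and noise drawn once) make it a
#' deterministic function of w, so bisection converges cleanly.
#'
#' @param target_rho target Spearman correlation, in (-1, 1).
#' @param row_length length of the profile rows (>= 10).
#' @param noise_sd Gaussian noise standard deviation.
#' @param nrep Monte-Carlo rows.
#' @param tol calibration tolerance on the mean correlation.
#' @param max_iter bisection iteration cap.
#' @param sc_rows optional matrix of representative SC rows (`nrep` are
#'   resampled from it); by default continuous standard-normal rows are
#'   used.
#' @param seed optional seed for the common random numbers.
#' @return the calibrated weight, with attribute `achieved_rho`.
#' @export
calibrate_mixing <- function(target_rho, row_length, noise_sd = 1,
                             nrep = 200, tol = 0.01, max_iter = 60,
                             sc_rows = NULL, seed = NULL) {
  if (!(target_rho > -1 && target_rho < 1)) stop("target_rho must be in (-1, 1)")
  row_length <- as.integer(row_length)
  if (row_length < 10) stop("row_length must be >= 10")
  if (!is.null(seed)) set.seed(seed)

  if (is.null(sc_rows)) {
    X <- matrix(stats::rnorm(nrep * row_length), nrep, row_length)
  } else {
    X <- sc_rows[sample.int(nrow(sc_rows), nrep, replace = TRUE), ,
                 drop = FALSE]
    if (ncol(X) != row_length) stop("sc_rows width must equal row_length")
  }
  EPS <- matrix(stats::rnorm(nrep * row_length, 0, noise_sd), nrep, row_length)
  RX <- t(apply(X, 1, rank))
  G <- t(apply(X, 1, function(x)
    stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1))))
  cx <- RX - rowMeans(RX)
  sx <- rowSums(cx^2)
  f <- function(w) {
    Y <- w * G + (1 - w) * EPS
    RY <- t(apply(Y, 1, rank))
    cy <- RY - rowMeans(RY)
    mean(rowSums(cx * cy) / sqrt(sx * rowSums(cy^2)))
  }

  lo <- -1; hi <- 1
  f_lo <- f(lo); f_hi <- f(hi)
  if (target_rho <= f_lo || target_rho >= f_hi + tol) {
    if (abs(f_hi - target_rho) <= tol) return(structure(hi, achieved_rho = f_hi))
    stop(sprintf("target rho %.3f outside attainable range [%.3f, %.3f]",
                 target_rho, f_lo, f_hi))
  }
  best_w <- NA_real_; best_f <- Inf
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - target_rho) < abs(best_f - target_rho)) {
      best_w <- mid; best_f <- fm
    }
    if (abs(fm - target_rho) <= tol) {
      return(structure(mid, achieved_rho = fm))
    }
    if (fm < target_rho) lo <- mid else hi <- mid
    if (hi - lo < 1e-7) break
  }
  stop(sprintf(
    "calibration tolerance %.3g not reached in %d iterations; best achieved rho = %.4f (target %.4f)",
    tol, max_iter, best_f, target_rho))
}

#' Generate an FC matrix with planted per-node coupling
#'
#' Builds a symmetric functional connectivity matrix whose per-node Spearman
#' correlation with the matched SC row (self-connection excluded) has
#' expectation equal to the planted target.  Each entry mixes the
#' rank-preserving normal-score transform of SC with independent symmetric
#' Gaussian noise, `FC_ij = w_ij g_ij + (1 - w_ij) eps_ij`.  Because entry
#' (i, j) is shared by rows i and j, entry-level targets are set to the
#' average of the two nodes' adjusted targets, with the adjustment
#' `c_i = 2 t_i - mean(t)` chosen so that each row's average association
#' equals its own target; weights are read off a Monte-Carlo calibration
#' curve estimated from the actual SC rows (see [mixing_curve()]).
#'
#' @param sc a `conn_matrix` with modality `SC`; every row must be
#'   non-constant.
#' @param planted_rho_row length-N vector of target couplings in (-1, 1).
#' @param noise_sd Gaussian noise standard deviation.
#' @param curve optional precomputed [mixing_curve()]; computed from `sc`
#'   when `NULL`.
#' @param seed optional seed.
#' @return a `conn_matrix` with modality `FC_z`.
#' @export
generate_fc_with_target_coupling <- function(sc, planted_rho_row,
                                             noise_sd = 1, curve = NULL,
                                             seed = NULL) {
  stopifnot(inherits(sc, "conn_matrix"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(sc$node_labels)
  if (length(planted_rho_row) != n) {
    stop("planted_rho_row must have one target per node")
  }
  if (any(planted_rho_row <= -1 | planted_rho_row >= 1)) {
    stop("targets must lie in (-1, 1)")
  }
  # constant-row check (all off-diagonal entries equal)
  for (i in seq_len(n)) {
    x <- sc$values[i, -i]
    if (max(x) == min(x)) {
      stop(sprintf("SC row for node %s is constant; target coupling unattainable",
                   sc$node_labels[i]))
    }
  }
  g <- sc_normal_scores(sc$values)
  if (is.null(curve)) curve <- mixing_curve(sc, noise_sd = noise_sd)

  targets <- as.numeric(planted_rho_row)
  cc <- if (length(unique(targets)) > 1) 2 * targets - mean(targets) else targets
  rho_rng <- range(curve$rho)
  cc <- pmin(pmax(cc, rho_rng[1]), rho_rng[2])

  ut <- which(upper.tri(sc$values))
  pi_ <- row(sc$values)[ut]
  pj_ <- col(sc$values)[ut]
  rho_entry <- (cc[pi_] + cc[pj_]) / 2
  w_entry <- curve$inverse(rho_entry)
  # targets indistinguishable from a perfect monotone copy get the exact
  # noise-free weight (interpolation on the calibration grid cannot)
  w_entry[rho_entry >= 1 - 1e-9] <- 1
  w_entry[rho_entry <= -1 + 1e-9] <- -1
  eps <- stats::rnorm(length(ut), 0, noise_sd)
  vals <- w_entry * g[ut] + (1 - w_entry) * eps
  fc <- matrix(0, n, n)
  fc[ut] <- vals
  fc <- fc + t(fc)
  conn_matrix(fc, node_labels = sc$node_labels, modality = "FC_z")
}

#' Synthesise a BOLD-like time series realising a target FC
#'
#' Maps the (unbounded) generated FC to a correlation scale with a monotone
#' `tanh` squashing, repairs it to the nearest positive-definite correlation
#' matrix by eigenvalue clipping, and draws `T` Gaussian samples with that
#' correlation, so the sample Pearson matrix of the returned series
#' approximates the target (rank structure preserved by monotonicity).
#'
#' @param fc a `conn_matrix` (modality `FC_z`).
#' @param n_timepoints series length T.
#' @param squash scale applied inside `tanh`.
#' @param subject_id identifier attached to the series.
#' @return a `timeseries_matrix`.
#' @export
timeseries_from_fc <- function(fc, n_timepoints = 770, squash = 0.5,
                               subject_id = NA_character_) {
  stopifnot(inherits(fc, "conn_matrix"))
  C <- tanh(squash * fc$values)
  diag(C) <- 1
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 1e-6)
  C <- e$vectors %*% (ev * t(e$vectors))
  C <- stats::cov2cor((C + t(C)) / 2)
  L <- chol(C)
  X <- matrix(stats::rnorm(n_timepoints * ncol(C)), n_timepoints) %*% L
  timeseries_matrix(X, node_labels = fc$node_labels, subject_id = subject_id)
}

#' Generate a full synthetic cohort with planted ground truth
#'
#' Draws one SC and one FC per subject (plus a time series in
#' `"timeseries"` mode), a subject metadata table and the planted ground
#' truth: node strata (random interleaving of strata across the atlas),
#' per-subject target coupling (stratum target, minus the group's
#' decoupling delta for patients), and clinical correlations (designated
#' top-stratum nodes whose target coupling depends on the patient's seizure
#' duration with the planted sign).  A single master seed fans out to
#' per-subject substreams.
#'
#' @param config a [sim_config()].
#' @param curve optional precomputed [mixing_curve()] to amortise
#'   calibration across replicate cohorts with the same configuration.
#' @return an `scfc_cohort`: list with `subjects` (each with `subject_id`,
#'   `group`, `sc`, `fc`, optionally `ts`), `table` (metadata data.frame),
#'   `truth` (node strata, planted rho matrix, clinical plan), `atlas`, and
#'   `config`.
#' @export
generate_cohort <- function(config, curve = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_nodes
  labels <- default_node_labels(n)

  networks <- rep(names(config$network_sizes), config$network_sizes)
  atlas <- atlas_labels(
    node_id = labels,
    region = sprintf("%s_%d", networks, unlist(lapply(config$network_sizes, seq_len))),
    network = networks,
    hemisphere = rep_len(c("L", "R"), n))

  node_stratum <- sample(rep(seq_len(config$n_strata), config$stratum_sizes))
  names(node_stratum) <- labels

  top_nodes <- which(node_stratum == config$n_strata)
  n_neg <- config$clinical$n_negative
  n_pos <- config$clinical$n_positive
  clin_idx <- top_nodes[seq_len(n_neg + n_pos)]
  clin_signs <- c(rep(-1, n_neg), rep(1, n_pos))

  groups_all <- rep(names(config$group_sizes), config$group_sizes)
  S <- length(groups_all)
  ids <- sprintf("sub%03d", seq_len(S))
  is_patient <- groups_all != names(config$group_sizes)[1]

  demo <- demographic_params()
  age <- sex <- education <- numeric(S)
  sexc <- character(S)
  for (g in unique(groups_all)) {
    sel <- groups_all == g
    p <- demo[[g]] %||% demo$default
    age[sel] <- stats::rnorm(sum(sel), p$age[1], p$age[2])
    education[sel] <- pmax(1, round(stats::rnorm(sum(sel), p$edu[1], p$edu[2])))
    sexc[sel] <- ifelse(stats::runif(sum(sel)) < p$male_frac, "M", "F")
  }
  age[is_patient] <- age[is_patient] + config$confound_age_shift
  duration <- rep(NA_real_, S)
  duration[is_patient] <- pmax(
    0.5, stats::rnorm(sum(is_patient), config$clinical$duration_mean,
                      config$clinical$duration_sd))

  table <- data.frame(
    subject_id = ids, group = groups_all, age = round(age, 1), sex = sexc,
    education = education, seizure_duration = round(duration, 1),
    stringsAsFactors = FALSE)

  # planted per-subject, per-node targets
  base <- config$stratum_coupling_targets[node_stratum]
  planted <- matrix(rep(base, each = S), S, n,
                    dimnames = list(ids, labels))
  for (g in rownames(config$decoupling_deltas)) {
    sel <- groups_all == g
    if (!any(sel)) next
    delta_node <- config$decoupling_deltas[g, node_stratum]
    planted[sel, ] <- sweep(planted[sel, , drop = FALSE], 2, delta_node, `-`)
  }
  beta <- config$clinical$beta
  zdur <- (duration - config$clinical$duration_mean) / config$clinical$duration_sd
  for (k in seq_along(clin_idx)) {
    planted[is_patient, clin_idx[k]] <-
      planted[is_patient, clin_idx[k]] + beta * clin_signs[k] * zdur[is_patient]
  }
  planted <- pmin(pmax(planted, -0.99), 0.99)

  subject_seeds <- sample.int(.Machine$integer.max - 1L, S)
  if (is.null(curve)) {
    sc0 <- generate_sc(config)
    curve <- mixing_curve(sc0, noise_sd = config$noise_sd)
  }

  subjects <- vector("list", S)
  for (s in seq_len(S)) {
    set.seed(subject_seeds[s])
    sc_s <- generate_sc(config)
    fc_s <- generate_fc_with_target_coupling(sc_s, planted[s, ],
                                             noise_sd = config$noise_sd,
                                             curve = curve)
    rec <- list(subject_id = ids[s], group = groups_all[s],
                sc = sc_s, fc = fc_s)
    if (config$mode == "timeseries") {
      rec$ts <- timeseries_from_fc(fc_s, config$timeseries_length,
                                   subject_id = ids[s])
    }
    subjects[[s]] <- rec
  }

  truth <- list(
    node_stratum = node_stratum,
    subject_group = stats::setNames(groups_all, ids),
    planted_rho = planted,
    stratum_targets = config$stratum_coupling_targets,
    clinical = list(nodes = labels[clin_idx], signs = clin_signs,
                    beta = beta))

  structure(list(subjects = subjects, table = table, truth = truth,
                 atlas = atlas, config = config, curve = curve),
            class = "scfc_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Demographic sampling parameters for the default three-group cohort
# (means and SDs in years; male fraction).  Groups are demographically
# matched; unknown group names fall back to the pooled default.
demographic_params <- function() {
  list(
    HC = list(age = c(30.3, 8.4), edu = c(11.6, 2.6), male_frac = 30 / 48),
    LTLE = list(age = c(29.9, 8.9), edu = c(10.6, 3.5), male_frac = 17 / 34),
    RTLE = list(age = c(30.6, 11.7), edu = c(10.7, 3.2), male_frac = 17 / 31),
    default = list(age = c(30.2, 9.5), edu = c(11.0, 3.0), male_frac = 0.57))
}

#' @export
print.scfc_cohort <- function(x, ...) {
  cat(sprintf("<scfc_cohort> %d subjects (%s), %d nodes, %d strata, mode %s\n",
              length(x$subjects),
              paste(sprintf("%s=%d", names(x$config$group_sizes),
                            x$config$group_sizes), collapse = " "),
              x$config$n_nodes, x$config$n_strata, x$config$mode))
  invisible(x)
}

#' Write / read a cohort as delimited text files
#'
#' Writes one matrix file per subject per modality (`sc_<id>.tsv`,
#' `fc_<id>.tsv`, and `ts_<id>.tsv` in time-series mode), a `subjects.tsv`
#' metadata table, `atlas.tsv`, and the planted truth as
#' `ground_truth.json`.
#'
#' @param cohort an `scfc_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   list with `subjects`, `table`, `atlas`, `truth` (if present on disk).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "scfc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sub in cohort$subjects) {
    write_conn_matrix(sub$sc, file.path(dir, sprintf("sc_%s.tsv", sub$subject_id)))
    write_conn_matrix(sub$fc, file.path(dir, sprintf("fc_%s.tsv", sub$subject_id)))
    if (!is.null(sub$ts)) {
      write_timeseries(sub$ts, file.path(dir, sprintf("ts_%s.tsv", sub$subject_id)))
    }
  }
  utils::write.table(cohort$table, file.path(dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  truth <- cohort$truth
  truth$planted_rho <- NULL    # large; strata + targets reconstruct it
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  table <- utils::read.table(file.path(dir, "subjects.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  atlas_path <- file.path(dir, "atlas.tsv")
  atlas <- if (file.exists(atlas_path)) read_atlas(atlas_path) else NULL
  subjects <- vector("list", nrow(table))
  for (s in seq_len(nrow(table))) {
    id <- table$subject_id[s]
    sc_path <- file.path(dir, sprintf("sc_%s.tsv", id))
    fc_path <- file.path(dir, sprintf("fc_%s.tsv", id))
    if (!file.exists(sc_path)) stop(sprintf("missing SC file for subject %s", id))
    if (!file.exists(fc_path)) stop(sprintf("missing FC file for subject %s", id))
    rec <- list(subject_id = id, group = table$group[s],
                sc = read_conn_matrix(sc_path, modality = "SC"),
                fc = read_conn_matrix(fc_path, modality = "FC_z"))
    ts_path <- file.path(dir, sprintf("ts_%s.tsv", id))
    if (file.exists(ts_path)) rec$ts <- read_timeseries(ts_path, subject_id = id)
    subjects[[s]] <- rec
  }
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path,
                                                            simplifyVector = TRUE)
           else NULL
  list(subjects = subjects, table = table, atlas = atlas, truth = truth)
}
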