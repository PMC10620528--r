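#' Configuration for the synthetic connectome cohort generator
#'
#' Describes a simulated multi-subject cohort of paired structural (SC) and
#' functional (FC) connectivity matrices with planted per-node coupling
#' strata, planted group decoupling in the high-coupling strata, and planted
#' clinical correlations.  Defaults reproduce the study conditions the
#' package is validated against: 246 nodes in 8 functional networks, five
#' coupling strata with healthy-control targets (0.103, 0.150, 0.176,
#' 0.201, 0.247), groups of 48 controls and 34 + 31 patients, 10.2% SC
#' density, and patient decoupling planted in the upper three strata.
#'
#' @param n_nodes number of brain regions (nodes).
#' @param network_sizes named integer vector of nodes per functional
#'   network; must sum to `n_nodes`.  Defaults to an 8-network layout
#'   (seven canonical resting-state networks plus subcortical) scaled to
#'   `n_nodes`.
#' @param n_strata number of planted coupling strata.
#' @param stratum_coupling_targets per-stratum target Spearman coupling for
#'   healthy controls, increasing.
#' @param stratum_sizes nodes per stratum (summing to `n_nodes`); defaults
#'   to the 27/71/55/64/29 layout scaled to `n_nodes`.
#' @param group_sizes named counts for the control group followed by the
#'   patient groups (default `c(HC = 48, LTLE = 34, RTLE = 31)`).  A size of
#'   0 omits a group; nonzero groups need at least 2 subjects.
#' @param decoupling_deltas patient-groups x strata matrix subtracted from
#'   the stratum targets for each patient group.  Default plants decoupling
#'   in strata 3-5 only.
#' @param sc_density fraction of nonzero off-diagonal SC entries.
#' @param timeseries_length timepoints per subject in time-series mode.
#' @param noise_sd standard deviation of the independent Gaussian noise
#'   mixed into the FC generator.
#' @param seed integer master seed; per-subject substreams are derived from
#'   it so subjects are independent yet reproducible.
#' @param mode `"matrix"` emits SC/FC matrix pairs (default);
#'   `"timeseries"` additionally synthesises a T x N BOLD-like series whose
#'   sample Pearson matrix approximates the target FC.
#' @param sc_weight_meanlog,sc_weight_sdlog log-normal parameters of the
#'   streamline-count edge weights (rounded to integers >= 1).
#' @param isolated_policy what to do when the sampled edge set leaves a node
#'   with no connections: `"repair"` (rewire, default) or `"error"`.
#' @param clinical list controlling the planted coupling-duration
#'   correlations: `n_negative`/`n_positive` top-stratum nodes with
#'   negative/positive planted dependence, effect slope `beta` (coupling
#'   units per SD of seizure duration), and the duration distribution
#'   (`duration_mean`, `duration_sd`, years).
#' @param confound_age_shift years added to patients' ages (default 0 keeps
#'   the groups demographically balanced; set nonzero to exercise covariate
#'   adjustment).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_nodes = 246,
                       network_sizes = NULL,
                       n_strata = 5,
                       stratum_coupling_targets = c(0.103, 0.150, 0.176, 0.201, 0.247),
                       stratum_sizes = NULL,
                       group_sizes = c(HC = 48, LTLE = 34, RTLE = 31),
                       decoupling_deltas = NULL,
                       sc_density = 0.102,
                       timeseries_length = 770,
                       noise_sd = 1,
                       seed = 1,
                       mode = c("matrix", "timeseries"),
                       sc_weight_meanlog = 3.5,
                       sc_weight_sdlog = 1,
                       isolated_policy = c("repair", "error"),
                       clinical = list(),
                       confound_age_shift = 0) {
  mode <- match.arg(mode)
  isolated_policy <- match.arg(isolated_policy)
  # YAML/JSON configs deliver named lists; coerce to the vector forms
  if (is.list(group_sizes)) group_sizes <- unlist(group_sizes)
  if (is.list(network_sizes)) network_sizes <- unlist(network_sizes)
  if (is.list(stratum_sizes)) stratum_sizes <- unlist(stratum_sizes)
  if (is.list(stratum_coupling_targets)) {
    stratum_coupling_targets <- unlist(stratum_coupling_targets)
  }
  if (is.list(decoupling_deltas)) {
    decoupling_deltas <- do.call(rbind, decoupling_deltas)
  }
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 10) stop("n_nodes must be at least 10")

  if (is.null(network_sizes)) {
    base <- c(limbic = 27, default_mode = 40, dorsal_attention = 30,
              sensorimotor = 35, visual = 35, ventral_attention = 25,
              frontoparietal = 18, subcortical = 36)
    network_sizes <- apportion(n_nodes, base)
  }
  if (sum(network_sizes) != n_nodes) {
    stop("network_sizes must sum to n_nodes")
  }
  if (is.null(names(network_sizes))) {
    names(network_sizes) <- sprintf("net%d", seq_along(network_sizes))
  }

  n_strata <- as.integer(n_strata)
  if (length(stratum_coupling_targets) != n_strata) {
    stop("stratum_coupling_targets must have one value per stratum")
  }
  if (is.unsorted(stratum_coupling_targets)) {
    stop("stratum_coupling_targets must be nondecreasing")
  }
  if (is.null(stratum_sizes)) {
    stratum_sizes <- apportion(n_nodes, c(27, 71, 55, 64, 29)[seq_len(n_strata)])
  }
  if (sum(stratum_sizes) != n_nodes) stop("stratum_sizes must sum to n_nodes")
  if (any(stratum_sizes < 1)) stop("every stratum needs at least one node")

  if (is.null(names(group_sizes))) {
    stop("group_sizes must be named (control group first)")
  }
  group_sizes <- as.integer(round(group_sizes)) |> stats::setNames(names(group_sizes))
  if (any(group_sizes < 0) || group_sizes[1] < 2) {
    stop("control group needs >= 2 subjects; sizes must be nonnegative")
  }
  if (any(group_sizes > 0 & group_sizes < 2)) {
    stop("every nonempty group needs at least 2 subjects")
  }
  patient_groups <- names(group_sizes)[-1]

  if (is.null(decoupling_deltas)) {
    defaults <- rbind(LTLE = c(0, 0, 0.013, 0.010, 0.019),
                      RTLE = c(0, 0, 0.011, 0.011, 0.028))
    decoupling_deltas <- matrix(0, length(patient_groups), n_strata,
                                dimnames = list(patient_groups, NULL))
    for (g in patient_groups) {
      if (g %in% rownames(defaults) && n_strata == 5) {
        decoupling_deltas[g, ] <- defaults[g, ]
      }
    }
  }
  decoupling_deltas <- as.matrix(decoupling_deltas)
  if (nrow(decoupling_deltas) != length(patient_groups) ||
      ncol(decoupling_deltas) != n_strata) {
    stop("decoupling_deltas must be patient-groups x strata")
  }
  rownames(decoupling_deltas) <- patient_groups
  eff <- sweep(-decoupling_deltas, 2, stratum_coupling_targets, `+`)
  if (any(abs(c(stratum_coupling_targets, eff)) >= 1)) {
    stop("every stratum target minus any applicable delta must lie in (-1, 1)")
  }

  if (!(sc_density > 0 && sc_density <= 1)) stop("sc_density must be in (0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")

  clin_default <- list(n_negative = 2, n_positive = 1, beta = 0.04,
                       duration_mean = 14.8, duration_sd = 9.7)
  user_counts <- any(c("n_negative", "n_positive") %in% names(clinical))
  clinical <- utils::modifyList(clin_default, clinical)
  top <- stratum_sizes[n_strata]
  if (clinical$n_negative + clinical$n_positive > top) {
    if (user_counts) {
      stop("not enough top-stratum nodes for the planted clinical correlations")
    }
    # default plan shrunk to fit a small atlas
    clinical$n_negative <- max(0L, min(clinical$n_negative, top - 1L))
    clinical$n_positive <- max(0L, min(clinical$n_positive,
                                       top - clinical$n_negative))
  }

  structure(list(
    n_nodes = n_nodes,
    n_networks = length(network_sizes),
    network_sizes = network_sizes,
    n_strata = n_strata,
    stratum_coupling_targets = stratum_coupling_targets,
    stratum_sizes = stratum_sizes,
    group_sizes = group_sizes,
    decoupling_deltas = decoupling_deltas,
    sc_density = sc_density,
    timeseries_length = as.integer(timeseries_length),
    noise_sd = noise_sd,
    seed = as.integer(seed),
    mode = mode,
    sc_weight_meanlog = sc_weight_meanlog,
    sc_weight_sdlog = sc_weight_sdlog,
    isolated_policy = isolated_policy,
    clinical = clinical,
    confound_age_shift = confound_age_shift
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d nodes, %d networks, %d strata, groups: %s, density %.3f, mode %s\n",
    x$n_nodes, x$n_networks, x$n_strata,
    paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes), collapse = " "),
    x$sc_density, x$mode))
  invisible(x)
}

# Integer apportionment by largest remainder: scales `weights` to sum to
# `total` while keeping every part >= 1.
apportion <- function(total, weights) {
  raw <- weights / sum(weights) * total
  base <- pmax(1L, floor(raw))
  while (sum(base) > total) {
    i <- which.max(base - raw)
    base[i] <- base[i] - 1L
  }
  rem <- raw - base
  while (sum(base) < total) {
    i <- which.max(rem)
    base[i] <- base[i] + 1L
    rem[i] <- -Inf
  }
  stats::setNames(as.integer(base), names(weights))
}
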