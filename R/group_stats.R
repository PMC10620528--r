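#' Omnibus three-group test with optional covariate adjustment
#'
#' Fits the linear model `outcome ~ covariates + group` and reports the
#' F statistic for the group factor (one-way ANOVA when no covariates are
#' given, ANCOVA otherwise).  Covariates are coded as in the clinical
#' convention: sex as a binary indicator, continuous covariates mean-centred.
#' An optional permutation p-value is obtained by freely permuting the group
#' labels (covariates fixed) and recomputing F.
#'
#' @param data a data.frame with a `group` factor column, the outcome and
#'   any covariate columns.
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param method `"anova"` for the parametric F p-value, `"permutation"`
#'   for a label-permutation p-value.
#' @param n_perm number of permutations when `method = "permutation"`.
#' @param seed RNG seed for the permutations.
#' @return a one-row `stat_result` data.frame: `contrast`, `statistic`,
#'   `p_value`, `direction`, `method`, `n`.
#' @export
omnibus_test <- function(data, outcome, covariates = character(),
                         method = c("anova", "permutation"),
                         n_perm = 9999, seed = NULL) {
  method <- match.arg(method)
  d <- prepare_stats_data(data, outcome, covariates)
  f_obs <- group_F(d, outcome, covariates)
  groups <- levels(d$group)
  n_by <- table(d$group)

  if (method == "anova") {
    df1 <- length(groups) - 1
    df2 <- nrow(d) - length(groups) - length(covariates)
    p <- stats::pf(f_obs, df1, df2, lower.tail = FALSE)
    tag <- if (length(covariates)) "ancova_F" else "anova_F"
  } else {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      dp <- d
      dp$group <- sample(d$group)
      if (group_F(dp, outcome, covariates) >= f_obs) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
    tag <- sprintf("permutation_F(B=%d%s)", n_perm,
                   if (is.null(seed)) "" else sprintf(", seed=%d", seed))
  }
  stat_result(contrast = paste(groups, collapse = "/"),
              statistic = f_obs, p_value = p, direction = NA_character_,
              method = tag, n = paste(n_by, collapse = "/"))
}

group_F <- function(d, outcome, covariates) {
  rhs0 <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f_full <- stats::as.formula(paste(outcome, "~", rhs0, "+ group"))
  f_red <- stats::as.formula(paste(outcome, "~", rhs0))
  fit_full <- stats::lm(f_full, data = d)
  check_full_rank(fit_full)
  fit_red <- stats::lm(f_red, data = d)
  a <- stats::anova(fit_red, fit_full)
  a$F[2]
}

check_full_rank <- function(fit) {
  alias <- is.na(stats::coef(fit))
  if (any(alias)) {
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(names(alias)[alias], collapse = ", ")))
  }
}

#' Pairwise two-group contrast
#'
#' Compares one outcome between two groups.  The default nonparametric mode
#' is a seeded permutation test of the difference in group means (two-sided);
#' `mode = "ranksum"` uses the Wilcoxon rank-sum test instead, and
#' `mode = "adjusted"` first residualises the outcome on the covariates
#' (fitted across both groups) and then permutes the residual mean
#' difference.
#'
#' @inheritParams omnibus_test
#' @param groups length-2 character vector: the contrast `a vs b`
#'   (direction is the sign of `mean(a) - mean(b)`).
#' @param mode `"nonparametric"`, `"adjusted"` or `"ranksum"`.
#' @return a one-row `stat_result` data.frame.
#' @export
pairwise_test <- function(data, outcome, groups,
                          mode = c("nonparametric", "adjusted", "ranksum"),
                          covariates = character(),
                          n_perm = 9999, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(groups) == 2)
  covs <- if (mode == "adjusted") covariates else character()
  d <- prepare_stats_data(data, outcome, covs)
  d <- d[d$group %in% groups, , drop = FALSE]
  d$group <- factor(as.character(d$group), levels = groups)
  n_by <- table(d$group)
  if (any(n_by < 3)) stop("both groups need n >= 3")

  y <- d[[outcome]]
  if (mode == "adjusted" && length(covs)) {
    fit <- stats::lm(stats::as.formula(
      paste(outcome, "~", paste(covs, collapse = " + "))), data = d)
    check_full_rank(fit)
    y <- stats::residuals(fit)
  }
  ga <- d$group == groups[1]
  delta_obs <- mean(y[ga]) - mean(y[!ga])

  if (mode == "ranksum") {
    wt <- stats::wilcox.test(y[ga], y[!ga], exact = FALSE, correct = TRUE)
    res <- stat_result(
      contrast = paste(groups, collapse = " vs "),
      statistic = unname(wt$statistic), p_value = wt$p.value,
      direction = direction_of(delta_obs),
      method = "wilcoxon_ranksum", n = paste(n_by, collapse = "/"))
    return(res)
  }

  if (!is.null(seed)) set.seed(seed)
  n_a <- sum(ga)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(y), n_a)
    delta <- mean(y[idx]) - mean(y[-idx])
    if (abs(delta) >= abs(delta_obs) - 1e-15) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (n_perm + 1)
  stat_result(
    contrast = paste(groups, collapse = " vs "),
    statistic = delta_obs, p_value = p,
    direction = direction_of(delta_obs),
    method = sprintf("permutation_meandiff(B=%d%s)%s", n_perm,
                     if (is.null(seed)) "" else sprintf(", seed=%d", seed),
                     if (mode == "adjusted") "+covariate_residualized" else ""),
    n = paste(n_by, collapse = "/"))
}

direction_of <- function(delta) {
  if (is.na(delta) || delta == 0) return("none")
  if (delta > 0) "greater" else "less"
}

#' Full post-hoc contrast battery over clusters
#'
#' Runs all three pairwise group contrasts (each patient group vs controls,
#' and patients vs patients) for every outcome in the family (typically one
#' ASFC or CSFC column per cluster) and applies a single multiplicity
#' correction across the whole family of contrasts x outcomes.
#'
#' @inheritParams pairwise_test
#' @param outcomes character vector of outcome columns (e.g. per-cluster
#'   indices).
#' @param group_levels the three group labels, reference (control) group
#'   last-vs-first convention: contrasts are `g2 vs g1`, `g3 vs g1`,
#'   `g3 vs g2` for `group_levels = c(g1, g2, g3)`.
#' @param correct `"BH"` (Benjamini-Hochberg, default) or `"none"`.
#' @return a `stat_result` data.frame with one row per outcome x contrast,
#'   including an `adjusted_p` column and an `outcome` column.
#' @export
posthoc_battery <- function(data, outcomes,
                            group_levels = c("HC", "LTLE", "RTLE"),
                            mode = "nonparametric",
                            covariates = character(),
                            correct = c("BH", "none"),
                            n_perm = 9999, seed = NULL) {
  correct <- match.arg(correct)
  stopifnot(length(group_levels) == 3)
  contrasts <- list(c(group_levels[2], group_levels[1]),
                    c(group_levels[3], group_levels[1]),
                    c(group_levels[3], group_levels[2]))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (oc in outcomes) {
    for (ct in contrasts) {
      r <- pairwise_test(data, oc, ct, mode = mode, covariates = covariates,
                         n_perm = n_perm, seed = NULL)
      r$outcome <- oc
      rows[[length(rows) + 1]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- if (correct == "BH") stats::p.adjust(out$p_value, "BH")
                    else out$p_value
  rownames(out) <- NULL
  out
}

#' Partial correlation between node coupling and a clinical variable
#'
#' Residualises both variables on the covariates with linear models (fitted
#' on complete cases) and correlates the residuals; Spearman by default, for
#' consistency with the coupling statistic itself.  If either residual
#' vector is (numerically) constant — e.g. when a covariate equals the
#' clinical variable — the correlation is reported as exactly 0 with p = 1.
#'
#' @param data data.frame containing all columns.
#' @param x,y names of the two columns to correlate (e.g. a node's coupling
#'   and seizure duration in years).
#' @param covariates covariate column names to residualise on.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return a one-row `stat_result` data.frame with the residual correlation
#'   as `statistic`.
#' @export
partial_correlation <- function(data, x, y, covariates = character(),
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  cols <- unique(c(x, y, covariates))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  if (nrow(d) < 5) stop("need at least 5 complete observations")
  if (stats::sd(d[[y]]) == 0) stop(sprintf("clinical variable %s is constant", y))
  resid_on <- function(v) {
    if (!length(covariates)) return(d[[v]] - mean(d[[v]]))
    # a covariate equal to v itself is dropped by lm (with a warning we
    # silence); the projection property then makes the partial correlation
    # of the other variable exactly zero under Pearson
    fit <- suppressWarnings(stats::lm(stats::as.formula(
      paste(v, "~", paste(covariates, collapse = " + "))), data = d))
    stats::residuals(fit)
  }
  rx <- resid_on(x)
  ry <- resid_on(y)
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
    est <- 0; p <- 1
  } else {
    ct <- suppressWarnings(stats::cor.test(rx, ry, method = method,
                                           exact = FALSE))
    est <- unname(ct$estimate); p <- ct$p.value
  }
  stat_result(contrast = sprintf("%s ~ %s | %s", x, y,
                                 if (length(covariates))
                                   paste(covariates, collapse = "+") else "-"),
              statistic = est, p_value = p,
              direction = direction_of(est),
              method = sprintf("partial_%s", method), n = as.character(nrow(d)))
}

#' Partial correlations for a set of nodes, with multiplicity correction
#'
#' @inheritParams partial_correlation
#' @param nodes character vector of coupling columns to test against `y`.
#' @param correct `"BH"` or `"none"` across the tested nodes.
#' @return a `stat_result` data.frame, one row per node, with `adjusted_p`.
#' @export
partial_correlation_battery <- function(data, nodes, y,
                                        covariates = character(),
                                        method = "spearman",
                                        correct = c("BH", "none")) {
  correct <- match.arg(correct)
  rows <- lapply(nodes, function(nd) {
    r <- partial_correlation(data, nd, y, covariates, method)
    r$node <- nd
    r
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- if (correct == "BH") stats::p.adjust(out$p_value, "BH")
                    else out$p_value
  rownames(out) <- NULL
  out
}

# ---- helpers ---------------------------------------------------------------

stat_result <- function(contrast, statistic, p_value, direction, method, n) {
  stopifnot(p_value >= 0, p_value <= 1)
  data.frame(contrast = contrast, statistic = statistic, p_value = p_value,
             direction = direction, method = method, n = n,
             stringsAsFactors = FALSE)
}

# Validate columns, coerce group to factor, code covariates (binary sex
# indicator, mean-centred continuous covariates).
prepare_stats_data <- function(data, outcome, covariates) {
  cols <- c("group", outcome, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  d <- data[, cols, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$group <- factor(as.character(d$group))
  if (nlevels(d$group) < 2) stop("need at least 2 nonempty groups")
  if (any(table(d$group) < 3)) stop("every group needs n >= 3")
  for (cv in covariates) {
    v <- d[[cv]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      lv <- unique(as.character(v))
      if (length(lv) > 2) {
        stop(sprintf("categorical covariate %s has > 2 levels; recode first", cv))
      }
      d[[cv]] <- as.numeric(as.character(v) == lv[1])
    } else {
      d[[cv]] <- v - mean(v)
    }
  }
  d
}
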