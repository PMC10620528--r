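# Independent brute-force oracles, deliberately written from first
# principles (no shared code with the package's vectorised paths).

# tie-corrected Spearman: average ranks, then Pearson from the definition
bf_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Pearson correlation from the covariance/variance-ratio definition
bf_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# elbow: perpendicular distance of every normalised curve point below the
# chord joining the endpoints, largest wins
bf_elbow <- function(wss, ks) {
  x <- (ks - ks[1]) / (ks[length(ks)] - ks[1])
  y <- (wss - wss[length(wss)]) / (wss[1] - wss[length(wss)])
  x1 <- x[1]; y1 <- y[1]; x2 <- x[length(x)]; y2 <- y[length(y)]
  d <- numeric(length(ks))
  for (i in seq_along(ks)) {
    # point-line distance, signed so that points below the chord are positive
    d[i] <- ((x2 - x1) * (y1 - y[i]) - (x1 - x[i]) * (y2 - y1)) /
      sqrt((x2 - x1)^2 + (y2 - y1)^2)
  }
  ks[which.max(d)]
}

# random symmetric matrix with zero diagonal
random_symmetric <- function(n, seed, fun = stats::rnorm) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- fun(n * (n - 1) / 2)
  m + t(m)
}

# small cached default-parameter cohort shared across test files
small_cohort_cache <- new.env(parent = emptyenv())
get_small_cohort <- function() {
  if (is.null(small_cohort_cache$cohort)) {
    cfg <- sim_config(n_nodes = 40,
                      group_sizes = c(HC = 8, LTLE = 5, RTLE = 5),
                      seed = 42)
    small_cohort_cache$cohort <- generate_cohort(cfg)
  }
  small_cohort_cache$cohort
}
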