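make_stats_data <- function(n = c(12, 10, 10), effect = 0, seed = 1) {
  set.seed(seed)
  g <- rep(c("HC", "LTLE", "RTLE"), n)
  data.frame(
    group = g,
    age = rnorm(sum(n), 30, 8),
    sex = sample(c("M", "F"), sum(n), replace = TRUE),
    education = rnorm(sum(n), 11, 3),
    y = rnorm(sum(n)) + effect * (g != "HC"),
    stringsAsFactors = FALSE)
}

test_that("omnibus F is location-invariant and detects an obvious group effect", {
  d <- make_stats_data(effect = 2, seed = 3)
  r <- omnibus_test(d, "y", covariates = c("age", "sex", "education"))
  expect_lt(r$p_value, 0.001)

  d2 <- d; d2$y <- d2$y + 100
  r2 <- omnibus_test(d2, "y", covariates = c("age", "sex", "education"))
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-9)

  # no covariates reduces to one-way ANOVA
  r3 <- omnibus_test(d, "y")
  a <- anova(lm(y ~ group, data = d))
  expect_equal(r3$statistic, a$`F value`[1], tolerance = 1e-12)
  expect_equal(r3$p_value, a$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  d <- make_stats_data(seed = 4)
  d$age2 <- d$age * 2
  expect_error(omnibus_test(d, "y", covariates = c("age", "age2")),
               "collinear.*age2")
})

test_that("permutation p-values are seeded-reproducible and match exact enumeration", {
  d <- make_stats_data(n = c(5, 5, 5), effect = 1.2, seed = 6)
  r1 <- omnibus_test(d, "y", method = "permutation", n_perm = 299, seed = 11)
  r2 <- omnibus_test(d, "y", method = "permutation", n_perm = 299, seed = 11)
  expect_identical(r1$p_value, r2$p_value)

  # two tiny groups: exact enumeration oracle over all assignments
  set.seed(8)
  da <- data.frame(group = rep(c("A", "B"), c(4, 4)),
                   y = c(rnorm(4, 1), rnorm(4)))
  obs <- mean(da$y[da$group == "A"]) - mean(da$y[da$group == "B"])
  combs <- combn(8, 4)
  exact <- mean(apply(combs, 2, function(idx) {
    abs(mean(da$y[idx]) - mean(da$y[-idx])) >= abs(obs) - 1e-15
  }))
  r3 <- pairwise_test(da, "y", c("A", "B"), n_perm = 9999, seed = 12)
  # Monte-Carlo estimate within binomial error of the exact p
  se <- sqrt(exact * (1 - exact) / 9999)
  expect_lt(abs(r3$p_value - exact), 4 * se + 2e-4)
})

test_that("pairwise contrasts are symmetric under group swap and support all modes", {
  d <- make_stats_data(effect = 1, seed = 9)
  a <- pairwise_test(d, "y", c("LTLE", "HC"), n_perm = 499, seed = 3)
  b <- pairwise_test(d, "y", c("HC", "LTLE"), n_perm = 499, seed = 3)
  expect_equal(a$statistic, -b$statistic)
  expect_identical(a$p_value, b$p_value)
  expect_true(a$direction != b$direction)

  rs <- pairwise_test(d, "y", c("LTLE", "HC"), mode = "ranksum")
  expect_lt(rs$p_value, 0.05)

  adj <- pairwise_test(d, "y", c("LTLE", "HC"), mode = "adjusted",
                       covariates = c("age", "sex"), n_perm = 499, seed = 3)
  expect_lt(adj$p_value, 0.05)
})

test_that("post-hoc battery has 3k rows with a family-wide correction", {
  cohort <- get_small_cohort()
  coupling <- cohort_coupling(cohort)
  model <- cluster_nodes(coupling[cohort$table$group == "HC", ],
                         k_range = 2:6, seed = 1, k = 5)
  wide <- cohort_stats_table(cohort$table,
                             cluster_metrics_table(cohort, model,
                                                   coupling = coupling))
  outcomes <- sprintf("asfc_%d", 1:5)
  out <- posthoc_battery(wide, outcomes, n_perm = 199, seed = 4)
  expect_equal(nrow(out), 3 * 5)
  expect_true(all(out$adjusted_p >= out$p_value - 1e-15))
  expect_equal(out$adjusted_p, p.adjust(out$p_value, "BH"))
  none <- posthoc_battery(wide, outcomes[1], correct = "none",
                          n_perm = 99, seed = 4)
  expect_equal(none$adjusted_p, none$p_value)
})

test_that("partial correlation residualises exactly and recovers planted signs", {
  set.seed(14)
  n <- 40
  d <- data.frame(age = rnorm(n, 30, 8), sex = sample(c("M", "F"), n, TRUE),
                  duration = rnorm(n, 15, 9))
  d$rho_neg <- 0.25 - 0.01 * d$duration + rnorm(n, sd = 0.02)
  d$rho_pos <- 0.20 + 0.01 * d$duration + rnorm(n, sd = 0.02)
  d$rho_null <- rnorm(n, 0.2, 0.05)

  neg <- partial_correlation(d, "rho_neg", "duration", c("age", "sex"))
  pos <- partial_correlation(d, "rho_pos", "duration", c("age", "sex"))
  expect_lt(neg$statistic, 0); expect_lt(neg$p_value, 0.01)
  expect_gt(pos$statistic, 0); expect_lt(pos$p_value, 0.01)

  # covariate equal to the clinical variable: x-residual is orthogonal to
  # duration, so the Pearson residual correlation is exactly zero
  z <- partial_correlation(d, "rho_neg", "duration", c("duration"),
                           method = "pearson")
  expect_lt(abs(z$statistic), 1e-10)

  # constant clinical variable errors
  d$flat <- 5
  expect_error(partial_correlation(d, "rho_neg", "flat"), "constant")
  expect_error(partial_correlation(d, "rho_neg", "missing_col"), "missing")

  bat <- partial_correlation_battery(d, c("rho_neg", "rho_pos", "rho_null"),
                                     "duration", c("age", "sex"))
  expect_equal(nrow(bat), 3)
  expect_equal(bat$adjusted_p, p.adjust(bat$p_value, "BH"))
})

test_that("null data give well-behaved p-values on average", {
  ps <- numeric(40)
  for (r in 1:40) {
    d <- make_stats_data(effect = 0, seed = 100 + r)
    ps[r] <- omnibus_test(d, "y")$p_value
  }
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})
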