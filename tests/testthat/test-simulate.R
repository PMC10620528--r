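test_that("sim_config validates its invariants", {
  cfg <- sim_config()
  expect_equal(cfg$n_nodes, 246L)
  expect_equal(sum(cfg$network_sizes), 246L)
  expect_equal(sum(cfg$stratum_sizes), 246L)
  expect_equal(unname(cfg$group_sizes), c(48L, 34L, 31L))
  expect_equal(cfg$stratum_coupling_targets,
               c(0.103, 0.150, 0.176, 0.201, 0.247))
  expect_error(sim_config(sc_density = 0), "sc_density")
  expect_error(sim_config(sc_density = 1.2), "sc_density")
  expect_error(sim_config(network_sizes = c(a = 10, b = 10)), "sum to n_nodes")
  expect_error(sim_config(group_sizes = c(HC = 48, LTLE = 1, RTLE = 31)),
               "at least 2")
  expect_error(sim_config(stratum_coupling_targets = c(0.9, 0.92, 0.95, 0.97, 0.999),
                          decoupling_deltas = rbind(LTLE = c(0, 0, 0, 0, -0.1),
                                                    RTLE = rep(0, 5))),
               "lie in")
  # scaled-down configs keep the partitions consistent
  small <- sim_config(n_nodes = 60)
  expect_equal(sum(small$stratum_sizes), 60L)
  expect_equal(sum(small$network_sizes), 60L)
})

test_that("generated SC matrices honour density, symmetry and weight contracts", {
  # full density: every off-diagonal entry nonzero
  full <- generate_sc(sim_config(n_nodes = 10, sc_density = 1), seed = 1)
  expect_true(all(full$values[upper.tri(full$values)] > 0))

  # default density at 246 nodes within one percentage point
  sc <- generate_sc(sim_config(), seed = 2)
  expect_lt(abs(conn_density(sc) - 0.102), 0.01)

  # symmetric, zero diagonal, nonnegative integers, heavy-tailed
  expect_equal(sc$values, t(sc$values))
  expect_equal(diag(sc$values), rep(0, 246), ignore_attr = TRUE)
  w <- sc$values[sc$values > 0]
  expect_true(all(w == round(w)) && all(w >= 1))
  expect_gt(mean(w > 5 * median(w)), 0.001)   # tail mass well beyond the median

  # determinism: same seed, bitwise-identical matrices
  expect_identical(generate_sc(sim_config(), seed = 9)$values,
                   generate_sc(sim_config(), seed = 9)$values)

  # isolation policy at a density that cannot cover all nodes
  lowcfg_err <- sim_config(n_nodes = 12, sc_density = 0.05,
                           isolated_policy = "error")
  expect_error(generate_sc(lowcfg_err, seed = 3), "no edges")
  lowcfg_fix <- sim_config(n_nodes = 12, sc_density = 0.2,
                           isolated_policy = "repair")
  for (s in 1:5) {
    scr <- generate_sc(lowcfg_fix, seed = 100 + s)
    expect_true(all(rowSums(scr$values > 0) >= 1))
  }
})

test_that("mixing calibration hits its target and agrees with grid search", {
  # target 0: weight near 0, measured rho near 0
  w0 <- calibrate_mixing(0, 245, nrep = 100, seed = 5)
  expect_lt(abs(attr(w0, "achieved_rho")), 0.02)
  expect_lt(abs(w0), 0.1)

  # high target: weight near 1
  w99 <- calibrate_mixing(0.99, 245, nrep = 100, seed = 6)
  expect_gt(w99, 0.8)
  expect_lt(abs(attr(w99, "achieved_rho") - 0.99), 0.01)

  # bisection agrees with a 1000-point grid under common random numbers
  target <- 0.3
  wb <- calibrate_mixing(target, 100, nrep = 100, seed = 7)
  set.seed(7)
  X <- matrix(rnorm(100 * 100), 100)
  EPS <- matrix(rnorm(100 * 100), 100)
  G <- t(apply(X, 1, function(x) qnorm(rank(x) / 101)))
  RX <- t(apply(X, 1, rank))
  cx <- RX - rowMeans(RX); sx <- rowSums(cx^2)
  f <- function(w) {
    RY <- t(apply(w * G + (1 - w) * EPS, 1, rank))
    cy <- RY - rowMeans(RY)
    mean(rowSums(cx * cy) / sqrt(sx * rowSums(cy^2)))
  }
  grid <- seq(0, 1, length.out = 1000)
  fg <- vapply(grid, f, numeric(1))
  wg <- grid[which.min(abs(fg - target))]
  expect_lt(abs(as.numeric(wb) - wg), diff(grid[1:2]) * 20 + 0.01)

  # a tolerance below the Monte-Carlo granularity cannot be reached
  expect_error(calibrate_mixing(0.51234, 20, nrep = 50, tol = 1e-9,
                                seed = 8), "not reached|outside")
})

test_that("planted per-node coupling is realised by the FC generator", {
  # weight-1 limit: FC is a monotone copy, coupling exactly 1
  m <- random_symmetric(15, seed = 51, fun = function(k) runif(k, 1, 9))
  sc <- conn_matrix(m, modality = "SC")
  fc1 <- generate_fc_with_target_coupling(sc, rep(1 - 1e-10, 15), seed = 52)
  rho1 <- regional_coupling(sc, fc1)$rho
  expect_equal(unname(rho1), rep(1, 15), tolerance = 1e-10)

  # symmetry contract
  expect_equal(fc1$values, t(fc1$values))

  # constant SC row is rejected with the node named
  mc <- m; mc[4, ] <- 2; mc[, 4] <- 2; diag(mc) <- 0
  expect_error(generate_fc_with_target_coupling(conn_matrix(mc, modality = "SC"),
                                                rep(0.5, 15)),
               "N004")

  # Monte-Carlo calibration: mean measured coupling ~ planted 0.25
  cfg <- sim_config(n_nodes = 50, sc_density = 0.3)
  sc50 <- generate_sc(cfg, seed = 53)
  curve <- mixing_curve(sc50, n_rows = 500)
  meas <- numeric(0)
  set.seed(54)
  for (r in 1:40) {
    scr <- generate_sc(cfg)
    fcr <- generate_fc_with_target_coupling(scr, rep(0.25, 50), curve = curve)
    meas <- c(meas, regional_coupling(scr, fcr)$rho)
  }
  expect_lt(abs(mean(meas) - 0.25), 0.02)
})

test_that("cohort generation plants the documented ground truth", {
  cohort <- get_small_cohort()
  cfg <- cohort$config
  expect_equal(length(cohort$subjects), 18)
  expect_equal(nrow(cohort$table), 18)
  expect_equal(sort(unique(cohort$table$group)), c("HC", "LTLE", "RTLE"))

  # stratum partition exhaustive and disjoint
  expect_equal(sort(as.integer(table(cohort$truth$node_stratum))),
               sort(as.integer(cfg$stratum_sizes)))

  # planted rho = stratum target - group delta away from clinical nodes
  clin <- cohort$truth$clinical$nodes
  for (g in c("HC", "LTLE", "RTLE")) {
    s_idx <- which(cohort$table$group == g)[1]
    for (st in 1:5) {
      nodes <- setdiff(names(which(cohort$truth$node_stratum == st)), clin)
      expected <- unname(cfg$stratum_coupling_targets[st] -
        (if (g == "HC") 0 else cfg$decoupling_deltas[g, st]))
      expect_equal(unname(cohort$truth$planted_rho[s_idx, nodes]),
                   rep(expected, length(nodes)), tolerance = 1e-12)
    }
  }

  # determinism of the metadata table and matrices across regeneration
  again <- generate_cohort(cfg)
  expect_identical(again$table, cohort$table)
  expect_identical(again$subjects[[3]]$sc$values, cohort$subjects[[3]]$sc$values)
  expect_identical(again$subjects[[3]]$fc$values, cohort$subjects[[3]]$fc$values)

  # null cohort: zero deltas make patient targets equal HC targets
  null_cfg <- sim_config(n_nodes = 40, group_sizes = c(HC = 4, LTLE = 3, RTLE = 3),
                         decoupling_deltas = matrix(0, 2, 5,
                           dimnames = list(c("LTLE", "RTLE"), NULL)),
                         clinical = list(beta = 0), seed = 8)
  nullco <- generate_cohort(null_cfg)
  expect_equal(max(apply(nullco$truth$planted_rho, 2, function(col)
    diff(range(col)))), 0)

  # default configuration mirrors the full cohort size
  expect_equal(sum(sim_config()$group_sizes), 113L)
})

test_that("cohorts round-trip through delimited files", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_nodes = 20, group_sizes = c(HC = 2, LTLE = 2, RTLE = 2),
                    seed = 77)
  cohort <- generate_cohort(cfg)
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$subjects), 6)
  expect_identical(back$subjects[[1]]$sc$values, cohort$subjects[[1]]$sc$values)
  expect_identical(back$subjects[[1]]$fc$values, cohort$subjects[[1]]$fc$values)
  expect_equal(back$table$group, cohort$table$group)
  expect_equal(back$truth$clinical$nodes, cohort$truth$clinical$nodes)

  # deleting one subject's SC file is detected by name
  file.remove(file.path(dir, sprintf("sc_%s.tsv", cohort$table$subject_id[3])))
  expect_error(read_cohort(dir), cohort$table$subject_id[3])
})

test_that("time-series mode realises the target FC through the Pearson chain", {
  cfg <- sim_config(n_nodes = 15, group_sizes = c(HC = 2, LTLE = 2, RTLE = 2),
                    mode = "timeseries", timeseries_length = 770, seed = 21)
  cohort <- generate_cohort(cfg)
  sub <- cohort$subjects[[1]]
  expect_equal(dim(sub$ts$values), c(770L, 15L))
  fc_emp <- fc_from_timeseries(sub$ts)
  target <- tanh(0.5 * sub$fc$values)
  ut <- upper.tri(target)
  expect_gt(cor(fc_emp$values[ut], target[ut]), 0.85)
})
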