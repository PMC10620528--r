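test_that("fc_from_timeseries matches the Pearson definition and handles exact dependence", {
  # identical and sign-flipped columns
  set.seed(7)
  base <- rnorm(30)
  ts <- timeseries_matrix(cbind(a = base, b = base, c = -base + rnorm(30, sd = 1e-8),
                                d = rnorm(30)))
  fc <- fc_from_timeseries(ts)
  expect_equal(fc$values["a", "b"], 1)
  expect_equal(fc$values["a", "c"], -1, tolerance = 1e-6)
  expect_equal(diag(fc$values), rep(0, 4), ignore_attr = TRUE)

  # 5 x 3 toy checked against the covariance/variance-ratio definition
  toy <- matrix(c(1, 4, 2, 8, 5,
                  2, 2, 7, 1, 9,
                  3, 6, 1, 4, 2), ncol = 3)
  fc2 <- fc_from_timeseries(timeseries_matrix(toy))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(fc2$values[i, j], bf_pearson(toy[, i], toy[, j]),
                 tolerance = 1e-12)
  }
})

test_that("fc_from_timeseries is permutation-equivariant and zero-fills flat nodes", {
  set.seed(11)
  X <- matrix(rnorm(40 * 6), 40, 6)
  colnames(X) <- sprintf("R%d", 1:6)
  fc <- fc_from_timeseries(timeseries_matrix(X))
  perm <- c(4, 2, 6, 1, 3, 5)
  fc_p <- fc_from_timeseries(timeseries_matrix(X[, perm]))
  expect_equal(fc_p$values, fc$values[perm, perm])

  X[, 3] <- 5  # constant region
  expect_warning(ts <- timeseries_matrix(X), "zero-variance")
  expect_warning(fc0 <- fc_from_timeseries(ts), "zero-variance")
  expect_true(all(fc0$values[3, ] == 0))
})

test_that("fisher_z is the elementwise atanh with clipping and preserved ordering", {
  m <- random_symmetric(6, seed = 3, fun = function(k) runif(k, -0.9, 0.9))
  fc <- conn_matrix(m, modality = "FC_raw")
  z <- fisher_z(fc)
  expect_equal(z$values[1, 2], atanh(m[1, 2]))
  expect_equal(z$values[lower.tri(m)], atanh(m[lower.tri(m)]))
  # r = 0 is a fixed point; r = 0.5 has the known closed form
  r5 <- matrix(0, 3, 3); r5[1, 2] <- r5[2, 1] <- 0.5
  z5 <- fisher_z(conn_matrix(r5, modality = "FC_raw"))
  expect_equal(z5$values[1, 2], 0.5493061, tolerance = 1e-6)
  expect_equal(z5$values[1, 3], 0)
  # monotone: ordering of any two off-diagonal entries preserved
  ut <- upper.tri(m)
  expect_equal(order(m[ut]), order(z$values[ut]))
  # clipping
  r1 <- matrix(0, 3, 3); r1[1, 2] <- r1[2, 1] <- 1
  expect_warning(zc <- fisher_z(conn_matrix(r1, modality = "FC_raw")), "clipped")
  expect_true(is.finite(zc$values[1, 2]))
})

test_that("proportional_threshold keeps exactly the top fraction of edges", {
  # identity at sparsity 1
  fc <- conn_matrix(random_symmetric(8, seed = 5), modality = "FC_z")
  expect_equal(proportional_threshold(fc, 1)$values, fc$values)

  # 4-node toy with 6 distinct values, sparsity 0.5: the 3 largest survive
  v <- c(0.9, -0.2, 0.4, 0.1, 0.7, -0.5)
  m <- matrix(0, 4, 4); m[upper.tri(m)] <- v; m <- m + t(m)
  thr <- proportional_threshold(conn_matrix(m, modality = "FC_z"), 0.5)
  kept <- sort(thr$values[upper.tri(thr$values)][thr$values[upper.tri(thr$values)] != 0],
               decreasing = TRUE)
  expect_equal(kept, sort(v, decreasing = TRUE)[1:3])

  # surviving entries are unchanged, symmetric result, correct density
  big <- conn_matrix(random_symmetric(246, seed = 9), modality = "FC_z")
  thr10 <- proportional_threshold(big, 0.10)
  E <- 246 * 245 / 2
  expect_equal(sum(thr10$values[upper.tri(thr10$values)] != 0), ceiling(0.10 * E))
  nz <- thr10$values != 0
  expect_equal(thr10$values[nz], big$values[nz])
  expect_equal(thr10$values, t(thr10$values))

  # idempotence at the same sparsity
  expect_equal(proportional_threshold(thr10, 0.10)$values, thr10$values)

  # absolute mode keeps large negatives that signed mode drops
  thr_abs <- proportional_threshold(conn_matrix(m, modality = "FC_z"), 0.5,
                                    mode = "absolute")
  expect_true(thr_abs$values[cbind(which(m == -0.5, arr.ind = TRUE))][1] == -0.5)

  # ties at the cutoff are reported and broken stably
  tie <- matrix(0, 4, 4); tie[upper.tri(tie)] <- c(1, 1, 1, 1, 1, 1)
  tie <- tie + t(tie)
  expect_message(tt <- proportional_threshold(conn_matrix(tie, modality = "FC_z"), 0.5),
                 "tie")
  expect_equal(sum(tt$values[upper.tri(tt$values)] != 0), 3)
})

test_that("volume discarding drops exactly the initial timepoints", {
  set.seed(2)
  ts <- timeseries_matrix(matrix(rnorm(788 * 5), 788, 5))
  out <- discard_initial_volumes(ts, 18)
  expect_equal(nrow(out$values), 770)
  expect_equal(out$values, ts$values[-(1:18), ])
  expect_identical(discard_initial_volumes(ts, 0), ts)
  short <- timeseries_matrix(matrix(rnorm(50), 10, 5))
  expect_error(discard_initial_volumes(short, 10), "cannot discard")
})

test_that("matrix and atlas I/O validates and round-trips bitwise", {
  dir <- withr::local_tempdir()
  sc <- generate_sc(sim_config(n_nodes = 20), seed = 4)
  p <- file.path(dir, "sc.tsv")
  write_conn_matrix(sc, p)
  back <- read_conn_matrix(p, modality = "SC")
  expect_identical(back$values, sc$values)

  # negative SC entry rejected with the node named
  m <- sc$values; m[2, 5] <- m[5, 2] <- -3
  expect_error(conn_matrix(m, modality = "SC"), "negative.*N002")

  # asymmetry rejected
  m2 <- sc$values; m2[1, 2] <- m2[1, 2] + 1
  expect_error(conn_matrix(m2, modality = "SC"), "asymmetric")

  # atlas round trip and missing-node validation
  atl <- atlas_labels(sc$node_labels, paste0("r", 1:20),
                      rep(c("visual", "limbic"), 10), rep(c("L", "R"), 10))
  ap <- file.path(dir, "atlas.tsv")
  write_atlas(atl, ap)
  expect_equal(read_atlas(ap)$network, atl$network)
  expect_error(read_atlas(ap, expect_nodes = c(sc$node_labels, "N999")), "N999")

  # label mismatch between a matrix file and the expected node set
  expect_error(read_conn_matrix(p, expect_labels = sprintf("X%03d", 1:20)),
               "labels.*do not match")
})
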