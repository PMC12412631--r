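test_that("block delta is the difference of windowed means", {
  fs <- 10
  t <- seq(0, 60, by = 1 / fs)
  expect_equal(block_delta(rep(2, length(t)), 20, fs, time = t), 0)

  step <- ifelse(t >= 27 & t < 38, 3, 0)  # constant c on [onset+7, onset+18)
  expect_equal(block_delta(step, 20, fs, time = t), 3)

  ramp <- 0.1 * t + sin(t / 3)
  a <- t >= 27 & t < 38
  b <- t >= 18 & t < 20
  expect_equal(block_delta(ramp, 20, fs, time = t),
               mean(ramp[a]) - mean(ramp[b]), tolerance = 1e-12)
  expect_error(block_delta(ramp, 55, fs, time = t), "cover")
})

test_that("t statistics follow the mean-over-standard-error definition", {
  expect_equal(tstat(c(1.5, -1.5))$t, 0)
  out <- tstat(c(1, 2, 3))
  expect_equal(out$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(out$mean, 2)
  expect_equal(out$se, 1 / sqrt(3), tolerance = 1e-12)
  deg <- tstat(c(2, 2, 2))
  expect_true(deg$degenerate)
  expect_identical(deg$t, Inf)
})

test_that("t-critical reproduces the group-map threshold", {
  expect_equal(round(t_critical(17, 0.05), 2), 2.12)
  expect_equal(t_critical(17, 1), 0)
  expect_equal(t_critical(1e6, 0.05), qnorm(0.975), tolerance = 1e-3)
  expect_error(t_critical(1), "at least 2")
})

test_that("ROI vertex selection applies the two-stage rule", {
  mk <- function(vals, surface = rep("brain", length(vals))) {
    list(values = list(`760` = matrix(vals, 1)),
         vertices = data.frame(vertex_id = seq_along(vals), surface = surface))
  }
  # uniform map: nothing strictly exceeds the stage-1 mean
  expect_length(select_roi_vertices(mk(rep(0.5, 6)), 1), 0)
  # two-level map: only the high level survives stage 2
  S2 <- mk(c(0.02, 0.02, 0.5, 0.5, 0.5, 0.001) * 2)
  expect_identical(select_roi_vertices(S2, 1), 3:5)
  # threshold above everything
  expect_error(select_roi_vertices(mk(rep(0.5, 4)), 1, threshold = 2),
               "threshold")
})

test_that("max-t selection honours chromophore direction and tie rule", {
  tv <- c(`3` = 1.0, `7` = 2.5, `9` = 2.5)
  expect_equal(select_max_t(tv, "HbO"), 7L)
  expect_equal(select_max_t(c(`4` = -3, `2` = 1, `8` = 0.5), "HbR"), 4L)
  expect_equal(select_max_t(c(`12` = 0.3), "HbO"), 12L)
  expect_error(select_max_t(numeric(0)), "no unpruned")
  # random tables equal an exhaustive scan
  set.seed(9)
  for (i in 1:20) {
    tv <- round(rnorm(8), 2)
    names(tv) <- sample(100, 8)
    sel <- select_max_t(tv, "HbO")
    best <- max(tv)
    expect_equal(unname(tv[as.character(sel)]), best)
    expect_equal(sel, min(as.integer(names(tv)[tv == best])))
  }
})

test_that("paired t test matches hand computation and symmetry", {
  a <- c(1, 2, 3, 4)
  same <- paired_ttest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  b <- a - c(1, 2, 3, 3)  # differences 1,2,3 on the first three pairs
  out <- paired_ttest(c(2, 4, 6), c(1, 2, 3))
  expect_equal(out$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)

  swap <- paired_ttest(c(1, 2, 3), c(2, 4, 6))
  expect_equal(swap$t, -out$t)
  expect_equal(swap$p, out$p)
  expect_error(paired_ttest(c(1, NA), c(2, 3)), "pairs")
  # one-sample t against zero equals tstat on the same data
  z <- c(0.4, -0.1, 0.9, 0.3)
  expect_equal(paired_ttest(z, rep(0, 4))$t, tstat(z)$t, tolerance = 1e-12)
})

test_that("group summary averages subject block-averages per channel", {
  m <- rbind(c(1, 5, NA), c(3, 5, NA))
  out <- group_summary(m)
  expect_equal(out$mean[1], 2)
  expect_equal(out$se[1], 1)
  expect_equal(out$t[1], 2)
  expect_true(out$degenerate[2])
  expect_identical(out$t[2], Inf)
  expect_true(is.na(out$t[3]))
  expect_equal(out$n, c(2L, 2L, 0L))
  set.seed(10)
  r <- matrix(rnorm(50), 10, 5)
  g <- group_summary(r)
  for (k in 1:5) {
    expect_equal(g$t[k], mean(r[, k]) / (sd(r[, k]) / sqrt(10)),
                 tolerance = 1e-12)
  }
})

test_that("cluster permutation groups channels by the adjacency radius", {
  pos <- cbind(seq(0, 190, by = 10), 0)  # 20 channels in a 10 mm line
  set.seed(11)
  X <- matrix(rnorm(15 * 20, 0, 0.3), 15, 20)
  X[, 5:9] <- X[, 5:9] + 2  # strong contiguous effect
  out <- cluster_permutation(pos, X, radius = 33, alpha = 0.05,
                             n_perm = 500, seed = 2)
  expect_equal(out$t_crit, t_critical(15, 0.05))
  expect_true(any(out$cluster_p <= 1 / 501 + 1e-12))
  expect_true(all(out$mask[5:9]))
  big <- out$clusters[[which.min(out$cluster_p)]]
  expect_true(all(5:9 %in% big))

  # radius 0 degenerates to per-channel (singleton) clusters
  out0 <- cluster_permutation(pos, X, radius = 0, n_perm = 100, seed = 3)
  expect_true(all(lengths(out0$clusters) == 1))

  # enlarging the radius can only merge clusters, never split them
  out_small <- cluster_permutation(pos, X, radius = 10, n_perm = 50, seed = 4)
  out_big <- cluster_permutation(pos, X, radius = 60, n_perm = 50, seed = 4)
  expect_lte(length(out_big$clusters), length(out_small$clusters))
  expect_error(cluster_permutation(pos, X, n_perm = 0), "n_perm")

  # an isolated supra-threshold channel forms a singleton cluster
  X2 <- matrix(rnorm(15 * 20, 0, 0.2), 15, 20)
  X2[, 1] <- X2[, 1] + 2
  out2 <- cluster_permutation(pos, X2, radius = 5, n_perm = 200, seed = 5)
  idx <- vapply(out2$clusters, function(cl) 1 %in% cl, logical(1))
  expect_true(any(idx))
  expect_true(all(lengths(out2$clusters[idx]) == 1))
})

test_that("per-channel rejection under the null stays near alpha", {
  # quick sanity check at reduced size; the full family-wise calibration
  # runs in the acceptance suite
  pos <- cbind(seq(0, 190, by = 10), 0)
  set.seed(12)
  rej <- vapply(1:60, function(r) {
    X <- matrix(rnorm(15 * 20), 15, 20)
    out <- cluster_permutation(pos, X, radius = 33, n_perm = 100, seed = r)
    any(out$cluster_p <= 0.05)
  }, logical(1))
  expect_lt(mean(rej), 0.2)
})
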