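# Macrostate assignment: superposition, clustering, MSM estimation,
# coarse graining, CK test and per-state statistics.

test_that("Kabsch superposition is exact under rigid motion", {
  ref <- random_structure(30, seed = 101)
  expect_equal(kabsch_superpose(ref, ref)$rmsd, 0, tolerance = 1e-12)
  moved <- ref %*% t(rotation_matrix_z(pi / 2)) +
    matrix(c(5, -3, 8), 30, 3, byrow = TRUE)
  expect_lt(kabsch_superpose(moved, ref)$rmsd, 1e-10)
  expect_error(kabsch_superpose(moved[1:10, ], ref), "mismatch")
})

test_that("Kabsch RMSD matches a brute-force rotational search", {
  ref <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE)
  frame <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 1), 3, 3, byrow = TRUE)
  r_kabsch <- kabsch_superpose(frame, ref)$rmsd
  r_brute <- bruteforce_min_rmsd(frame, ref)
  expect_equal(r_kabsch, r_brute, tolerance = 1e-6)
  # a larger random perturbation case
  set.seed(7)
  frame2 <- ref + matrix(rnorm(9, sd = 0.3), 3, 3)
  expect_equal(kabsch_superpose(frame2, ref)$rmsd,
               bruteforce_min_rmsd(frame2, ref), tolerance = 1e-6)
})

test_that("feature pipeline is invariant to rigid motion of all frames", {
  ref <- random_structure(40, seed = 102)
  set.seed(103)
  frames <- lapply(1:5, function(i) ref + matrix(rnorm(120, sd = 0.5), 40, 3))
  s1 <- kabsch_rmsd_series(frames, ref)
  rot <- rotation_matrix_z(1.1)
  frames_moved <- lapply(frames, function(f)
    f %*% t(rot) + matrix(c(-4, 9, 2), 40, 3, byrow = TRUE))
  s2 <- kabsch_rmsd_series(frames_moved, ref)
  expect_equal(s1[[1]], s2[[1]], tolerance = 1e-9)
})

test_that("1-D k-means clustering approaches the exact DP optimum", {
  # exact zero-variance cases
  vals <- rep(c(1, 5, 9), each = 10)
  mm <- cluster_features(list(vals), k = 3, seed = 1)
  expect_equal(mm$wcss, 0)
  expect_equal(mm$centers, c(1, 5, 9))
  # two well-separated blobs split perfectly
  set.seed(4)
  blobs <- c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1))
  m2 <- cluster_features(list(blobs), k = 2, seed = 1)
  expect_equal(m2$assignments[[1]], rep(1:2, each = 50))
  # general case within 1 % of the exact dynamic-programming optimum
  set.seed(9)
  x <- runif(200)
  m5 <- cluster_features(list(x), k = 5, seed = 1, nstart = 25)
  expect_lte(m5$wcss, dp_kmeans_1d(x, 5) * 1.01)
  # determinism given the seed
  m5b <- cluster_features(list(x), k = 5, seed = 1, nstart = 25)
  expect_identical(m5$assignments, m5b$assignments)
  expect_error(cluster_features(list(1:3), k = 10), "exceeds")
})

test_that("MSM estimation recovers exact chains", {
  # deterministic 3-cycle: permutation matrix, uniform stationary
  cyc <- rep(1:3, 400)
  m <- build_msm(cyc, lag = 1)
  expect_equal(sort(m$transition_matrix[m$transition_matrix > 0.5]),
               rep(1, 3))
  expect_equal(m$stationary, rep(1 / 3, 3), tolerance = 1e-12)
  # rows sum to one within 1e-12, stationarity within 1e-10
  expect_lt(max(abs(rowSums(m$transition_matrix) - 1)), 1e-12)
  expect_lt(max(abs(m$stationary %*% m$transition_matrix - m$stationary)),
            1e-10)
  # two-state chain, analytic stationary distribution (2/3, 1/3)
  set.seed(11)
  n <- 1e5
  s <- integer(n); s[1] <- 1
  for (t in 1:(n - 1)) {
    pswitch <- if (s[t] == 1) 0.1 else 0.2
    s[t + 1] <- if (runif(1) < pswitch) 3 - s[t] else s[t]
  }
  m2 <- build_msm(s, lag = 1)
  expect_equal(m2$stationary, c(2 / 3, 1 / 3), tolerance = 0.02)
  expect_lt(max(abs(m2$stationary %*% m2$transition_matrix - m2$stationary)),
            1e-10)
  expect_error(build_msm(rep(1, 100), lag = 1), "disconnected")
})

test_that("coarse graining recovers planted metastable blocks", {
  set.seed(5)
  # 9 microstates in 3 blocks; intra-block hopping 0.98 total
  n_micro <- 9
  blocks <- rep(1:3, each = 3)
  P <- matrix(0.02 / 6, n_micro, n_micro)
  for (i in 1:n_micro) {
    mates <- which(blocks == blocks[i])
    P[i, mates] <- 0.98 / 3
    P[i, -mates] <- 0.02 / 6
  }
  # simulate and rebuild
  n <- 4e4
  s <- integer(n); s[1] <- 1
  for (t in 1:(n - 1)) s[t + 1] <- sample.int(n_micro, 1, prob = P[s[t], ])
  msm <- build_msm(s, lag = 1)
  means <- stats::setNames(c(2, 2.2, 1.8, 8, 8.3, 7.9, 14, 14.5, 13.6),
                           1:9)
  macro <- coarse_grain_label(msm, 3, means, seed = 5)
  grp <- macro$macro_of_micro[as.character(1:9)]
  expect_equal(unname(grp), blocks)
  expect_equal(sum(macro$populations), 1, tolerance = 1e-9)
  expect_true(macro$mean_rmsd["folded"] < macro$mean_rmsd["intermediate"])
  expect_true(macro$mean_rmsd["intermediate"] < macro$mean_rmsd["unfolded"])
})

test_that("four-macrostate models merge the two middle states", {
  set.seed(6)
  n_micro <- 8
  blocks <- rep(1:4, each = 2)
  P <- matrix(0.02 / 6, n_micro, n_micro)
  for (i in 1:n_micro) {
    mates <- which(blocks == blocks[i])
    P[i, mates] <- 0.98 / 2
    P[i, -mates] <- 0.02 / 6
  }
  n <- 4e4
  s <- integer(n); s[1] <- 1
  for (t in 1:(n - 1)) s[t + 1] <- sample.int(n_micro, 1, prob = P[s[t], ])
  msm <- build_msm(s, lag = 1)
  means <- stats::setNames(c(2, 2, 6, 6, 9, 9, 15, 15), 1:8)
  macro <- coarse_grain_label(msm, 4, means, seed = 6)
  expect_equal(macro$labels, c("folded", "intermediate", "unfolded"))
  expect_equal(unname(macro$mean_rmsd["folded"]), 2, tolerance = 0.2)
  expect_equal(unname(macro$mean_rmsd["unfolded"]), 15, tolerance = 0.2)
  # merged intermediate sits between the two source blocks
  expect_gt(macro$mean_rmsd["intermediate"], 6 - 0.2)
  expect_lt(macro$mean_rmsd["intermediate"], 9 + 0.2)
  expect_equal(length(unique(macro$macro_of_micro)), 3)
})

test_that("Chapman-Kolmogorov deviations separate Markov from non-Markov", {
  # exact two-state Markov chain: deviations within the sampling bound
  set.seed(13)
  n <- 1e5
  s <- integer(n); s[1] <- 1
  for (t in 1:(n - 1)) {
    pswitch <- if (s[t] == 1) 0.05 else 0.1
    s[t + 1] <- if (runif(1) < pswitch) 3 - s[t] else s[t]
  }
  ck <- ck_test(s, lag = 2, factors = c(1, 2, 3, 5))
  expect_equal(ck$deviation[ck$factor == 1], 0, tolerance = 1e-12)
  expect_true(all(ck$deviation <= ck$sampling_bound))
  # deterministic period-4 oscillation is strongly non-Markov at lag 1
  osc <- rep(c(1, 1, 2, 2), 2500)
  ck2 <- ck_test(osc, lag = 1, factors = 2)
  expect_gt(ck2$deviation, ck2$sampling_bound)
  expect_error(ck_test(s[1:10], lag = 5, factors = 5), "insufficient")
})

test_that("B-factors recover planted isotropic jitter", {
  base <- random_structure(50, seed = 2)
  expect_warning(b0 <- per_residue_bfactors(list(base), seq_len(50)),
                 "single-frame")
  expect_true(all(b0 == 0))
  # identical frames: zero fluctuation
  b1 <- per_residue_bfactors(list(base, base, base), seq_len(50))
  expect_lt(max(b1), 1e-18)
  # atom 7 jittered with per-axis variance 0.04 A^2: B = 8 pi^2 * 0.04
  set.seed(2)
  frames <- lapply(1:4000, function(i) {
    f <- base
    f[7, ] <- f[7, ] + rnorm(3, 0, 0.2)
    f
  })
  b <- per_residue_bfactors(frames, seq_len(50))
  expect_equal(unname(b[7]), 8 * pi^2 * 0.04, tolerance = 0.05)
  # residue B is the mean over its backbone atoms
  resid4 <- rep(1:10, each = 5)
  b4 <- per_residue_bfactors(frames[1:200], resid4)
  msf_atoms <- per_residue_bfactors(frames[1:200], seq_len(50))
  expect_equal(unname(b4[2]), mean(msf_atoms[6:10]))
})

test_that("state frame sampling is reproducible and exhaustive", {
  set.seed(17)
  assign_ <- sample(1:3, 1e4, replace = TRUE)
  idx <- sample_state_frames(assign_, state = 2, n = 100, seed = 17)
  expect_length(idx, 100)
  expect_true(all(assign_[idx] == 2))
  expect_identical(idx, sample_state_frames(assign_, 2, 100, seed = 17))
  # independent re-implementation of the same seeded sampling contract
  pool <- which(assign_ == 2)
  set.seed(17)
  expect_identical(idx, sort(sample(pool, 100)))
  # n >= available returns everything in index order
  small <- c(1, 2, 1, 1, 2)
  expect_identical(sample_state_frames(small, 2, 10, seed = 1), c(2L, 5L))
  expect_error(sample_state_frames(small, 9, 5), "empty")
})

test_that("hidden-Markov synthetic series round-trips through the pipeline", {
  macro_T <- matrix(c(0.98, 0.02, 0.00,
                      0.01, 0.98, 0.01,
                      0.00, 0.02, 0.98), 3, 3, byrow = TRUE)
  emissions <- cbind(mean = c(2, 8, 14), sd = c(1, 1, 1))
  hm <- gen_markov_feature_series(macro_T, emissions, n_traj = 2,
                                  n_frames = 10000, seed = 23)
  micro <- cluster_features(hm$series, k = 50, seed = 23)
  msm <- build_msm(micro, lag = 10)
  means <- stats::setNames(micro$centers, seq_len(micro$k))
  macro <- coarse_grain_label(msm, 3, means, seed = 23)
  pred <- unlist(assign_macrostates(macro, micro))
  truth <- unlist(hm$labels)
  ok <- !is.na(pred)
  expect_gt(mean(pred[ok] == truth[ok]), 0.95)
  emp <- tabulate(truth, 3) / length(truth)
  expect_lt(max(abs(macro$populations - emp)), 0.05)
})
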