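mk_two_cluster <- function(n = 60, p = 15, sep = 1.5, noise = 1, seed = 1) {
  set.seed(seed)
  mu <- rep(c(0, sep), each = n / 2)
  X <- matrix(rnorm(n * p, mu, noise), n, p)
  rownames(X) <- sprintf("s%02d", seq_len(n))
  X
}
ari <- function(a, b) igraph::compare(as.integer(factor(a)),
                                      as.integer(factor(b)),
                                      method = "adjusted.rand")

test_that("affinity kernel honours its invariants", {
  X <- mk_two_cluster(seed = 2)
  W <- view_affinity(X, K = 10)
  expect_lt(max(abs(W - t(W))), 1e-10)
  expect_true(all(W >= 0) && all(diag(W) > 0))
  # duplicate subjects attain the maximal affinity exp(0) = 1
  X2 <- rbind(X, dup = X[1, ])
  rownames(X2) <- c(rownames(X), "dup")
  W2 <- view_affinity(X2, K = 10)
  expect_equal(unname(W2["s01", "dup"]), 1)
  # scale invariance of the standardized-Euclidean metric
  W3 <- view_affinity(X * 2, K = 10)
  expect_lt(max(abs(unclass(W) - unclass(W3))), 1e-8)
  expect_error(view_affinity(X, K = nrow(X)), "smaller")
  expect_warning(view_affinity(matrix(1, 10, 3,
    dimnames = list(sprintf("s%d", 1:10), NULL)), K = 3), "constant view")
})

test_that("fusion preserves row-stochastic status matrices at every step", {
  X1 <- mk_two_cluster(seed = 3); X2 <- mk_two_cluster(seed = 4)
  a1 <- view_affinity(X1, K = 10); a2 <- view_affinity(X2, K = 10)
  # manual iteration to inspect intermediate states
  np <- csmomics:::normalize_p; ns <- csmomics:::normalize_s
  P <- list(np(unclass(a1)), np(unclass(a2)))
  S <- list(ns(unclass(a1), 10), ns(unclass(a2), 10))
  for (it in 1:5) {
    for (v in 1:2) {
      Q <- S[[v]] %*% P[[3 - v]] %*% t(S[[v]])
      P[[v]] <- np((Q + t(Q)) / 2)
      expect_lt(max(abs(rowSums(P[[v]]) - 1)), 1e-8)
    }
  }
  f <- snf_fuse(list(a1, a2), K = 10, t = 20)
  for (Pv in f$per_view_p)
    expect_lt(max(abs(rowSums(Pv) - 1)), 1e-8)
  expect_lt(max(abs(f$fused - t(f$fused))), 1e-10)
  expect_lt(f$converged_delta, 1e-4)
  expect_error(snf_fuse(list(a1)), "two views")
})

test_that("identical views reduce fusion to self-diffusion", {
  X <- mk_two_cluster(seed = 5)
  a <- view_affinity(X, K = 10)
  f <- snf_fuse(list(a, a), K = 10, t = 20)
  ref <- csmomics:::self_diffuse(unclass(a), K = 10, t = 20)
  expect_lt(max(abs(f$fused - ref)), 1e-10)
})

test_that("fusion is permutation-equivariant", {
  X1 <- mk_two_cluster(seed = 6); X2 <- mk_two_cluster(seed = 7)
  a1 <- view_affinity(X1, K = 10); a2 <- view_affinity(X2, K = 10)
  f <- suppressWarnings(snf_fuse(list(a1, a2), K = 10, t = 5)$fused)
  perm <- sample(nrow(X1))
  b1 <- view_affinity(X1[perm, ], K = 10)
  b2 <- view_affinity(X2[perm, ], K = 10)
  g <- suppressWarnings(snf_fuse(list(b1, b2), K = 10, t = 5)$fused)
  expect_equal(g, f[rownames(g), colnames(g)], tolerance = 1e-10)
})

test_that("spectral clustering recovers planted partitions", {
  # disconnected blocks: exact recovery
  W <- matrix(0, 6, 6); W[1:3, 1:3] <- 0.8; W[4:6, 4:6] <- 0.8; diag(W) <- 1
  rownames(W) <- colnames(W) <- sprintf("s%d", 1:6)
  lab <- spectral_cluster(W, 2)
  expect_equal(length(unique(lab[1:3])), 1)
  expect_equal(length(unique(lab[4:6])), 1)
  expect_false(lab[1] == lab[4])
  expect_equal(unname(spectral_cluster(W, 1)), rep(1L, 6))
  expect_error(spectral_cluster(W, 10), "exceeds")
  # strongly separated 4-cluster structure: perfect ARI across seeds
  for (seed in 1:3) {
    set.seed(seed)
    mu <- rep(c(0, 6, 12, 18), each = 10)
    X <- matrix(rnorm(40 * 5, mu, 0.5), 40, 5)
    rownames(X) <- sprintf("s%d", 1:40)
    lab4 <- spectral_cluster(unclass(view_affinity(X, K = 5)), 4)
    expect_equal(ari(lab4, rep(1:4, each = 10)), 1)
  }
})

test_that("fusing noisy views of shared structure helps clustering", {
  ok <- 0
  for (seed in 1:5) {
    X1 <- mk_two_cluster(sep = 1, noise = 1, seed = 100 + seed)
    X2 <- mk_two_cluster(sep = 1, noise = 1, seed = 200 + seed)
    truec <- rep(1:2, each = 30)
    a1 <- view_affinity(X1, K = 10); a2 <- view_affinity(X2, K = 10)
    f <- snf_fuse(list(a1, a2), K = 10)
    a_f <- ari(spectral_cluster(f$fused, 2), truec)
    a_1 <- ari(spectral_cluster(csmomics:::self_diffuse(unclass(a1), 10), 2), truec)
    a_2 <- ari(spectral_cluster(csmomics:::self_diffuse(unclass(a2), 10), 2), truec)
    if (a_f >= max(a_1, a_2) - 0.05) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("concordance is 1 for the fused network itself and ~0 for noise", {
  X <- mk_two_cluster(seed = 9)
  a <- view_affinity(X, K = 10)
  f <- snf_fuse(list(a, view_affinity(mk_two_cluster(seed = 10), K = 10)),
                K = 10)
  expect_equal(view_concordance(f, f), 1)
  # unrelated random structure: concordance near zero
  vals <- numeric(5)
  for (seed in 1:5) {
    Xr <- matrix(rnorm(60 * 15), 60, 15,
                 dimnames = list(rownames(X), NULL))
    set.seed(seed)
    vals[seed] <- view_concordance(view_affinity(Xr, K = 10), f)
  }
  expect_lt(mean(vals), 0.1)
})

test_that("deviation Z-scores measure distance from the survivor profile", {
  set.seed(12)
  n_s <- 40; n_ns <- 30
  ids <- sprintf("s%03d", seq_len(n_s + n_ns))
  X <- matrix(rnorm((n_s + n_ns) * 3), n_s + n_ns, 3,
              dimnames = list(ids, c("A", "B", "C")))
  subjects <- data.frame(
    subject_id = ids,
    outcome = rep(c("S", "NS"), c(n_s, n_ns)),
    time_to_event_days = c(rep(10L, n_s), rep(c(2L, 5L, 9L), each = 10)),
    stringsAsFactors = FALSE)
  # shift the early-death stratum by exactly one survivor SD on analyte A
  sd_a <- sd(X[1:n_s, "A"]); mu_a <- mean(X[1:n_s, "A"])
  early <- ids[(n_s + 1):(n_s + 10)]
  X[early, "A"] <- mu_a + sd_a + (X[early, "A"] - mean(X[early, "A"])) * 0
  z <- deviation_zscores(X, subjects)
  za <- z[z$analyte_id == "A", ]
  expect_equal(za$z[za$stratum == "<=3d"], 1, tolerance = 1e-10)
  # a stratum drawn from the survivor distribution sits near zero
  expect_lt(abs(za$z[za$stratum == ">7d"]), 1)
  expect_equal(sort(unique(z$stratum)), sort(c("<=3d", "4-7d", ">7d")))
})

test_that("an early-death severity gradient shows in the Z profile", {
  ds <- generate_cohort(cohort_config(n_pairs = 60, blocks = list(
    metabolite = list(n_analytes = 30, n_differential = 10)),
    delta_range = c(0.8, 0.8), lod_quantile = 0, low_detect_frac = 0,
    n_corr_pairs = 0, seed = 15))
  # amplify the planted shift for early deaths to emulate severity
  lx <- log10(ds$matrices$metabolite$values)
  early <- ds$subjects$outcome == "NS" & ds$subjects$time_to_event_days <= 3
  diff_ids <- ds$truth$differential_set$metabolite
  sgn <- sign(ds$truth$effect_sizes[diff_ids])
  lx[early, diff_ids] <- lx[early, diff_ids] +
    matrix(0.4 * sgn, sum(early), length(diff_ids), byrow = TRUE)
  z <- deviation_zscores(lx, ds$subjects)
  m_early <- mean(abs(z$z[z$stratum == "<=3d" & z$analyte_id %in% diff_ids]))
  m_late <- mean(abs(z$z[z$stratum == ">7d" & z$analyte_id %in% diff_ids]))
  expect_gt(m_early, m_late)
})

test_that("cluster characterization reports composition and planted features", {
  ds <- generate_cohort(cohort_config(n_pairs = 40, blocks = list(
    metabolite = list(n_analytes = 30, n_differential = 8)),
    delta_range = c(1.2, 1.2), lod_quantile = 0, low_detect_frac = 0,
    n_corr_pairs = 0, seed = 16))
  pb <- prep_block(ds)
  X <- pb$proc$values
  oc <- pb$outcome
  # labels identical to outcome: pure compositions
  ch <- cluster_characterization(X, setNames(as.integer(factor(oc)),
                                             names(oc)), oc)
  expect_equal(sort(ch$composition$ns_fraction), c(0, 1))
  # the NS cluster's top features overlap the planted differential set
  ns_cl <- ch$composition$cluster[ch$composition$ns_fraction == 1]
  top <- ch$top_features$feature[ch$top_features$cluster == ns_cl]
  planted <- ds$truth$differential_set$metabolite
  jac <- length(intersect(top, planted)) / length(union(top, planted))
  expect_gt(jac, 0.3)
  # random labels give compositions near prevalence
  set.seed(1)
  rnd <- setNames(sample(1:2, length(oc), TRUE), names(oc))
  ch2 <- cluster_characterization(X, rnd, oc)
  expect_true(all(abs(ch2$composition$ns_fraction - 0.5) < 0.25))
})
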