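mk_mat <- function(values, block = "metabolite", lod = NULL) {
  analyte_matrix(block, values, rep("amino acid", ncol(values)), lod = lod)
}

test_that("CV filter applies the 30% rule on raw QC replicates", {
  v <- matrix(1, 6, 3, dimnames = list(sprintf("s%d", 1:6), c("A", "B", "C")))
  qc <- cbind(A = c(1, 1, 1), B = c(1, 2, 3), C = c(10, 10.5, 9.5))
  grp <- rep(c("NS", "S"), 3)
  res <- cv_detection_filter(mk_mat(v), qc, grp)
  rep_ <- res$report
  expect_equal(rep_$cv[rep_$analyte_id == "A"], 0)
  expect_equal(rep_$cv[rep_$analyte_id == "B"], 0.5)  # sd 1 / mean 2
  expect_true(rep_$retained[rep_$analyte_id == "A"])
  expect_false(rep_$retained[rep_$analyte_id == "B"])
  expect_match(rep_$reasons[rep_$analyte_id == "B"], "cv_fail")
  expect_identical(colnames(res$matrix$values), c("A", "C"))
  # every removal carries a reason; counts are auditable
  expect_true(all(nzchar(rep_$reasons[!rep_$retained])))
  expect_equal(sum(rep_$retained) + sum(!rep_$retained), nrow(rep_))
})

test_that("detection in either group suffices", {
  set.seed(1)
  n <- 40
  grp <- rep(c("NS", "S"), each = n / 2)
  v <- matrix(runif(n * 2) + 1, n, 2, dimnames = list(NULL, c("X", "Y")))
  # X: 85% detected in NS, 10% in S -> retained under the either-group rule
  v[1:3, 1] <- NA                          # NS detection 17/20 = 85%
  v[(n / 2 + 1):(n - 2), 1] <- NA          # S detection 2/20 = 10%
  # Y: 50% in both -> removed
  v[seq(1, n, by = 2), 2] <- NA
  qc <- rbind(X = c(1, 1.01, 0.99), Y = c(1, 1.01, 0.99))
  res <- cv_detection_filter(mk_mat(v), t(qc), grp)
  expect_true(res$report$retained[res$report$analyte_id == "X"])
  expect_false(res$report$retained[res$report$analyte_id == "Y"])
  expect_match(res$report$reasons[res$report$analyte_id == "Y"],
               "detection_fail")
})

test_that("joint CV+detection filtering equals sequential application", {
  set.seed(42)
  ds <- generate_cohort(cohort_config(n_pairs = 15, blocks = list(
    metabolite = list(n_analytes = 60, n_differential = 0)),
    cv_fail_frac = 0.3, low_detect_frac = 0.2, seed = 8))
  grp <- setNames(ds$subjects$outcome, ds$subjects$subject_id)
  m <- ds$matrices$metabolite
  joint <- cv_detection_filter(m, ds$qc_samples, grp)
  # sequential: CV-only (detect_min 0) then detection-only
  s1 <- cv_detection_filter(m, ds$qc_samples, grp, detect_min = 0)
  s2 <- cv_detection_filter(s1$matrix, ds$qc_samples, grp, cv_max = Inf)
  expect_identical(colnames(joint$matrix$values), colnames(s2$matrix$values))
})

test_that("LOD/2 imputation fills exactly the masked cells", {
  v <- matrix(c(1, NA, 3, NA, NA, NA), 3, 2, dimnames = list(NULL, c("A", "B")))
  out <- impute_lod(mk_mat(v, lod = c(0.2, 4)))
  expect_equal(unname(out$values[2, "A"]), 0.1)
  expect_equal(unname(out$values[c(1, 3), "A"]), c(1, 3))
  expect_equal(unname(out$values[, "B"]), c(2, 2, 2))
  # identity when nothing is missing
  v2 <- matrix(1:4, 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_identical(impute_lod(mk_mat(v2, lod = c(1, 1)))$values, v2)
})

test_that("protein missingness filter uses the >20% rule", {
  n <- 92
  v <- matrix(1, n, 3, dimnames = list(NULL, c("P1", "P2", "P3")))
  v[1:19, 1] <- NA  # 19/92 = 20.7% -> removed
  v[1:18, 2] <- NA  # 18/92 = 19.6% -> retained
  res <- protein_missingness_filter(mk_mat(v, block = "protein"))
  expect_identical(colnames(res$matrix$values), c("P2", "P3"))
  expect_identical(res$report$reasons[1], "missingness_fail")
  vbad <- matrix(c(NA, 1, NA, 1), 2,
                 dimnames = list(NULL, c("P1", "P2")))
  expect_error(protein_missingness_filter(
    mk_mat(vbad, block = "protein"), max_missing = 0), "no analytes")
})

test_that("kNN imputation averages the nearest subjects", {
  # identity with no missing values
  v <- matrix(runif(12) + 1, 4, 3, dimnames = list(sprintf("s%d", 1:4), NULL))
  expect_identical(knn_impute(mk_mat(v, block = "protein"), k = 2)$values, v)
  # a twin donates its value at k = 1
  v2 <- rbind(c(1, 2, 3), c(1, 2, NA), c(9, 9, 9), c(8, 8, 8))
  colnames(v2) <- c("a", "b", "c")
  out <- knn_impute(mk_mat(v2, block = "protein"), k = 1)
  expect_equal(unname(out$values[2, "c"]), 3)
  # hand-computed neighbour means on a 4x3 toy
  v3 <- rbind(c(1, 10, 5), c(1.1, 10.2, NA), c(50, 60, 70), c(49, 59, 71))
  colnames(v3) <- c("a", "b", "c")
  # distances from row 2 on shared columns (a, b): row 1 ~ 0.16,
  # row 3 ~ 49.4, row 4 ~ 48.4 -> the two nearest are rows 1 and 4
  out3 <- knn_impute(mk_mat(v3, block = "protein"), k = 2)
  expect_equal(unname(out3$values[2, "c"]), mean(c(5, 71)))
  expect_error(knn_impute(mk_mat(v3, block = "protein"), k = 4), "smaller")
})

test_that("batch correction removes location shifts", {
  set.seed(9)
  n <- 40
  v <- matrix(10^rnorm(n * 5, 2, 0.2), n, 5,
              dimnames = list(NULL, paste0("P", 1:5)))
  batch <- rep(c("B1", "B2"), each = n / 2)
  # single batch: identity up to floating point
  same <- batch_correct(mk_mat(v, block = "protein"), rep("B1", n))
  expect_equal(same$values, v, tolerance = 1e-9)
  # constant multiplicative shift between batches, no extra noise
  v2 <- v
  v2[batch == "B2", ] <- v2[batch == "B2", ] * 10
  corr <- batch_correct(mk_mat(v2, block = "protein"), batch,
                        shrinkage = FALSE)
  lm1 <- colMeans(log10(corr$values[batch == "B1", ]))
  lm2 <- colMeans(log10(corr$values[batch == "B2", ]))
  expect_equal(lm1, lm2, tolerance = 1e-6)
})

test_that("planted batch shifts are suppressed below the null F quantile", {
  ds <- generate_cohort(cohort_config(n_pairs = 30, blocks = list(
    protein = list(n_analytes = 40, n_differential = 0)),
    n_batches = 3, batch_shift_sd = 1, dropout_mean = 0, seed = 13))
  m <- ds$matrices$protein
  batch <- ds$subjects$batch
  fstat <- function(vals) {
    apply(log10(vals), 2, function(col)
      summary(stats::aov(col ~ factor(batch)))[[1]]$`F value`[1])
  }
  f_before <- fstat(m$values)
  corr <- batch_correct(m, batch, shrinkage = TRUE)
  f_after <- fstat(corr$values)
  crit <- qf(0.99, 2, nrow(m$values) - 3)
  expect_gt(mean(f_before > crit), 0.8)   # shifts really were planted
  expect_true(all(f_after < crit))
})

test_that("batch correction agrees with the reference EB implementation", {
  skip_if_not_installed("sva")
  set.seed(21)
  n <- 30; p <- 25
  batch <- rep(c("B1", "B2", "B3"), each = n / 3)
  shift <- matrix(rnorm(3 * p, 0, 0.5), 3, p)
  lx <- matrix(rnorm(n * p, 2, 0.3), n, p) + shift[as.integer(factor(batch)), ]
  colnames(lx) <- paste0("P", 1:p)
  ours <- batch_correct(mk_mat(10^lx, block = "protein"), batch,
                        shrinkage = TRUE)
  ref <- t(sva::ComBat(t(lx), batch = factor(batch)))
  expect_gt(cor(as.vector(log10(ours$values)), as.vector(ref)), 0.995)
})

test_that("autoscaling matches the worked example and is idempotent", {
  v <- matrix(c(10, 100, 1000), 3, 1, dimnames = list(NULL, "A"))
  out <- transform_autoscale(mk_mat(v))
  expect_equal(unname(out$values[, 1]), c(-1, 0, 1))
  # any column: mean 0, sd 1 within 1e-8
  ds <- small_cohort(seed = 6)
  pm <- transform_autoscale(impute_lod(ds$matrices$metabolite))
  expect_lt(max(abs(colMeans(pm$values))), 1e-8)
  expect_lt(max(abs(apply(pm$values, 2, sd) - 1)), 1e-8)
  # re-autoscaling without re-log returns the matrix unchanged
  again <- transform_autoscale(pm, log10_transform = FALSE)
  expect_equal(again$values, pm$values, tolerance = 1e-8)
  # constant column dropped with a warning
  v2 <- cbind(A = c(10, 100, 1000), B = c(5, 5, 5))
  expect_warning(out2 <- transform_autoscale(mk_mat(v2)), "zero-variance")
  expect_identical(colnames(out2$values), "A")
  expect_error(transform_autoscale(mk_mat(matrix(c(0, 1), 2, 1,
    dimnames = list(NULL, "A")))), "non-positive")
})
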