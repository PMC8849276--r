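test_that("group correlations match hand-computed Pearson values", {
  X <- cbind(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5), z = 2 * c(1, 2, 3, 4, 5))
  X <- rbind(X, X)  # both groups identical, 5 subjects each
  rownames(X) <- sprintf("s%d", 1:10)
  grp <- rep(c("NS", "S"), each = 5)
  gc_ <- group_correlations(X, grp)
  expect_equal(gc_$NS$r["x", "y"], 0.8, tolerance = 1e-12)
  expect_equal(gc_$NS$r["x", "z"], 1, tolerance = 1e-12)
  expect_lt(gc_$NS$p["x", "z"], 1e-10)
  expect_equal(diag(gc_$NS$r), rep(1, 3), ignore_attr = TRUE)
  # zero-variance analyte excluded with a warning
  X2 <- cbind(X, const = 1)
  w <- capture_warnings(gc2 <- group_correlations(X2, grp))
  expect_match(w, "zero-variance", all = TRUE)  # warned once per group
  expect_false("const" %in% gc2$analytes)
})

test_that("Fisher z test matches its closed form and symmetries", {
  # equal correlations: no difference
  ft <- fisher_z_test(0.5, 30, 0.5, 50)
  expect_equal(ft$z_stat, 0)
  expect_equal(ft$p_delta, 1)
  # antisymmetry
  a <- fisher_z_test(0.7, 40, 0.2, 40)
  b <- fisher_z_test(0.2, 40, 0.7, 40)
  expect_equal(a$z_stat, -b$z_stat)
  expect_equal(a$p_delta, b$p_delta)
  # the urea-cycle worked example: strong decoupling is detectable
  ex <- fisher_z_test(0.1, 92, 0.7, 92)
  expect_lt(ex$p_delta, 1e-4)
  expect_error(fisher_z_test(1, 10, 0.5, 10), "infinite")
  expect_error(fisher_z_test(0.5, 3, 0.5, 10), "n >= 4")
})

test_that("Fisher z agrees with a permutation oracle", {
  n <- 80
  for (seed in c(1, 3)) {
    set.seed(seed)
    z <- rnorm(n); x1 <- z + rnorm(n); y1 <- 0.8 * z + rnorm(n)
    x2 <- rnorm(n); y2 <- rnorm(n)
    r1 <- cor(x1, y1); r2 <- cor(x2, y2)
    obs <- abs(atanh(r1) - atanh(r2))
    pooled_x <- c(x1, x2); pooled_y <- c(y1, y2)
    stat <- replicate(4000, {
      idx <- sample(2 * n)
      g1 <- idx[1:n]; g2 <- idx[(n + 1):(2 * n)]
      abs(atanh(cor(pooled_x[g1], pooled_y[g1])) -
          atanh(cor(pooled_x[g2], pooled_y[g2])))
    })
    p_perm <- mean(stat >= obs)
    p_fisher <- fisher_z_test(r1, n, r2, n)$p_delta
    expect_lt(abs(p_perm - p_fisher), 0.05)
  }
})

test_that("identical correlation structure yields an empty network", {
  set.seed(31)
  base <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, LETTERS[1:5]))
  X <- rbind(base, base)
  rownames(X) <- sprintf("s%d", 1:80)
  grp <- rep(c("NS", "S"), each = 40)
  net <- build_differential_network(group_correlations(X, grp))
  expect_equal(net$n_edges, 0)
  expect_true(all(net$nodes$degree == 0))
})

test_that("edge set is invariant to analyte input order", {
  ds <- generate_cohort(cohort_config(n_pairs = 45, blocks = list(
    metabolite = list(n_analytes = 20, n_differential = 0)),
    n_corr_pairs = 3, r_s = 0.8, r_ns = 0, lod_quantile = 0,
    low_detect_frac = 0, seed = 41))
  pb <- prep_block(ds)
  X <- pb$proc$values
  grp <- pb$outcome[rownames(X)]
  e1 <- build_differential_network(group_correlations(X, grp))$edges
  perm <- sample(ncol(X))
  e2 <- build_differential_network(group_correlations(X[, perm], grp))$edges
  key <- function(e) sort(paste(pmin(e$analyte_i, e$analyte_j),
                                pmax(e$analyte_i, e$analyte_j)))
  expect_identical(key(e1), key(e2))
})

test_that("planted correlation shifts are recovered as weakened edges", {
  hits <- 0; total <- 0
  for (seed in 1:3) {
    ds <- generate_cohort(cohort_config(n_pairs = 90, blocks = list(
      metabolite = list(n_analytes = 30, n_differential = 0)),
      n_corr_pairs = 5, r_s = 0.7, r_ns = 0, lod_quantile = 0,
      low_detect_frac = 0, seed = 50 + seed))
    pb <- prep_block(ds)
    net <- build_differential_network(
      group_correlations(pb$proc$values, pb$outcome))
    cp <- ds$truth$correlation_shift_pairs
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    planted <- key(cp$analyte_i, cp$analyte_j)
    found <- key(net$edges$analyte_i, net$edges$analyte_j)
    hits <- hits + sum(planted %in% found)
    total <- total + length(planted)
    rec <- net$edges[key(net$edges$analyte_i, net$edges$analyte_j) %in%
                       planted, ]
    expect_true(all(rec$direction == "weakened"))
  }
  expect_gte(hits / total, 0.9)
})

test_that("clustered heatmap merges correlated analytes first", {
  set.seed(61)
  n <- 50
  a <- rnorm(n); b <- a + rnorm(n, 0, 0.01); c_ <- rnorm(n)
  X <- cbind(A = a, B = b, C = c_)
  hm <- cluster_heatmap(X)
  expect_equal(sort(hm$hclust$merge[1, ]), c(-2, -1))  # A,B merge first
  # three analytes with r(A,B)=0.9, r(.,C)=0: first merge is (A,B)
  S <- matrix(c(1, .9, 0, .9, 1, 0, 0, 0, 1), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  L <- chol(S)
  X2 <- matrix(rnorm(3 * 500), 500, 3) %*% L
  colnames(X2) <- c("A", "B", "C")
  hm2 <- cluster_heatmap(X2)
  expect_equal(sort(hm2$hclust$merge[1, ]), c(-2, -1))
  expect_error(cluster_heatmap(X[, 1, drop = FALSE]), "two analytes")
})

test_that("block structure groups contiguously in the leaf order", {
  set.seed(71)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(sapply(1:4, function(i) f1 + rnorm(n, 0, 0.3)),
             sapply(1:4, function(i) f2 + rnorm(n, 0, 0.3)))
  colnames(X) <- c(paste0("b1_", 1:4), paste0("b2_", 1:4))
  ord <- cluster_heatmap(X)$order
  grp_of <- substr(ord, 1, 2)
  expect_equal(length(rle(grp_of)$lengths), 2)  # two contiguous blocks
})

test_that("pooled SCFA analysis recovers the planted association", {
  set.seed(81)
  n <- 180
  ids <- sprintf("s%03d", 1:n)
  base <- 10^rnorm(n, 1, 0.25)
  v <- cbind(Propionate = base * 10^rnorm(n, 0, 0.05),
             Isobutyrate = base * 10^rnorm(n, 0, 0.05),
             Butyrate = base * 10^rnorm(n, 0, 0.05))
  rownames(v) <- ids
  m <- analyte_matrix("metabolite", v, rep("organic acid", 3))
  # proportional target: r = 1
  prop <- pooled_scfa_analysis(m, target_values = setNames(rowSums(v), ids))
  expect_equal(prop$r, 1, tolerance = 1e-10)
  # planted r ~ 0.3 on the log scale
  rs <- numeric(10)
  for (i in 1:10) {
    lp <- scale(log10(rowSums(v)))
    il8 <- 10^(0.3 * lp + sqrt(1 - 0.09) * rnorm(n) + 1)
    res <- pooled_scfa_analysis(m, target_values = setNames(drop(il8), ids))
    rs[i] <- res$r
  }
  expect_lt(abs(mean(rs) - 0.3), 0.15)
  # constant target is flagged
  expect_warning(bad <- pooled_scfa_analysis(
    m, target_values = setNames(rep(2, n), ids)), "degenerate")
  expect_true(is.na(bad$r))
})
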