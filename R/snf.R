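#' Scaled exponential similarity kernel for one data view
#'
#' Subject-subject affinity \eqn{W(i,j) = \exp(-d^2(i,j)/(\mu\,\epsilon_{ij}))}
#' with the locally adaptive bandwidth
#' \eqn{\epsilon_{ij} = (\bar d_{i,K} + \bar d_{j,K} + d(i,j))/3}, where
#' \eqn{\bar d_{i,K}} is the mean distance from i to its K nearest
#' neighbours. Distances are standardized Euclidean for omic views and
#' Gower (via cluster::daisy) for the mixed-type clinical view.
#'
#' @param X_view numeric matrix (subjects x features) or, for
#'   `metric = "gower"`, a data.frame with mixed types.
#' @param K neighbourhood size (default 20, must be < n).
#' @param mu kernel bandwidth multiplier (default 0.5).
#' @param metric "euclidean_scaled" or "gower".
#' @return n x n symmetric nonnegative matrix of class `affinity_matrix`
#'   with attributes K, mu, metric.
#' @export
view_affinity <- function(X_view, K = 20, mu = 0.5,
                          metric = c("euclidean_scaled", "gower")) {
  metric <- match.arg(metric)
  n <- nrow(X_view)
  if (K >= n) stop("K must be smaller than the number of subjects")
  if (metric == "gower") {
    d <- as.matrix(cluster::daisy(as.data.frame(X_view), metric = "gower"))
  } else {
    if (anyNA(X_view)) stop("missing values in view")
    Xs <- as.matrix(X_view)
    sds <- apply(Xs, 2, stats::sd)
    keep <- sds > 0
    if (!any(keep)) {
      warning("constant view: using uniform affinity")
      W <- matrix(1, n, n, dimnames = list(rownames(X_view), rownames(X_view)))
      return(structure(W, K = K, mu = mu, metric = metric,
                       class = c("affinity_matrix", "matrix", "array")))
    }
    Xs <- sweep(sweep(Xs[, keep, drop = FALSE], 2,
                      colMeans(Xs[, keep, drop = FALSE])), 2, sds[keep], "/")
    d <- as.matrix(stats::dist(Xs))
  }
  mean_knn <- apply(d, 1, function(row) {
    s <- sort(row)[-1]  # drop self (distance zero)
    mean(s[seq_len(K)])
  })
  # epsilon per pair: (mean d(i,KNN) + mean d(j,KNN) + d(i,j)) / 3
  eps <- (outer(mean_knn, mean_knn, "+") + d) / 3
  eps[eps <= 0] <- .Machine$double.eps
  W <- exp(-d^2 / (mu * eps))
  W <- (W + t(W)) / 2
  dimnames(W) <- list(rownames(X_view), rownames(X_view))
  structure(W, K = K, mu = mu, metric = metric,
            class = c("affinity_matrix", "matrix", "array"))
}

# Full-kernel transition matrix: off-diagonal mass 1/2, diagonal 1/2.
normalize_p <- function(W) {
  P <- W
  diag(P) <- 0
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- P / (2 * rs)
  diag(P) <- 0.5
  P
}

# Row-normalized K-NN kernel (local transition matrix).
normalize_s <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    w <- W[i, ]; w[i] <- -Inf
    nb <- order(w, decreasing = TRUE)[seq_len(K)]
    S[i, nb] <- W[i, nb] / sum(W[i, nb])
  }
  S
}

#' Similarity network fusion across data views
#'
#' Iterative cross-diffusion: per view v, the full-kernel transition
#' matrix \eqn{P^{(v)}} is updated as
#' \eqn{S^{(v)} \bar P^{(-v)} S^{(v)T}} where \eqn{\bar P^{(-v)}} is the
#' mean of the other views' current status matrices and \eqn{S^{(v)}} the
#' row-normalized K-NN kernel; each step re-symmetrizes and re-normalizes
#' (rows sum to one throughout). The fused network is the mean of the
#' final status matrices.
#'
#' @param affinities list of >= 2 `affinity_matrix` objects over the same
#'   subjects.
#' @param K neighbourhood size for the local kernels (default 20).
#' @param t number of fusion iterations (default 20).
#' @return list of class `fused_network`: `fused` (n x n), `per_view_p`,
#'   `iterations`, `converged_delta` (final Frobenius change).
#' @export
snf_fuse <- function(affinities, K = 20, t = 20) {
  m <- length(affinities)
  if (m < 2) stop("need at least two views")
  ns <- vapply(affinities, nrow, integer(1))
  if (length(unique(ns)) != 1) stop("mismatched view dimensions")
  P <- lapply(affinities, function(W) normalize_p(unclass(W)))
  S <- lapply(affinities, function(W) normalize_s(unclass(W), K))
  delta <- NA_real_
  for (it in seq_len(t)) {
    prev_fused <- Reduce(`+`, P) / m
    Pnew <- vector("list", m)
    for (v in seq_len(m)) {
      others <- Reduce(`+`, P[-v]) / (m - 1)
      Q <- S[[v]] %*% others %*% t(S[[v]])
      Q <- (Q + t(Q)) / 2
      Pnew[[v]] <- normalize_p(Q)
    }
    P <- Pnew
    fused <- Reduce(`+`, P) / m
    delta <- sqrt(sum((fused - prev_fused)^2))
  }
  if (is.finite(delta) && delta >= 1e-4)
    warning(sprintf("fusion not fully converged (Frobenius change %.2e at t=%d)",
                    delta, t))
  fused <- Reduce(`+`, P) / m
  fused <- (fused + t(fused)) / 2
  structure(list(fused = fused, per_view_p = P, iterations = t,
                 converged_delta = delta),
            class = "fused_network")
}

#' Normalized-cut spectral clustering of a similarity matrix
#'
#' Computes the top-k eigenvectors of the symmetrically normalized
#' similarity \eqn{D^{-1/2} W D^{-1/2}}, row-normalizes them, and runs
#' k-means with a fixed seed and 50 restarts.
#'
#' @param similarity symmetric nonnegative matrix.
#' @param k number of clusters.
#' @param seed RNG seed for k-means (default 42).
#' @param nstart k-means restarts (default 50).
#' @return integer vector of cluster labels in 1..k.
#' @export
spectral_cluster <- function(similarity, k, seed = 42L, nstart = 50L) {
  W <- as.matrix(similarity)
  n <- nrow(W)
  if (k > n) stop("k exceeds the number of subjects")
  if (k == 1) return(stats::setNames(rep(1L, n), rownames(W)))
  dg <- rowSums(W)
  dg[dg == 0] <- 1e-12
  L <- W / sqrt(outer(dg, dg))
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  km <- with_seed(seed, stats::kmeans(U, centers = k, nstart = nstart,
                                      iter.max = 100))
  stats::setNames(km$cluster, rownames(W))
}

# Normalized mutual information between two labelings.
nmi <- function(a, b) {
  if (length(unique(a)) < 2 || length(unique(b)) < 2) return(0)
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)),
                  method = "nmi")
}

# Local self-diffusion of a single view (its own S and P), the same
# smoothing the fusion applies; stabilizes spectral clustering of raw
# high-dimensional affinities where distances concentrate.
self_diffuse <- function(W, K = 20, t = 20) {
  P <- normalize_p(W)
  S <- normalize_s(W, K)
  for (i in seq_len(t)) {
    Q <- S %*% P %*% t(S)
    P <- normalize_p((Q + t(Q)) / 2)
  }
  (P + t(P)) / 2
}

#' Concordance of a data view with the fused network
#'
#' Normalized mutual information between the spectral-cluster labels of
#' the view and of the fused similarity at the chosen k. A raw
#' `affinity_matrix` is first locally self-diffused (its own K-NN kernel,
#' the same smoothing fusion applies) so its cluster structure is
#' comparable with the diffused fused matrix; an already-diffused
#' `fused_network` (e.g. the omics-only fusion, for an aggregate
#' biomolecular concordance) is used as is. Degenerate single-cluster
#' labelings give 0.
#'
#' @param view_aff an `affinity_matrix`, a `fused_network`, or a plain
#'   similarity matrix (used as is).
#' @param fused the reference `fused_network` (or its fused matrix).
#' @param k number of clusters (default 2).
#' @param seed k-means seed.
#' @param K,t smoothing parameters for raw affinity views.
#' @return concordance score in `[0, 1]`.
#' @export
view_concordance <- function(view_aff, fused, k = 2, seed = 42L,
                             K = 20, t = 20) {
  fm <- if (inherits(fused, "fused_network")) fused$fused else as.matrix(fused)
  vm <- if (inherits(view_aff, "fused_network")) view_aff$fused
        else if (inherits(view_aff, "affinity_matrix"))
          self_diffuse(unclass(view_aff), K = min(K, nrow(view_aff) - 1), t = t)
        else as.matrix(view_aff)
  lab_v <- spectral_cluster(vm, k, seed = seed)
  lab_f <- spectral_cluster(fm, k, seed = seed)
  nmi(lab_v, lab_f)
}

#' Per-analyte deviation Z-scores of nonsurvivor strata from survivors
#'
#' For each time-to-event stratum of nonsurvivors,
#' \eqn{Z = (\bar x_{stratum} - \bar x_S) / sd_S} per analyte; zero means
#' the stratum sits at the survivor mean.
#'
#' @param X matrix (subjects x analytes), rownames = subject ids.
#' @param subjects subject data.frame with outcome and
#'   `time_to_event_days`.
#' @param breaks stratum upper bounds for days to death (default
#'   `c(3, 7, Inf)` giving strata <=3, 4-7, >7).
#' @return data.frame of class `deviation_zscores` in long format:
#'   analyte_id, stratum, z (flagged NA where the survivor SD is zero).
#' @export
deviation_zscores <- function(X, subjects, breaks = c(3, 7, Inf)) {
  rownames(subjects) <- subjects$subject_id
  sub <- subjects[rownames(X), ]
  s_rows <- sub$outcome == "S"
  ns_rows <- sub$outcome == "NS"
  if (!any(s_rows) || !any(ns_rows)) stop("need both NS and S subjects")
  mu_s <- colMeans(X[s_rows, , drop = FALSE])
  sd_s <- apply(X[s_rows, , drop = FALSE], 2, stats::sd)
  if (any(sd_s == 0)) warning("zero survivor SD for some analytes; Z = NA")
  sd_s[sd_s == 0] <- NA
  labels <- character(length(breaks))
  for (i in seq_along(breaks)) {
    labels[i] <- if (i == 1) paste0("<=", breaks[1], "d")
                 else if (is.finite(breaks[i]))
                   paste0(breaks[i - 1] + 1, "-", breaks[i], "d")
                 else paste0(">", breaks[i - 1], "d")
  }
  out <- NULL
  tt <- sub$time_to_event_days
  for (i in seq_along(breaks)) {
    in_str <- ns_rows & tt > c(-Inf, breaks)[i] & tt <= breaks[i]
    if (!any(in_str)) next
    mu_n <- colMeans(X[in_str, , drop = FALSE])
    z <- (mu_n - mu_s) / sd_s
    out <- rbind(out, data.frame(analyte_id = colnames(X),
                                 stratum = labels[i], z = unname(z),
                                 n_stratum = sum(in_str),
                                 stringsAsFactors = FALSE))
  }
  class(out) <- c("deviation_zscores", "data.frame")
  out
}

#' Characterize clusters by outcome composition and deviating features
#'
#' Per cluster: outcome composition (NS fraction) and features ranked by
#' the standardized deviation of the cluster mean from the overall mean.
#'
#' @param X matrix (subjects x features), rownames = subject ids.
#' @param labels named cluster labels.
#' @param outcome named outcome vector ("NS"/"S").
#' @param top number of top deviating features to keep per cluster.
#' @return list of class `cluster_characterization`: `composition`
#'   (data.frame cluster, n, ns_fraction), `top_features` (data.frame
#'   cluster, feature, deviation).
#' @export
cluster_characterization <- function(X, labels, outcome, top = 10L) {
  labels <- labels[rownames(X)]
  outcome <- outcome[rownames(X)]
  if (any(is.na(labels))) stop("labels missing for some subjects")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- NA
  comp <- NULL; feats <- NULL
  for (cl in sort(unique(labels))) {
    rows <- labels == cl
    if (!any(rows)) stop("empty cluster ", cl)
    comp <- rbind(comp, data.frame(
      cluster = cl, n = sum(rows),
      ns_fraction = mean(outcome[rows] == "NS"), stringsAsFactors = FALSE))
    dev <- (colMeans(X[rows, , drop = FALSE]) - mu) / sdv
    ord <- order(-abs(dev))[seq_len(min(top, ncol(X)))]
    feats <- rbind(feats, data.frame(
      cluster = cl, feature = colnames(X)[ord], deviation = unname(dev[ord]),
      stringsAsFactors = FALSE))
  }
  structure(list(composition = comp, top_features = feats),
            class = "cluster_characterization")
}
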