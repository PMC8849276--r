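#' Group-wise Pearson correlations with within-group significance
#'
#' Pearson correlations over all analyte pairs, computed separately within
#' each outcome group; within-group significance from the t-distribution
#' on n-2 df, BH-FDR adjusted over all pairs within each group. Analytes
#' with zero variance in a group are excluded (logged via warning).
#'
#' @param X processed matrix (subjects x analytes), rownames = subject ids.
#' @param groups named group vector ("NS"/"S") aligned with rows.
#' @return list of class `group_correlations` with per-group `r`, `p`,
#'   `q` matrices, per-group `n`, and `analytes`.
#' @export
group_correlations <- function(X, groups) {
  if (!is.null(names(groups))) groups <- groups[rownames(X)]
  out <- list()
  keep <- rep(TRUE, ncol(X))
  for (g in c("NS", "S")) {
    Xg <- X[groups == g, , drop = FALSE]
    if (nrow(Xg) < 4) stop("need >= 4 subjects per group")
    zv <- apply(Xg, 2, stats::sd) == 0
    if (any(zv)) {
      warning("zero-variance analytes in group ", g, ": ",
              paste(colnames(X)[zv], collapse = ", "))
      keep <- keep & !zv
    }
  }
  X <- X[, keep, drop = FALSE]
  for (g in c("NS", "S")) {
    Xg <- X[groups == g, , drop = FALSE]
    n <- nrow(Xg)
    r <- stats::cor(Xg)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    diag(p) <- NA
    ut <- upper.tri(p)
    q <- p
    q[ut] <- bh_adjust(p[ut])
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
    out[[g]] <- list(r = r, p = p, q = q, n = n)
  }
  structure(list(NS = out$NS, S = out$S, analytes = colnames(X)),
            class = "group_correlations")
}

#' Two-sample comparison of correlations via Fisher's z-transformation
#'
#' \deqn{z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2) /
#'   \sqrt{1/(n_1-3) + 1/(n_2-3)}}
#' with a two-sided normal p-value.
#'
#' @param r1,r2 correlations with |r| < 1.
#' @param n1,n2 per-group sample sizes (>= 4).
#' @return list with `z_stat` and `p_delta`.
#' @export
fisher_z_test <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) stop("|r| = 1: Fisher transform infinite")
  if (min(n1, n2) < 4) stop("need n >= 4 in both groups")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z_stat = z, p_delta = 2 * stats::pnorm(-abs(z)))
}

#' Build the differential correlation network
#'
#' An edge joins an analyte pair when its correlation is significant at
#' FDR `within_q` in either group AND the Fisher-z comparison of the two
#' group correlations has p below `delta_p`. Edge attributes: direction
#' (strengthened/weakened in NS, by |r_NS| vs |r_S|), sign (of the
#' significant correlation), width = |r_NS - r_S|. Node degrees count
#' differential edges.
#'
#' @param corr a `group_correlations` object.
#' @param classes optional named vector of analyte class labels.
#' @param within_q within-group FDR threshold (default 0.05).
#' @param delta_p Fisher-z threshold (default 0.05).
#' @return list of class `differential_network`: `edges` (data.frame),
#'   `nodes` (data.frame with class and degree), `n_edges`.
#' @export
build_differential_network <- function(corr, classes = NULL,
                                       within_q = 0.05, delta_p = 0.05) {
  stopifnot(inherits(corr, "group_correlations"))
  ids <- corr$analytes
  if (!length(ids)) stop("empty analyte set")
  edges <- NULL
  ut <- which(upper.tri(corr$NS$r), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  r_ns <- corr$NS$r[ut]; r_s <- corr$S$r[ut]
  q_ns <- corr$NS$q[ut]; q_s <- corr$S$q[ut]
  within_ok <- (q_ns < within_q) | (q_s < within_q)
  fz <- fisher_z_test(pmin(pmax(r_ns, -1 + 1e-12), 1 - 1e-12), corr$NS$n,
                      pmin(pmax(r_s, -1 + 1e-12), 1 - 1e-12), corr$S$n)
  is_edge <- within_ok & fz$p_delta < delta_p
  edges <- data.frame(
    analyte_i = ids[ut[is_edge, 1]],
    analyte_j = ids[ut[is_edge, 2]],
    r_s = r_s[is_edge], r_ns = r_ns[is_edge],
    z_stat = fz$z_stat[is_edge], p_delta = fz$p_delta[is_edge],
    direction = ifelse(abs(r_ns[is_edge]) > abs(r_s[is_edge]),
                       "strengthened", "weakened"),
    sign = ifelse(ifelse(q_ns[is_edge] < within_q, r_ns[is_edge],
                         r_s[is_edge]) >= 0, "positive", "negative"),
    width = abs(r_ns[is_edge] - r_s[is_edge]),
    stringsAsFactors = FALSE)
  deg <- stats::setNames(integer(length(ids)), ids)
  if (nrow(edges)) {
    tb <- table(c(edges$analyte_i, edges$analyte_j))
    deg[names(tb)] <- as.integer(tb)
  }
  nodes <- data.frame(analyte_id = ids,
                      class = if (is.null(classes)) NA_character_
                              else unname(classes[ids]),
                      degree = unname(deg), stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes, n_edges = nrow(edges)),
            class = "differential_network")
}

#' @export
print.differential_network <- function(x, ...) {
  cat(sprintf("<differential_network> %d nodes, %d edges (%d weakened, %d strengthened in NS)\n",
              nrow(x$nodes), x$n_edges,
              sum(x$edges$direction == "weakened"),
              sum(x$edges$direction == "strengthened")))
  invisible(x)
}

#' Hierarchically clustered cross-block correlation structure
#'
#' Pooled-subject Pearson correlation among analytes, clustered by
#' average-linkage agglomeration on the distance 1 - r; emits the leaf
#' order, the merge tree and the correlation matrix for heatmap rendering.
#'
#' @param X processed matrix (pooled subjects x analytes).
#' @param classes optional analyte class labels (named or positional).
#' @param method linkage (default "average"; "single" exposed for outlier
#'   inspection).
#' @return list of class `cluster_heatmap`: `order` (leaf order of
#'   analyte ids), `hclust`, `correlation`, `classes`.
#' @export
cluster_heatmap <- function(X, classes = NULL, method = "average") {
  if (ncol(X) < 2) stop("need at least two analytes to cluster")
  r <- stats::cor(X)
  hc <- stats::hclust(stats::as.dist(1 - r), method = method)
  structure(list(order = colnames(X)[hc$order], hclust = hc,
                 correlation = r, classes = classes),
            class = "cluster_heatmap")
}

#' Pooled short-chain fatty acid vs target correlation
#'
#' Sums the SCFA constituents per subject (raw scale), correlates the
#' pooled value with a target analyte on the log10 scale, and
#' cross-tabulates subjects above/below the two medians.
#'
#' @param raw an [analyte_matrix()] of raw concentrations containing the
#'   SCFAs and the target.
#' @param scfas constituent analyte ids (default propionate, isobutyrate,
#'   butyrate).
#' @param target target analyte id (default "IL8"); may come from a
#'   second matrix via `target_values`.
#' @param target_values optional named numeric vector of target raw
#'   concentrations (overrides `target` lookup in `raw`).
#' @return list of class `scfa_analysis`: `pooled`, `target`, `r`, `p`,
#'   `medians`, `crosstab`.
#' @export
pooled_scfa_analysis <- function(raw,
                                 scfas = c("Propionate", "Isobutyrate",
                                           "Butyrate"),
                                 target = "IL8", target_values = NULL) {
  v <- raw$values
  miss <- setdiff(scfas, colnames(v))
  if (length(miss)) stop("missing SCFA constituent(s): ",
                         paste(miss, collapse = ", "))
  pooled <- rowSums(v[, scfas, drop = FALSE])
  tv <- if (!is.null(target_values)) target_values[rownames(v)]
        else {
          if (!target %in% colnames(v)) stop("missing target analyte ", target)
          v[, target]
        }
  ok <- stats::complete.cases(pooled, tv)
  pooled <- pooled[ok]; tv <- tv[ok]
  if (stats::sd(tv) == 0 || stats::sd(pooled) == 0) {
    warning("degenerate (constant) variable; correlation undefined")
    return(structure(list(pooled = pooled, target = tv, r = NA_real_,
                          p = NA_real_, medians = c(scfa = stats::median(pooled),
                                                    target = stats::median(tv)),
                          crosstab = NULL), class = "scfa_analysis"))
  }
  ct <- stats::cor.test(log10(pooled), log10(tv))
  crosstab <- table(scfa_high = pooled > stats::median(pooled),
                    target_high = tv > stats::median(tv))
  structure(list(pooled = pooled, target = tv,
                 r = unname(ct$estimate), p = ct$p.value,
                 medians = c(scfa = stats::median(pooled),
                             target = stats::median(tv)),
                 crosstab = crosstab),
            class = "scfa_analysis")
}
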