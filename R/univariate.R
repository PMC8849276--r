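#' Conditional logistic regression for 1:1 matched pairs
#'
#' Maximises the 1:1 conditional likelihood
#' \eqn{\prod_i \sigma(\beta^T d_i)} over the per-pair case-minus-control
#' difference vectors \eqn{d_i} by Newton-Raphson (this is algebraically an
#' intercept-free logistic regression on the differences with all
#' responses 1). Convergence when the maximum absolute score is below
#' `tol` or after `max_iter` iterations. Complete separation (some linear
#' combination of differences uniformly one-signed drives the likelihood
#' to its supremum) is detected by coefficient divergence: the estimate is
#' flagged and p-values fall back to the score test at beta = 0.
#'
#' @param pair_diffs n_pairs x p numeric matrix of case - control
#'   differences.
#' @param tol score convergence tolerance (default 1e-8).
#' @param max_iter maximum Newton iterations (default 50).
#' @return list of class `clogit_fit`: `beta`, `vcov`, `se`, `wald_z`,
#'   `p`, `converged`, `separation` (logical), `loglik`.
#' @export
fit_clogit_1to1 <- function(pair_diffs, tol = 1e-8, max_iter = 50L) {
  D <- as.matrix(pair_diffs)
  n <- nrow(D); p <- ncol(D)
  if (n < 2) stop("need at least 2 pairs")
  if (any(colSums(abs(D)) == 0)) stop("all-zero difference column")
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(D %*% beta)
    mu <- logistic(eta)
    score <- drop(crossprod(D, 1 - mu))
    W <- mu * (1 - mu)
    info <- crossprod(D * sqrt(W))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    # dampen huge steps (separation path)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(beta)) > 30) break
  }
  separation <- !converged && max(abs(beta)) > 10
  eta <- drop(D %*% beta)
  mu <- logistic(eta)
  W <- mu * (1 - mu)
  info <- crossprod(D * sqrt(W))
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vc))
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  if (separation || any(!is.finite(pv))) {
    # score test at beta = 0: U = colSums(D)/2, I = t(D) %*% D / 4
    U <- colSums(D) / 2
    I0 <- crossprod(D) / 4
    z_sc <- U / sqrt(diag(I0))
    pv <- 2 * stats::pnorm(-abs(z_sc))
    z <- z_sc
  }
  loglik <- sum(log(logistic(drop(D %*% beta))))
  structure(list(beta = stats::setNames(beta, colnames(D)), vcov = vc,
                 se = se, wald_z = z, p = pv, converged = converged,
                 separation = separation, loglik = loglik),
            class = "clogit_fit")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement (delegates to
#' [stats::p.adjust()]).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-analyte conditional logistic screening of a matched cohort
#'
#' One 1:1 conditional logistic fit per analyte on the autoscaled data,
#' with optional adjustment for an admission covariate (entering the
#' conditional likelihood as an additional difference term). P-values are
#' BH-FDR adjusted across the analytes supplied (one block = one family).
#' The `top_significant` flag applies the block-specific criterion:
#' q < 0.01 for metabolites, p < 0.05 for proteins and cytokines. Fold
#' change is the NS/S ratio of arithmetic group means on the raw
#' concentration scale (geometric-mean option available).
#'
#' @param processed a `processed_matrix` (autoscaled).
#' @param pairs a `pair_set`; all pair members must be rows of the matrix.
#' @param raw optional [analyte_matrix()] of raw concentrations for the
#'   fold change (same analytes); if NULL fold changes are NA.
#' @param adjust_for optional numeric/logical covariate vector named by
#'   subject id (e.g. edema or WHZ) added as a difference term.
#' @param block block label determining the significance rule (default
#'   taken from `processed$block`; metabolites use q < `q_thresh`, other
#'   blocks p < `p_thresh`).
#' @param q_thresh,p_thresh block-specific thresholds (0.01 / 0.05).
#' @param fold_change "arithmetic" (default) or "geometric" group means.
#' @return data.frame of class `univariate_table`: analyte_id, beta, se,
#'   wald_z, p, q, fold_change, separation, top_significant.
#' @export
screen_analytes <- function(processed, pairs, raw = NULL, adjust_for = NULL,
                            block = NULL, q_thresh = 0.01, p_thresh = 0.05,
                            fold_change = c("arithmetic", "geometric")) {
  stopifnot(inherits(processed, "processed_matrix"),
            inherits(pairs, "pair_set"))
  fold_change <- match.arg(fold_change)
  X <- processed$values
  pr <- pairs$pairs
  missing_sub <- setdiff(c(pr$case_id, pr$control_id), rownames(X))
  if (length(missing_sub))
    stop("pair members absent from matrix: ",
         paste(utils::head(missing_sub, 5), collapse = ", "))
  D <- X[pr$case_id, , drop = FALSE] - X[pr$control_id, , drop = FALSE]
  cov_d <- NULL
  if (!is.null(adjust_for)) {
    cov_d <- as.numeric(adjust_for[pr$case_id]) -
             as.numeric(adjust_for[pr$control_id])
  }
  p_ids <- colnames(X)
  res <- lapply(seq_along(p_ids), function(j) {
    d <- D[, j]
    if (all(d == 0))
      return(list(beta = 0, se = NA_real_, z = 0, p = 1, sep = FALSE))
    Dj <- if (is.null(cov_d)) matrix(d, ncol = 1) else cbind(d, cov_d)
    fit <- tryCatch(fit_clogit_1to1(Dj),
                    error = function(e) NULL)
    if (is.null(fit))
      return(list(beta = NA_real_, se = NA_real_, z = NA_real_,
                  p = NA_real_, sep = TRUE))
    list(beta = fit$beta[1], se = fit$se[1], z = fit$wald_z[1],
         p = fit$p[1], sep = fit$separation)
  })
  pv <- vapply(res, `[[`, numeric(1), "p")
  q <- bh_adjust(pv)
  fc <- rep(NA_real_, length(p_ids))
  if (!is.null(raw)) {
    rv <- raw$values[, p_ids, drop = FALSE]
    ns_rows <- pr$case_id; s_rows <- pr$control_id
    if (fold_change == "arithmetic") {
      fc <- colMeans(rv[ns_rows, , drop = FALSE], na.rm = TRUE) /
            colMeans(rv[s_rows, , drop = FALSE], na.rm = TRUE)
    } else {
      fc <- 10^(colMeans(log10(rv[ns_rows, , drop = FALSE]), na.rm = TRUE) -
                colMeans(log10(rv[s_rows, , drop = FALSE]), na.rm = TRUE))
    }
  }
  block <- block %||% processed$block
  top <- if (identical(block, "metabolite")) q < q_thresh else pv < p_thresh
  out <- data.frame(
    analyte_id = p_ids,
    beta = vapply(res, `[[`, numeric(1), "beta"),
    se = vapply(res, `[[`, numeric(1), "se"),
    wald_z = vapply(res, `[[`, numeric(1), "z"),
    p = pv, q = q, fold_change = unname(fc),
    separation = vapply(res, `[[`, logical(1), "sep"),
    top_significant = top,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "block") <- block
  class(out) <- c("univariate_table", "data.frame")
  out
}

#' Built-in metabolite ratio definitions
#'
#' The four ratios named in the main analysis: Fischer's ratio
#' (branched-chain amino acids over tyrosine + phenylalanine), the total
#' urea-cycle amino acid pool (citrulline + ornithine + arginine +
#' aspartate, as a sum), acetylcarnitine/carnitine (C2/C0, a beta-oxidation
#' marker) and kynurenine/tryptophan (immune activation). Additional
#' ratios can be supplied in the same list-of-lists format.
#'
#' @return named list of ratio definitions, each with `numerator` and
#'   `denominator` (character vectors of analyte ids; a denominator of
#'   `"1"` denotes the unit constant, i.e. a plain sum).
#' @export
builtin_ratios <- function() {
  list(
    fischer = list(numerator = c("Val", "Leu", "Ile"),
                   denominator = c("Tyr", "Phe")),
    urea_cycle = list(numerator = c("Cit", "Orn", "Arg", "Asp"),
                      denominator = "1"),
    c2_c0 = list(numerator = "C2", denominator = "C0"),
    kyn_trp = list(numerator = "Kynurenine", denominator = "Trp")
  )
}

#' Compute metabolite ratios as derived analytes
#'
#' Each ratio is sum(numerator)/sum(denominator) per subject on the raw
#' concentration scale; a denominator of `"1"` is the unit constant (plain
#' sum). The resulting matrix can enter [screen_analytes()] like any block.
#'
#' @param raw an [analyte_matrix()] of raw concentrations.
#' @param definitions list of ratio definitions (see [builtin_ratios()]).
#' @return an [analyte_matrix()] (block "metabolite") of ratio values.
#' @export
compute_ratios <- function(raw, definitions = builtin_ratios()) {
  stopifnot(inherits(raw, "analyte_matrix"))
  v <- raw$values
  out <- matrix(NA_real_, nrow(v), length(definitions),
                dimnames = list(rownames(v), names(definitions)))
  for (k in seq_along(definitions)) {
    def <- definitions[[k]]
    num_ids <- setdiff(def$numerator, "1")
    den_ids <- setdiff(def$denominator, "1")
    if (!length(num_ids)) stop("empty numerator in ratio ", names(definitions)[k])
    if (length(intersect(num_ids, den_ids)))
      stop("numerator and denominator overlap in ratio ", names(definitions)[k])
    miss <- setdiff(c(num_ids, den_ids), colnames(v))
    if (length(miss))
      stop("constituent analytes missing for ratio '", names(definitions)[k],
           "': ", paste(miss, collapse = ", "))
    num <- rowSums(v[, num_ids, drop = FALSE])
    den <- if (length(den_ids)) rowSums(v[, den_ids, drop = FALSE]) else 1
    if (any(den == 0, na.rm = TRUE))
      stop("zero denominator in ratio ", names(definitions)[k])
    out[, k] <- num / den
  }
  analyte_matrix("metabolite", out, rep("ratio", ncol(out)), units = "ratio")
}
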