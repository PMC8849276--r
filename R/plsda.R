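#' Within-pair (multilevel) decomposition
#'
#' Removes between-pair variation for a paired design: for each matched
#' pair the pair-mean row is subtracted from both members, so each row
#' becomes plus/minus half the case-minus-control difference. Column sums
#' of the result are exactly zero.
#'
#' @param X matrix with rownames = subject ids (pair members only).
#' @param pairs a `pair_set` covering every row of `X`.
#' @return matrix `X_within` with the same dimnames as `X`.
#' @export
within_pair_decompose <- function(X, pairs) {
  pr <- pairs$pairs
  ids <- c(pr$case_id, pr$control_id)
  extra <- setdiff(rownames(X), ids)
  if (length(extra))
    stop("unpaired subjects in matrix: ",
         paste(utils::head(extra, 5), collapse = ", "))
  Xw <- X * 0
  for (i in seq_len(nrow(pr))) {
    rows <- c(pr$case_id[i], pr$control_id[i])
    pm <- colMeans(X[rows, , drop = FALSE])
    Xw[rows[1], ] <- X[rows[1], ] - pm
    Xw[rows[2], ] <- X[rows[2], ] - pm
  }
  Xw[rownames(X), , drop = FALSE]
}

#' PLS-DA by NIPALS (PLS1 against a class-coded response)
#'
#' Iteratively extracts unit-norm weight vectors \eqn{w \propto X^T y},
#' scores \eqn{t = Xw}, X-loadings \eqn{p = X^T t / t^T t} and Y-loadings
#' \eqn{c = y^T t / t^T t}, deflating X by \eqn{t p^T} after each
#' component. Successive scores are mutually orthogonal. Per-component
#' analyte-score correlations are stored for the correlation-circle plot.
#'
#' @param X column-centered matrix (typically the within-pair decomposed
#'   autoscaled data).
#' @param y class response coded -1/+1.
#' @param n_components number of latent components (default 2).
#' @return list of class `plsda_model`: `weights` (p x a), `loadings`,
#'   `scores` (n x a), `y_loadings`, `coefficients` (for prediction),
#'   `correlations` (analyte x component), `r2y` (training discounted
#'   R2), `explained_x` (fraction of X variance per component).
#' @export
fit_plsda <- function(X, y, n_components = 2L) {
  X <- as.matrix(X)
  if (all(abs(X) < 1e-14)) stop("zero-variance X")
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X)
  a <- min(n_components, p, n - 1L)
  W <- matrix(0, p, a); P <- matrix(0, p, a); Tm <- matrix(0, n, a)
  Cc <- numeric(a)
  Xd <- X
  ssx_tot <- sum(X^2)
  expl <- numeric(a)
  for (k in seq_len(a)) {
    w <- drop(crossprod(Xd, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { a <- k - 1L; break }
    w <- w / nw
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(Xd, t_)) / tt
    c_ <- sum(y * t_) / tt
    Xd <- Xd - tcrossprod(t_, p_)
    W[, k] <- w; P[, k] <- p_; Tm[, k] <- t_; Cc[k] <- c_
    expl[k] <- tt * sum(p_^2) / ssx_tot
  }
  if (a < 1) stop("no usable PLS component (y orthogonal to X)")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]; Cc <- Cc[seq_len(a)]
  # regression coefficients for raw X: B = W (P'W)^-1 c
  B <- W %*% solve(crossprod(P, W), Cc)
  yhat <- drop(X %*% B)
  corr <- suppressWarnings(stats::cor(X, Tm))
  corr[!is.finite(corr)] <- 0
  r2y <- 1 - sum(discount_residuals(y, yhat)^2) / sum((y - mean(y))^2)
  structure(list(weights = W, loadings = P, scores = Tm, y_loadings = Cc,
                 coefficients = drop(B), correlations = corr,
                 r2y = r2y, explained_x = expl[seq_len(a)],
                 n_components = a),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d component(s); X variance explained: %s; DR2 = %.3f\n",
              x$n_components,
              paste(sprintf("%.1f%%", 100 * x$explained_x), collapse = " + "),
              x$r2y))
  invisible(x)
}

#' Predict from a PLS-DA model
#'
#' @param object a `plsda_model`.
#' @param newdata matrix with the model's analytes as columns.
#' @param ... unused.
#' @return numeric vector of continuous predictions (classify at 0).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coefficients)
}

# Discriminant-Q2 residual: zero when the prediction is on the correct
# side of the +-1 label with |yhat| >= 1, else the plain residual.
discount_residuals <- function(y, yhat) {
  e <- y - yhat
  e[y * yhat >= 1] <- 0
  e
}

#' Cross-validated multilevel PLS-DA performance
#'
#' Repeated cross-validation assigning whole matched pairs to folds. Per
#' split, training pairs are within-pair decomposed and a PLS-DA fit;
#' held-out pairs are decomposed with their own pair means (which requires
#' no label information) and projected. Per repeat, pooling over its
#' folds: ROC AUC over all held-out predictions, misclassification at the
#' 0 threshold, training discounted R2 (DR2) and held-out discounted Q2
#' (DQ2 = 1 - sum(e_disc^2)/sum((y - ybar)^2), discounting residuals of
#' predictions already past the correct class label). Summaries are mean
#' and SD across repeats.
#'
#' @param X autoscaled matrix, rownames = subject ids.
#' @param y named -1/+1 (or 0/1, recoded) vector.
#' @param pairs a `pair_set`.
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats repeats (default 50).
#' @param n_components PLS components (default 2).
#' @param seed integer seed.
#' @return list of class `cv_performance`: `summary` (data.frame of mean
#'   and sd for auc, misclassification, r2, dq2), `per_repeat`
#'   (data.frame), `dq2_le_r2` (logical, one per repeat: held-out DQ2 did
#'   not exceed the training DR2).
#' @export
cross_validate <- function(X, y, pairs, n_folds = 10, n_repeats = 50,
                           n_components = 2L, seed = 1L) {
  pr <- pairs$pairs
  n_pairs <- nrow(pr)
  y <- stats::setNames(ifelse(as.numeric(y) > 0, 1, -1), names(y))
  seeds <- derive_seeds(seed, n_repeats)
  rep_stats <- data.frame(auc = numeric(0), misclassification = numeric(0),
                          r2 = numeric(0), dq2 = numeric(0))
  dq2_le_r2 <- logical(0)
  for (r in seq_len(n_repeats)) {
    res <- with_seed(seeds[r], {
      fold <- pair_folds(n_pairs, n_folds)
      preds <- numeric(0); labs <- numeric(0)
      sse_tr <- 0; sst_tr <- 0; sse_te <- 0; sst_te <- 0
      for (f in sort(unique(fold))) {
        tr <- which(fold != f); te <- which(fold == f)
        tr_pairs <- sub_pairs(pr, tr); te_pairs <- sub_pairs(pr, te)
        tr_ids <- c(pr$case_id[tr], pr$control_id[tr])
        te_ids <- c(pr$case_id[te], pr$control_id[te])
        Xw_tr <- within_pair_decompose(X[tr_ids, , drop = FALSE], tr_pairs)
        fit <- fit_plsda(Xw_tr, y[tr_ids], n_components)
        Xw_te <- within_pair_decompose(X[te_ids, , drop = FALSE], te_pairs)
        yhat_te <- predict(fit, Xw_te)
        yhat_tr <- predict(fit, Xw_tr)
        preds <- c(preds, yhat_te); labs <- c(labs, y[te_ids])
        sse_tr <- sse_tr + sum(discount_residuals(y[tr_ids], yhat_tr)^2)
        sst_tr <- sst_tr + sum((y[tr_ids] - mean(y[tr_ids]))^2)
        sse_te <- sse_te + sum(discount_residuals(y[te_ids], yhat_te)^2)
        sst_te <- sst_te + sum((y[te_ids] - mean(y[te_ids]))^2)
      }
      list(auc = auc_rank(preds, as.integer(labs > 0)),
           mis = mean((preds > 0) != (labs > 0)),
           r2 = 1 - sse_tr / sst_tr, dq2 = 1 - sse_te / sst_te)
    })
    rep_stats <- rbind(rep_stats, data.frame(
      auc = res$auc, misclassification = res$mis, r2 = res$r2,
      dq2 = res$dq2))
    dq2_le_r2 <- c(dq2_le_r2, res$dq2 <= res$r2 + 1e-12)
  }
  summary <- data.frame(
    statistic = c("auc", "misclassification", "r2", "dq2"),
    mean = c(mean(rep_stats$auc), mean(rep_stats$misclassification),
             mean(rep_stats$r2), mean(rep_stats$dq2)),
    sd = c(stats::sd(rep_stats$auc), stats::sd(rep_stats$misclassification),
           stats::sd(rep_stats$r2), stats::sd(rep_stats$dq2)),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, per_repeat = rep_stats,
                 dq2_le_r2 = dq2_le_r2),
            class = "cv_performance")
}

sub_pairs <- function(pr, idx) {
  structure(list(pairs = pr[idx, , drop = FALSE], unmatched = character(0)),
            class = "pair_set")
}

#' @export
print.cv_performance <- function(x, ...) {
  s <- x$summary
  cat("<cv_performance>\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s %.3f +/- %.3f\n", s$statistic[i], s$mean[i], s$sd[i]))
  invisible(x)
}
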