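#' Elastic-net penalized logistic regression
#'
#' Minimises the mean negative Bernoulli log-likelihood plus
#' \eqn{\lambda[\alpha\|\beta\|_1 + (1-\alpha)/2\,\|\beta\|_2^2]} with an
#' unpenalized intercept, by cyclic coordinate descent (via glmnet, with
#' no internal standardisation: X is expected autoscaled).
#'
#' @param X autoscaled n x p matrix.
#' @param y 0/1 outcome vector.
#' @param alpha elastic-net mixing parameter in `[0, 1]`.
#' @param lambda penalty strength (scalar).
#' @return list with `beta` (named vector) and `intercept`.
#' @export
fit_elastic_net_logistic <- function(X, y, alpha = 0.75, lambda) {
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("non-finite inputs")
  stopifnot(alpha >= 0, alpha <= 1, lambda >= 0)
  # fit along a path ending at the requested lambda (glmnet's warm starts
  # make single-lambda fits unreliable)
  path <- sort(unique(c(lambda_grid_default(X, y, alpha), lambda)),
               decreasing = TRUE)
  path <- path[path >= lambda]
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                        lambda = path, standardize = FALSE,
                        thresh = 1e-10)
  co <- as.matrix(stats::coef(fit, s = lambda, exact = FALSE))
  list(beta = stats::setNames(co[-1, 1], colnames(X)),
       intercept = co[1, 1])
}

# 100 log-spaced lambdas from the all-zero lambda_max down to 1e-3*lambda_max.
lambda_grid_default <- function(X, y, alpha, n_lambda = 100L) {
  yb <- mean(y)
  lmax <- max(abs(crossprod(X, y - yb))) / (nrow(X) * max(alpha, 1e-3))
  exp(seq(log(lmax), log(lmax * 1e-3), length.out = n_lambda))
}

# Assign pairs to folds, keeping both members of a pair together (each
# pair carries one case and one control, so folds stay outcome-balanced).
pair_folds <- function(n_pairs, n_folds) {
  sample(rep(seq_len(n_folds), length.out = n_pairs))
}

#' Tune the elastic-net penalty by pairwise cross-validated misclassification
#'
#' Five-fold (by default) cross-validation with matched pairs kept in the
#' same fold; returns the lambda minimising mean CV misclassification at a
#' 0.5 prediction threshold, preferring the largest lambda on ties.
#'
#' @param X autoscaled matrix with rownames = subject ids.
#' @param y named 0/1 vector.
#' @param pairs a `pair_set`.
#' @param alpha elastic-net mixing parameter.
#' @param n_folds number of CV folds (default 5).
#' @param lambda_grid decreasing lambda grid (default: 100 log-spaced
#'   values from lambda_max down to 1e-3 lambda_max).
#' @return list with `lambda_opt`, `cv_error` (per-lambda mean
#'   misclassification) and `lambda_grid`.
#' @export
tune_lambda_cv <- function(X, y, pairs, alpha = 0.75, n_folds = 5,
                           lambda_grid = NULL) {
  pr <- pairs$pairs
  n_pairs <- nrow(pr)
  if (is.null(lambda_grid)) lambda_grid <- lambda_grid_default(X, y, alpha)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  fold <- pair_folds(n_pairs, n_folds)
  err <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (f in seq_len(n_folds)) {
    te_pairs <- which(fold == f)
    tr_pairs <- which(fold != f)
    tr_ids <- c(pr$case_id[tr_pairs], pr$control_id[tr_pairs])
    te_ids <- c(pr$case_id[te_pairs], pr$control_id[te_pairs])
    if (length(unique(y[tr_ids])) < 2) stop("degenerate single-class fold")
    fit <- glmnet::glmnet(X[tr_ids, , drop = FALSE], y[tr_ids],
                          family = "binomial", alpha = alpha,
                          lambda = lambda_grid, standardize = FALSE)
    pred <- stats::predict(fit, X[te_ids, , drop = FALSE], type = "response")
    # pad if glmnet dropped path tail
    if (ncol(pred) < length(lambda_grid))
      pred <- cbind(pred, pred[, rep(ncol(pred),
                                     length(lambda_grid) - ncol(pred))])
    err[f, ] <- colMeans((pred > 0.5) != y[te_ids])
  }
  m_err <- colMeans(err)
  list(lambda_opt = lambda_grid[which.min(m_err)],  # first = largest on ties
       cv_error = m_err, lambda_grid = lambda_grid)
}

#' Bootstrap elastic-net stability selection
#'
#' Resamples matched pairs with replacement `B` times; within each
#' bootstrap sample the penalty is tuned by pair-preserving 5-fold CV
#' misclassification, the elastic net is refit at the tuned lambda, and
#' the nonzero support is recorded. Analytes selected in more than
#' `threshold` of the `B` fits are flagged influential. Per-iteration RNG
#' streams are derived from `seed`, so results are independent of
#' execution order. Degenerate single-class resamples (impossible under
#' pair resampling, but checked) are redrawn and counted.
#'
#' @param X autoscaled matrix with rownames = subject ids.
#' @param y named 0/1 vector (1 = case/NS).
#' @param pairs a `pair_set`.
#' @param B number of bootstrap iterations (default 200).
#' @param alpha elastic-net mixing parameter (default 0.75).
#' @param threshold influence threshold on the selection frequency
#'   (default 0.70, strict inequality).
#' @param seed integer seed.
#' @param n_folds CV folds inside each bootstrap (default 5).
#' @return data.frame of class `selection_profile`: analyte_id,
#'   selection_frequency, mean_coefficient, influential; attributes `B`,
#'   `alpha`, `threshold`, `seed`, `redrawn`.
#' @export
bootstrap_selection <- function(X, y, pairs, B = 200L, alpha = 0.75,
                                threshold = 0.70, seed = 1L, n_folds = 5) {
  stopifnot(B >= 1)
  pr <- pairs$pairs
  n_pairs <- nrow(pr)
  p <- ncol(X)
  seeds <- derive_seeds(seed, B)
  sel <- matrix(0, B, p, dimnames = list(NULL, colnames(X)))
  coefs <- matrix(0, B, p)
  redrawn <- 0L
  for (b in seq_len(B)) {
    res <- with_seed(seeds[b], {
      for (attempt in 1:10) {
        idx <- sample.int(n_pairs, n_pairs, replace = TRUE)
        ids <- c(pr$case_id[idx], pr$control_id[idx])
        if (length(unique(y[ids])) == 2) break
        redrawn <- redrawn + 1L
      }
      bpr <- structure(list(pairs = data.frame(
        case_id = pr$case_id[idx], control_id = pr$control_id[idx],
        distance = NA_real_, stringsAsFactors = FALSE),
        unmatched = character(0)), class = "pair_set")
      Xb <- X[ids, , drop = FALSE]
      yb <- y[ids]
      tun <- tune_lambda_cv(Xb, yb, bpr, alpha = alpha, n_folds = n_folds)
      fit <- fit_elastic_net_logistic(Xb, yb, alpha = alpha,
                                      lambda = tun$lambda_opt)
      fit$beta
    })
    sel[b, ] <- res != 0
    coefs[b, ] <- res
  }
  out <- data.frame(
    analyte_id = colnames(X),
    selection_frequency = colMeans(sel),
    mean_coefficient = colMeans(coefs),
    row.names = NULL, stringsAsFactors = FALSE)
  out$influential <- out$selection_frequency > threshold
  attr(out, "B") <- B; attr(out, "alpha") <- alpha
  attr(out, "threshold") <- threshold; attr(out, "seed") <- seed
  attr(out, "redrawn") <- redrawn
  class(out) <- c("selection_profile", "data.frame")
  out
}

#' Union of univariate top-significant and multivariable influential analytes
#'
#' The differential set is the union of the analytes flagged
#' `top_significant` by the univariate screen and those flagged
#' `influential` by stability selection, with per-analyte provenance.
#'
#' @param univ a `univariate_table` from [screen_analytes()].
#' @param prof a `selection_profile` from [bootstrap_selection()].
#' @return data.frame of class `differential_set`: analyte_id, provenance
#'   (univariate / multivariable / both).
#' @export
union_differential <- function(univ, prof) {
  if (!setequal(univ$analyte_id, prof$analyte_id))
    stop("mismatched analyte universes between univariate table and profile")
  u <- univ$analyte_id[univ$top_significant]
  m <- prof$analyte_id[prof$influential]
  ids <- union(u, m)
  out <- data.frame(
    analyte_id = ids,
    provenance = ifelse(ids %in% u & ids %in% m, "both",
                        ifelse(ids %in% u, "univariate", "multivariable")),
    stringsAsFactors = FALSE)
  class(out) <- c("differential_set", "data.frame")
  out
}
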