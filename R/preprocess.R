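#' QC CV and detection filtering
#'
#' Retains analytes whose coefficient of variation across raw QC replicate
#' samples is below `cv_max` and whose detection fraction is at least
#' `detect_min` in at least one outcome group ("either group" rule). The CV
#' is computed on the raw (not log) QC values as sample SD / mean. With
#' `qc = NULL`, only the detection rule is applied (used for blocks without
#' QC replicates, e.g. the cytokine panel).
#'
#' @param matrix an [analyte_matrix()].
#' @param qc replicate x analyte QC matrix covering all analytes, or NULL.
#' @param groups character/factor of length n_subjects with levels NS/S
#'   (other levels, e.g. HC, are ignored for detection fractions).
#' @param cv_max maximum QC CV (default 0.30).
#' @param detect_min minimum detection fraction in either group (default 0.80).
#' @return list with elements `matrix` (filtered) and `report` (a
#'   `qc_report` data.frame: analyte, cv, detect_ns, detect_s, retained,
#'   reasons).
#' @export
cv_detection_filter <- function(matrix, qc, groups,
                                cv_max = 0.30, detect_min = 0.80) {
  stopifnot(inherits(matrix, "analyte_matrix"))
  v <- matrix$values
  ids <- colnames(v)
  if (!is.null(qc)) {
    missing_qc <- setdiff(ids, colnames(qc))
    if (length(missing_qc))
      stop("analytes missing from QC matrix: ",
           paste(utils::head(missing_qc, 5), collapse = ", "))
    qc <- qc[, ids, drop = FALSE]
    mu <- colMeans(qc)
    cv <- ifelse(mu == 0, Inf, apply(qc, 2, stats::sd) / mu)
  } else {
    cv <- rep(NA_real_, length(ids))
  }
  ns <- groups == "NS"
  s <- groups == "S"
  det_ns <- colMeans(!is.na(v[ns, , drop = FALSE]))
  det_s <- colMeans(!is.na(v[s, , drop = FALSE]))
  cv_ok <- is.na(cv) | cv < cv_max
  det_ok <- det_ns >= detect_min | det_s >= detect_min
  retained <- cv_ok & det_ok
  reasons <- mapply(function(c_ok, d_ok) paste(
    c(if (!c_ok) "cv_fail", if (!d_ok) "detection_fail"), collapse = ";"),
    cv_ok, det_ok)
  report <- data.frame(analyte_id = ids, cv = unname(cv),
                       detect_ns = unname(det_ns), detect_s = unname(det_s),
                       retained = unname(retained), reasons = unname(reasons),
                       stringsAsFactors = FALSE)
  class(report) <- c("qc_report", "data.frame")
  out <- analyte_matrix(matrix$block, v[, retained, drop = FALSE],
                        matrix$classes[retained],
                        lod = if (is.null(matrix$lod)) NULL
                              else matrix$lod[retained],
                        units = matrix$units)
  list(matrix = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d assayed: %d retained, %d removed (%s)\n",
              nrow(x), sum(x$retained), sum(!x$retained),
              paste(names(table(x$reasons[!x$retained])),
                    table(x$reasons[!x$retained]), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Impute non-detects at half the limit of detection
#'
#' Every masked (NA) value is replaced by LOD/2 for its analyte; detected
#' values are untouched.
#'
#' @param matrix an [analyte_matrix()] with per-analyte `lod`. If `lod` is
#'   absent, it is taken as the minimum observed value per analyte
#'   (half-minimum imputation, the platform fallback for blocks without
#'   calibrated detection limits).
#' @return the imputed [analyte_matrix()].
#' @export
impute_lod <- function(matrix) {
  stopifnot(inherits(matrix, "analyte_matrix"))
  v <- matrix$values
  lod <- matrix$lod
  if (is.null(lod)) lod <- apply(v, 2, min, na.rm = TRUE)
  nd <- colSums(is.na(v))
  if (any(nd > 0 & !is.finite(lod)))
    stop("missing LOD for analytes with non-detects: ",
         paste(colnames(v)[nd > 0 & !is.finite(lod)], collapse = ", "))
  for (j in which(nd > 0)) v[is.na(v[, j]), j] <- lod[j] / 2
  analyte_matrix(matrix$block, v, matrix$classes, lod = matrix$lod,
                 units = matrix$units)
}

#' Remove proteins with excessive missingness
#'
#' Proteins not detected in more than `max_missing` of subjects are
#' removed; the remainder passes on to kNN imputation.
#'
#' @param matrix an [analyte_matrix()].
#' @param max_missing maximum tolerated missing fraction (default 0.20).
#' @return list with `matrix` and `report` (a `qc_report`).
#' @export
protein_missingness_filter <- function(matrix, max_missing = 0.20) {
  stopifnot(inherits(matrix, "analyte_matrix"))
  v <- matrix$values
  miss <- colMeans(is.na(v))
  retained <- miss <= max_missing
  if (!any(retained)) stop("no analytes left after missingness filtering")
  report <- data.frame(analyte_id = colnames(v), cv = NA_real_,
                       detect_ns = NA_real_, detect_s = NA_real_,
                       missing_fraction = unname(miss),
                       retained = unname(retained),
                       reasons = ifelse(retained, "", "missingness_fail"),
                       stringsAsFactors = FALSE)
  class(report) <- c("qc_report", "data.frame")
  out <- analyte_matrix(matrix$block, v[, retained, drop = FALSE],
                        matrix$classes[retained], units = matrix$units)
  list(matrix = out, report = report)
}

#' k-nearest-neighbour imputation of missing entries
#'
#' For each subject with missing values, neighbours are the `k` closest
#' subjects by Euclidean distance over the analytes observed in both
#' (normalised per shared analyte count); a missing entry is replaced by
#' the mean of the neighbours' observed values for that analyte.
#'
#' @param matrix an [analyte_matrix()].
#' @param k number of neighbours (default 10; must be < n subjects).
#' @return the imputed [analyte_matrix()].
#' @export
knn_impute <- function(matrix, k = 10) {
  stopifnot(inherits(matrix, "analyte_matrix"))
  v <- matrix$values
  n <- nrow(v)
  if (k >= n) stop("k must be smaller than the number of subjects")
  if (!anyNA(v)) return(matrix)
  if (any(rowSums(!is.na(v)) == 0))
    stop("subjects with no observed values cannot be imputed")
  lv <- v
  obs <- !is.na(lv)
  out <- v
  need <- which(rowSums(is.na(v)) > 0)
  for (i in need) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) {
      if (j == i) next
      sh <- obs[i, ] & obs[j, ]
      if (!any(sh)) next
      d[j] <- sqrt(mean((lv[i, sh] - lv[j, sh])^2))
    }
    ord <- order(d, seq_len(n))
    miss_j <- which(is.na(v[i, ]))
    for (g in miss_j) {
      donors <- ord[obs[ord, g] & is.finite(d[ord])]
      donors <- utils::head(donors, k)
      if (!length(donors))
        stop("no donors available for subject ", rownames(v)[i],
             " analyte ", colnames(v)[g])
      out[i, g] <- mean(v[donors, g])
    }
  }
  analyte_matrix(matrix$block, out, matrix$classes, lod = matrix$lod,
                 units = matrix$units)
}

#' Location/scale batch correction with optional empirical-Bayes shrinkage
#'
#' ComBat-style adjustment on the log10 scale: per analyte, data are
#' standardised against the grand mean and pooled variance; per-batch
#' location (gamma) and scale (delta^2) parameters are estimated and, with
#' `shrinkage = TRUE`, shrunk toward their across-analyte means via the
#' parametric empirical-Bayes iteration (normal prior on gamma,
#' inverse-gamma on delta^2) before the adjusted data are back-transformed.
#'
#' @param matrix an [analyte_matrix()] without missing values.
#' @param batch_labels character/factor of batch assignments (>= 2 subjects
#'   per batch).
#' @param shrinkage apply empirical-Bayes shrinkage (default TRUE).
#' @return batch-corrected [analyte_matrix()] (raw concentration scale).
#' @export
batch_correct <- function(matrix, batch_labels, shrinkage = TRUE) {
  stopifnot(inherits(matrix, "analyte_matrix"))
  v <- matrix$values
  if (anyNA(v)) stop("impute missing values before batch correction")
  batch <- factor(batch_labels)
  if (nlevels(batch) < 2) return(matrix)
  nb <- table(batch)
  if (any(nb < 2) && !shrinkage)
    stop("singleton batch requires shrinkage = TRUE")
  x <- log10(v)
  n <- nrow(x)
  grand <- colMeans(x)
  # pooled variance of residuals around batch means (location effects
  # removed), as in the reference EB batch-correction model
  pooled_var <- vapply(seq_len(ncol(x)), function(j) {
    bm <- tapply(x[, j], batch, mean)
    sum((x[, j] - bm[as.integer(batch)])^2) / n
  }, numeric(1))
  pooled_var[pooled_var == 0] <- 1e-12
  z <- sweep(sweep(x, 2, grand), 2, sqrt(pooled_var), "/")

  gamma_hat <- apply(z, 2, function(col) tapply(col, batch, mean))
  delta_hat <- apply(z, 2, function(col) tapply(col, batch, stats::var))
  if (nlevels(batch) == 1) {
    gamma_hat <- matrix(gamma_hat, 1); delta_hat <- matrix(delta_hat, 1)
  }
  delta_hat[is.na(delta_hat)] <- 1

  if (shrinkage) {
    gamma_star <- gamma_hat; delta_star <- delta_hat
    for (b in seq_len(nlevels(batch))) {
      g <- gamma_hat[b, ]; d <- delta_hat[b, ]; nbb <- nb[b]
      g_bar <- mean(g); t2 <- stats::var(g)
      # method-of-moments inverse-gamma prior on delta^2
      v_bar <- mean(d); s2 <- stats::var(d)
      a_prior <- (2 * s2 + v_bar^2) / s2
      b_prior <- (v_bar * s2 + v_bar^3) / s2
      if (!is.finite(a_prior) || s2 == 0) { a_prior <- 2; b_prior <- v_bar }
      g_new <- g; d_new <- d
      for (it in 1:100) {
        g_old <- g_new; d_old <- d_new
        g_new <- (t2 * nbb * g + d_new * g_bar) / (t2 * nbb + d_new)
        zb <- z[batch == levels(batch)[b], , drop = FALSE]
        sse <- colSums((sweep(zb, 2, g_new))^2)
        d_new <- (b_prior + 0.5 * sse) / (nbb / 2 + a_prior - 1)
        if (max(abs(g_new - g_old), abs(d_new - d_old)) < 1e-8) break
      }
      gamma_star[b, ] <- g_new
      delta_star[b, ] <- d_new
    }
  } else {
    gamma_star <- gamma_hat; delta_star <- delta_hat
  }

  adj <- z
  for (b in seq_len(nlevels(batch))) {
    rows <- batch == levels(batch)[b]
    adj[rows, ] <- sweep(sweep(z[rows, , drop = FALSE], 2, gamma_star[b, ]),
                         2, sqrt(pmax(delta_star[b, ], 1e-12)), "/")
  }
  xc <- sweep(sweep(adj, 2, sqrt(pooled_var), "*"), 2, grand, "+")
  analyte_matrix(matrix$block, 10^xc, matrix$classes, lod = matrix$lod,
                 units = matrix$units)
}

#' Log10 transform and autoscale
#'
#' Column-wise log10 transform followed by mean-centering and scaling to
#' unit sample variance (autoscaling). Zero-variance columns are dropped
#' with a warning.
#'
#' @param matrix an [analyte_matrix()] with strictly positive values and no
#'   missing entries, or a plain numeric matrix already on the log-like
#'   scale (then only centered/scaled — used for re-autoscaling residuals).
#' @param log10_transform apply the log10 transform first (default TRUE).
#' @return object of class `processed_matrix`: list with `values`
#'   (subjects x analytes, dimensionless), `classes`, `block`, `provenance`.
#' @export
transform_autoscale <- function(matrix, log10_transform = TRUE) {
  if (inherits(matrix, "analyte_matrix")) {
    v <- matrix$values; classes <- matrix$classes; block <- matrix$block
    prov <- list()
  } else if (inherits(matrix, "processed_matrix")) {
    v <- matrix$values; classes <- matrix$classes; block <- matrix$block
    prov <- matrix$provenance
  } else {
    v <- as.matrix(matrix); classes <- rep("analyte", ncol(v)); block <- NA
    prov <- list()
  }
  if (anyNA(v)) stop("missing values present; impute before autoscaling")
  if (log10_transform) {
    if (any(v <= 0)) stop("non-positive values; cannot log10 transform")
    v <- log10(v)
    prov <- c(prov, list("log10"))
  }
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  # treat numerically-degenerate columns (e.g. exact-fit residuals) as zero
  zero <- !is.finite(sdv) | sdv <= 1e-10 * max(1, max(abs(v)))
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance column(s): ",
            paste(utils::head(colnames(v)[zero], 5), collapse = ", "))
    v <- v[, !zero, drop = FALSE]; mu <- mu[!zero]; sdv <- sdv[!zero]
    classes <- classes[!zero]
  }
  v <- sweep(sweep(v, 2, mu), 2, sdv, "/")
  prov <- c(prov, list(list(step = "autoscale")))
  structure(list(values = v, classes = classes, block = block,
                 provenance = prov),
            class = "processed_matrix")
}

#' @export
print.processed_matrix <- function(x, ...) {
  cat(sprintf("<processed_matrix> %d x %d (log10 autoscaled)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
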