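#' Cohort descriptive summary with between-group tests
#'
#' Continuous variables are summarized as mean +/- SD (median/IQR
#' available) with a Welch two-sample t-test; categorical/logical
#' variables as n (%) per group with a chi-square test without continuity
#' correction (Fisher's exact test when a 2x2 cell is zero). Percentages
#' use non-missing denominators.
#'
#' @param subjects subject data.frame with `outcome` (NS/S; other levels
#'   are ignored).
#' @param variables character vector of columns to summarize.
#' @param continuous_summary "mean_sd" (default) or "median_iqr".
#' @return data.frame of class `cohort_summary`: variable, level,
#'   summary_ns, summary_s, p, test.
#' @export
summarize_cohort <- function(subjects, variables,
                             continuous_summary = c("mean_sd", "median_iqr")) {
  continuous_summary <- match.arg(continuous_summary)
  miss <- setdiff(variables, names(subjects))
  if (length(miss)) stop("variables not in metadata: ",
                         paste(miss, collapse = ", "))
  dat <- subjects[subjects$outcome %in% c("NS", "S"), ]
  grp <- dat$outcome
  out <- NULL
  for (v in variables) {
    col <- dat[[v]]
    if (all(is.na(col))) stop("all-missing variable: ", v)
    if (is.numeric(col)) {
      xn <- col[grp == "NS"]; xs <- col[grp == "S"]
      fmt <- function(x) {
        x <- x[!is.na(x)]
        if (continuous_summary == "mean_sd")
          sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
        else sprintf("%.1f [%.1f-%.1f]", stats::median(x),
                     stats::quantile(x, 0.25), stats::quantile(x, 0.75))
      }
      p <- tryCatch(stats::t.test(xn, xs)$p.value, error = function(e) NA_real_)
      out <- rbind(out, data.frame(variable = v, level = "",
                                   summary_ns = fmt(xn), summary_s = fmt(xs),
                                   p = p, test = "welch_t",
                                   stringsAsFactors = FALSE))
    } else {
      f <- factor(col)
      tab <- table(f, factor(grp, levels = c("NS", "S")))
      zero_cell <- any(tab == 0)
      test <- if (zero_cell) "fisher" else "chisq"
      p <- tryCatch(
        if (zero_cell) stats::fisher.test(tab)$p.value
        else suppressWarnings(stats::chisq.test(tab,
                                                correct = FALSE)$p.value),
        error = function(e) NA_real_)
      lev <- levels(f)
      show <- if (is.logical(col) || setequal(lev, c("FALSE", "TRUE")))
        "TRUE" else lev
      for (l in show) {
        n_ns <- sum(col[grp == "NS"] == (if (is.logical(col)) as.logical(l) else l),
                    na.rm = TRUE)
        n_s <- sum(col[grp == "S"] == (if (is.logical(col)) as.logical(l) else l),
                   na.rm = TRUE)
        d_ns <- sum(!is.na(col[grp == "NS"]))
        d_s <- sum(!is.na(col[grp == "S"]))
        out <- rbind(out, data.frame(
          variable = v, level = if (length(show) == 1) "" else l,
          summary_ns = sprintf("%d (%.1f%%)", n_ns, 100 * n_ns / d_ns),
          summary_s = sprintf("%d (%.1f%%)", n_s, 100 * n_s / d_s),
          p = p, test = test, stringsAsFactors = FALSE))
      }
    }
  }
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Residualize analytes on a covariate
#'
#' Per analyte: ordinary least squares on the covariate (with intercept);
#' residuals are returned re-autoscaled. Columns left with zero variance
#' (analyte collinear with the covariate) are dropped with a warning.
#'
#' @param processed a `processed_matrix` (or plain matrix).
#' @param covariate numeric/logical vector, named by subject id or aligned
#'   with rows; must be non-constant.
#' @return a `processed_matrix` of autoscaled residuals.
#' @export
residualize <- function(processed, covariate) {
  X <- if (inherits(processed, "processed_matrix")) processed$values
       else as.matrix(processed)
  cv <- if (!is.null(names(covariate))) as.numeric(covariate[rownames(X)])
        else as.numeric(covariate)
  if (anyNA(cv)) stop("covariate missing for some subjects")
  if (stats::sd(cv) == 0) stop("constant covariate")
  cvc <- cv - mean(cv)
  beta <- drop(crossprod(X, cvc)) / sum(cvc^2)
  res <- sweep(X, 2, colMeans(X)) - outer(cvc, beta)
  rownames(res) <- rownames(X)
  out <- transform_autoscale(res, log10_transform = FALSE)
  if (inherits(processed, "processed_matrix")) {
    out$block <- processed$block
    out$classes <- processed$classes[colnames(processed$values) %in%
                                     colnames(out$values)]
  }
  out
}

#' Pipeline configuration
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort (or
#'   NULL to read an existing cohort from `input_dir`).
#' @param input_dir directory with a cohort written by [write_cohort()]
#'   (used when `cohort` is NULL).
#' @param outdir output directory for stage artifacts.
#' @param seed master seed; all stage seeds derive from it.
#' @param B,alpha,threshold stability-selection parameters.
#' @param n_folds_cv,n_repeats_cv PLS-DA cross-validation design.
#' @param n_components PLS-DA components.
#' @param snf_K,snf_mu,snf_t SNF kernel and fusion parameters.
#' @param adjust_for "none", "edema" or "whz" (univariate adjustment).
#' @param residualize_on NULL, "edema" or "whz" (multivariable
#'   sensitivity analysis on residualized matrices).
#' @param cv_max,detect_min,max_missing,knn_k preprocessing thresholds.
#' @param resume skip stages whose outputs already exist.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), input_dir = NULL,
                            outdir = tempfile("csmomics_run_"),
                            seed = 1L, B = 200L, alpha = 0.75,
                            threshold = 0.70, n_folds_cv = 10L,
                            n_repeats_cv = 20L, n_components = 2L,
                            snf_K = 20L, snf_mu = 0.5, snf_t = 20L,
                            adjust_for = c("none", "edema", "whz"),
                            residualize_on = NULL,
                            cv_max = 0.30, detect_min = 0.80,
                            max_missing = 0.20, knn_k = 10L,
                            resume = FALSE) {
  adjust_for <- match.arg(adjust_for)
  stopifnot(B >= 1, alpha >= 0, alpha <= 1, threshold > 0, threshold < 1,
            cv_max > 0, detect_min > 0, detect_min <= 1)
  if (!is.null(residualize_on))
    residualize_on <- match.arg(residualize_on, c("edema", "whz"))
  if (is.null(cohort) && is.null(input_dir))
    stop("either a cohort config or an input directory is required")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full discovery pipeline
#'
#' Executes simulate (or load) -> preprocess -> summarize -> univariate
#' (+ ratios) -> stability -> union -> multilevel PLS-DA -> differential
#' correlation network -> SNF, writing versioned TSV/JSON artifacts per
#' stage plus a manifest of parameters and file hashes. Deterministic
#' under a fixed master seed.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the in-memory stage results and the
#'   output directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  # coarse resumption: a completed run with identical seed and parameters
  # is not recomputed (its manifest vouches for the artifacts)
  man_path <- file.path(out, "manifest.json")
  if (isTRUE(config$resume) && file.exists(man_path)) {
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    if (identical(as.integer(man$seed), as.integer(config$seed)))
      return(invisible(list(outdir = out, resumed = TRUE)))
  }
  seeds <- derive_seeds(config$seed, 10)
  wtsv <- function(df, f) utils::write.table(
    df, file.path(out, f), sep = "\t", quote = FALSE, row.names = FALSE,
    na = "NA")
  results <- list(outdir = out)

  # -- simulate / load --------------------------------------------------
  if (!is.null(config$cohort)) {
    cfg <- config$cohort
    cfg$seed <- seeds[1]
    ds <- generate_cohort(cfg)
    write_cohort(ds, file.path(out, "cohort"))
  } else {
    if (!dir.exists(config$input_dir))
      stop("input directory does not exist: ", config$input_dir)
    ds <- read_cohort(config$input_dir)
  }
  results$dataset <- ds
  subjects <- ds$subjects
  paired <- subjects[!is.na(subjects$pair_id), ]
  pairs <- pairs_from_subjects(subjects)
  outcome <- stats::setNames(subjects$outcome, subjects$subject_id)
  groups <- outcome[paired$subject_id]

  # -- cohort summary ---------------------------------------------------
  flag_cols <- grep("^flag_", names(subjects), value = TRUE)
  cont_cols <- intersect(c("age_months", "muac_cm", "whz"), names(subjects))
  summ <- summarize_cohort(subjects, c(cont_cols, "hiv", "edema", flag_cols))
  wtsv(summ, "cohort_summary.tsv")
  results$summary <- summ

  # -- preprocess -------------------------------------------------------
  processed <- list(); raw_filtered <- list(); qc_reports <- list()
  for (b in names(ds$matrices)) {
    m <- ds$matrices[[b]]
    # restrict to paired subjects for the case-control analysis sample
    m <- analyte_matrix(b, m$values[paired$subject_id, , drop = FALSE],
                        m$classes, lod = m$lod, units = m$units)
    if (b == "metabolite") {
      flt <- cv_detection_filter(m, ds$qc_samples, groups,
                                 cv_max = config$cv_max,
                                 detect_min = config$detect_min)
      imp <- impute_lod(flt$matrix)
    } else if (b == "protein") {
      flt <- protein_missingness_filter(m, max_missing = config$max_missing)
      imp <- knn_impute(flt$matrix, k = config$knn_k)
      imp <- batch_correct(imp, subjects$batch[match(rownames(imp$values),
                                                     subjects$subject_id)])
    } else {
      flt <- cv_detection_filter(m, NULL, groups,
                                 detect_min = config$detect_min)
      imp <- impute_lod(flt$matrix)  # half-minimum (no calibrated LOD)
    }
    qc_reports[[b]] <- flt$report
    wtsv(flt$report, paste0("qc_report_", b, ".tsv"))
    proc <- transform_autoscale(imp)
    processed[[b]] <- proc
    raw_filtered[[b]] <- imp
    wtsv(data.frame(subject_id = rownames(proc$values), proc$values,
                    check.names = FALSE), paste0("processed_", b, ".tsv"))
  }
  results$processed <- processed
  results$qc_reports <- qc_reports

  # optional covariate vectors
  adj_vec <- NULL
  if (config$adjust_for != "none") {
    adj_vec <- stats::setNames(
      if (config$adjust_for == "edema") as.numeric(subjects$edema)
      else subjects$whz, subjects$subject_id)
  }

  # -- univariate + ratios ---------------------------------------------
  univ <- list()
  for (b in names(processed)) {
    univ[[b]] <- screen_analytes(processed[[b]], pairs,
                                 raw = raw_filtered[[b]],
                                 adjust_for = adj_vec)
    tab <- univ[[b]]
    tab$log2_fc <- log2(tab$fold_change)
    tab$neg_log10_q <- -log10(pmax(tab$q, 1e-300))
    wtsv(tab, paste0("univariate_", b, ".tsv"))
  }
  results$univariate <- univ
  if ("metabolite" %in% names(raw_filtered)) {
    have <- colnames(raw_filtered$metabolite$values)
    defs <- Filter(function(d) all(setdiff(c(d$numerator, d$denominator), "1")
                                   %in% have), builtin_ratios())
    if (length(defs)) {
      ratios <- compute_ratios(raw_filtered$metabolite, defs)
      proc_r <- transform_autoscale(ratios)
      univ_r <- screen_analytes(proc_r, pairs, raw = ratios,
                                adjust_for = adj_vec, block = "metabolite")
      wtsv(univ_r, "univariate_ratios.tsv")
      results$ratios <- univ_r
    }
  }

  # -- stability selection + union -------------------------------------
  stab <- list(); diff_sets <- list()
  stab_blocks <- intersect(c("metabolite", "protein"), names(processed))
  for (i in seq_along(stab_blocks)) {
    b <- stab_blocks[i]
    Xb <- processed[[b]]$values
    if (!is.null(config$residualize_on)) {
      rv <- stats::setNames(
        if (config$residualize_on == "edema") as.numeric(subjects$edema)
        else subjects$whz, subjects$subject_id)
      Xb <- residualize(processed[[b]], rv)$values
    }
    yb <- stats::setNames(as.integer(outcome[rownames(Xb)] == "NS"),
                          rownames(Xb))
    stab[[b]] <- bootstrap_selection(Xb, yb, pairs, B = config$B,
                                     alpha = config$alpha,
                                     threshold = config$threshold,
                                     seed = seeds[2 + i])
    wtsv(stab[[b]], paste0("selection_", b, ".tsv"))
    diff_sets[[b]] <- union_differential(univ[[b]], stab[[b]])
    wtsv(diff_sets[[b]], paste0("differential_", b, ".tsv"))
  }
  results$stability <- stab
  results$differential <- diff_sets

  # -- multilevel PLS-DA on differential analytes ----------------------
  plsda_perf <- list()
  for (b in names(diff_sets)) {
    ids <- diff_sets[[b]]$analyte_id
    if (length(ids) < 2) next
    Xd <- processed[[b]]$values[, ids, drop = FALSE]
    yd <- stats::setNames(ifelse(outcome[rownames(Xd)] == "NS", 1, -1),
                          rownames(Xd))
    perf <- cross_validate(Xd, yd, pairs, n_folds = config$n_folds_cv,
                           n_repeats = config$n_repeats_cv,
                           n_components = config$n_components,
                           seed = seeds[5])
    plsda_perf[[b]] <- perf
    Xw <- within_pair_decompose(Xd, pairs)
    fit <- fit_plsda(Xw, yd, config$n_components)
    wtsv(data.frame(subject_id = rownames(Xw), fit$scores,
                    check.names = FALSE), paste0("plsda_scores_", b, ".tsv"))
    wtsv(data.frame(analyte_id = ids, fit$correlations, check.names = FALSE),
         paste0("plsda_correlation_circle_", b, ".tsv"))
    jsonlite::write_json(
      list(summary = perf$summary, explained_x = fit$explained_x,
           dr2_full = fit$r2y),
      file.path(out, paste0("plsda_performance_", b, ".json")),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  results$plsda <- plsda_perf

  # -- differential correlation network --------------------------------
  net_ids <- unlist(lapply(names(diff_sets),
                           function(b) diff_sets[[b]]$analyte_id))
  if ("cytokine" %in% names(processed))
    net_ids <- c(net_ids, colnames(processed$cytokine$values))
  Xall <- do.call(cbind, lapply(processed, `[[`, "values"))
  classes_all <- stats::setNames(
    unlist(lapply(processed, `[[`, "classes")), colnames(Xall))
  net_ids <- intersect(net_ids, colnames(Xall))
  if (length(net_ids) >= 3) {
    Xn <- Xall[, net_ids, drop = FALSE]
    gc_ <- group_correlations(Xn, outcome[rownames(Xn)])
    net <- build_differential_network(gc_, classes = classes_all)
    wtsv(net$edges, "network_edges.tsv")
    wtsv(net$nodes, "network_nodes.tsv")
    hm <- cluster_heatmap(Xn, classes = classes_all[net_ids])
    wtsv(data.frame(analyte_id = rownames(hm$correlation), hm$correlation,
                    check.names = FALSE), "heatmap_correlation.tsv")
    jsonlite::write_json(list(order = hm$order, merge = hm$hclust$merge,
                              height = hm$hclust$height),
                         file.path(out, "heatmap_tree.json"), digits = NA)
    results$network <- net
    results$heatmap <- hm
  }

  # -- SNF --------------------------------------------------------------
  clin_df <- data.frame(
    age_months = paired$age_months, muac_cm = paired$muac_cm,
    hiv = factor(paired$hiv), edema = factor(paired$edema),
    whz = paired$whz,
    lapply(paired[, flag_cols, drop = FALSE], factor),
    row.names = paired$subject_id, check.names = FALSE)
  affinities <- list(clinical = view_affinity(clin_df, K = config$snf_K,
                                              mu = config$snf_mu,
                                              metric = "gower"))
  for (b in names(processed))
    affinities[[b]] <- view_affinity(processed[[b]]$values, K = config$snf_K,
                                     mu = config$snf_mu)
  fused <- snf_fuse(affinities, K = config$snf_K, t = config$snf_t)
  lab2 <- spectral_cluster(fused$fused, 2, seed = seeds[7])
  lab4 <- spectral_cluster(fused$fused, 4, seed = seeds[7])
  conc <- vapply(affinities, view_concordance, numeric(1),
                 fused = fused, k = 2, seed = seeds[7],
                 K = config$snf_K, t = config$snf_t)
  # aggregate biomolecular concordance: omics-only fusion vs full fusion
  omic_views <- setdiff(names(affinities), "clinical")
  if (length(omic_views) >= 2) {
    omics_fused <- snf_fuse(affinities[omic_views], K = config$snf_K,
                            t = config$snf_t)
    conc <- c(conc, biomolecular = view_concordance(
      omics_fused, fused, k = 2, seed = seeds[7]))
  }
  wtsv(data.frame(subject_id = names(lab2), cluster_k2 = lab2,
                  cluster_k4 = lab4[names(lab2)]), "snf_clusters.tsv")
  jsonlite::write_json(as.list(conc), file.path(out, "snf_concordance.json"),
                       auto_unbox = TRUE, digits = NA)
  wtsv(data.frame(subject_id = rownames(fused$fused),
                  round(fused$fused, 10), check.names = FALSE),
       "snf_fused.tsv")
  zx <- deviation_zscores(Xall, subjects)
  wtsv(zx, "deviation_zscores.tsv")
  char <- cluster_characterization(Xall, lab2, outcome)
  wtsv(char$composition, "snf_cluster_composition.tsv")
  results$snf <- list(fused = fused, labels_k2 = lab2, labels_k4 = lab4,
                      concordance = conc, zscores = zx,
                      characterization = char)

  # -- manifest ---------------------------------------------------------
  files <- setdiff(list.files(out, recursive = TRUE),
                   "manifest.json")
  hashes <- as.list(tools::md5sum(file.path(out, files)))
  names(hashes) <- files
  manifest <- list(
    seed = config$seed,
    parameters = list(B = config$B, alpha = config$alpha,
                      threshold = config$threshold,
                      cv_max = config$cv_max, detect_min = config$detect_min,
                      max_missing = config$max_missing, knn_k = config$knn_k,
                      n_folds_cv = config$n_folds_cv,
                      n_repeats_cv = config$n_repeats_cv,
                      snf_K = config$snf_K, snf_mu = config$snf_mu,
                      snf_t = config$snf_t,
                      adjust_for = config$adjust_for,
                      residualize_on = config$residualize_on),
    files = hashes)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
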