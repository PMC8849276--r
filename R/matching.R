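#' Fit a propensity-score model for case status
#'
#' Logistic regression of case status (NS) on the matching covariates,
#' fitted by maximum likelihood; returns the fitted probabilities. An HIV
#' status of "unknown" is treated as its own category.
#'
#' @param subjects data.frame with `outcome` (NS/S) and the covariates.
#' @param covariates character vector of covariate column names
#'   (default age, HIV and MUAC).
#' @return named numeric vector of propensity scores in (0, 1).
#' @export
fit_propensity <- function(subjects,
                           covariates = c("age_months", "hiv", "muac_cm")) {
  stopifnot(all(covariates %in% names(subjects)))
  y <- as.integer(subjects$outcome == "NS")
  dat <- subjects[, covariates, drop = FALSE]
  dat[] <- lapply(dat, function(col)
    if (is.character(col)) factor(col) else col)
  # constant covariates carry no information; drop to keep glm well-posed
  keep <- vapply(dat, function(col) length(unique(col)) > 1, logical(1))
  dat <- dat[, keep, drop = FALSE]
  fit <- if (ncol(dat) == 0)
    stats::glm(y ~ 1, family = stats::binomial())
  else
    stats::glm(y ~ ., data = cbind(y = y, dat), family = stats::binomial())
  ps <- stats::fitted(fit)
  if (any(ps > 1 - 1e-10) || any(ps < 1e-10))
    stop("perfect separation in the propensity model; consider a penalized ",
         "(ridge) fit or coarser covariates")
  names(ps) <- subjects$subject_id
  ps
}

#' Greedy 1:1 nearest-neighbour matching on the propensity logit
#'
#' Matches each case to the closest unmatched control by
#' |logit(score_case) - logit(score_control)|, without replacement. Cases
#' are processed in descending propensity order (hardest to match first);
#' ties are broken by lexicographic subject id.
#'
#' @param scores named propensity vector from [fit_propensity()].
#' @param cases,controls character vectors of subject ids.
#' @param caliper optional maximum logit distance; pairs beyond it are not
#'   formed (default `Inf`, no caliper).
#' @return object of class `pair_set`: data.frame `pairs`
#'   (case_id, control_id, distance) plus attribute `unmatched`.
#' @export
nearest_neighbor_match <- function(scores, cases, controls, caliper = Inf) {
  if (!length(cases) || !length(controls))
    stop("empty case or control set")
  lg <- stats::qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
  ord <- cases[order(-scores[cases], cases)]
  avail <- sort(controls)
  out <- data.frame(case_id = character(0), control_id = character(0),
                    distance = numeric(0), stringsAsFactors = FALSE)
  unmatched <- character(0)
  for (cs in ord) {
    if (!length(avail)) { unmatched <- c(unmatched, cs); next }
    d <- abs(lg[cs] - lg[avail])
    j <- order(d, avail)[1]
    if (d[j] > caliper) { unmatched <- c(unmatched, cs); next }
    out <- rbind(out, data.frame(case_id = cs, control_id = avail[j],
                                 distance = unname(d[j]),
                                 stringsAsFactors = FALSE))
    avail <- avail[-j]
  }
  structure(list(pairs = out, unmatched = c(unmatched, avail)),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d pairs, %d unmatched\n",
              nrow(x$pairs), length(x$unmatched)))
  invisible(x)
}

#' Pair set from a matched cohort's metadata
#'
#' Builds the `pair_set` implied by the `pair_id` column of a cohort's
#' subject table (used when pairs were constructed at generation time).
#'
#' @param subjects subject data.frame with `pair_id` and `outcome`.
#' @return a `pair_set`.
#' @export
pairs_from_subjects <- function(subjects) {
  validate_pairs(subjects)
  m <- subjects[!is.na(subjects$pair_id), ]
  ns <- m[m$outcome == "NS", c("pair_id", "subject_id")]
  s <- m[m$outcome == "S", c("pair_id", "subject_id")]
  mg <- merge(ns, s, by = "pair_id", suffixes = c("_case", "_control"))
  structure(list(pairs = data.frame(case_id = mg$subject_id_case,
                                    control_id = mg$subject_id_control,
                                    distance = NA_real_,
                                    stringsAsFactors = FALSE),
                 unmatched = character(0)),
            class = "pair_set")
}

#' Covariate balance diagnostics for a matched sample
#'
#' Standardised mean differences (SMD) per covariate before matching (all
#' cases vs all controls) and after matching (matched sample only), with
#' variance ratios. SMD = (mean_case - mean_control) /
#' sqrt((var_case + var_control)/2); binary/categorical covariates are
#' expanded to indicator proportions.
#'
#' @param pair_set a `pair_set` from [nearest_neighbor_match()].
#' @param subjects the subject data.frame.
#' @param covariates covariate column names.
#' @return data.frame `balance_table` with columns covariate, smd_before,
#'   smd_after, var_ratio_before, var_ratio_after.
#' @export
balance_diagnostics <- function(pair_set, subjects,
                                covariates = c("age_months", "hiv", "muac_cm")) {
  if (!nrow(pair_set$pairs)) stop("empty pair set")
  num_cols <- function(df) {
    out <- list()
    for (cv in covariates) {
      col <- df[[cv]]
      if (is.numeric(col)) out[[cv]] <- col
      else {
        lv <- sort(unique(as.character(subjects[[cv]])))
        for (l in lv[-1]) out[[paste0(cv, ":", l)]] <- as.numeric(col == l)
      }
    }
    as.data.frame(out, check.names = FALSE)
  }
  smd1 <- function(xc, xt) {
    v <- (stats::var(xc) + stats::var(xt)) / 2
    if (v == 0) return(if (mean(xc) == mean(xt)) 0 else Inf)
    (mean(xc) - mean(xt)) / sqrt(v)
  }
  vr1 <- function(xc, xt) {
    vt <- stats::var(xt)
    if (vt == 0) return(NA_real_)
    stats::var(xc) / vt
  }
  rownames(subjects) <- subjects$subject_id
  all_cases <- subjects[subjects$outcome == "NS", ]
  all_ctrls <- subjects[subjects$outcome == "S", ]
  m_cases <- subjects[pair_set$pairs$case_id, ]
  m_ctrls <- subjects[pair_set$pairs$control_id, ]
  Xc_b <- num_cols(all_cases); Xt_b <- num_cols(all_ctrls)
  Xc_a <- num_cols(m_cases); Xt_a <- num_cols(m_ctrls)
  out <- data.frame(
    covariate = names(Xc_b),
    smd_before = mapply(smd1, Xc_b, Xt_b),
    smd_after = mapply(smd1, Xc_a, Xt_a),
    var_ratio_before = mapply(vr1, Xc_b, Xt_b),
    var_ratio_after = mapply(vr1, Xc_a, Xt_a),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("balance_table", "data.frame")
  out
}
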