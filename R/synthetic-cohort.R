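#' Configuration for the synthetic matched cohort generator
#'
#' Builds the parameter list consumed by [generate_cohort()]. Defaults
#' emulate the structure of a nested matched case-control multi-omics study
#' of mortality in complicated severe malnutrition: 92 nonsurvivor/survivor
#' pairs, a targeted metabolite panel (206 assayed), an untargeted protein
#' block (229 quantified) with missing-at-random dropout and batch shifts,
#' and an inflammatory-mediator block (29 assayed, ~10 poorly detected).
#'
#' Analyte concentrations are log10-normal: for analyte \eqn{g} and subject
#' \eqn{j} in pair \eqn{i},
#' \deqn{\log_{10} x_{gij} = m_g + b_{gi} + 1\{NS\}\,\delta_g \sigma + e_{gij},}
#' where \eqn{b_{gi}} is a pair-shared latent effect (variance
#' \code{icc_pair} \eqn{\sigma^2}), \eqn{\delta_g} is the planted
#' standardized mean shift (nonzero only for the differential set) and
#' residuals are correlated within analyte class with correlation
#' \code{rho_class}. Non-detects arise by left-censoring metabolites at a
#' per-analyte LOD; proteins get per-analyte Beta-distributed dropout rates
#' and per-batch mean shifts.
#'
#' @param n_pairs number of matched NS/S pairs (>= 3).
#' @param n_hc number of unmatched healthy-community reference subjects.
#' @param blocks named list (names in metabolite/protein/cytokine); each
#'   element a list with `n_analytes` and `n_differential`.
#' @param delta_range range of |delta| (standardized log10 mean shift) for
#'   differential analytes; signs are drawn at random. Must lie in (0, 5).
#' @param sigma_log10 within-group SD of log10 concentrations.
#' @param icc_pair fraction of within-group variance shared within a pair.
#' @param rho_class residual correlation among analytes of the same class.
#' @param lod_quantile left-censoring quantile for metabolites.
#' @param low_detect_frac fraction of metabolites censored at their median
#'   (these fail an 80% detection rule by construction).
#' @param dropout_mean mean of the per-protein Beta dropout rate.
#' @param n_batches,batch_shift_sd protein batch structure: number of
#'   batches and SD of the per-batch per-protein log10 mean shift.
#' @param n_corr_pairs number of planted differential-correlation analyte
#'   pairs (among non-differential metabolites), with group-wise Pearson
#'   correlations `r_s` (survivors) and `r_ns` (nonsurvivors).
#' @param r_s,r_ns planted group-wise correlations, |r| < 1.
#' @param clinical_logodds log-odds increment on each clinical danger flag
#'   for nonsurvivors (weak clinical signal).
#' @param n_qc_replicates,cv_fail_frac,cv_pass_range,cv_fail_range QC
#'   sample design: replicate count, fraction of metabolites whose QC CV
#'   exceeds 30%, and the CV ranges for passing/failing analytes.
#' @param seed integer master seed.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 92,
                          n_hc = 0,
                          blocks = list(
                            metabolite = list(n_analytes = 206, n_differential = 32),
                            protein    = list(n_analytes = 229, n_differential = 25),
                            cytokine   = list(n_analytes = 29,  n_differential = 8)
                          ),
                          delta_range = c(0.4, 1.0),
                          sigma_log10 = 0.25,
                          icc_pair = 0.3,
                          rho_class = 0.2,
                          lod_quantile = 0.02,
                          low_detect_frac = 0.08,
                          dropout_mean = 0.08,
                          n_batches = 4,
                          batch_shift_sd = 0.3,
                          n_corr_pairs = 6,
                          r_s = 0.7,
                          r_ns = 0.0,
                          clinical_logodds = 0.7,
                          n_qc_replicates = 10,
                          cv_fail_frac = 0.25,
                          cv_pass_range = c(0.03, 0.25),
                          cv_fail_range = c(0.32, 0.45),
                          seed = 1L) {
  stopifnot(n_pairs >= 3, n_hc >= 0, length(blocks) >= 1)
  if (is.null(names(blocks)) || !all(names(blocks) %in%
        c("metabolite", "protein", "cytokine")))
    stop("blocks must be named among 'metabolite', 'protein', 'cytokine'")
  if (any(abs(delta_range) >= 5))
    stop("delta outside (-5, 5) rejected as implausible")
  for (b in names(blocks)) {
    bl <- blocks[[b]]
    if (bl$n_analytes < 1) stop("non-positive analyte count in block ", b)
    nd <- bl$n_differential %||% 0
    if (nd < 0 || nd > bl$n_analytes)
      stop("n_differential out of range in block ", b)
    blocks[[b]]$n_differential <- nd
  }
  if (abs(r_s) >= 1 || abs(r_ns) >= 1) stop("planted |r| must be < 1")
  structure(as.list(environment()), class = "cohort_config")
}

# ---- analyte panels ---------------------------------------------------------

amino_acids <- c("Ala", "Arg", "Asn", "Asp", "Cit", "Gln", "Glu", "Gly",
                 "His", "Ile", "Leu", "Lys", "Met", "Orn", "Phe", "Pro",
                 "Ser", "Thr", "Trp", "Tyr", "Val", "xLeu")

organic_acids <- c("Propionate", "Isobutyrate", "Butyrate", "Pyruvate",
                   "Fumarate", "Succinate", "Lactate", "Citrate",
                   "a-Ketoglutarate", "b-Hydroxybutyrate", "Urate", "HVA",
                   "p-HPA", "5-HIAA", "Glycolate", "Oxalate", "Malonate",
                   "Methylmalonate")

cytokine_panel <- c("TNFa", "IL7", "IL8", "IL15", "GCSF", "MCP1", "MIP1b",
                    "IL4", "IL6", "IL10", "IL1b", "IL2", "IL5", "IL12p70",
                    "IL13", "IL17A", "IFNg", "GMCSF", "EGF", "VEGF", "FGF2",
                    "TGFa", "Eotaxin", "Fractalkine", "IP10", "MDC",
                    "sCD40L", "IL1RA", "IL9")

# Curated targeted panel of 206 metabolites with class labels; used when a
# metabolite block is requested at exactly that size, otherwise generic ids.
metabolite_panel <- function() {
  ba <- c("Kynurenine", "Creatinine", "Taurine",
          sprintf("BA%02d", 4:20))                       # 20 biogenic amines
  ac <- c("C0", "C2", "C3", "C4", "C5", "C6", "C8", "C10", "C12", "C14",
          "C16", "C18", sprintf("AC%02d", 13:40))        # 40 acylcarnitines
  lyso <- sprintf("lysoPC a C%d:%d",
                  rep(c(14, 16, 17, 18, 20, 24, 26, 28), each = 2),
                  rep(0:1, 8))                           # 16 lysoPC
  pc <- sprintf("PC aa C%d:%d",
                rep(seq(24, 42, by = 2), each = 6)[1:60],
                rep(0:5, 10))                            # 60 PC aa
  pce <- sprintf("PC ae C%d:%d", rep(seq(30, 42, 2), each = 2), rep(1:2, 7))
  sm <- c(sprintf("SM C%d:%d", rep(c(16, 18, 20, 22, 24, 26), each = 2),
                  rep(0:1, 6)),
          "SM(OH)C22:1", "SM(OH)C22:2", "SM(OH)C24:1")   # 15 sphingolipids
  ids <- c(amino_acids, ba, ac, lyso, pc, pce, sm, "Hexoses", organic_acids)
  cls <- c(rep("amino acid", length(amino_acids)),
           rep("biogenic amine", length(ba)),
           rep("acylcarnitine", length(ac)),
           rep("lysoPC", length(lyso)),
           rep("PC", length(pc) + length(pce)),
           rep("SM", length(sm)),
           "sugar",
           rep("organic acid", length(organic_acids)))
  stopifnot(!anyDuplicated(ids))
  data.frame(analyte_id = ids, class = cls, stringsAsFactors = FALSE)
}

block_panel <- function(block, n) {
  if (block == "metabolite") {
    full <- metabolite_panel()
    if (n == nrow(full)) return(full)
    if (n < nrow(full)) return(full[seq_len(n), , drop = FALSE])
    data.frame(analyte_id = sprintf("M%03d", seq_len(n)),
               class = rep(c("amino acid", "organic acid", "acylcarnitine",
                             "lysoPC", "SM", "PC"), length.out = n),
               stringsAsFactors = FALSE)
  } else if (block == "protein") {
    data.frame(analyte_id = sprintf("PROT%03d", seq_len(n)),
               class = "protein", stringsAsFactors = FALSE)
  } else {
    ids <- if (n <= length(cytokine_panel)) cytokine_panel[seq_len(n)]
           else c(cytokine_panel, sprintf("CK%02d",
                  seq_len(n - length(cytokine_panel))))
    data.frame(analyte_id = ids, class = "cytokine", stringsAsFactors = FALSE)
  }
}

block_units <- c(metabolite = "uM", protein = "intensity", cytokine = "pg/mL")

# ---- constructors -----------------------------------------------------------

#' Construct an analyte matrix
#'
#' @param block one of "metabolite", "protein", "cytokine".
#' @param values subjects x analytes numeric matrix on the raw concentration
#'   scale; `NA` marks non-detected/missing entries.
#' @param classes character vector of analyte class labels.
#' @param lod per-analyte limit of detection (metabolites), or NULL.
#' @param units concentration units.
#' @return object of class `analyte_matrix`.
#' @export
analyte_matrix <- function(block, values, classes,
                           lod = NULL, units = block_units[[block]]) {
  block <- match.arg(block, c("metabolite", "protein", "cytokine"))
  stopifnot(is.matrix(values), length(classes) == ncol(values))
  if (any(values < 0, na.rm = TRUE))
    stop("negative concentrations are not allowed on the raw scale")
  if (!is.null(lod)) stopifnot(length(lod) == ncol(values))
  structure(list(block = block, values = values, classes = classes,
                 lod = lod, units = units),
            class = "analyte_matrix")
}

#' @export
print.analyte_matrix <- function(x, ...) {
  cat(sprintf("<analyte_matrix> block=%s: %d subjects x %d analytes (%s), %.1f%% missing\n",
              x$block, nrow(x$values), ncol(x$values), x$units,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects (%d pairs%s)\n",
              nrow(x$subjects), sum(x$subjects$outcome == "NS"),
              if (any(x$subjects$outcome == "HC"))
                sprintf(", %d HC", sum(x$subjects$outcome == "HC")) else ""))
  for (m in x$matrices) print(m)
  if (!is.null(x$truth)) {
    nd <- sum(lengths(x$truth$differential_set))
    cat(sprintf("  planted truth: %d differential analytes, %d correlation-shift pairs\n",
                nd, NROW(x$truth$correlation_shift_pairs)))
  }
  invisible(x)
}

# ---- generator --------------------------------------------------------------

#' Generate a synthetic matched case-control multi-omics cohort
#'
#' Draws a full cohort (subject metadata, per-block concentration matrices
#' with missingness, QC samples, and ground-truth annotations) under the
#' model described in [cohort_config()]. Matched pairs are constructed
#' directly (shared latent pair effect) rather than via simulated
#' propensity matching.
#'
#' @param config a [cohort_config()] list.
#' @return object of class `cohort_dataset` with elements `subjects`
#'   (data.frame), `matrices` (named list of [analyte_matrix()]),
#'   `qc_samples` (replicate x metabolite matrix or NULL) and `truth`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n_pairs <- cfg$n_pairs
  n_sub <- 2L * n_pairs + cfg$n_hc
  pair_id <- sprintf("P%03d", seq_len(n_pairs))

  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_sub)),
    outcome = c(rep(c("NS", "S"), n_pairs), rep("HC", cfg$n_hc)),
    pair_id = c(rep(pair_id, each = 2), rep(NA_character_, cfg$n_hc)),
    stringsAsFactors = FALSE
  )

  # clinical covariates; pair members are similar by construction
  age_ns <- exp(rnorm(n_pairs, log(15), 0.8)) + 5
  muac_ns <- pmax(6, rnorm(n_pairs, 10.8, 1.5))
  hiv_lv <- c("pos", "neg", "unknown")
  hiv_ns <- sample(hiv_lv, n_pairs, TRUE, prob = c(0.38, 0.49, 0.13))
  hiv_s <- ifelse(runif(n_pairs) < 0.9, hiv_ns,
                  sample(hiv_lv, n_pairs, TRUE, prob = c(0.38, 0.49, 0.13)))
  age <- as.vector(rbind(age_ns, age_ns * exp(rnorm(n_pairs, 0, 0.1))))
  muac <- as.vector(rbind(muac_ns, pmax(6, muac_ns + rnorm(n_pairs, 0, 0.4))))
  hiv <- as.vector(rbind(hiv_ns, hiv_s))
  if (cfg$n_hc > 0) {
    age <- c(age, exp(rnorm(cfg$n_hc, log(18), 0.6)) + 5)
    muac <- c(muac, rnorm(cfg$n_hc, 14.5, 1))
    hiv <- c(hiv, rep("neg", cfg$n_hc))
  }
  subjects$age_months <- age
  subjects$muac_cm <- muac
  subjects$hiv <- hiv
  subjects$edema <- runif(n_sub) < ifelse(subjects$outcome == "HC", 0.01, 0.30)
  subjects$whz <- rnorm(n_sub, ifelse(subjects$outcome == "HC", -0.2, -3.6),
                        ifelse(subjects$outcome == "HC", 0.8, 1.6))
  subjects$site <- sample(c("Kilifi", "Mombasa", "Blantyre"), n_sub, TRUE,
                          prob = c(0.24, 0.43, 0.33))
  subjects$batch <- sprintf("B%d", sample(cfg$n_batches, n_sub, TRUE))
  tt <- ifelse(subjects$outcome == "NS",
               exp(rnorm(n_sub, log(6), 0.6)),
               exp(rnorm(n_sub, log(8), 0.45)))
  subjects$time_to_event_days <- pmax(1L, as.integer(round(tt)))
  is_ns <- subjects$outcome == "NS"
  flags <- c(flag_diarrhea = 0.33, flag_chest_indrawing = 0.14,
             flag_pneumonia = 0.24, flag_fever = 0.24, flag_vomiting = 0.20)
  for (f in names(flags)) {
    p0 <- flags[[f]]
    eta <- qlogis(p0) + cfg$clinical_logodds * is_ns
    subjects[[f]] <- runif(n_sub) < plogis(eta)
    n_hc_ <- sum(subjects$outcome == "HC")
    if (n_hc_ > 0)
      subjects[[f]][subjects$outcome == "HC"] <- runif(n_hc_) < 0.05
  }

  sigma <- cfg$sigma_log10
  sd_pair <- sqrt(cfg$icc_pair) * sigma
  sd_e <- sqrt(1 - cfg$icc_pair) * sigma
  pair_of <- c(rep(seq_len(n_pairs), each = 2), rep(NA_integer_, cfg$n_hc))

  matrices <- list()
  truth_diff <- list()
  truth_es <- list()
  corr_pairs <- NULL

  for (b in names(cfg$blocks)) {
    bl <- cfg$blocks[[b]]
    p <- bl$n_analytes
    panel <- block_panel(b, p)
    m_g <- switch(b,
      metabolite = runif(p, 0, 2.5),
      protein    = runif(p, 4, 7),
      cytokine   = runif(p, 0.5, 2.5))

    idx_diff <- if (bl$n_differential > 0) sort(sample.int(p, bl$n_differential))
                else integer(0)
    delta <- numeric(p)
    if (length(idx_diff))
      delta[idx_diff] <- runif(length(idx_diff), cfg$delta_range[1],
                               cfg$delta_range[2]) *
                         sample(c(-1, 1), length(idx_diff), TRUE)

    # residuals with within-class correlation via a shared class factor
    cls <- panel$class
    f_cls <- matrix(rnorm(n_sub * length(unique(cls))), n_sub)
    colnames(f_cls) <- unique(cls)
    u <- matrix(rnorm(n_sub * p), n_sub, p)
    rho <- cfg$rho_class
    eps <- sd_e * (sqrt(rho) * f_cls[, cls, drop = FALSE] + sqrt(1 - rho) * u)

    # pair effects, independent across analytes
    b_pair <- matrix(rnorm(n_pairs * p, 0, sd_pair), n_pairs, p)
    bmat <- matrix(0, n_sub, p)
    bmat[!is.na(pair_of), ] <- b_pair[pair_of[!is.na(pair_of)], ]

    shift <- outer(as.numeric(is_ns), delta * sigma)
    lx <- matrix(m_g, n_sub, p, byrow = TRUE) + bmat + shift + eps

    # planted differential-correlation pairs (first block). Differential
    # analytes are preferred hosts (group-specific correlation changes
    # accompany mean shifts, as in the study's networks) so the shifts are
    # visible to the downstream differential-analyte network; the hosts
    # keep their planted mean shift but trade the pair effect for an
    # exactly controlled group-wise correlation.
    if (b == names(cfg$blocks)[1] && cfg$n_corr_pairs > 0) {
      need <- 2L * cfg$n_corr_pairs
      pool <- if (length(idx_diff) >= need) idx_diff
              else seq_len(p)
      if (length(pool) >= need) {
        sel <- sample(pool, need)
        cp <- matrix(sel, ncol = 2, byrow = TRUE)
        for (k in seq_len(nrow(cp))) {
          a <- cp[k, 1]; bcol <- cp[k, 2]
          r_by_g <- ifelse(is_ns, cfg$r_ns, cfg$r_s)
          z1 <- rnorm(n_sub); z2 <- rnorm(n_sub)
          za <- z1
          zb <- r_by_g * z1 + sqrt(1 - r_by_g^2) * z2
          lx[, a] <- m_g[a] + is_ns * delta[a] * sigma + sigma * za
          lx[, bcol] <- m_g[bcol] + is_ns * delta[bcol] * sigma + sigma * zb
        }
        corr_pairs <- data.frame(
          analyte_i = panel$analyte_id[cp[, 1]],
          analyte_j = panel$analyte_id[cp[, 2]],
          r_s = cfg$r_s, r_ns = cfg$r_ns, stringsAsFactors = FALSE)
      }
    }

    if (b == "protein") {
      bshift <- matrix(rnorm(cfg$n_batches * p, 0, cfg$batch_shift_sd),
                       cfg$n_batches, p)
      bi <- as.integer(sub("^B", "", subjects$batch))
      lx <- lx + bshift[bi, , drop = FALSE]
    }

    vals <- 10^lx
    colnames(vals) <- panel$analyte_id
    rownames(vals) <- subjects$subject_id
    lod <- NULL

    if (b == "metabolite") {
      qs <- rep(cfg$lod_quantile, p)
      if (cfg$low_detect_frac > 0) {
        nld <- round(cfg$low_detect_frac * p)
        if (nld > 0) qs[sample(setdiff(seq_len(p), idx_diff), nld)] <- 0.5
      }
      lod <- 10^(m_g + qnorm(qs) * sigma)
      vals[sweep(vals, 2, lod, "<")] <- NA
    } else if (b == "protein") {
      rate <- rbeta(p, 2, 2 / cfg$dropout_mean - 2)
      drop <- sweep(matrix(runif(n_sub * p), n_sub, p), 2, rate, "<")
      vals[drop] <- NA
    } else if (b == "cytokine") {
      # a third of analytes poorly detected (platform sensitivity limits)
      nld <- max(0L, round(p / 3) - 0L)
      if (nld > 0) {
        idl <- sample(setdiff(seq_len(p), idx_diff),
                      min(nld, p - length(idx_diff)))
        for (j in idl) vals[runif(n_sub) < 0.5, j] <- NA
      }
    }

    matrices[[b]] <- analyte_matrix(b, vals, panel$class, lod = lod)
    truth_diff[[b]] <- panel$analyte_id[idx_diff]
    es <- delta[idx_diff]
    names(es) <- panel$analyte_id[idx_diff]
    truth_es[[b]] <- es
  }

  qc <- NULL
  if ("metabolite" %in% names(cfg$blocks)) {
    mb <- matrices$metabolite
    lm_ <- colMeans(log10(mb$values), na.rm = TRUE)
    bad <- !is.finite(lm_)
    lm_[bad] <- log10(mb$lod[bad])
    qc <- qc_matrix_impl(cfg, colnames(mb$values), 10^lm_)
  }

  truth <- list(
    differential_set = truth_diff,
    effect_sizes = unlist(unname(truth_es)),
    correlation_shift_pairs = corr_pairs,
    seed = cfg$seed
  )

  structure(list(subjects = subjects, matrices = matrices,
                 qc_samples = qc, truth = truth, config = cfg),
            class = "cohort_dataset")
}

# QC replicate generator: per-analyte sample CV hits its target exactly by
# affine rescaling of the drawn replicates (guarded against negatives).
qc_matrix_impl <- function(cfg, analyte_ids, means) {
  p <- length(analyte_ids)
  n <- cfg$n_qc_replicates
  if (n < 2) stop("fewer than 2 QC replicates")
  fail <- runif(p) < cfg$cv_fail_frac
  cv <- ifelse(fail,
               runif(p, cfg$cv_fail_range[1], cfg$cv_fail_range[2]),
               runif(p, cfg$cv_pass_range[1], cfg$cv_pass_range[2]))
  out <- matrix(0, n, p, dimnames = list(sprintf("QC%02d", seq_len(n)),
                                         analyte_ids))
  for (j in seq_len(p)) {
    if (cv[j] == 0) { out[, j] <- means[j]; next }
    for (try in 1:100) {
      z <- rnorm(n)
      s <- (z - mean(z)) / sd(z)
      if (min(s) > -0.95 / cv[j]) break
    }
    out[, j] <- means[j] * (1 + cv[j] * s)
  }
  out
}

#' Generate QC replicate samples for the metabolite panel
#'
#' Draws a replicate x metabolite matrix whose per-analyte sample CV equals
#' a target drawn from the configured pass/fail mixture, so a configurable
#' fraction of analytes fails the 30% CV filter.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return replicate x metabolite numeric matrix.
#' @export
generate_qc_samples <- function(config = cohort_config(), seed = config$seed) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  if (config$n_qc_replicates < 3) stop("need at least 3 QC replicates")
  p <- config$blocks$metabolite$n_analytes
  panel <- block_panel("metabolite", p)
  with_seed(seed, {
    means <- 10^runif(p, 0, 2.5)
    qc_matrix_impl(config, panel$analyte_id, means)
  })
}

#' Generate an unmatched case/control pool for matching experiments
#'
#' Produces subject metadata only (no analytes) with confounded covariates:
#' cases are on average younger, with lower MUAC and higher HIV prevalence,
#' so that propensity matching has imbalance to remove.
#'
#' @param n_cases,n_controls group sizes.
#' @param confounding multiplier on the covariate-outcome associations.
#' @param seed integer seed.
#' @return data.frame of subjects with `outcome` in NS/S and matching
#'   covariates (`age_months`, `muac_cm`, `hiv`).
#' @export
generate_matching_pool <- function(n_cases = 30, n_controls = 120,
                                   confounding = 1, seed = 1L) {
  with_seed(seed, {
    n <- n_cases + n_controls
    case <- rep(c(TRUE, FALSE), c(n_cases, n_controls))
    age <- exp(rnorm(n, log(16) - 0.25 * confounding * case, 0.7)) + 5
    muac <- pmax(6, rnorm(n, 11.2 - 0.8 * confounding * case, 1.4))
    hiv <- ifelse(runif(n) < plogis(-0.6 + 0.8 * confounding * case),
                  "pos", "neg")
    data.frame(subject_id = sprintf("U%03d", seq_len(n)),
               outcome = ifelse(case, "NS", "S"),
               age_months = age, muac_cm = muac, hiv = hiv,
               stringsAsFactors = FALSE)
  })
}
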