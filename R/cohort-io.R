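#' Write a cohort dataset to a directory of plain-text files
#'
#' One TSV per block (subjects in rows, analytes in columns, `NA` for
#' missing), a per-block analyte annotation TSV (class, LOD, units), a
#' subject metadata TSV, the QC replicate matrix, and the ground-truth
#' annotations as JSON. [read_cohort()] round-trips losslessly.
#'
#' @param dataset a `cohort_dataset`.
#' @param directory output directory (created if absent).
#' @return `directory`, invisibly.
#' @export
write_cohort <- function(dataset, directory) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, f) utils::write.table(
    df, file.path(directory, f), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA")
  wtsv(dataset$subjects, "subjects.tsv")
  for (b in names(dataset$matrices)) {
    m <- dataset$matrices[[b]]
    df <- data.frame(subject_id = rownames(m$values), m$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    wtsv(df, paste0(b, ".tsv"))
    ann <- data.frame(analyte_id = colnames(m$values), class = m$classes,
                      lod = if (is.null(m$lod)) NA_real_ else m$lod,
                      units = m$units, stringsAsFactors = FALSE)
    wtsv(ann, paste0(b, "_analytes.tsv"))
  }
  if (!is.null(dataset$qc_samples)) {
    qdf <- data.frame(replicate_id = rownames(dataset$qc_samples),
                      dataset$qc_samples, check.names = FALSE)
    wtsv(qdf, "qc_samples.tsv")
  }
  if (!is.null(dataset$truth)) {
    tr <- dataset$truth
    jsonlite::write_json(
      list(differential_set = tr$differential_set,
           effect_sizes = as.list(tr$effect_sizes),
           correlation_shift_pairs = tr$correlation_shift_pairs,
           seed = tr$seed),
      file.path(directory, "truth.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  invisible(directory)
}

#' Read a cohort dataset written by [write_cohort()]
#'
#' Validates invariants on load: non-negative concentrations (violations
#' are reported with subject and analyte), and complete NS/S pairing
#' (orphan pair ids are listed).
#'
#' @param directory directory produced by [write_cohort()].
#' @return a `cohort_dataset`.
#' @export
read_cohort <- function(directory) {
  rtsv <- function(f) utils::read.table(
    file.path(directory, f), sep = "\t", header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, na.strings = "NA")
  subjects <- rtsv("subjects.tsv")
  validate_pairs(subjects)

  blocks <- sub("_analytes\\.tsv$", "",
                list.files(directory, pattern = "_analytes\\.tsv$"))
  ord <- intersect(c("metabolite", "protein", "cytokine"), blocks)
  matrices <- list()
  for (b in ord) {
    df <- rtsv(paste0(b, ".tsv"))
    ann <- rtsv(paste0(b, "_analytes.tsv"))
    vals <- as.matrix(df[, -1, drop = FALSE])
    rownames(vals) <- df$subject_id
    neg <- which(vals < 0, arr.ind = TRUE)
    if (nrow(neg))
      stop(sprintf("negative concentration in block '%s' at subject %s, analyte %s",
                   b, rownames(vals)[neg[1, 1]], colnames(vals)[neg[1, 2]]))
    if (!identical(colnames(vals), ann$analyte_id))
      stop("analyte annotation does not match matrix columns in block ", b)
    lod <- if (all(is.na(ann$lod))) NULL else ann$lod
    matrices[[b]] <- analyte_matrix(b, vals, ann$class, lod = lod,
                                    units = ann$units[1])
  }

  qc <- NULL
  if (file.exists(file.path(directory, "qc_samples.tsv"))) {
    qdf <- rtsv("qc_samples.tsv")
    qc <- as.matrix(qdf[, -1, drop = FALSE])
    rownames(qc) <- qdf$replicate_id
  }

  truth <- NULL
  tf <- file.path(directory, "truth.json")
  if (file.exists(tf)) {
    tj <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth <- list(
      differential_set = as.list(tj$differential_set),
      effect_sizes = unlist(tj$effect_sizes),
      correlation_shift_pairs = if (is.null(tj$correlation_shift_pairs) ||
                                    !NROW(tj$correlation_shift_pairs)) NULL
                                else as.data.frame(tj$correlation_shift_pairs),
      seed = tj$seed)
  }

  structure(list(subjects = subjects, matrices = matrices,
                 qc_samples = qc, truth = truth, config = NULL),
            class = "cohort_dataset")
}

validate_pairs <- function(subjects) {
  m <- subjects[subjects$outcome %in% c("NS", "S") & !is.na(subjects$pair_id), ]
  tab <- table(factor(m$pair_id), factor(m$outcome, levels = c("NS", "S")))
  bad <- rownames(tab)[tab[, "NS"] != 1 | tab[, "S"] != 1]
  if (length(bad))
    stop("orphan or malformed pair_ids (need exactly one NS and one S): ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}
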