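# Shared fixtures: small cohorts and matrices built in code at test time.

# A small, fast cohort: 20 pairs, one metabolite-like block.
small_cohort <- function(seed = 1, n_pairs = 20, n_analytes = 12,
                         n_differential = 3, delta = c(0.8, 1.2), ...) {
  generate_cohort(cohort_config(
    n_pairs = n_pairs,
    blocks = list(metabolite = list(n_analytes = n_analytes,
                                    n_differential = n_differential)),
    delta_range = delta, lod_quantile = 0, low_detect_frac = 0,
    n_corr_pairs = 0, seed = seed, ...))
}

# Processed matrix + pairs + outcome for a cohort's first block.
prep_block <- function(ds, block = "metabolite") {
  paired <- ds$subjects[!is.na(ds$subjects$pair_id), ]
  m <- ds$matrices[[block]]
  m <- analyte_matrix(block, m$values[paired$subject_id, , drop = FALSE],
                      m$classes, lod = m$lod)
  if (anyNA(m$values)) m <- impute_lod(m)
  list(proc = transform_autoscale(m),
       raw = m,
       pairs = pairs_from_subjects(ds$subjects),
       y = stats::setNames(as.integer(paired$outcome == "NS"),
                           paired$subject_id),
       outcome = stats::setNames(paired$outcome, paired$subject_id))
}

# Brute-force conditional-likelihood maximizer: cyclic grid descent, fully
# independent of the Newton fitter.
grid_clogit <- function(D, step = 1e-3, lim = 10) {
  D <- as.matrix(D)
  ll <- function(beta) sum(stats::plogis(drop(D %*% beta), log.p = TRUE))
  p <- ncol(D)
  grid <- seq(-lim, lim, by = step)
  beta <- numeric(p)
  if (p == 1) {
    vals <- vapply(grid, function(b) ll(b), numeric(1))
    return(grid[which.max(vals)])
  }
  for (sweep in 1:8) {
    for (j in seq_len(p)) {
      vals <- vapply(grid, function(b) {
        bb <- beta; bb[j] <- b; ll(bb)
      }, numeric(1))
      beta[j] <- grid[which.max(vals)]
    }
  }
  # refinement sweeps on a fine local grid (coordinate descent stalls at
  # coarse-grid resolution when coordinates are correlated)
  for (sweep in 1:20) {
    for (j in seq_len(p)) {
      fine <- seq(beta[j] - 2 * step, beta[j] + 2 * step, by = step / 20)
      vals <- vapply(fine, function(b) {
        bb <- beta; bb[j] <- b; ll(bb)
      }, numeric(1))
      beta[j] <- fine[which.max(vals)]
    }
  }
  beta
}
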