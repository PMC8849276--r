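#' @keywords internal
"_PACKAGE"

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 1009 + 7919 * seq_len(n)) %% 2147483647
}

logistic <- function(x) 1 / (1 + exp(-x))

# Rank-based (Mann-Whitney) area under the ROC curve.
auc_rank <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
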