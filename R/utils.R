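# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package funnel through this so that a
# single integer seed makes every output bit-reproducible.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a base seed; keeps derived seeds < 2^31
# (double arithmetic, exact below 2^53).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset) * 7919) %%
               2147483399)
}

abort_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "phonovibe_error")
}

check_scalar <- function(x, field, lo = -Inf, hi = Inf,
                         lo_open = FALSE, hi_open = FALSE,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort_field(field, "must not be NULL")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_field(field, "must be a finite numeric scalar")
  }
  if (x < lo || (lo_open && x == lo)) {
    abort_field(field, sprintf("must be %s %s", if (lo_open) ">" else ">=", lo))
  }
  if (x > hi || (hi_open && x == hi)) {
    abort_field(field, sprintf("must be %s %s", if (hi_open) "<" else "<=", hi))
  }
  invisible(x)
}

# Linear-interpolated time at which `x` crosses `level` between samples
# i and i+1 (1-based). Assumes x[i] and x[i+1] straddle the level.
cross_time <- function(x, i, level, up = TRUE) {
  x0 <- x[i]; x1 <- x[i + 1L]
  if (x1 == x0) return(i + 0.5)
  i + (level - x0) / (x1 - x0)
}

# Mann-Whitney AUC of scores for a binary outcome (TRUE = positive class).
auc_mw <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
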