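# Internal numerics and small helpers shared across modules.

# Row-wise log-sum-exp of a matrix; returns a vector of length nrow(m).
# max.col is C-level; "first" tie-breaking keeps it RNG-free.
.rowLogSumExp <- function(m) {
  n <- nrow(m)
  mx <- m[seq_len(n) + n * (max.col(m, ties.method = "first") - 1L)]
  mx + log(.rowSums(exp(m - mx), n, ncol(m)))
}

.logSumExp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
# A NULL seed leaves the global stream untouched.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a base seed, staying inside the
# 32-bit integer range.
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647)
}

.msg <- function(stage, ..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf("[%s] %s", stage, paste0(...)))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
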