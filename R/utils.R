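# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so no function mutates global random state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from a run seed and a stage name.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

assert_scalar_num <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

# Population (1/n) standard deviation per column, the z-score convention.
col_sd_pop <- function(m) {
  mu <- colMeans(m)
  sqrt(colMeans(sweep(m, 2L, mu)^2))
}

# L2-normalize the rows of a matrix; all-zero rows are left untouched.
normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  keep <- nrm > 0
  m[keep, , drop = FALSE] <- m[keep, , drop = FALSE] / nrm[keep]
  m
}

# Cosine similarity between all row pairs of two matrices with equal ncol.
# All-zero rows yield similarity 0 by convention.
row_cosine <- function(a, b) {
  an <- sqrt(rowSums(a^2))
  bn <- sqrt(rowSums(b^2))
  s <- tcrossprod(a, b)
  denom <- outer(an, bn)
  out <- matrix(0, nrow(a), nrow(b))
  ok <- denom > 0
  out[ok] <- s[ok] / denom[ok]
  # clamp FP overshoot so downstream [0,1] invariants hold exactly
  pmin(pmax(out, 0), 1)
}
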