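# Internal helpers shared across modules.

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
# All generators route their randomness through this so that
# seed + preset => bit-identical output, without clobbering the session RNG.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("`%s` must be a single positive finite number", name)
  invisible(x)
}

check_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stopf("`%s` must be a single non-negative finite number", name)
  invisible(x)
}

# Pairwise squared Euclidean distances between rows of a (n x d) and b (m x d),
# computed blockwise to bound memory. Returns, for each row of a, the minimum
# distance to any row of b (nm units preserved).
min_dist_to_set <- function(a, b, block = 512L) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(b) == 0L) stopf("reference point set is empty")
  if (nrow(a) == 0L) return(numeric(0))
  b2 <- rowSums(b * b)
  out <- numeric(nrow(a))
  i <- 1L
  while (i <= nrow(a)) {
    j <- min(i + block - 1L, nrow(a))
    ab <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(ab * ab), b2, "+") - 2 * tcrossprod(ab, b)
    mins <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
    out[i:j] <- sqrt(pmax(mins, 0))
    i <- j + 1L
  }
  out
}

# Rolling mean over a centered window (odd width enforced by caller pad).
roll_stat <- function(x, width, fun) {
  n <- length(x)
  half <- width %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    fun(x[lo:hi])
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
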