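#' @include AllClasses.R
NULL

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring
# the caller's state afterwards. All seeded package operations funnel
# through this helper so that user RNG streams are never disturbed.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a sub-seed for stream `i` from a base seed, staying inside the
# 32-bit integer range.
subSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

# Squared Euclidean cross-distance matrix between rows of A (n x d) and
# rows of B (m x d); clamped at zero against cancellation.
pairwiseSqDist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

pairwiseDist <- function(A, B) sqrt(pairwiseSqDist(A, B))

# Projection of a symmetric matrix onto the PSD cone (eigenvalue clip).
psdProject <- function(m) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  pos <- e$values > 0
  if (all(pos)) {
    return(m)
  }
  v <- e$vectors[, pos, drop = FALSE]
  out <- v %*% (e$values[pos] * t(v))
  (out + t(out)) / 2
}

# Uniform random unit vectors as rows of an n x d matrix.
randomUnitRows <- function(n, d) {
  g <- matrix(stats::rnorm(n * d), n, d)
  g / pmax(sqrt(rowSums(g^2)), .Machine$double.eps)
}

# Stable ascending order by value with ties broken by original index.
stableOrder <- function(values) {
  order(values, seq_along(values), method = "radix")
}
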