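#' @include AllClasses.R utils.R
NULL

asSetMatrix <- function(x) {
  if (is(x, "SampleSet")) {
    return(x@vectors)
  }
  if (is.null(dim(x))) {
    return(matrix(x, nrow = 1))
  }
  as.matrix(x)
}

#' Point-to-set distance
#'
#' The minimum Euclidean distance from a point to any member of a set.
#'
#' @param a numeric vector.
#' @param B a [SampleSet-class] or matrix (rows = members).
#' @return scalar distance.
#' @examples
#' pointToSet(c(1, 0), rbind(c(0, 0), c(3, 0))) # 1
#' @export
pointToSet <- function(a, B) {
  B <- asSetMatrix(B)
  if (nrow(B) == 0) {
    stop("the set must be non-empty")
  }
  if (length(a) != ncol(B)) {
    stop("dimension mismatch between point and set")
  }
  min(pairwiseDist(matrix(a, 1), B))
}

#' Minority subset nearest to another set
#'
#' The `alpha` members of `A` with the smallest point-to-set distance
#' to `B`; ties are broken by original index (stable).
#'
#' @param A,B sample sets (or matrices).
#' @param alpha subset size, `1 <= alpha <= |A|`.
#' @return A [SampleSet-class] holding the selected members of `A`, in
#'   increasing order of their distance to `B`.
#' @export
minoritySubset <- function(A, B, alpha) {
  mA <- asSetMatrix(A)
  mB <- asSetMatrix(B)
  if (alpha < 1 || alpha > nrow(mA)) {
    stop(sprintf(
      "alpha must lie in [1, %d]; got %s", nrow(mA), format(alpha)
    ))
  }
  d <- apply(pairwiseDist(mA, mB), 1, min)
  sel <- stableOrder(d)[seq_len(alpha)]
  SampleSet(mA[sel, , drop = FALSE],
    setId = if (is(A, "SampleSet")) paste0(A@setId, ".minority") else "minority",
    classLabel = if (is(A, "SampleSet")) A@classLabel else NA_character_
  )
}

#' Minority-Based Dissimilarity between two sets
#'
#' For each set, the mean point-to-set distance of its `alpha` members
#' closest to the other set is computed
#' (`alpha = max(1, floor(beta * min(|A|, |B|)))`, the same size on
#' both sides); the two directional terms are combined by `op`. With
#' `alpha` forced to 1 and `op = "min"` this is the minimum point-wise
#' distance; with `beta = 1` and `op = "sum"` it is the mean approach
#' distance.
#'
#' @param A,B sample sets (or matrices).
#' @param beta minority ratio in (0, 1\] (default 0.1).
#' @param op combination of the two directional terms: `"sum"`
#'   (default), `"max"` or `"min"`.
#' @param alpha optional explicit minority size overriding `beta`.
#' @return scalar dissimilarity; symmetric in `A` and `B`.
#' @examples
#' mbd(rbind(c(0, 0)), rbind(c(3, 4))) # 10: both directions 5, summed
#' @export
mbd <- function(A, B, beta = 0.1, op = c("sum", "max", "min"),
                alpha = NULL) {
  op <- match.arg(op)
  mA <- asSetMatrix(A)
  mB <- asSetMatrix(B)
  if (nrow(mA) == 0 || nrow(mB) == 0) {
    stop("both sets must be non-empty")
  }
  if (is.null(alpha)) {
    if (beta <= 0 || beta > 1) {
      stop("beta must lie in (0, 1]")
    }
    alpha <- max(1, floor(beta * min(nrow(mA), nrow(mB))))
  }
  alpha <- min(alpha, nrow(mA), nrow(mB))
  dm <- pairwiseDist(mA, mB)
  dA <- apply(dm, 1, min) # d(a, B)
  dB <- apply(dm, 2, min) # d(A, b)
  termA <- mean(sort(dA, method = "radix")[seq_len(alpha)])
  termB <- mean(sort(dB, method = "radix")[seq_len(alpha)])
  switch(op,
    sum = termA + termB,
    max = max(termA, termB),
    min = min(termA, termB)
  )
}

#' Classic set-to-set distances
#'
#' `MPD` is the global minimum pairwise distance; `MAD` the sum of the
#' two directional means of point-to-set distances; `APD` the mean of
#' all pairwise distances.
#'
#' @param A,B sample sets (or matrices).
#' @param kind `"mpd"`, `"mad"` or `"apd"`.
#' @return scalar distance; symmetric in `A` and `B`.
#' @examples
#' A <- rbind(c(0, 0)); B <- rbind(c(3, 4))
#' c(setDistance(A, B, "mpd"), setDistance(A, B, "mad"),
#'   setDistance(A, B, "apd")) # 5 10 5
#' @export
setDistance <- function(A, B, kind = c("mpd", "mad", "apd")) {
  kind <- match.arg(kind)
  mA <- asSetMatrix(A)
  mB <- asSetMatrix(B)
  if (nrow(mA) == 0 || nrow(mB) == 0) {
    stop("both sets must be non-empty")
  }
  dm <- pairwiseDist(mA, mB)
  switch(kind,
    mpd = min(dm),
    mad = mean(apply(dm, 1, min)) + mean(apply(dm, 2, min)),
    apd = mean(dm)
  )
}

# Dispatch a measure name to its function; measure is one of
# mbd/mpd/mad/apd.
measureFun <- function(measure, beta, op) {
  switch(measure,
    mbd = function(A, B) mbd(A, B, beta = beta, op = op),
    mpd = function(A, B) setDistance(A, B, "mpd"),
    mad = function(A, B) setDistance(A, B, "mad"),
    apd = function(A, B) setDistance(A, B, "apd"),
    stop(sprintf("unknown measure '%s'", measure))
  )
}

projectSet <- function(m, projection) {
  if (is.null(projection)) {
    return(m)
  }
  m %*% t(projection)
}

#' Dissimilarity matrix between query and corpus sets
#'
#' Computes `measure(query_i, corpus_j)` for all pairs, optionally
#' after projecting every vector by the metric factor `l` (rows of
#' each set are replaced by `l x`), so that Euclidean base distances
#' become Mahalanobis distances under `w = t(l) %*% l`.
#'
#' @param queries,corpus lists of [SampleSet-class] objects (or
#'   matrices).
#' @param measure `"mbd"`, `"mpd"`, `"mad"` or `"apd"`.
#' @param beta,op MBD parameters (see [mbd()]).
#' @param projection optional projection matrix `l`.
#' @return numeric matrix, `length(queries)` x `length(corpus)`.
#' @export
setDistanceMatrix <- function(queries, corpus, measure = "mbd",
                              beta = 0.1, op = "sum",
                              projection = NULL) {
  f <- measureFun(measure, beta, op)
  qm <- lapply(queries, function(s) projectSet(asSetMatrix(s), projection))
  cm <- lapply(corpus, function(s) projectSet(asSetMatrix(s), projection))
  out <- matrix(0, length(qm), length(cm))
  for (i in seq_along(qm)) {
    for (j in seq_along(cm)) {
      out[i, j] <- f(qm[[i]], cm[[j]])
    }
  }
  rownames(out) <- names(queries)
  colnames(out) <- names(corpus)
  out
}
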