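#' @include AllClasses.R utils.R mlr-solver.R
NULL

#' Construct a ranking instance
#'
#' @param query numeric query vector.
#' @param relevant matrix (or vector) of same-class corpus vectors.
#' @param irrelevant matrix (or vector) of different-class corpus
#'   vectors.
#' @return A [RankingInstance-class]. Corpus items are indexed
#'   `1..(P+N)` with the `P` relevant items first.
#' @export
rankingInstance <- function(query, relevant, irrelevant) {
  if (is.null(dim(relevant))) relevant <- matrix(relevant, nrow = 1)
  if (is.null(dim(irrelevant))) irrelevant <- matrix(irrelevant, nrow = 1)
  new("RankingInstance",
    query = as.numeric(query),
    relevant = as.matrix(relevant),
    irrelevant = as.matrix(irrelevant)
  )
}

#' Mahalanobis similarity score
#'
#' The score of corpus item `x` for query `q` under metric `w`:
#' `-(q - x)' w (q - x)`, i.e. the matrix inner product of `w` with the
#' negated outer product of the difference. Higher means more similar;
#' `w = I` gives the negative squared Euclidean distance.
#'
#' @param w symmetric d x d metric matrix.
#' @param q,x numeric vectors of length d.
#' @return a scalar score.
#' @examples
#' mahalScore(diag(2), c(0, 0), c(1, 1)) # -2
#' @export
mahalScore <- function(w, q, x) {
  if (length(q) != length(x) || length(q) != nrow(w) ||
      nrow(w) != ncol(w)) {
    stop("dimension mismatch between w, q and x")
  }
  d <- q - x
  -drop(crossprod(d, w %*% d))
}

# Scores of all corpus items of an instance under w (vectorised).
instanceScores <- function(w, instance) {
  D <- rbind(instance@relevant, instance@irrelevant)
  D <- sweep(D, 2, instance@query)
  -rowSums((D %*% w) * D)
}

#' Partial-order feature of a ranking
#'
#' The matrix-valued joint feature of a ranking: the signed average
#' over all (relevant, irrelevant) pairs of the difference of their
#' per-item outer-product features, the sign being +1 when the relevant
#' item precedes the irrelevant one and -1 otherwise. For the
#' ground-truth ranking (all relevant items first) this reduces to the
#' mean relevant feature minus the mean irrelevant feature.
#'
#' @param instance a [RankingInstance-class].
#' @param ranking integer permutation of `1..(P+N)` (item order, best
#'   first); items `1..P` are the relevant ones.
#' @return a symmetric d x d matrix.
#' @export
partialOrderFeature <- function(instance, ranking) {
  P <- nrow(instance@relevant)
  N <- nrow(instance@irrelevant)
  if (length(ranking) != P + N || !setequal(ranking, seq_len(P + N))) {
    stop("ranking must be a permutation of the instance's corpus items")
  }
  pos <- integer(P + N)
  pos[ranking] <- seq_len(P + N)
  isRel <- c(rep(TRUE, P), rep(FALSE, N))
  relPos <- pos[isRel]
  irrPos <- pos[!isRel]
  # v_i: irrelevant items before relevant item i; u_j: relevant before j
  v <- vapply(relPos, function(p) sum(irrPos < p), numeric(1))
  u <- vapply(irrPos, function(p) sum(relPos < p), numeric(1))
  Dp <- sweep(instance@relevant, 2, instance@query)
  Dn <- sweep(instance@irrelevant, 2, instance@query)
  # phi_i = -D_i D_i'; coefficients (N - 2 v_i) and -(2 u_j - P)
  out <- -crossprod(Dp * (N - 2 * v), Dp) + crossprod(Dn * (2 * u - P), Dn)
  (out + t(out)) / (2 * P * N)
}

#' Rank corpus items by metric score
#'
#' Sorts the instance's corpus items by descending [mahalScore()] under
#' `w`; among all rankings this one maximises the inner product of `w`
#' with the partial-order feature. Ties are broken by original item
#' index (stable).
#'
#' @param w metric matrix.
#' @param instance a [RankingInstance-class].
#' @return integer permutation of `1..(P+N)`, best first.
#' @export
rankingScoreSort <- function(w, instance) {
  s <- instanceScores(w, instance)
  order(-s, seq_along(s), method = "radix")
}

#' Truncated reciprocal-rank loss of a ranking
#'
#' With `r` the 1-based position of the first relevant item, the score
#' is `1/r` when `r <= k` and 0 otherwise; the loss is one minus the
#' score, so it lies in \[0, 1\] and is 0 exactly when a relevant item
#' is ranked first.
#'
#' @param instance a [RankingInstance-class].
#' @param ranking integer permutation as in [partialOrderFeature()].
#' @param k truncation rank (default 3).
#' @return loss in \[0, 1\].
#' @export
queryLoss <- function(instance, ranking, k = 3) {
  stopifnot(k >= 1)
  P <- nrow(instance@relevant)
  r <- match(TRUE, ranking <= P)
  if (is.na(r)) {
    stop("ranking contains no relevant item")
  }
  1 - if (r <= k) 1 / r else 0
}

# Core loss-augmented argmax over rankings, parameterised by item
# scores only. Relevant/irrelevant items are each sorted by descending
# score; a ranking is then characterised by v_i = number of irrelevant
# items placed before the i-th (score-sorted) relevant item. Returns
# the optimal v in original relevant-item order, the item orders used,
# and the objective parts.
oracleCore <- function(sPos, sNeg, k) {
  P <- length(sPos)
  N <- length(sNeg)
  op <- order(-sPos, seq_len(P), method = "radix")
  on <- order(-sNeg, seq_len(N), method = "radix")
  sp <- sPos[op]
  sn <- sNeg[on]
  Cv <- c(0, cumsum(sn))
  vgrid <- 0:N
  # f[i, v+1] = (N - 2v) sp_i + 2 C(v)
  f <- outer(sp, N - 2 * vgrid) + matrix(2 * Cv, P, N + 1, byrow = TRUE)
  # suffix maxima over v (per row, right to left)
  M <- f
  amax <- matrix(N, P, N + 1)
  if (N >= 1) {
    for (v in (N - 1):0) {
      better <- f[, v + 1] >= M[, v + 2] # prefer smaller v on ties
      M[, v + 1] <- ifelse(better, f[, v + 1], M[, v + 2])
      amax[, v + 1] <- ifelse(better, v, amax[, v + 2])
    }
  }
  delta <- 1 - ifelse(vgrid + 1 <= k, 1 / (vgrid + 1), 0)
  base <- colSums(M)
  forceCost <- M - f # cost of pinning row i at v = m
  minCost <- apply(forceCost, 2, min)
  total <- delta + (base - minCost) / (P * N)
  mStar <- which.max(total) - 1
  iStar <- which.min(forceCost[, mStar + 1])
  v <- amax[, mStar + 1]
  v[iStar] <- mStar
  # map back to original relevant-item order
  vOrig <- integer(P)
  vOrig[op] <- v
  T <- sum(sn)
  objHat <- sum(f[cbind(seq_len(P), v + 1)]) / (P * N) - T / N
  objStar <- mean(sp) - mean(sn)
  list(
    v = vOrig, negOrder = on, posOrder = op, iStar = op[iStar],
    loss = delta[mStar + 1], obj = objHat, objStar = objStar,
    augmented = delta[mStar + 1] + objHat
  )
}

# Build a full ranking permutation from a v-pattern (original order)
# and the sorted item orders.
rankingFromPattern <- function(core, P, N) {
  v <- core$v[core$posOrder]
  posIds <- core$posOrder
  # ensure the pinned item leads its v-group so the first relevant item
  # sits exactly after v* negatives
  ordKey <- rank(v, ties.method = "first")
  pin <- which(posIds == core$iStar)
  ordPos <- order(v, ifelse(seq_len(P) == pin, 0, 1), seq_len(P),
    method = "radix"
  )
  seqPos <- posIds[ordPos]
  vSorted <- v[ordPos]
  out <- integer(P + N)
  oi <- 1
  pi <- 1
  for (t in 0:N) {
    while (pi <= P && vSorted[pi] == t) {
      out[oi] <- seqPos[pi]
      oi <- oi + 1
      pi <- pi + 1
    }
    if (t < N) {
      out[oi] <- P + core$negOrder[t + 1]
      oi <- oi + 1
    }
  }
  out
}

#' Loss-augmented separation oracle
#'
#' Finds the ranking maximising `loss + <w, psi(ranking)>`, i.e. the
#' most violated ranking constraint at the current metric, exactly for
#' the truncated reciprocal-rank loss. The returned violation is
#' `loss + <w, psi(ranking)> - <w, psi(groundTruth)>`; values at or
#' below zero mean no ranking beats the ground truth by more than its
#' loss margin.
#'
#' @param w metric matrix.
#' @param instance a [RankingInstance-class].
#' @param k truncation rank of the loss (default 3).
#' @return list with `ranking` (integer permutation), `violation`,
#'   and `loss` (the loss of the returned ranking).
#' @export
separationOracle <- function(w, instance, k = 3) {
  P <- nrow(instance@relevant)
  N <- nrow(instance@irrelevant)
  s <- instanceScores(w, instance)
  core <- oracleCore(s[seq_len(P)], s[P + seq_len(N)], k)
  list(
    ranking = rankingFromPattern(core, P, N),
    violation = core$augmented - core$objStar,
    loss = core$loss
  )
}

# delta-psi matrix (psi(groundTruth) - psi(ranking)) from a v-pattern.
# v is in original relevant-item order; negOrder gives the descending-
# score order the ranking places the negatives in.
deltaPsiFromPattern <- function(Dp, Dn, v, negOrder, P, N) {
  # u for the t-th *sorted* negative = #\{i : v_i <= t - 1\}
  uSorted <- cumsum(tabulate(v + 1, nbins = N + 1))[seq_len(N)]
  u <- integer(N)
  u[negOrder] <- uSorted
  out <- -crossprod(Dp * v, Dp) + crossprod(Dn * (P - u), Dn)
  (out + t(out)) / (P * N)
}

#' Eigendecomposition factor of a PSD metric
#'
#' Returns `l` with `t(l) %*% l = w` built from the eigenpairs of `w`
#' whose eigenvalues exceed `rankTol`; for any vectors u, v the
#' quadratic form `(u-v)' w (u-v)` equals the squared Euclidean
#' distance between `l u` and `l v`, so `l` projects features into the
#' space where the learned metric is plain Euclidean distance.
#'
#' @param w symmetric PSD matrix (within tolerance `1e-6` relative).
#' @param rankTol eigenvalues at or below this are dropped.
#' @return matrix `l` with `rank(w)` rows.
#' @export
factorizeMetric <- function(w, rankTol = 1e-8) {
  w <- as.matrix(w)
  e <- eigen((w + t(w)) / 2, symmetric = TRUE)
  mx <- max(abs(e$values), 0)
  if (min(e$values) < -1e-6 * max(mx, 1)) {
    stop("w is not positive semidefinite")
  }
  keep <- e$values > rankTol
  if (!any(keep)) {
    return(matrix(0, 1, ncol(w)))
  }
  sqrt(e$values[keep]) * t(e$vectors[, keep, drop = FALSE])
}

#' Learn a Mahalanobis metric by ranking-loss structural optimisation
#'
#' Every training sample in turn serves as a query against the
#' remaining samples (leave-one-out); same-class items are relevant,
#' all others irrelevant. The metric minimises a regularizer (trace of
#' `w`, optionally with a small quadratic damping term for a unique
#' solution, or the squared Frobenius norm) plus `C/|Q|` times the sum
#' of per-query slacks over ranking constraints with truncated
#' reciprocal-rank margins. Constraints are generated by the exact
#' separation oracle in a cutting-plane loop; each working-set problem
#' is solved in its dual, where the PSD cone constraint on `w` is
#' enforced exactly through eigenvalue shrinkage.
#'
#' @param features a [FeatureTable-class] (or numeric matrix with
#'   `labels` supplied).
#' @param labels class symbols when `features` is a bare matrix.
#' @param C trade-off between slack and regularizer (default 1).
#' @param regularizer `"frobenius"` (default) or `"trace"` (damped).
#' @param k truncation rank of the reciprocal-rank loss (default 3).
#' @param tol stop when no ranking constraint is violated by more than
#'   this (default 1e-4).
#' @param maxIter cap on cutting-plane iterations (default 200).
#' @param traceDamp quadratic damping added to the trace regularizer
#'   so the subproblem is strongly convex and has the closed primal
#'   map `w = (M - I)_+ / traceDamp` (default 1; ignored for
#'   `"frobenius"`).
#' @param maxInner iteration cap for each working-set dual solve.
#' @param standardize centre and scale features to unit variance
#'   before optimisation (default TRUE). The standardisation is folded
#'   back into the returned `w` and `l`, which always live in the
#'   original feature space; it only conditions the optimisation, it
#'   does not change what the model measures.
#' @return A [MetricModel-class]. If the loop hits `maxIter` before
#'   all violations fall below `tol` the model is returned with
#'   `isConverged(model) = FALSE` and a warning.
#' @export
trainMetric <- function(features, labels = NULL, C = 1,
                        regularizer = c("frobenius", "trace"), k = 3,
                        tol = 1e-4, maxIter = 200, traceDamp = 1,
                        maxInner = 1500, standardize = TRUE) {
  regularizer <- match.arg(regularizer)
  if (is(features, "FeatureTable")) {
    X <- features@features
    labels <- features@labels
  } else {
    X <- as.matrix(features)
    if (is.null(labels)) {
      stop("labels must be supplied with a bare feature matrix")
    }
  }
  scl <- rep(1, ncol(X))
  if (standardize) {
    ctr <- colMeans(X)
    scl <- pmax(apply(X, 2, stats::sd), 1e-12)
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  n <- nrow(X)
  d <- ncol(X)
  counts <- table(labels)
  queries <- which(labels %in% names(counts)[counts >= 2])
  if (length(queries) == 0 || length(counts) < 2) {
    stop("training needs >= 2 classes with >= 2 samples each")
  }
  nQ <- length(queries)
  cap <- C / nQ
  lambda <- if (regularizer == "trace") 1 else 0
  mu <- if (regularizer == "trace") traceDamp else 1
  # per-query difference matrices and relevance masks
  qdata <- lapply(queries, function(qi) {
    rel <- which(labels == labels[qi])
    rel <- rel[rel != qi]
    irr <- which(labels != labels[qi])
    D <- sweep(X[c(rel, irr), , drop = FALSE], 2, X[qi, ])
    list(P = length(rel), N = length(irr), D = D)
  })
  w <- matrix(0, d, d)
  PsiList <- list()
  Delta <- numeric(0)
  qidx <- integer(0)
  sigs <- vector("list", nQ)
  alpha <- numeric(0)
  hist <- data.frame(
    iteration = integer(0), objective = numeric(0), primal = numeric(0),
    maxViolation = numeric(0), nConstraints = integer(0)
  )
  converged <- FALSE
  Psi <- NULL
  for (iter in seq_len(maxIter)) {
    # slacks implied by the working set at the current w
    xi <- numeric(nQ)
    if (length(Delta) > 0) {
      marg <- Delta - drop(Psi %*% as.vector(w))
      for (q in seq_len(nQ)) {
        rows <- which(qidx == q)
        if (length(rows) > 0) {
          xi[q] <- max(0, marg[rows])
        }
      }
    }
    maxViol <- 0
    added <- 0
    for (q in seq_len(nQ)) {
      qd <- qdata[[q]]
      s <- -rowSums((qd$D %*% w) * qd$D)
      core <- oracleCore(s[seq_len(qd$P)], s[qd$P + seq_len(qd$N)], k)
      viol <- core$augmented - core$objStar - xi[q]
      maxViol <- max(maxViol, viol)
      if (viol > tol) {
        # signature must pin down delta-psi: the v-pattern in original
        # item order plus the negative-item order it was built against
        sig <- paste(c(core$v, core$negOrder), collapse = ",")
        if (!sig %in% sigs[[q]]) {
          sigs[[q]] <- c(sigs[[q]], sig)
          dPsi <- deltaPsiFromPattern(
            qd$D[seq_len(qd$P), , drop = FALSE],
            qd$D[qd$P + seq_len(qd$N), , drop = FALSE],
            core$v, core$negOrder, qd$P, qd$N
          )
          PsiList[[length(PsiList) + 1]] <- as.vector(dPsi)
          Delta <- c(Delta, core$loss)
          qidx <- c(qidx, q)
          added <- added + 1
        }
      }
    }
    if (added == 0) {
      converged <- maxViol <= tol
      break
    }
    Psi <- do.call(rbind, PsiList)
    alpha <- c(alpha, numeric(added))
    sol <- solveWorkingSet(Psi, Delta, qidx, cap, lambda, mu, d,
      alpha0 = alpha, maxInner = maxInner
    )
    alpha <- sol$alpha
    w <- sol$w
    marg <- Delta - drop(Psi %*% as.vector(w))
    xiNew <- vapply(seq_len(nQ), function(q) {
      rows <- which(qidx == q)
      if (length(rows) > 0) max(0, marg[rows]) else 0
    }, numeric(1))
    primal <- lambda * sum(diag(w)) + mu / 2 * sum(w^2) +
      cap * sum(xiNew)
    hist <- rbind(hist, data.frame(
      iteration = iter, objective = sol$dual, primal = primal,
      maxViolation = maxViol, nConstraints = length(Delta)
    ))
    if (iter == maxIter) {
      warning("metric training reached maxIter before convergence")
    }
  }
  if (standardize) {
    # fold the feature scaling back so w and l act on raw features:
    # distances on standardized features equal distances under
    # S w S with S = diag(1/scale)
    w <- sweep(sweep(w, 1, scl, "/"), 2, scl, "/")
    w <- (w + t(w)) / 2
  }
  # note: `C` is spelled out after construction because a named `C =`
  # argument to new() would partially match its `Class` parameter
  model <- new("MetricModel",
    w = w, l = factorizeMetric(w), regularizer = regularizer,
    k = k, history = hist, converged = converged
  )
  model@C <- C
  model
}
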