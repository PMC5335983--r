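# Brute-force reference implementations used as independent oracles.

# All permutations of a vector (for exhaustive ranking enumeration).
allPerms <- function(v) {
  if (length(v) <= 1) {
    return(list(v))
  }
  out <- list()
  for (i in seq_along(v)) {
    for (p in allPerms(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], p)
    }
  }
  out
}

# Partial-order feature by direct double loop over (relevant,
# irrelevant) pairs.
brutePartialOrder <- function(instance, ranking) {
  P <- nrow(instance@relevant)
  N <- nrow(instance@irrelevant)
  q <- instance@query
  pos <- integer(P + N)
  pos[ranking] <- seq_len(P + N)
  d <- length(q)
  acc <- matrix(0, d, d)
  for (i in seq_len(P)) {
    di <- instance@relevant[i, ] - q
    phiI <- -tcrossprod(di)
    for (j in seq_len(N)) {
      dj <- instance@irrelevant[j, ] - q
      phiJ <- -tcrossprod(dj)
      s <- if (pos[i] < pos[P + j]) 1 else -1
      acc <- acc + s * (phiI - phiJ)
    }
  }
  acc / (P * N)
}

# Exhaustive loss-augmented argmax over all rankings.
bruteOracle <- function(w, instance, k = 3) {
  P <- nrow(instance@relevant)
  N <- nrow(instance@irrelevant)
  best <- -Inf
  bestRanking <- NULL
  for (p in allPerms(seq_len(P + N))) {
    val <- queryLoss(instance, p, k) +
      sum(w * brutePartialOrder(instance, p))
    if (val > best) {
      best <- val
      bestRanking <- p
    }
  }
  list(ranking = bestRanking, value = best)
}

# Naive double-loop MBD.
bruteMbd <- function(A, B, beta = 0.1, op = "sum", alpha = NULL) {
  dm <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      dm[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
    }
  }
  if (is.null(alpha)) {
    alpha <- max(1, floor(beta * min(nrow(A), nrow(B))))
  }
  dA <- sort(apply(dm, 1, min))[seq_len(alpha)]
  dB <- sort(apply(dm, 2, min))[seq_len(alpha)]
  switch(op,
    sum = mean(dA) + mean(dB),
    max = max(mean(dA), mean(dB)),
    min = min(mean(dA), mean(dB))
  )
}

# Small random ranking instance.
randomInstance <- function(P, N, d = 2) {
  rankingInstance(
    rnorm(d),
    matrix(rnorm(P * d), P, d),
    matrix(rnorm(N * d), N, d)
  )
}

# Random symmetric PSD matrix.
randomPSD <- function(d) {
  a <- matrix(rnorm(d * d), d, d)
  crossprod(a) / d
}
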