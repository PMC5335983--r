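# Mahalanobis metric learning to rank.

test_that("mahalScore evaluates the negated quadratic form", {
  expect_equal(mahalScore(diag(2), c(0, 0), c(0, 0)), 0)
  expect_equal(mahalScore(diag(2), c(0, 0), c(1, 1)), -2)
  expect_equal(mahalScore(diag(c(2, 1)), c(1, 0), c(0, 0)), -2)
  set.seed(1)
  w <- matrix(rnorm(9), 3, 3)
  q <- rnorm(3)
  expect_equal(mahalScore(w, q, q), 0)
  expect_error(mahalScore(diag(2), c(0, 0), c(1, 1, 1)), "dimension")
})

test_that("partialOrderFeature matches the brute-force pair sum", {
  set.seed(7)
  for (rep in 1:20) {
    P <- sample(1:4, 1)
    N <- sample(1:4, 1)
    inst <- randomInstance(P, N, d = 3)
    rk <- sample(P + N)
    expect_equal(
      partialOrderFeature(inst, rk),
      brutePartialOrder(inst, rk),
      tolerance = 1e-10
    )
  }
})

test_that("the ground-truth feature is the mean relevant minus mean irrelevant term", {
  set.seed(8)
  inst <- randomInstance(3, 4, d = 3)
  q <- inst@query
  phi <- function(x) -tcrossprod(x - q)
  direct <- Reduce(`+`, lapply(1:3, function(i) phi(inst@relevant[i, ]))) / 3 -
    Reduce(`+`, lapply(1:4, function(j) phi(inst@irrelevant[j, ]))) / 4
  expect_equal(partialOrderFeature(inst, 1:7), direct, tolerance = 1e-10)
})

test_that("the feature is invariant to within-block permutations and flips under reversal", {
  set.seed(9)
  inst <- randomInstance(3, 3, d = 2)
  gt <- partialOrderFeature(inst, 1:6)
  expect_equal(partialOrderFeature(inst, c(3, 1, 2, 5, 6, 4)), gt)
  expect_equal(partialOrderFeature(inst, 6:1), -gt, tolerance = 1e-12)
  expect_error(partialOrderFeature(inst, c(1, 1, 2, 3, 4, 5)), "permutation")
})

test_that("score sorting maximises the feature inner product (enumeration)", {
  set.seed(10)
  for (rep in 1:15) {
    inst <- randomInstance(sample(1:3, 1), sample(1:3, 1), d = 2)
    w <- if (rep %% 3 == 0) {
      m <- matrix(rnorm(4), 2, 2)
      (m + t(m)) / 2
    } else {
      randomPSD(2)
    }
    rs <- rankingScoreSort(w, inst)
    vals <- vapply(
      allPerms(seq_len(nrow(inst@relevant) + nrow(inst@irrelevant))),
      function(p) sum(w * partialOrderFeature(inst, p)), numeric(1)
    )
    expect_equal(sum(w * partialOrderFeature(inst, rs)), max(vals),
      tolerance = 1e-10
    )
  }
  # zero metric: stable tie rule returns the input order
  inst <- randomInstance(2, 2, d = 2)
  expect_equal(rankingScoreSort(matrix(0, 2, 2), inst), 1:4)
})

test_that("separable clusters rank all same-class items first under the identity", {
  inst <- rankingInstance(
    c(0, 0),
    matrix(c(0.1, 0, -0.1, 0), 2, 2, byrow = TRUE),
    matrix(c(10, 0, 0, 10), 2, 2, byrow = TRUE)
  )
  expect_equal(sort(rankingScoreSort(diag(2), inst)[1:2]), 1:2)
})

test_that("queryLoss implements the truncated reciprocal rank", {
  inst <- randomInstance(2, 3, d = 2)
  expect_equal(queryLoss(inst, c(1, 3, 4, 2, 5), k = 3), 0) # r = 1
  expect_equal(queryLoss(inst, c(3, 4, 1, 2, 5), k = 3), 1 - 1 / 3)
  expect_equal(queryLoss(inst, c(3, 4, 5, 1, 2), k = 3), 1) # r = 4 > k
  expect_equal(queryLoss(inst, c(3, 1, 4, 2, 5), k = 1), 1) # r = 2 > k = 1
  expect_error(queryLoss(inst, c(3, 4, 5), k = 3), "no relevant")
  expect_error(queryLoss(inst, 1:5, k = 0))
})

test_that("the separation oracle is exact against exhaustive enumeration", {
  set.seed(11)
  for (rep in 1:25) {
    P <- sample(1:3, 1)
    N <- sample(1:3, 1)
    inst <- randomInstance(P, N, d = 2)
    w <- if (rep %% 4 == 0) matrix(0, 2, 2) else randomPSD(2)
    o <- separationOracle(w, inst, k = 3)
    b <- bruteOracle(w, inst, k = 3)
    got <- queryLoss(inst, o$ranking) +
      sum(w * partialOrderFeature(inst, o$ranking))
    expect_equal(got, b$value, tolerance = 1e-9)
    gt <- sum(w * partialOrderFeature(inst, seq_len(P + N)))
    expect_equal(o$violation, b$value - gt, tolerance = 1e-9)
  }
})

test_that("a dominant margin yields a zero-loss ranking with no violation", {
  inst <- rankingInstance(
    c(0, 0),
    matrix(c(0.01, 0, 0, 0.01), 2, 2, byrow = TRUE),
    matrix(c(100, 0, 0, 100), 2, 2, byrow = TRUE)
  )
  o <- separationOracle(diag(2), inst, k = 3)
  expect_equal(queryLoss(inst, o$ranking), 0)
  expect_lte(o$violation, 0)
})

test_that("with one relevant, one irrelevant and tied scores the oracle returns loss 1/2", {
  inst <- rankingInstance(c(0, 0), c(1, 0), c(0, 1)) # equidistant
  o <- separationOracle(diag(2), inst, k = 3)
  expect_equal(o$ranking, c(2, 1)) # irrelevant first
  expect_equal(o$violation, 0.5)
})

test_that("factorizeMetric reproduces the quadratic form as a projected distance", {
  set.seed(12)
  for (rep in 1:10) {
    d <- sample(2:6, 1)
    w <- randomPSD(d)
    l <- factorizeMetric(w)
    u <- rnorm(d)
    v <- rnorm(d)
    qf <- drop(crossprod(u - v, w %*% (u - v)))
    pd <- sum((l %*% u - l %*% v)^2)
    expect_equal(pd, qf, tolerance = 1e-6 * max(1, qf))
  }
  # identity: distances are preserved exactly
  l <- factorizeMetric(diag(3))
  expect_equal(crossprod(l), diag(3), tolerance = 1e-12)
  # rank-1 case keeps a single row
  expect_equal(nrow(factorizeMetric(diag(c(4, 0)), rankTol = 1e-8)), 1)
  expect_error(factorizeMetric(diag(c(1, -1))), "not positive")
})

test_that("training on perfectly ordered 1-D two-class data converges with zero loss", {
  X <- matrix(c(0, 0.1, 0.2, 5, 5.1, 5.2), ncol = 1)
  lab <- c("a", "a", "a", "b", "b", "b")
  m <- trainMetric(X, lab, C = 10, maxIter = 50, standardize = FALSE)
  expect_true(isConverged(m))
  w <- metricMatrix(m)
  # every leave-one-out query ranks its own class first
  for (qi in seq_along(lab)) {
    rel <- setdiff(which(lab == lab[qi]), qi)
    irr <- which(lab != lab[qi])
    inst <- rankingInstance(X[qi, ], X[rel, , drop = FALSE],
      X[irr, , drop = FALSE]
    )
    expect_equal(queryLoss(inst, rankingScoreSort(w, inst)), 0)
  }
})

test_that("the working-set objective is non-decreasing and the metric is PSD", {
  ft <- simulateFeatureClusters(defaultClusterSpec(0), rep(12, 4), seed = 31)
  m <- trainMetric(ft, C = 100, maxIter = 40)
  h <- trainingHistory(m)
  expect_gt(nrow(h), 1)
  expect_true(all(diff(h$objective) >= -1e-9))
  ev <- eigen(metricMatrix(m), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-9 * max(abs(ev)))
  # factor reconstructs the metric
  expect_equal(crossprod(metricFactor(m)), metricMatrix(m),
    tolerance = 1e-6
  )
})

test_that("trace and frobenius regularizers give closely matching accuracy", {
  ft <- simulateFeatureClusters(defaultClusterSpec(0), rep(40, 4), seed = 11)
  X <- featureMatrix(ft)
  lab <- beatLabels(ft)
  sp <- splitTrials(lab, 1, 0.5, seed = 7)[[1]]
  mF <- trainMetric(X[sp$train, ], lab[sp$train],
    C = 1,
    regularizer = "frobenius", maxIter = 25
  )
  mT <- suppressWarnings(trainMetric(X[sp$train, ], lab[sp$train],
    C = 1000, regularizer = "trace", traceDamp = 0.01,
    maxIter = 25, maxInner = 2500
  ))
  evalSingles <- function(model) {
    p <- experimentParams(
      nTrials = 1, metric = model,
      smallClassSizes = NULL, seed = 7
    )
    overallRates(runEvaluation(ft, p, method = "mlr+baseline"))["rank1"]
  }
  rF <- evalSingles(mF)
  rT <- evalSingles(mT)
  expect_lt(abs(rF - rT), 2)
  # and both clearly beat the raw Euclidean single-sample baseline
  base <- overallRates(baselineSingleSample(
    ft, experimentParams(nTrials = 1, smallClassSizes = NULL, seed = 7)
  ))["rank1"]
  expect_gt(rF, base)
  expect_gt(rT, base)
})
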