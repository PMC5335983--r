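# Set-to-set dissimilarity measures.

test_that("pointToSet takes the minimum distance to any member", {
  expect_equal(pointToSet(c(1, 0), rbind(c(0, 0), c(3, 0))), 1)
  B <- matrix(rnorm(10), 5, 2)
  expect_equal(pointToSet(B[3, ], B), 0)
  expect_equal(pointToSet(c(1, 1), rbind(c(4, 5))), 5)
  expect_error(pointToSet(c(1, 0), matrix(numeric(0), 0, 2)), "non-empty")
  expect_error(pointToSet(c(1, 0, 0), rbind(c(0, 0))), "dimension")
})

test_that("minoritySubset picks the alpha members nearest the other set", {
  A <- rbind(c(0, 0), c(1, 0), c(5, 0))
  B <- rbind(c(2, 0))
  ms <- minoritySubset(A, B, 2)
  expect_equal(setVectors(ms), rbind(c(1, 0), c(0, 0)), ignore_attr = TRUE)
  expect_equal(
    setVectors(minoritySubset(A, B, 3)),
    A[c(2, 1, 3), ],
    ignore_attr = TRUE
  )
  expect_error(minoritySubset(A, B, 0), "alpha")
  expect_error(minoritySubset(A, B, 4), "alpha")
})

test_that("mbd evaluates the hand example and vanishes on identical sets", {
  expect_equal(mbd(rbind(c(0, 0)), rbind(c(3, 4)), op = "sum"), 10)
  set.seed(21)
  A <- matrix(rnorm(20), 10, 2)
  for (op in c("sum", "max", "min")) {
    expect_equal(mbd(A, A, beta = 0.3, op = op), 0)
  }
  expect_error(mbd(A, A, beta = 0), "beta")
  expect_error(mbd(A, A, beta = 1.2), "beta")
})

test_that("mbd degenerates exactly to MPD and MAD", {
  set.seed(22)
  for (rep in 1:50) {
    A <- matrix(rnorm(2 * sample(2:12, 1)), ncol = 2)
    B <- matrix(rnorm(2 * sample(2:12, 1)), ncol = 2)
    expect_identical(
      mbd(A, B, alpha = 1, op = "min"),
      setDistance(A, B, "mpd")
    )
    # the MAD identity needs full minority subsets on both sides,
    # which under the equal-minority-size rule is the equal-
    # cardinality case
    n <- sample(2:12, 1)
    A2 <- matrix(rnorm(2 * n), ncol = 2)
    B2 <- matrix(rnorm(2 * n), ncol = 2)
    expect_identical(
      mbd(A2, B2, beta = 1, op = "sum"),
      setDistance(A2, B2, "mad")
    )
  }
})

test_that("mbd is symmetric and matches the naive double-loop implementation", {
  set.seed(23)
  for (rep in 1:15) {
    A <- matrix(rnorm(3 * sample(5:30, 1)), ncol = 3)
    B <- matrix(rnorm(3 * sample(5:30, 1)), ncol = 3)
    for (op in c("sum", "max", "min")) {
      expect_equal(mbd(A, B, 0.2, op), bruteMbd(A, B, 0.2, op),
        tolerance = 1e-12
      )
      expect_equal(mbd(A, B, 0.2, op), mbd(B, A, 0.2, op),
        tolerance = 1e-12
      )
    }
  }
})

test_that("classic measures evaluate the single-pair example", {
  A <- rbind(c(0, 0))
  B <- rbind(c(3, 4))
  expect_equal(setDistance(A, B, "mpd"), 5)
  expect_equal(setDistance(A, B, "mad"), 10)
  expect_equal(setDistance(A, B, "apd"), 5)
  expect_error(setDistance(A, B, "hausdorff"))
})

test_that("classic measures are symmetric and non-negative; overlap gives MPD 0", {
  set.seed(24)
  for (rep in 1:50) {
    A <- matrix(rnorm(2 * sample(2:10, 1)), ncol = 2)
    B <- matrix(rnorm(2 * sample(2:10, 1)), ncol = 2)
    for (kind in c("mpd", "mad", "apd")) {
      dab <- setDistance(A, B, kind)
      expect_gte(dab, 0)
      expect_equal(dab, setDistance(B, A, kind), tolerance = 1e-12)
    }
  }
  A <- matrix(rnorm(10), 5, 2)
  B <- rbind(A[2, ], matrix(rnorm(6), 3, 2))
  expect_equal(setDistance(A, B, "mpd"), 0)
})

test_that("setDistanceMatrix matches per-pair calls and honours projection", {
  set.seed(25)
  qs <- lapply(1:3, function(i) SampleSet(matrix(rnorm(12), 6, 2), paste0("q", i)))
  cs <- lapply(1:2, function(i) SampleSet(matrix(rnorm(16), 8, 2), paste0("c", i)))
  dm <- setDistanceMatrix(qs, cs, "mbd", beta = 0.4)
  for (i in 1:3) {
    for (j in 1:2) {
      expect_equal(
        dm[i, j],
        mbd(setVectors(qs[[i]]), setVectors(cs[[j]]), beta = 0.4)
      )
    }
  }
  expect_equal(setDistanceMatrix(qs, cs, "mpd", projection = diag(2)),
    setDistanceMatrix(qs, cs, "mpd"),
    tolerance = 1e-12
  )
})

test_that("projection by the metric factor equals a Mahalanobis base distance", {
  set.seed(26)
  w <- randomPSD(3)
  l <- factorizeMetric(w)
  A <- matrix(rnorm(15), 5, 3)
  B <- matrix(rnorm(21), 7, 3)
  # Mahalanobis pairwise distances under w, brute force
  dm <- matrix(0, 5, 7)
  for (i in 1:5) {
    for (j in 1:7) {
      dd <- A[i, ] - B[j, ]
      dm[i, j] <- sqrt(drop(crossprod(dd, w %*% dd)))
    }
  }
  alpha <- max(1, floor(0.2 * 5))
  dA <- sort(apply(dm, 1, min))[seq_len(alpha)]
  dB <- sort(apply(dm, 2, min))[seq_len(alpha)]
  mahalMbd <- mean(dA) + mean(dB)
  projMbd <- mbd(A %*% t(l), B %*% t(l), beta = 0.2, op = "sum")
  expect_equal(projMbd, mahalMbd, tolerance = 1e-9)
})
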