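# Evaluation protocol: splits, caps, query sets, ranking, rates.

test_that("stratified halving splits every class and is reproducible", {
  lab <- rep(c("a", "b", "c"), c(10, 7, 2))
  sp <- splitTrials(lab, nTrials = 4, seed = 3)
  for (s in sp) {
    expect_equal(sort(c(s$train, s$test)), seq_along(lab))
    expect_length(intersect(s$train, s$test), 0)
    # the class with 2 samples is halved 1/1
    expect_equal(sum(lab[s$train] == "c"), 1)
    expect_equal(sum(lab[s$test] == "c"), 1)
    # odd counts put the extra sample in training
    expect_equal(sum(lab[s$train] == "b"), 4)
  }
  expect_identical(sp, splitTrials(lab, nTrials = 4, seed = 3))
  expect_false(identical(sp[[1]], sp[[2]]))
})

test_that("training caps subsample only classes above the cap", {
  lab <- rep(c("big", "small"), c(1200, 30))
  train <- seq_along(lab)
  capped <- capTraining(train, lab, cap = 500, seed = 2)
  expect_equal(sum(lab[capped] == "big"), 500)
  expect_equal(sum(lab[capped] == "small"), 30)
  expect_identical(capped, capTraining(train, lab, cap = 500, seed = 2))
  # below-cap classes are untouched
  capped2 <- capTraining(train, lab, cap = 5000, seed = 2)
  expect_identical(capped2, train)
})

test_that("query sets partition each class's test half with a kept remainder", {
  X <- matrix(rnorm(240 * 2), 240, 2)
  lab <- rep("a", 240)
  testIdx <- 1:120
  qs <- buildQuerySets(X, testIdx, lab, setSize = 50, seed = 4)
  sizes <- sort(vapply(qs, function(s) nrow(setVectors(s)), numeric(1)))
  expect_equal(sizes, c(20, 50, 50))
  # disjoint cover
  got <- unlist(lapply(qs, function(s) {
    apply(setVectors(s), 1, function(r) which(colSums(abs(t(X) - r)) == 0)[1])
  }))
  expect_equal(sort(got), testIdx)

  # a singleton class forms a singleton set
  qs1 <- buildQuerySets(X, 7, c(rep("a", 6), "s", rep("a", 233)),
    setSize = 50, seed = 4
  )
  expect_length(qs1, 1)
  expect_equal(nrow(setVectors(qs1[[1]])), 1)

  # remainder can be discarded
  qs2 <- buildQuerySets(X, testIdx, lab,
    setSize = 50, seed = 4,
    keepRemainder = FALSE
  )
  expect_equal(
    sort(vapply(qs2, function(s) nrow(setVectors(s)), numeric(1))),
    c(50, 50)
  )
})

test_that("per-class set-size overrides mirror the rare-class protocol", {
  lab <- rep(c("N", "J"), c(100, 10))
  X <- matrix(rnorm(110 * 2), 110, 2)
  qs <- buildQuerySets(X, 1:110, lab,
    setSize = 50,
    smallClassSizes = c(J = 5), seed = 1
  )
  sizes <- vapply(qs, function(s) nrow(setVectors(s)), numeric(1))
  cls <- vapply(qs, setLabel, character(1))
  expect_equal(sort(sizes[cls == "J"]), c(5, 5))
  expect_equal(sort(sizes[cls == "N"]), c(50, 50))
})

test_that("rankClasses orders by dissimilarity with a deterministic tie rule", {
  set.seed(5)
  corpus <- list(
    a = SampleSet(matrix(rnorm(20, 0), 10, 2), "a", "a"),
    b = SampleSet(matrix(rnorm(20, 10), 10, 2), "b", "b"),
    c = SampleSet(matrix(rnorm(20, 20), 10, 2), "c", "c")
  )
  q <- SampleSet(setVectors(corpus$b), "q", "b")
  ranked <- rankClasses(q, corpus, measure = "mbd")
  expect_equal(ranked[1], "b")
  # permuting samples inside the query set changes nothing
  qPerm <- SampleSet(setVectors(q)[10:1, ], "q", "b")
  expect_equal(rankClasses(qPerm, corpus, measure = "mbd"), ranked)
  # matches a brute-force recomputation
  d <- vapply(
    corpus,
    function(cs) mbd(setVectors(q), setVectors(cs)), numeric(1)
  )
  expect_equal(ranked, names(sort(d)))
  # exact ties fall back to ascending class symbol
  corpus2 <- list(
    z = SampleSet(rbind(c(1, 0)), "z", "z"),
    y = SampleSet(rbind(c(-1, 0)), "y", "y")
  )
  q0 <- SampleSet(rbind(c(0, 0)), "q")
  expect_equal(rankClasses(q0, corpus2, "mpd"), c("y", "z"))
})

test_that("perfectly separable classes score Rank-1 = 100 and Rank-5 >= Rank-1", {
  spec <- clusterSpec(4, 5, classSeparation = 60, withinSd = 1)
  ft <- simulateFeatureClusters(spec, rep(24, 4), seed = 6)
  p <- experimentParams(
    nTrials = 3, setSize = 6,
    smallClassSizes = NULL, seed = 6
  )
  r <- runEvaluation(ft, p)
  expect_equal(unname(overallRates(r)["rank1"]), 100)
  expect_gte(overallRates(r)["rank5"], overallRates(r)["rank1"])
  # noisy case still satisfies the nesting
  ftn <- simulateFeatureClusters(defaultClusterSpec(0.1), rep(24, 4),
    seed = 6
  )
  rn <- runEvaluation(ftn, p)
  expect_gte(overallRates(rn)["rank5"], overallRates(rn)["rank1"])
  pt <- perTrialRates(rn)
  expect_true(all(pt$rank5 >= pt$rank1))
})

test_that("identical configuration and seed reproduce the ResultTable exactly", {
  ft <- simulateFeatureClusters(defaultClusterSpec(0.1), rep(20, 4), seed = 9)
  p <- experimentParams(
    nTrials = 2, setSize = 5,
    smallClassSizes = NULL, seed = 11
  )
  a <- runEvaluation(ft, p)
  b <- runEvaluation(ft, p)
  expect_identical(overallRates(a), overallRates(b))
  expect_identical(perTrialRates(a), perTrialRates(b))
  expect_identical(perClassRates(a), perClassRates(b))
})

test_that("the single-sample baseline equals the protocol with singleton MPD sets", {
  ft <- simulateFeatureClusters(defaultClusterSpec(0.1), rep(30, 4), seed = 4)
  p <- experimentParams(
    nTrials = 3, setSize = 1, measure = "mpd",
    smallClassSizes = NULL, seed = 9
  )
  a <- runEvaluation(ft, p)
  b <- baselineSingleSample(ft, p)
  expect_equal(overallRates(a), overallRates(b))
  expect_equal(perTrialRates(a)$rank1, perTrialRates(b)$rank1)
})

test_that("duplicating a training sample never changes the baseline", {
  ft <- simulateFeatureClusters(defaultClusterSpec(0), rep(10, 4), seed = 13)
  X <- featureMatrix(ft)
  lab <- beatLabels(ft)
  # corpus: first five samples of each class
  corpus <- lapply(sort(unique(lab)), function(cl) {
    SampleSet(X[head(which(lab == cl), 5), , drop = FALSE], cl, cl)
  })
  names(corpus) <- sort(unique(lab))
  corpusDup <- corpus
  corpusDup[["k1"]] <- SampleSet(
    rbind(setVectors(corpus[["k1"]]), setVectors(corpus[["k1"]])[1, ]),
    "k1", "k1"
  )
  q <- SampleSet(X[30, , drop = FALSE], "q", lab[30])
  expect_identical(
    rankClasses(q, corpus, "mpd"),
    rankClasses(q, corpusDup, "mpd")
  )
})

test_that("compared pipelines consume identical splits", {
  ft <- simulateFeatureClusters(defaultClusterSpec(0.1), rep(16, 4), seed = 2)
  p <- experimentParams(
    nTrials = 2, setSize = 4,
    smallClassSizes = NULL, seed = 21
  )
  lab <- beatLabels(ft)
  s1 <- splitTrials(lab, p$nTrials, p$trainFraction, p$seed)
  s2 <- splitTrials(lab, p$nTrials, p$trainFraction, p$seed)
  expect_identical(s1, s2)
  # and the engine rejects metric-prefixed methods without a metric
  expect_error(
    runEvaluation(ft, p, method = "mlr+mbd"),
    "metric"
  )
})

test_that("the AAMI label scheme groups classes before evaluation", {
  beats <- simulateBeats(defaultBeatSpecs(), rep(12, 4), seed = 3)
  # relabel synthetic classes with MIT-BIH symbols: two map to NonEctopic
  lab <- c(N = "c1", L = "c2", V = "c3", P = "c4")
  bs <- BeatSet(beatMatrix(beats),
    names(lab)[match(beatLabels(beats), lab)]
  )
  ft <- featurizeBeats(bs)
  p <- experimentParams(
    nTrials = 1, setSize = 3, smallClassSizes = NULL,
    labelScheme = "aami", seed = 5
  )
  r <- runEvaluation(ft, p)
  expect_setequal(
    perClassRates(r)$class,
    c("NonEctopic", "VentricularEctopic", "Unknown")
  )
})

test_that("larger query sets improve contaminated-set recognition (seeded regression)", {
  ft <- simulateFeatureClusters(defaultClusterSpec(0.1), rep(300, 4), seed = 3)
  r10 <- runEvaluation(ft, experimentParams(
    nTrials = 3, setSize = 10,
    smallClassSizes = NULL, seed = 5
  ))
  r50 <- runEvaluation(ft, experimentParams(
    nTrials = 3, setSize = 50,
    smallClassSizes = NULL, seed = 5
  ))
  expect_gte(
    overallRates(r50)["rank1"],
    overallRates(r10)["rank1"]
  )
})
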