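#' @include AllClasses.R utils.R set-dissimilarity.R mlr-metric.R wavelet-features.R
NULL

#' Experiment parameters for the evaluation protocol
#'
#' Bundles every knob of the evaluation protocol: repeated stratified
#' random halving, per-class training caps, query-set construction,
#' the set dissimilarity and its parameters, the optional learned
#' metric, and the label scheme.
#'
#' @param nTrials number of repeated random splits (default 10).
#' @param trainFraction fraction of each class assigned to training
#'   (default 0.5; odd counts put the extra sample in training).
#' @param cap per-class training maximum (default 500).
#' @param setSize query-set size (default 50).
#' @param smallClassSizes named vector of per-class set-size overrides
#'   (default `c(J = 5, Q = 5, e = 5, S = 1)`, the rare MIT-BIH
#'   classes).
#' @param measure set dissimilarity: `"mbd"`, `"mpd"`, `"mad"`,
#'   `"apd"`.
#' @param beta,op MBD minority ratio and combination operation.
#' @param metric `"none"`, `"mlr"` (train per trial on the capped
#'   training half), or a fixed [MetricModel-class].
#' @param C,regularizer,k,tol,maxIter,traceDamp training options
#'   forwarded to [trainMetric()] when `metric = "mlr"`.
#' @param labelScheme `"native"` (use labels as they are) or `"aami"`
#'   (group through [mapToAami()] first).
#' @param keepRemainder keep a final partial query set instead of
#'   discarding leftover test samples (default TRUE).
#' @param family,levels,encoding wavelet settings used when a
#'   [BeatSet-class] (rather than a feature table) is evaluated.
#' @param seed integer seed driving splits, caps and set shuffles.
#' @return named list of resolved parameters.
#' @export
experimentParams <- function(nTrials = 10, trainFraction = 0.5,
                             cap = 500, setSize = 50,
                             smallClassSizes = c(J = 5, Q = 5, e = 5, S = 1),
                             measure = "mbd", beta = 0.1, op = "sum",
                             metric = "none", C = 1,
                             regularizer = "frobenius", k = 3, tol = 1e-4,
                             maxIter = 50, traceDamp = 1,
                             labelScheme = c("native", "aami"),
                             keepRemainder = TRUE,
                             family = "bior6.8", levels = 8,
                             encoding = "stats", seed = 1) {
  stopifnot(
    trainFraction > 0, trainFraction < 1, setSize >= 1, nTrials >= 1
  )
  list(
    nTrials = nTrials, trainFraction = trainFraction, cap = cap,
    setSize = setSize, smallClassSizes = smallClassSizes,
    measure = measure, beta = beta, op = op, metric = metric, C = C,
    regularizer = regularizer, k = k, tol = tol, maxIter = maxIter,
    traceDamp = traceDamp, labelScheme = match.arg(labelScheme),
    keepRemainder = keepRemainder, family = family, levels = levels,
    encoding = encoding, seed = seed
  )
}

#' Stratified repeated random halves
#'
#' For each trial, every class is shuffled and split into a training
#' and a testing part; with `trainFraction = 0.5` and an odd class
#' count the extra sample goes to training. Splits are deterministic
#' per `(seed, trial)`, so different pipelines evaluated with the same
#' seed consume identical splits.
#'
#' @param labels class symbols.
#' @param nTrials number of splits.
#' @param trainFraction training fraction per class.
#' @param seed integer seed.
#' @return list of `nTrials` lists with integer `train` and `test`
#'   index vectors.
#' @export
splitTrials <- function(labels, nTrials = 10, trainFraction = 0.5,
                        seed = 1) {
  classes <- unique(labels)
  lapply(seq_len(nTrials), function(trial) {
    withSeed(subSeed(seed, trial), {
      train <- integer(0)
      test <- integer(0)
      for (cl in classes) {
        idx <- which(labels == cl)
        sh <- if (length(idx) == 1) idx else sample(idx)
        nTrain <- ceiling(length(idx) * trainFraction)
        train <- c(train, sh[seq_len(nTrain)])
        if (nTrain < length(idx)) {
          test <- c(test, sh[(nTrain + 1):length(idx)])
        }
      }
      list(train = sort(train), test = sort(test))
    })
  })
}

#' Cap per-class training counts
#'
#' Classes whose training count exceeds `cap` are randomly subsampled
#' to exactly `cap`; smaller classes are untouched.
#'
#' @param trainIdx integer indices of the training half.
#' @param labels class symbols for all samples.
#' @param cap maximum training count per class (default 500).
#' @param seed integer seed.
#' @return integer index vector.
#' @export
capTraining <- function(trainIdx, labels, cap = 500, seed = 1) {
  stopifnot(cap >= 1)
  withSeed(subSeed(seed, 104395301), {
    out <- integer(0)
    for (cl in unique(labels[trainIdx])) {
      idx <- trainIdx[labels[trainIdx] == cl]
      if (length(idx) > cap) {
        idx <- sample(idx, cap)
      }
      out <- c(out, idx)
    }
    sort(out)
  })
}

#' Partition test samples into query sets
#'
#' Per class, the test samples are shuffled (seeded) and cut into
#' disjoint chunks of the class's set size (`smallClassSizes` override,
#' else `setSize`); a final partial chunk is kept as a smaller set when
#' `keepRemainder` is TRUE, otherwise discarded (single remaining
#' samples always form a singleton set when they are the class's only
#' test data).
#'
#' @param features a [FeatureTable-class] or numeric matrix.
#' @param testIdx integer indices of the test half.
#' @param labels class symbols for all samples (defaults to the table
#'   labels).
#' @param setSize default query-set size.
#' @param smallClassSizes named per-class overrides.
#' @param keepRemainder keep the final partial chunk.
#' @param seed integer seed.
#' @return list of [SampleSet-class] objects carrying true class
#'   labels.
#' @export
buildQuerySets <- function(features, testIdx, labels = NULL,
                           setSize = 50, smallClassSizes = NULL,
                           keepRemainder = TRUE, seed = 1) {
  if (is(features, "FeatureTable")) {
    X <- features@features
    if (is.null(labels)) labels <- features@labels
  } else {
    X <- as.matrix(features)
  }
  stopifnot(setSize >= 1)
  withSeed(subSeed(seed, 15485863), {
    sets <- list()
    for (cl in unique(labels[testIdx])) {
      idx <- testIdx[labels[testIdx] == cl]
      size <- if (!is.null(smallClassSizes) && cl %in% names(smallClassSizes)) {
        smallClassSizes[[cl]]
      } else {
        setSize
      }
      sh <- if (length(idx) == 1) idx else sample(idx)
      nFull <- length(sh) %/% size
      chunks <- list()
      if (nFull > 0) {
        chunks <- lapply(seq_len(nFull), function(i) {
          sh[((i - 1) * size + 1):(i * size)]
        })
      }
      rest <- length(sh) - nFull * size
      if (rest > 0 && (keepRemainder || nFull == 0)) {
        chunks <- c(chunks, list(sh[(nFull * size + 1):length(sh)]))
      }
      for (i in seq_along(chunks)) {
        sets[[length(sets) + 1]] <- SampleSet(
          X[chunks[[i]], , drop = FALSE],
          setId = sprintf("%s.%d", cl, i), classLabel = cl
        )
      }
    }
    sets
  })
}

#' Rank corpus classes against a query set
#'
#' Classes are sorted by ascending dissimilarity between the query set
#' and their corpus set; ties are broken by ascending class symbol.
#'
#' @param query a [SampleSet-class].
#' @param corpusSets named list of per-class [SampleSet-class] corpus
#'   sets.
#' @param measure,beta,op dissimilarity settings (see
#'   [setDistanceMatrix()]).
#' @param projection optional metric factor `l`.
#' @return character vector of class names, best match first.
#' @export
rankClasses <- function(query, corpusSets, measure = "mbd", beta = 0.1,
                        op = "sum", projection = NULL) {
  if (any(vapply(corpusSets, function(s) nrow(asSetMatrix(s)) == 0, logical(1)))) {
    stop("corpus classes must be non-empty")
  }
  d <- drop(setDistanceMatrix(
    list(query), corpusSets,
    measure = measure,
    beta = beta, op = op, projection = projection
  ))
  nm <- names(corpusSets)
  nm[order(d, nm, method = "radix")]
}

# ---- evaluation engine ----------------------------------------------

# One pipeline spec: list(label, measure, useMetric, baseline)
parseMethod <- function(m) {
  useMetric <- startsWith(m, "mlr+")
  base <- sub("^mlr\\+", "", m)
  if (!base %in% c("mbd", "mpd", "mad", "apd", "baseline")) {
    stop(sprintf("unknown method '%s'", m))
  }
  list(
    label = m, measure = base, useMetric = useMetric,
    baseline = base == "baseline"
  )
}

resolveFeatures <- function(features, params) {
  if (is(features, "BeatSet")) {
    features <- featurizeBeats(
      features,
      family = params$family,
      levels = params$levels, encoding = params$encoding
    )
  }
  if (!is(features, "FeatureTable")) {
    stop("features must be a BeatSet or FeatureTable")
  }
  features
}

# Shared-split evaluation of several pipelines; returns a named list
# of RankResult.
evalEngine <- function(features, params, methods) {
  features <- resolveFeatures(features, params)
  X <- features@features
  labels <- features@labels
  if (params$labelScheme == "aami") {
    labels <- mapToAami(labels)
  }
  specs <- lapply(methods, parseMethod)
  needTrain <- any(vapply(specs, `[[`, logical(1), "useMetric")) &&
    identical(params$metric, "mlr")
  fixedProj <- NULL
  if (is(params$metric, "MetricModel")) {
    fixedProj <- metricFactor(params$metric)
  }
  if (any(vapply(specs, `[[`, logical(1), "useMetric")) &&
      is.null(fixedProj) && !identical(params$metric, "mlr")) {
    stop("methods with an 'mlr+' prefix need params$metric = 'mlr' or a MetricModel")
  }
  splits <- splitTrials(
    labels, params$nTrials, params$trainFraction,
    params$seed
  )
  classes <- sort(unique(labels))
  acc <- lapply(specs, function(s) {
    list(
      perTrial = data.frame(), perClassNum = NULL, perClassDen = NULL
    )
  })
  names(acc) <- vapply(specs, `[[`, character(1), "label")
  models <- list()
  for (trial in seq_along(splits)) {
    sp <- splits[[trial]]
    capped <- capTraining(
      sp$train, labels, params$cap,
      subSeed(params$seed, trial)
    )
    proj <- fixedProj
    if (needTrain && is.null(fixedProj)) {
      model <- trainMetric(X[capped, , drop = FALSE], labels[capped],
        C = params$C, regularizer = params$regularizer, k = params$k,
        tol = params$tol, maxIter = params$maxIter,
        traceDamp = params$traceDamp
      )
      proj <- metricFactor(model)
      models[[trial]] <- model
    }
    corpus <- lapply(classes, function(cl) {
      SampleSet(X[capped[labels[capped] == cl], , drop = FALSE],
        setId = cl, classLabel = cl
      )
    })
    names(corpus) <- classes
    qSets <- buildQuerySets(X, sp$test, labels,
      setSize = params$setSize,
      smallClassSizes = params$smallClassSizes,
      keepRemainder = params$keepRemainder,
      seed = subSeed(params$seed, trial)
    )
    for (si in seq_along(specs)) {
      s <- specs[[si]]
      p <- if (s$useMetric) proj else NULL
      if (s$baseline) {
        res <- rateSingles(X, sp$test, labels, corpus, p, classes)
      } else {
        res <- rateSets(qSets, corpus, s, params, p, classes)
      }
      acc[[si]]$perTrial <- rbind(
        acc[[si]]$perTrial,
        data.frame(
          trial = trial, rank1 = res$rank1, rank5 = res$rank5,
          nSets = res$n
        )
      )
      if (is.null(acc[[si]]$perClassNum)) {
        acc[[si]]$perClassNum <- res$clsNum * 0
        acc[[si]]$perClassNum5 <- res$clsNum * 0
        acc[[si]]$perClassDen <- res$clsDen * 0
        acc[[si]]$clsRateSum <- res$clsNum * 0
        acc[[si]]$clsRateSum5 <- res$clsNum * 0
        acc[[si]]$clsTrials <- res$clsDen * 0
      }
      acc[[si]]$perClassNum <- acc[[si]]$perClassNum + res$clsNum
      acc[[si]]$perClassNum5 <- acc[[si]]$perClassNum5 + res$clsNum5
      acc[[si]]$perClassDen <- acc[[si]]$perClassDen + res$clsDen
      pres <- res$clsDen > 0
      acc[[si]]$clsRateSum[pres] <- acc[[si]]$clsRateSum[pres] +
        res$clsNum[pres] / res$clsDen[pres]
      acc[[si]]$clsRateSum5[pres] <- acc[[si]]$clsRateSum5[pres] +
        res$clsNum5[pres] / res$clsDen[pres]
      acc[[si]]$clsTrials <- acc[[si]]$clsTrials + as.numeric(pres)
    }
  }
  out <- lapply(seq_along(specs), function(si) {
    a <- acc[[si]]
    ok <- a$clsTrials > 0
    perClass <- data.frame(
      class = classes,
      rank1 = ifelse(ok, 100 * a$clsRateSum / pmax(a$clsTrials, 1), NA),
      rank5 = ifelse(ok, 100 * a$clsRateSum5 / pmax(a$clsTrials, 1), NA),
      nSets = a$perClassDen
    )
    new("RankResult",
      method = specs[[si]]$label,
      overall = c(
        rank1 = mean(a$perTrial$rank1),
        rank5 = mean(a$perTrial$rank5)
      ),
      perClass = perClass, perTrial = a$perTrial,
      params = c(params, list(models = if (length(models)) models else NULL))
    )
  })
  names(out) <- names(acc)
  out
}

rateSets <- function(qSets, corpus, spec, params, proj, classes) {
  hit1 <- 0
  hit5 <- 0
  clsNum <- stats::setNames(numeric(length(classes)), classes)
  clsNum5 <- clsNum
  clsDen <- clsNum
  for (qs in qSets) {
    ranked <- rankClasses(qs, corpus,
      measure = spec$measure,
      beta = params$beta, op = params$op, projection = proj
    )
    truth <- qs@classLabel
    r <- match(truth, ranked)
    hit1 <- hit1 + (r == 1)
    hit5 <- hit5 + (r <= 5)
    clsNum[truth] <- clsNum[truth] + (r == 1)
    clsNum5[truth] <- clsNum5[truth] + (r <= 5)
    clsDen[truth] <- clsDen[truth] + 1
  }
  n <- length(qSets)
  list(
    rank1 = 100 * hit1 / n, rank5 = 100 * hit5 / n, n = n,
    clsNum = clsNum, clsNum5 = clsNum5, clsDen = clsDen
  )
}

# Single-sample baseline: every test sample is its own singleton query
# and classes are ranked by the distance to their nearest training
# sample (singleton-query MPD), optionally in the projected space.
rateSingles <- function(X, testIdx, labels, corpus, proj, classes) {
  cm <- lapply(corpus, function(s) projectSet(s@vectors, proj))
  Q <- projectSet(X[testIdx, , drop = FALSE], proj)
  dmat <- vapply(cm, function(m) {
    apply(pairwiseSqDist(Q, m), 1, min)
  }, numeric(nrow(Q)))
  dmat <- matrix(dmat, nrow = nrow(Q))
  hit1 <- 0
  hit5 <- 0
  clsNum <- stats::setNames(numeric(length(classes)), classes)
  clsNum5 <- clsNum
  clsDen <- clsNum
  for (i in seq_len(nrow(Q))) {
    ranked <- classes[order(dmat[i, ], classes, method = "radix")]
    truth <- labels[testIdx[i]]
    r <- match(truth, ranked)
    hit1 <- hit1 + (r == 1)
    hit5 <- hit5 + (r <= 5)
    clsNum[truth] <- clsNum[truth] + (r == 1)
    clsNum5[truth] <- clsNum5[truth] + (r <= 5)
    clsDen[truth] <- clsDen[truth] + 1
  }
  n <- nrow(Q)
  list(
    rank1 = 100 * hit1 / n, rank5 = 100 * hit5 / n, n = n,
    clsNum = clsNum, clsNum5 = clsNum5, clsDen = clsDen
  )
}

#' Run the set-based evaluation protocol
#'
#' Per trial: stratified random halving, per-class training cap,
#' optional metric training on the capped training half, corpus-set
#' construction (one set per class holding all capped training samples
#' of that class), query-set construction from the test half, class
#' ranking by set dissimilarity, and Rank-1/Rank-5 scoring (a query
#' set counts as correct at rank k when its true class is among the k
#' smallest dissimilarities). Rates are averaged across trials.
#'
#' @param features a [FeatureTable-class] or [BeatSet-class].
#' @param params list from [experimentParams()].
#' @param method pipeline label: one of `"mbd"`, `"mpd"`, `"mad"`,
#'   `"apd"`, `"baseline"`, optionally prefixed with `"mlr+"` to
#'   evaluate in the learned metric space. Defaults to the measure and
#'   metric configured in `params`.
#' @return A [RankResult-class].
#' @export
runEvaluation <- function(features, params = experimentParams(),
                          method = NULL) {
  if (is.null(method)) {
    method <- if (identical(params$metric, "none")) {
      params$measure
    } else {
      paste0("mlr+", params$measure)
    }
  }
  evalEngine(features, params, method)[[1]]
}

#' Compare several pipelines on shared splits
#'
#' All listed methods are evaluated trial by trial on identical splits,
#' caps and query sets (and share one trained metric per trial), so
#' their rates are directly comparable.
#'
#' @param features a [FeatureTable-class] or [BeatSet-class].
#' @param params list from [experimentParams()]; set `metric = "mlr"`
#'   if any method carries the `"mlr+"` prefix.
#' @param methods character vector of pipeline labels (see
#'   [runEvaluation()]).
#' @return named list of [RankResult-class] objects.
#' @export
compareMeasures <- function(features, params = experimentParams(),
                            methods = c("mbd", "mpd", "mad", "apd")) {
  evalEngine(features, params, methods)
}

#' Single-sample Euclidean baseline
#'
#' Every test sample is classified on its own by the distance to the
#' nearest training sample of each class (equivalently, the evaluation
#' with singleton query sets and the minimum point-wise distance), in
#' the original feature space.
#'
#' @param features a [FeatureTable-class] or [BeatSet-class].
#' @param params list from [experimentParams()].
#' @return A [RankResult-class].
#' @export
baselineSingleSample <- function(features, params = experimentParams()) {
  evalEngine(features, params, "baseline")[[1]]
}
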