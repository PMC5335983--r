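#' @include AllClasses.R
NULL

#' Construct a BeatSet
#'
#' @param samples numeric matrix, one beat per row.
#' @param labels character vector of beat-type symbols.
#' @param recordId source identifier(s), recycled to the number of rows.
#' @param rIndex R-peak sample indices (0-based) or `NA`.
#' @return A [BeatSet-class] object.
#' @export
BeatSet <- function(samples, labels, recordId = NA_character_,
                    rIndex = NA_integer_) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  new("BeatSet",
    samples = samples,
    labels = as.character(labels),
    recordId = rep_len(as.character(recordId), n),
    rIndex = rep_len(as.integer(rIndex), n)
  )
}

#' Construct a FeatureTable
#'
#' @param features numeric matrix, one row per beat.
#' @param labels class symbols aligned with rows.
#' @param featureNames optional column descriptors.
#' @return A [FeatureTable-class] object.
#' @export
FeatureTable <- function(features, labels, featureNames = NULL) {
  features <- as.matrix(features)
  if (is.null(featureNames)) {
    featureNames <- colnames(features)
    if (is.null(featureNames)) {
      featureNames <- paste0("f", seq_len(ncol(features)))
    }
  }
  colnames(features) <- featureNames
  new("FeatureTable",
    features = features,
    labels = as.character(labels),
    featureNames = as.character(featureNames)
  )
}

#' Construct a SampleSet
#'
#' @param vectors numeric matrix (n x d) or a single vector.
#' @param setId identifier.
#' @param classLabel class symbol or `NA`.
#' @return A [SampleSet-class] object.
#' @export
SampleSet <- function(vectors, setId = "set", classLabel = NA_character_) {
  if (is.null(dim(vectors))) {
    vectors <- matrix(vectors, nrow = 1)
  }
  new("SampleSet",
    vectors = as.matrix(vectors),
    setId = as.character(setId),
    classLabel = as.character(classLabel)
  )
}

#' @describeIn BeatSet-class the beats-by-samples waveform matrix.
#' @param x object.
#' @export
setMethod("beatMatrix", "BeatSet", function(x) x@samples)

#' @describeIn BeatSet-class per-beat class symbols.
#' @export
setMethod("beatLabels", "BeatSet", function(x) x@labels)

#' @describeIn BeatSet-class 0-based R-peak indices in the source signal.
#' @export
setMethod("rIndex", "BeatSet", function(x) x@rIndex)

#' @describeIn BeatSet-class source record identifiers.
#' @export
setMethod("recordId", "BeatSet", function(x) x@recordId)

#' @describeIn FeatureTable-class the beats-by-features matrix.
#' @param x object.
#' @export
setMethod("featureMatrix", "FeatureTable", function(x) x@features)

#' @describeIn FeatureTable-class per-row class symbols.
#' @export
setMethod("beatLabels", "FeatureTable", function(x) x@labels)

#' @describeIn FeatureTable-class feature column descriptors.
#' @export
setMethod("featureNames", "FeatureTable", function(x) x@featureNames)

#' @describeIn MetricModel-class the learned metric matrix w.
#' @param x object.
#' @export
setMethod("metricMatrix", "MetricModel", function(x) x@w)

#' @describeIn MetricModel-class the factor l with `w = t(l) %*% l`.
#' @export
setMethod("metricFactor", "MetricModel", function(x) x@l)

#' @describeIn MetricModel-class per-iteration solver diagnostics.
#' @export
setMethod("trainingHistory", "MetricModel", function(x) x@history)

#' @describeIn MetricModel-class did the cutting-plane loop converge?
#' @export
setMethod("isConverged", "MetricModel", function(x) x@converged)

#' @describeIn SampleSet-class the n-by-d matrix of member vectors.
#' @param x object.
#' @export
setMethod("setVectors", "SampleSet", function(x) x@vectors)

#' @describeIn SampleSet-class the class symbol carried by the set.
#' @export
setMethod("setLabel", "SampleSet", function(x) x@classLabel)

#' @describeIn RankResult-class across-trial mean Rank-1/Rank-5 rates.
#' @param x object.
#' @export
setMethod("overallRates", "RankResult", function(x) x@overall)

#' @describeIn RankResult-class per-class rates.
#' @export
setMethod("perClassRates", "RankResult", function(x) x@perClass)

#' @describeIn RankResult-class raw per-trial rates.
#' @export
setMethod("perTrialRates", "RankResult", function(x) x@perTrial)

setMethod("show", "BeatSet", function(object) {
  cat(sprintf(
    "BeatSet: %d beats x %d samples, %d classes\n",
    nrow(object@samples), ncol(object@samples),
    length(unique(object@labels))
  ))
  tab <- table(object@labels)
  cat("  classes:", paste(sprintf("%s(%d)", names(tab), tab),
    collapse = " "
  ), "\n")
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf(
    "FeatureTable: %d beats x %d features, %d classes\n",
    nrow(object@features), ncol(object@features),
    length(unique(object@labels))
  ))
})

setMethod("show", "MetricModel", function(object) {
  cat(sprintf(
    "MetricModel: %dx%d metric, rank %d, %s regularizer, C=%g, k=%d\n",
    nrow(object@w), ncol(object@w), nrow(object@l),
    object@regularizer, object@C, object@k
  ))
  cat(sprintf(
    "  %d outer iterations, converged: %s\n",
    nrow(object@history), object@converged
  ))
})

setMethod("show", "SampleSet", function(object) {
  cat(sprintf(
    "SampleSet '%s': %d vectors x %d dims, class %s\n",
    object@setId, nrow(object@vectors), ncol(object@vectors),
    object@classLabel
  ))
})

setMethod("show", "RankResult", function(object) {
  cat(sprintf(
    "RankResult [%s]: Rank-1 %.2f%%, Rank-5 %.2f%% (%d trials)\n",
    object@method, object@overall[["rank1"]], object@overall[["rank5"]],
    nrow(object@perTrial)
  ))
})
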