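#' @include AllGenerics.R
NULL

#' Container for fixed-length beat waveforms
#'
#' A `BeatSet` stores one beat per row: a fixed-length waveform segment
#' (by default 235 samples, i.e. 90 samples before the annotated R peak,
#' the peak itself, and 144 samples after), together with a beat-type
#' label, the identifier of the source record, and the sample index of
#' the R peak within that record. Synthetic beats carry `rIndex = NA`.
#'
#' @slot samples numeric matrix, one row per beat.
#' @slot labels character vector of beat-type symbols, one per row.
#' @slot recordId character vector of source identifiers, one per row.
#' @slot rIndex integer vector of R-peak positions in the source signal
#'   (0-based), `NA` when not applicable.
#'
#' @seealso [simulateBeats()], [segmentBeats()], [featurizeBeats()]
#' @export
setClass("BeatSet",
  representation(
    samples = "matrix",
    labels = "character",
    recordId = "character",
    rIndex = "integer"
  )
)

setValidity("BeatSet", function(object) {
  n <- nrow(object@samples)
  if (length(object@labels) != n) {
    return("labels length must equal the number of beat rows")
  }
  if (length(object@recordId) != n) {
    return("recordId length must equal the number of beat rows")
  }
  if (length(object@rIndex) != n) {
    return("rIndex length must equal the number of beat rows")
  }
  if (n > 0 && !is.numeric(object@samples)) {
    return("samples must be a numeric matrix")
  }
  TRUE
})

#' Per-beat feature vectors with aligned labels
#'
#' Rows of `features` align with `labels`; columns are named by
#' `featureNames`. Produced by [featurizeBeats()] or
#' [simulateFeatureClusters()], consumed by [trainMetric()] and the
#' evaluation harness.
#'
#' @slot features numeric matrix, one row per beat.
#' @slot labels character vector of class symbols, one per row.
#' @slot featureNames character vector naming the columns.
#' @export
setClass("FeatureTable",
  representation(
    features = "matrix",
    labels = "character",
    featureNames = "character"
  )
)

setValidity("FeatureTable", function(object) {
  if (nrow(object@features) != length(object@labels)) {
    return("labels length must equal the number of feature rows")
  }
  if (ncol(object@features) != length(object@featureNames)) {
    return("featureNames length must equal the number of feature columns")
  }
  TRUE
})

#' A learned Mahalanobis metric
#'
#' Holds the symmetric positive semidefinite metric matrix `w`, its
#' factor `l` with `w = t(l) %*% l` (so that the Mahalanobis distance
#' under `w` equals the Euclidean distance after projecting by `l`), the
#' training configuration, and per-iteration solver diagnostics.
#'
#' @slot w symmetric PSD metric matrix (d x d).
#' @slot l projection factor (r x d), `r = rank(w)`.
#' @slot C trade-off scalar between slack and regularizer.
#' @slot regularizer `"trace"` or `"frobenius"`.
#' @slot k truncation rank of the reciprocal-rank score.
#' @slot history data.frame of per-outer-iteration diagnostics:
#'   `objective` (working-set dual objective), `primal`, `maxViolation`,
#'   `nConstraints`.
#' @slot converged logical; `FALSE` means the iteration cap was reached
#'   before all ranking constraints were satisfied within tolerance.
#' @export
setClass("MetricModel",
  representation(
    w = "matrix",
    l = "matrix",
    C = "numeric",
    regularizer = "character",
    k = "numeric",
    history = "data.frame",
    converged = "logical"
  )
)

setValidity("MetricModel", function(object) {
  w <- object@w
  if (nrow(w) != ncol(w)) {
    return("w must be square")
  }
  if (nrow(w) > 0) {
    if (max(abs(w - t(w))) > 1e-9) {
      return("w must be symmetric within 1e-9")
    }
    ev <- eigen(w, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-9 * max(abs(ev), 1)) {
      return("w must be positive semidefinite")
    }
    rec <- crossprod(object@l)
    rel <- sqrt(sum((rec - w)^2)) / max(sqrt(sum(w^2)), 1e-12)
    if (sum(w^2) > 0 && rel > 1e-6) {
      return("t(l) %*% l must reconstruct w within 1e-6 relative")
    }
  }
  TRUE
})

#' An ordered collection of feature vectors treated as one unit
#'
#' Query and corpus sets for set-to-set dissimilarity: rows of `vectors`
#' are samples; `setId` identifies the set; `classLabel` is the class
#' the set belongs to (may be `NA` for unlabelled queries).
#'
#' @slot vectors numeric matrix (n x d), n >= 1.
#' @slot setId character identifier.
#' @slot classLabel character class symbol or `NA`.
#' @export
setClass("SampleSet",
  representation(
    vectors = "matrix",
    setId = "character",
    classLabel = "character"
  )
)

setValidity("SampleSet", function(object) {
  if (nrow(object@vectors) < 1) {
    return("a SampleSet must contain at least one vector")
  }
  TRUE
})

#' Rank-1/Rank-5 classification rates across trials
#'
#' All rates are percentages in \[0, 100\]. `overall` holds the across-
#' trial means; `perClass` one row per class with its Rank-1/Rank-5 rate
#' and the number of query sets; `perTrial` the raw per-trial rates.
#'
#' @slot method label of the evaluated pipeline (e.g. `"mlr+mbd"`).
#' @slot overall named numeric: `rank1`, `rank5`.
#' @slot perClass data.frame: `class`, `rank1`, `rank5`, `nSets`.
#' @slot perTrial data.frame: `trial`, `rank1`, `rank5`, `nSets`.
#' @slot params list of the resolved experiment parameters.
#' @export
setClass("RankResult",
  representation(
    method = "character",
    overall = "numeric",
    perClass = "data.frame",
    perTrial = "data.frame",
    params = "list"
  )
)

setValidity("RankResult", function(object) {
  r <- object@overall
  if (!all(c("rank1", "rank5") %in% names(r))) {
    return("overall must contain rank1 and rank5")
  }
  if (any(r < -1e-9 | r > 100 + 1e-9)) {
    return("rates must lie in [0, 100]")
  }
  TRUE
})

#' Waveform recipe for one synthetic beat class
#'
#' A beat class is a sum of Gaussian humps (P/QRS/T-like components)
#' plus optional baseline wander and white noise. Per-beat variation is
#' controlled by relative amplitude jitter and timing jitter.
#'
#' @slot classId character class label.
#' @slot amplitude,center,width numeric vectors (one entry per hump):
#'   dimensionless amplitude, centre in samples, width (Gaussian sd) in
#'   samples.
#' @slot ampJitterSd relative (multiplicative) amplitude jitter sd.
#' @slot timeJitterSd timing jitter sd in samples.
#' @slot noiseSd additive white noise sd.
#' @slot baselineAmp amplitude of the baseline-wander sinusoid.
#' @slot baselinePeriod period of the baseline sinusoid in samples.
#' @export
setClass("BeatClassSpec",
  representation(
    classId = "character",
    amplitude = "numeric",
    center = "numeric",
    width = "numeric",
    ampJitterSd = "numeric",
    timeJitterSd = "numeric",
    noiseSd = "numeric",
    baselineAmp = "numeric",
    baselinePeriod = "numeric"
  )
)

setValidity("BeatClassSpec", function(object) {
  k <- length(object@amplitude)
  if (length(object@center) != k || length(object@width) != k) {
    return("amplitude, center and width must have equal length")
  }
  if (any(object@width <= 0)) {
    return("all component widths must be > 0")
  }
  if (object@noiseSd < 0 || object@ampJitterSd < 0 ||
      object@timeJitterSd < 0) {
    return("noiseSd, ampJitterSd and timeJitterSd must be >= 0")
  }
  if (object@baselinePeriod <= 0) {
    return("baselinePeriod must be > 0")
  }
  TRUE
})

#' Recipe for synthetic feature-space clusters
#'
#' Class means are placed at scaled simplex vertices (all pairwise
#' separations equal), samples are drawn spherically and then distorted
#' by a linear map; a fraction of samples is displaced to emulate
#' outliers.
#'
#' @slot nClasses number of classes.
#' @slot dim feature dimension (must be >= nClasses).
#' @slot classSeparation distance between class means before distortion.
#' @slot withinSd within-class standard deviation before distortion.
#' @slot distortion dim x dim matrix applied to all samples.
#' @slot contaminationRate fraction of samples displaced, in \[0, 1\].
#' @slot contaminationMagnitude displacement length (after distortion).
#' @export
setClass("ClusterSpec",
  representation(
    nClasses = "numeric",
    dim = "numeric",
    classSeparation = "numeric",
    withinSd = "numeric",
    distortion = "matrix",
    contaminationRate = "numeric",
    contaminationMagnitude = "numeric"
  )
)

setValidity("ClusterSpec", function(object) {
  if (object@contaminationRate < 0 || object@contaminationRate > 1) {
    return("contaminationRate must lie in [0, 1]")
  }
  if (object@withinSd < 0) {
    return("withinSd must be >= 0")
  }
  if (nrow(object@distortion) != object@dim ||
      ncol(object@distortion) != object@dim) {
    return("distortion must be a square matrix with side = dim")
  }
  if (object@dim < object@nClasses) {
    return("dim must be >= nClasses (simplex mean placement)")
  }
  TRUE
})

#' A ranking problem: one query against a labelled corpus
#'
#' The corpus is the row-bind of `relevant` (same-class) and
#' `irrelevant` (different-class) vectors; items are indexed 1..(P+N)
#' with the first P rows relevant.
#'
#' @slot query numeric query vector.
#' @slot relevant matrix of relevant corpus vectors (P x d, P >= 1).
#' @slot irrelevant matrix of irrelevant corpus vectors (N x d, N >= 1).
#' @export
setClass("RankingInstance",
  representation(
    query = "numeric",
    relevant = "matrix",
    irrelevant = "matrix"
  )
)

setValidity("RankingInstance", function(object) {
  d <- length(object@query)
  if (nrow(object@relevant) < 1 || nrow(object@irrelevant) < 1) {
    return("relevant and irrelevant sets must both be non-empty")
  }
  if (ncol(object@relevant) != d || ncol(object@irrelevant) != d) {
    return("corpus vector dimension must match the query")
  }
  TRUE
})
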