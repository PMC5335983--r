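#' @include AllGenerics.R
NULL

#' @export
setGeneric("beatMatrix", function(x) standardGeneric("beatMatrix"))

#' @export
setGeneric("beatLabels", function(x) standardGeneric("beatLabels"))

#' @export
setGeneric("rIndex", function(x) standardGeneric("rIndex"))

#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @export
setGeneric("metricMatrix", function(x) standardGeneric("metricMatrix"))

#' @export
setGeneric("metricFactor", function(x) standardGeneric("metricFactor"))

#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @export
setGeneric("setVectors", function(x) standardGeneric("setVectors"))

#' @export
setGeneric("setLabel", function(x) standardGeneric("setLabel"))

#' @export
setGeneric("overallRates", function(x) standardGeneric("overallRates"))

#' @export
setGeneric("perClassRates", function(x) standardGeneric("perClassRates"))

#' @export
setGeneric("perTrialRates", function(x) standardGeneric("perTrialRates"))
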