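#' @include AllClasses.R utils.R
NULL

#' Specify synthetic feature-space clusters
#'
#' @param nClasses number of classes.
#' @param dim feature dimension; must be >= `nClasses` so that class
#'   means can sit at scaled simplex vertices with equal pairwise
#'   separation.
#' @param classSeparation distance between any two class means before
#'   distortion.
#' @param withinSd spherical within-class sd before distortion.
#' @param distortion square matrix applied to all samples (defaults to
#'   identity); near-singular maps are allowed.
#' @param contaminationRate fraction of samples displaced as outliers.
#' @param contaminationMagnitude displacement length, applied after
#'   distortion.
#' @return A [ClusterSpec-class] object.
#' @export
clusterSpec <- function(nClasses, dim, classSeparation = 5,
                        withinSd = 1, distortion = NULL,
                        contaminationRate = 0,
                        contaminationMagnitude = 0) {
  if (is.null(distortion)) {
    distortion <- diag(dim)
  }
  new("ClusterSpec",
    nClasses = nClasses, dim = dim,
    classSeparation = classSeparation, withinSd = withinSd,
    distortion = as.matrix(distortion),
    contaminationRate = contaminationRate,
    contaminationMagnitude = contaminationMagnitude
  )
}

#' Default distorted, contaminated cluster specification
#'
#' The reference conditions used throughout the package's synthetic
#' studies: four classes in six dimensions separated by five
#' within-class standard deviations. The centred class means span only
#' a three-dimensional subspace; the distortion amplifies the two pure
#' noise directions orthogonal to it six-fold and shears them into the
#' signal coordinates, so Euclidean distances are dominated by
#' class-irrelevant variation (large intra-class variation, small
#' inter-class difference) while a Mahalanobis metric can recover the
#' class geometry. Optionally a fraction of samples is displaced by
#' one full class separation in a random direction to emulate
#' irregular outlier beats.
#'
#' @param contaminationRate outlier fraction (default 0.1).
#' @return A [ClusterSpec-class] object.
#' @export
defaultClusterSpec <- function(contaminationRate = 0.1) {
  d <- 6
  shear <- diag(d)
  shear[1, 5] <- 2
  shear[2, 6] <- -2
  shear[3, 5] <- 1.5
  shear[4, 6] <- 1
  clusterSpec(
    nClasses = 4, dim = d, classSeparation = 5, withinSd = 1,
    distortion = shear %*% diag(c(1, 1, 1, 1, 6, 6)),
    contaminationRate = contaminationRate,
    contaminationMagnitude = 5
  )
}

# Class means at scaled simplex vertices (centred), all pairwise
# distances equal to `sep`; requires dim >= nClasses.
simplexMeans <- function(nClasses, dim, sep) {
  m <- matrix(0, nClasses, dim)
  for (i in seq_len(nClasses)) {
    m[i, i] <- 1
  }
  m <- m - matrix(colMeans(m), nClasses, dim, byrow = TRUE)
  m * sep / sqrt(2) # unit-vector vertices are sqrt(2) apart
}

#' Simulate labelled feature clusters
#'
#' Class means are placed at mutual distance `classSeparation`, samples
#' drawn spherically with `withinSd`, the distortion applied to all
#' samples (means included), and finally `ceiling(rate * n)` samples
#' displaced by `contaminationMagnitude` in a uniformly random
#' direction. Deterministic given `seed`.
#'
#' @param spec a [ClusterSpec-class].
#' @param nPerClass integer vector of per-class counts
#'   (length `nClasses`).
#' @param seed integer seed.
#' @return A [FeatureTable-class] with labels `"k1"`, `"k2"`, ...
#' @export
simulateFeatureClusters <- function(spec, nPerClass, seed = 1) {
  if (length(nPerClass) != spec@nClasses) {
    stop("nPerClass must have one entry per class")
  }
  withSeed(seed, {
    mu <- simplexMeans(spec@nClasses, spec@dim, spec@classSeparation)
    n <- sum(nPerClass)
    x <- matrix(0, n, spec@dim)
    labs <- character(n)
    at <- 0
    for (cl in seq_len(spec@nClasses)) {
      m <- nPerClass[cl]
      if (m == 0) next
      idx <- at + seq_len(m)
      x[idx, ] <- matrix(stats::rnorm(m * spec@dim, sd = spec@withinSd),
        m, spec@dim
      ) + matrix(mu[cl, ], m, spec@dim, byrow = TRUE)
      labs[idx] <- paste0("k", cl)
      at <- at + m
    }
    x <- x %*% t(spec@distortion)
    if (spec@contaminationRate > 0 && n > 0) {
      nBad <- ceiling(spec@contaminationRate * n)
      bad <- sample.int(n, nBad)
      x[bad, ] <- x[bad, ] +
        spec@contaminationMagnitude * randomUnitRows(nBad, spec@dim)
    }
    FeatureTable(x, labs)
  })
}

#' Displace a fraction of a sample set
#'
#' `ceiling(fraction * n)` members, chosen uniformly at random without
#' replacement, are displaced by `magnitude` along directions drawn
#' uniformly on the sphere; all other members are untouched. The output
#' has the same cardinality as the input.
#'
#' @param set a [SampleSet-class].
#' @param fraction fraction of members to displace, in \[0, 1\].
#' @param magnitude displacement length.
#' @param seed integer seed.
#' @return A [SampleSet-class] of the same size.
#' @export
contaminateSet <- function(set, fraction, magnitude, seed = 1) {
  if (fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]")
  }
  v <- set@vectors
  n <- nrow(v)
  nBad <- ceiling(fraction * n)
  if (nBad == 0 || magnitude == 0) {
    if (nBad > 0 && magnitude == 0) {
      # members are still "selected" for determinism parity, but the
      # zero displacement leaves the set unchanged
      withSeed(seed, sample.int(n, nBad))
    }
    return(set)
  }
  withSeed(seed, {
    bad <- sample.int(n, nBad)
    v[bad, ] <- v[bad, , drop = FALSE] +
      magnitude * randomUnitRows(nBad, ncol(v))
    SampleSet(v, setId = set@setId, classLabel = set@classLabel)
  })
}
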