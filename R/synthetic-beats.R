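#' @include AllClasses.R utils.R
NULL

#' Specify a synthetic beat class
#'
#' Builds the waveform recipe for one synthetic beat class: a sum of
#' Gaussian humps standing in for the P wave, QRS complex and T wave,
#' plus optional baseline wander (a sinusoid with random phase per
#' beat) and additive white noise.
#'
#' @param classId class label attached to generated beats.
#' @param amplitude,center,width parallel numeric vectors describing the
#'   Gaussian components: dimensionless amplitude, centre (sample
#'   index, 0-based) and width (sd in samples).
#' @param ampJitterSd relative per-beat amplitude jitter sd (0.05 means
#'   component amplitudes vary by about five percent).
#' @param timeJitterSd per-beat timing jitter sd in samples (applied as
#'   one common shift to all components of a beat).
#' @param noiseSd additive white noise sd.
#' @param baselineAmp baseline-wander sinusoid amplitude.
#' @param baselinePeriod baseline-wander period in samples.
#' @return A [BeatClassSpec-class] object.
#' @examples
#' spec <- beatClassSpec("N", amplitude = c(0.15, 1, 0.3),
#'                       center = c(55, 90, 150), width = c(8, 4, 12))
#' @export
beatClassSpec <- function(classId, amplitude, center, width,
                          ampJitterSd = 0.05, timeJitterSd = 2,
                          noiseSd = 0.02, baselineAmp = 0,
                          baselinePeriod = 300) {
  new("BeatClassSpec",
    classId = as.character(classId),
    amplitude = as.numeric(amplitude),
    center = as.numeric(center),
    width = as.numeric(width),
    ampJitterSd = ampJitterSd,
    timeJitterSd = timeJitterSd,
    noiseSd = noiseSd,
    baselineAmp = baselineAmp,
    baselinePeriod = baselinePeriod
  )
}

#' Default separable beat-class specifications
#'
#' Four morphologically distinct classes on a 235-sample window with the
#' R peak at sample 90: a normal-like beat (P, tall narrow QRS, T), a
#' bundle-branch-block-like beat (wide notched QRS), a PVC-like beat
#' (large inverted wide QRS, no P wave) and a paced-like beat (spike
#' followed by a broad wave). Jitter, noise and baseline wander are
#' turned on at moderate levels.
#'
#' @param noiseSd white noise sd shared by all classes.
#' @param baselineAmp baseline-wander amplitude shared by all classes.
#' @return list of [BeatClassSpec-class] objects.
#' @export
defaultBeatSpecs <- function(noiseSd = 0.03, baselineAmp = 0.05) {
  list(
    beatClassSpec("c1",
      amplitude = c(0.15, 1.0, -0.25, 0.35),
      center = c(55, 90, 97, 150), width = c(8, 3.5, 5, 14),
      ampJitterSd = 0.06, timeJitterSd = 2, noiseSd = noiseSd,
      baselineAmp = baselineAmp, baselinePeriod = 320
    ),
    beatClassSpec("c2",
      amplitude = c(0.1, 0.7, 0.55, 0.3),
      center = c(50, 84, 98, 160), width = c(8, 7, 7, 16),
      ampJitterSd = 0.06, timeJitterSd = 2, noiseSd = noiseSd,
      baselineAmp = baselineAmp, baselinePeriod = 280
    ),
    beatClassSpec("c3",
      amplitude = c(-1.3, 0.6),
      center = c(92, 160), width = c(9, 18),
      ampJitterSd = 0.08, timeJitterSd = 3, noiseSd = noiseSd,
      baselineAmp = baselineAmp, baselinePeriod = 350
    ),
    beatClassSpec("c4",
      amplitude = c(1.1, -0.5, 0.45),
      center = c(88, 104, 165), width = c(2, 10, 20),
      ampJitterSd = 0.06, timeJitterSd = 2, noiseSd = noiseSd,
      baselineAmp = baselineAmp, baselinePeriod = 260
    )
  )
}

#' Simulate labelled beat waveforms
#'
#' Each beat is the sum of the class template's jittered Gaussian
#' components, a random-phase baseline sinusoid, and white noise,
#' evaluated on a window of `length` samples. With all jitter, noise
#' and baseline amplitudes at zero every beat reproduces the class
#' template exactly. Output is deterministic given `seed`.
#'
#' @param specs list of [BeatClassSpec-class] objects.
#' @param nPerClass integer vector of beat counts, one per spec.
#' @param length window length in samples (default 235).
#' @param seed integer seed.
#' @return A [BeatSet-class]; labels are the spec `classId`s.
#' @examples
#' beats <- simulateBeats(defaultBeatSpecs(), rep(5, 4), seed = 1)
#' @export
simulateBeats <- function(specs, nPerClass, length = 235, seed = 1) {
  stopifnot(length(specs) == length(nPerClass))
  if (any(nPerClass < 0)) {
    stop("beat counts must be >= 0")
  }
  for (spec in specs) {
    if (any(spec@center < 0 | spec@center >= length)) {
      stop(sprintf(
        "component center outside [0, %d) in spec for class '%s'",
        length, spec@classId
      ))
    }
  }
  withSeed(seed, {
    rows <- vector("list", length(specs))
    labs <- character(0)
    t <- seq_len(length) - 1
    for (s in seq_along(specs)) {
      spec <- specs[[s]]
      n <- nPerClass[s]
      if (n == 0) {
        rows[[s]] <- matrix(numeric(0), 0, length)
        next
      }
      m <- matrix(0, n, length)
      for (b in seq_len(n)) {
        shift <- if (spec@timeJitterSd > 0) {
          stats::rnorm(1, 0, spec@timeJitterSd)
        } else 0
        y <- numeric(length)
        for (i in seq_along(spec@amplitude)) {
          a <- spec@amplitude[i]
          if (spec@ampJitterSd > 0) {
            a <- a * (1 + stats::rnorm(1, 0, spec@ampJitterSd))
          }
          y <- y + a *
            exp(-0.5 * ((t - spec@center[i] - shift) / spec@width[i])^2)
        }
        if (spec@baselineAmp > 0) {
          phase <- stats::runif(1, 0, 2 * pi)
          y <- y + spec@baselineAmp *
            sin(2 * pi * t / spec@baselinePeriod + phase)
        }
        if (spec@noiseSd > 0) {
          y <- y + stats::rnorm(length, 0, spec@noiseSd)
        }
        m[b, ] <- y
      }
      rows[[s]] <- m
      labs <- c(labs, rep(spec@classId, n))
    }
    BeatSet(do.call(rbind, rows), labs, recordId = "synthetic")
  })
}
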