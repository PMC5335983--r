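#' @include AllClasses.R utils.R wavelet-filters.R
NULL

#' Supported wavelet families
#'
#' @return character vector of family names accepted by
#'   [dwtDecompose()] and [featurizeBeats()].
#' @export
waveletFamilies <- function() names(.waveletFilters)

#' Decomposition filters of a wavelet family
#'
#' @param family one of [waveletFamilies()].
#' @return list with `loD` (low-pass) and `hiD` (high-pass) analysis
#'   filters.
#' @export
waveletFilters <- function(family) {
  family <- tolower(family)
  if (!family %in% names(.waveletFilters)) {
    stop(sprintf(
      "unknown wavelet family '%s'; supported: %s",
      family, paste(names(.waveletFilters), collapse = ", ")
    ))
  }
  .waveletFilters[[family]]
}

# Half-point symmetric extension with edge repetition
# (... x2 x1 | x1 x2 ... xn | xn xn-1 ...), folding as often as needed.
symExtend <- function(x, m) {
  n <- length(x)
  p <- (-m):(n + m - 1)
  q <- p %% (2 * n)
  idx <- ifelse(q < n, q, 2 * n - 1 - q)
  x[idx + 1]
}

# One analysis step: symmetric extension by F-1, full convolution,
# downsampling by 2. Output length floor((n + F - 1) / 2).
dwtStep <- function(x, f) {
  n <- length(x)
  F <- length(f)
  ext <- symExtend(x, F - 1)
  # direct convolution; lengths here are small enough that FFT buys
  # nothing and exactness of the plain sum is easier to reason about
  full <- numeric(length(ext) + F - 1)
  for (j in seq_len(F)) {
    full[(j):(j + length(ext) - 1)] <-
      full[(j):(j + length(ext) - 1)] + f[j] * ext
  }
  outlen <- (n + F - 1) %/% 2
  full[F + 1 + 2 * (seq_len(outlen) - 1)]
}

#' Multi-level discrete wavelet decomposition
#'
#' Cascades the analysis filter pair of the chosen family `levels`
#' times with half-point symmetric boundary extension. At each level
#' the low-pass branch (approximation) is decomposed further; the
#' high-pass outputs (details) are retained. Sub-band lengths follow
#' the recurrence `len_k = floor((len_{k-1} + F - 1) / 2)` with `F` the
#' filter length.
#'
#' @param signal numeric vector.
#' @param family wavelet family name, see [waveletFamilies()].
#' @param levels decomposition depth (default 8).
#' @return named list of `levels + 1` coefficient vectors: the final
#'   approximation first (`a<levels>`), then details from coarsest
#'   (`d<levels>`) to finest (`d1`).
#' @examples
#' sb <- dwtDecompose(sin(seq(0, 10, length.out = 235)))
#' lengths(sb)
#' @export
dwtDecompose <- function(signal, family = "bior6.8", levels = 8) {
  if (levels < 1) {
    stop("levels must be >= 1")
  }
  if (length(signal) < 2) {
    stop(sprintf(
      "signal of length %d is too short to decompose; need at least 2 samples",
      length(signal)
    ))
  }
  flt <- waveletFilters(family)
  a <- as.numeric(signal)
  details <- vector("list", levels)
  for (lev in seq_len(levels)) {
    details[[lev]] <- dwtStep(a, flt$hiD)
    a <- dwtStep(a, flt$loD)
  }
  out <- c(list(a), rev(details))
  names(out) <- c(paste0("a", levels), paste0("d", levels:1))
  out
}

#' Encode sub-bands into a feature vector
#'
#' Two encodings: `"stats"` emits, for each sub-band in order, its
#' maximum, minimum, mean and population variance (divide by n), giving
#' `4 * (levels + 1)` features (36 for an 8-level decomposition);
#' `"all"` concatenates the raw coefficients of every sub-band.
#'
#' @param subBands list of coefficient vectors as returned by
#'   [dwtDecompose()] (approximation first, details coarse to fine).
#' @param encoding `"stats"` or `"all"`.
#' @return named numeric feature vector.
#' @export
encodeSubbands <- function(subBands, encoding = c("stats", "all")) {
  encoding <- match.arg(encoding)
  if (length(subBands) < 1) {
    stop("at least one sub-band is required")
  }
  if (any(lengths(subBands) == 0)) {
    stop("empty sub-band")
  }
  nm <- names(subBands)
  if (is.null(nm)) {
    nm <- paste0("b", seq_along(subBands))
  }
  if (encoding == "stats") {
    out <- unlist(lapply(seq_along(subBands), function(i) {
      v <- subBands[[i]]
      stats::setNames(
        c(max(v), min(v), mean(v), mean((v - mean(v))^2)),
        paste0(nm[i], ".", c("max", "min", "mean", "var"))
      )
    }))
  } else {
    out <- unlist(lapply(seq_along(subBands), function(i) {
      stats::setNames(
        subBands[[i]],
        paste0(nm[i], ".", seq_along(subBands[[i]]))
      )
    }))
  }
  out
}

#' Wavelet feature extraction for a beat collection
#'
#' Applies [dwtDecompose()] and [encodeSubbands()] to every beat and
#' assembles the rows into a [FeatureTable-class], carrying the labels
#' through unchanged.
#'
#' @param beats a [BeatSet-class]; all beats share one length.
#' @param family wavelet family name (default `"bior6.8"`).
#' @param levels decomposition depth (default 8).
#' @param encoding `"stats"` (default) or `"all"`.
#' @return A [FeatureTable-class] with one row per beat.
#' @examples
#' beats <- simulateBeats(defaultBeatSpecs(), rep(3, 4), seed = 1)
#' ft <- featurizeBeats(beats)
#' dim(featureMatrix(ft))
#' @export
featurizeBeats <- function(beats, family = "bior6.8", levels = 8,
                           encoding = c("stats", "all")) {
  encoding <- match.arg(encoding)
  m <- beats@samples
  rows <- lapply(seq_len(nrow(m)), function(i) {
    tryCatch(
      encodeSubbands(dwtDecompose(m[i, ], family, levels), encoding),
      error = function(e) {
        stop(sprintf("beat %d: %s", i, conditionMessage(e)), call. = FALSE)
      }
    )
  })
  feat <- do.call(rbind, rows)
  FeatureTable(feat, beats@labels)
}
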