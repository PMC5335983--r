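#' @include AllClasses.R utils.R
NULL

# WFDB annotation code <-> beat symbol, restricted to the 16 beat types
# of the MIT-BIH Arrhythmia Database. Paced beats ('/') are denoted "P"
# and ventricular flutter waves ('!') are denoted "W". All other
# annotation codes (rhythm changes, noise, comments, ...) are non-beat.
.wfdbBeatCodes <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "P",
  "13" = "Q", "31" = "W", "34" = "e", "38" = "f"
)

.beatAlphabet <- unname(.wfdbBeatCodes)

.aamiMap <- c(
  N = "NonEctopic", L = "NonEctopic", R = "NonEctopic",
  e = "NonEctopic", j = "NonEctopic",
  a = "SupraVentricularEctopic", A = "SupraVentricularEctopic",
  S = "SupraVentricularEctopic", J = "SupraVentricularEctopic",
  E = "VentricularEctopic", V = "VentricularEctopic",
  F = "Fusion",
  Q = "Unknown", P = "Unknown", f = "Unknown"
)

#' Map beat symbols to AAMI classes
#'
#' Groups the MIT-BIH beat symbols into the five classes of the
#' ANSI/AAMI EC57 taxonomy: N, L, R, e, j -> NonEctopic; a, A, S, J ->
#' SupraVentricularEctopic; E, V -> VentricularEctopic; F -> Fusion;
#' Q, P, f -> Unknown. The ventricular flutter wave symbol `W` is not
#' covered by the taxonomy and raises an error.
#'
#' @param symbol character vector of beat symbols.
#' @return character vector of AAMI class names.
#' @examples
#' mapToAami(c("V", "P", "F"))
#' @export
mapToAami <- function(symbol) {
  out <- .aamiMap[symbol]
  if (anyNA(out)) {
    bad <- unique(symbol[is.na(out)])
    stop(sprintf(
      "symbol(s) %s not covered by the AAMI grouping; valid symbols: %s",
      paste(sQuote(bad), collapse = ", "),
      paste(names(.aamiMap), collapse = ", ")
    ))
  }
  unname(out)
}

# ---- WFDB record I/O -------------------------------------------------

parseHeader <- function(heaPath) {
  lines <- readLines(heaPath, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*", "", rec[3])) else 250
  sigs <- lapply(lines[1 + seq_len(nsig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    gainField <- f[3]
    baseline <- NA_real_
    if (grepl("\\(", gainField)) {
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gainField))
    }
    gain <- as.numeric(sub("[(/].*", "", gainField))
    if (is.na(gain) || gain == 0) gain <- 200
    adcZero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    if (is.na(baseline)) baseline <- adcZero
    list(
      file = f[1], format = as.integer(sub("[^0-9].*", "", f[2])),
      gain = gain, baseline = baseline
    )
  })
  list(name = rec[1], nsig = nsig, fs = fs,
       nsamp = if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_,
       signals = sigs)
}

readDat212 <- function(path, nsig, nsamp) {
  raw <- readBin(path, "integer", n = file.info(path)$size, size = 1,
                 signed = FALSE)
  nPairs <- length(raw) %/% 3
  b1 <- raw[seq(1, 3 * nPairs, 3)]
  b2 <- raw[seq(2, 3 * nPairs, 3)]
  b3 <- raw[seq(3, 3 * nPairs, 3)]
  s1 <- b1 + 256 * (b2 %% 16)
  s2 <- b3 + 256 * (b2 %/% 16)
  s1[s1 >= 2048] <- s1[s1 >= 2048] - 4096
  s2[s2 >= 2048] <- s2[s2 >= 2048] - 4096
  all <- as.vector(rbind(s1, s2))
  matrix(all[seq_len((length(all) %/% nsig) * nsig)],
    ncol = nsig, byrow = TRUE
  )
}

readDat16 <- function(path, nsig) {
  v <- readBin(path, "integer", n = file.info(path)$size %/% 2, size = 2,
               signed = TRUE, endian = "little")
  matrix(v[seq_len((length(v) %/% nsig) * nsig)], ncol = nsig, byrow = TRUE)
}

readAtr <- function(path) {
  raw <- readBin(path, "integer", n = file.info(path)$size, size = 1,
                 signed = FALSE)
  n <- length(raw) %/% 2
  samples <- integer(0)
  codes <- integer(0)
  t <- 0
  i <- 1
  while (i + 1 <= 2 * n) {
    a <- raw[i] + 256 * raw[i + 1]
    code <- a %/% 1024
    interval <- a %% 1024
    i <- i + 2
    if (code == 0 && interval == 0) break
    if (code == 59) { # SKIP: next 4 bytes hold a long interval
      hi <- raw[i] + 256 * raw[i + 1]
      lo <- raw[i + 2] + 256 * raw[i + 3]
      i <- i + 4
      t <- t + hi * 65536 + lo
    } else if (code == 63) { # AUX: interval = byte count, padded even
      i <- i + interval + (interval %% 2)
    } else if (code %in% c(60, 61, 62)) { # NUM/SUB/CHN: no time change
      # interval byte carries the value; nothing to do
    } else {
      t <- t + interval
      samples <- c(samples, t)
      codes <- c(codes, code)
    }
  }
  data.frame(sample = samples, code = codes)
}

#' Read a WFDB-format record
#'
#' Reads one channel of a WFDB record (`.hea` header, `.dat` signal in
#' format 212 or 16) and its beat annotations (`.atr`, MIT format).
#' Annotation codes that do not denote beats (rhythm changes, signal
#' quality, comments) are dropped; the remaining codes are mapped to the
#' single-letter beat symbols `N L R A V a J S F W e j E P f Q`.
#' Signal values are returned in physical units,
#' `(adc - baseline) / gain`.
#'
#' @param path record path without extension (e.g. `"mitdb/100"`).
#' @param channel 0-based channel index; channel 0 corresponds to the
#'   first signal (MLII for most MIT-BIH records), channel 1 to the
#'   second (usually a V lead).
#' @return list with elements `signal` (numeric vector), `fs` (sampling
#'   frequency, Hz), and `annotations` (data.frame with 0-based
#'   `sample` index and beat `symbol`), ordered by sample index.
#' @export
readWfdbRecord <- function(path, channel = 0) {
  hea <- paste0(path, ".hea")
  atr <- paste0(path, ".atr")
  if (!file.exists(hea)) {
    stop(sprintf("header file not found: %s", hea))
  }
  if (!file.exists(atr)) {
    stop(sprintf("annotation file not found: %s", atr))
  }
  hdr <- parseHeader(hea)
  if (channel < 0 || channel >= hdr$nsig) {
    stop(sprintf(
      "channel %d out of range; record has %d signal(s)",
      channel, hdr$nsig
    ))
  }
  sig <- hdr$signals[[channel + 1]]
  datPath <- file.path(dirname(hea), sig$file)
  mat <- switch(as.character(sig$format),
    "212" = readDat212(datPath, hdr$nsig, hdr$nsamp),
    "16" = readDat16(datPath, hdr$nsig),
    stop(sprintf("unsupported WFDB signal format: %d", sig$format))
  )
  adc <- mat[, channel + 1]
  ann <- readAtr(atr)
  isBeat <- as.character(ann$code) %in% names(.wfdbBeatCodes)
  ann <- ann[isBeat, , drop = FALSE]
  ann <- ann[order(ann$sample), , drop = FALSE]
  list(
    signal = (adc - sig$baseline) / sig$gain,
    fs = hdr$fs,
    annotations = data.frame(
      sample = ann$sample,
      symbol = unname(.wfdbBeatCodes[as.character(ann$code)]),
      stringsAsFactors = FALSE
    )
  )
}

#' Write a WFDB-format record
#'
#' Writes a single-channel record in WFDB format 16 with MIT-format
#' beat annotations. Mainly intended for building small test fixtures
#' and for exporting synthetic data to WFDB consumers; round-trips with
#' [readWfdbRecord()].
#'
#' @param path record path without extension.
#' @param signal numeric vector in physical units.
#' @param fs sampling frequency in Hz.
#' @param annotations data.frame with 0-based `sample` and `symbol`
#'   columns; symbols must belong to the 16-letter beat alphabet.
#' @param gain ADC units per physical unit (default 200).
#' @return the record path, invisibly.
#' @export
writeWfdbRecord <- function(path, signal, fs, annotations, gain = 200) {
  name <- basename(path)
  adc <- as.integer(round(signal * gain))
  if (any(abs(adc) > 32767)) {
    stop("signal exceeds 16-bit ADC range at the chosen gain")
  }
  writeLines(
    c(
      sprintf("%s 1 %g %d", name, fs, length(adc)),
      sprintf("%s.dat 16 %d 16 0 %d 0 0 ch0", name, as.integer(gain), adc[1])
    ),
    paste0(path, ".hea")
  )
  writeBin(adc, paste0(path, ".dat"), size = 2, endian = "little")
  symToCode <- stats::setNames(
    as.integer(names(.wfdbBeatCodes)), .wfdbBeatCodes
  )
  codes <- symToCode[annotations$symbol]
  if (anyNA(codes)) {
    stop("annotation symbols must belong to the beat alphabet")
  }
  ord <- order(annotations$sample)
  samp <- as.integer(annotations$sample)[ord]
  codes <- codes[ord]
  bytes <- integer(0)
  t <- 0
  for (i in seq_along(samp)) {
    dt <- samp[i] - t
    if (dt > 1023) { # emit SKIP with a 4-byte interval, then zero-delta
      w <- 59 * 1024
      hi <- dt %/% 65536
      lo <- dt %% 65536
      bytes <- c(
        bytes, w %% 256, w %/% 256,
        hi %% 256, hi %/% 256, lo %% 256, lo %/% 256
      )
      dt <- 0
    }
    w <- codes[i] * 1024 + dt
    bytes <- c(bytes, w %% 256, w %/% 256)
    t <- samp[i]
  }
  bytes <- c(bytes, 0, 0)
  writeBin(as.raw(bytes), paste0(path, ".atr"))
  invisible(path)
}

# ---- beat segmentation ----------------------------------------------

#' Segment beats around annotated R peaks
#'
#' Extracts one fixed-length segment per annotation: `pre` samples
#' before the R peak, the peak itself, and `post` samples after, for a
#' total of `pre + 1 + post` samples (235 with the defaults).
#' Annotations too close to either end of the signal for a full window
#' are dropped; dropping is the contract, not an error.
#'
#' @param signal numeric vector.
#' @param annotations data.frame with 0-based `sample` and `symbol`
#'   columns, sorted by sample.
#' @param pre samples before the R peak (default 90).
#' @param post samples after the R peak (default 144).
#' @param recordId identifier stored with the beats.
#' @return A [BeatSet-class] with one row per kept annotation.
#' @export
segmentBeats <- function(signal, annotations, pre = 90, post = 144,
                         recordId = "record") {
  stopifnot(pre >= 0, post >= 0)
  r <- annotations$sample
  keep <- r >= pre & (r + post) < length(signal)
  r <- r[keep]
  sym <- annotations$symbol[keep]
  if (length(r) == 0) {
    return(BeatSet(matrix(numeric(0), 0, pre + 1 + post), character(0)))
  }
  idx <- outer(r - pre, 0:(pre + post), "+") + 1 # to 1-based
  m <- matrix(signal[idx], nrow = length(r))
  BeatSet(m, sym, recordId = recordId, rIndex = as.integer(r))
}

# ---- delimited beat tables ------------------------------------------

#' Write beats to a delimited text table
#'
#' One row per beat: the label first, then the waveform samples, comma
#' separated, full double precision. The layout round-trips exactly
#' through [readBeatTable()].
#'
#' @param beats a [BeatSet-class].
#' @param path output file path.
#' @param header write a header line (default TRUE).
#' @return `path`, invisibly.
#' @export
writeBeatTable <- function(beats, path, header = TRUE) {
  m <- beats@samples
  lines <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(beats@labels[i], formatC(m[i, ], digits = 17, format = "g")),
      collapse = ","
    )
  }, character(1))
  if (header) {
    lines <- c(
      paste(c("label", paste0("s", seq_len(ncol(m)))), collapse = ","),
      lines
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read beats from a delimited text table
#'
#' Expects the layout written by [writeBeatTable()]: one row per beat,
#' label first, then samples. A header line is detected automatically
#' (first field `"label"`). Ragged rows are an error naming the first
#' offending row.
#'
#' @param path input file path.
#' @param expectedLength if given, rows whose sample count differs are
#'   an error.
#' @return A [BeatSet-class].
#' @export
readBeatTable <- function(path, expectedLength = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    len <- if (is.null(expectedLength)) 0 else expectedLength
    return(BeatSet(matrix(numeric(0), 0, len), character(0)))
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  if (identical(fields[[1]][1], "label")) {
    fields <- fields[-1]
  }
  if (length(fields) == 0) {
    len <- if (is.null(expectedLength)) 0 else expectedLength
    return(BeatSet(matrix(numeric(0), 0, len), character(0)))
  }
  lens <- lengths(fields) - 1
  want <- if (is.null(expectedLength)) lens[1] else expectedLength
  bad <- which(lens != want)
  if (length(bad) > 0) {
    stop(sprintf(
      "row %d has %d samples; expected %d", bad[1], lens[bad[1]], want
    ))
  }
  labels <- vapply(fields, `[`, character(1), 1)
  m <- do.call(rbind, lapply(fields, function(f) as.numeric(f[-1])))
  BeatSet(m, labels)
}
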