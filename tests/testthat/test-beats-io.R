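# WFDB record I/O, beat segmentation, AAMI grouping, beat tables.

makeWfdbFixture <- function(dir = tempfile("wfdb")) {
  dir.create(dir)
  path <- file.path(dir, "rec1")
  sig <- 0.5 * sin(2 * pi * (0:999) / 120)
  ann <- data.frame(
    sample = c(150, 480, 810),
    symbol = c("N", "V", "L")
  )
  writeWfdbRecord(path, sig, 360, ann)
  list(path = path, sig = sig, ann = ann)
}

test_that("a WFDB fixture with three annotated beats round-trips", {
  fx <- makeWfdbFixture()
  rec <- readWfdbRecord(fx$path, channel = 0)
  expect_equal(rec$fs, 360)
  expect_equal(nrow(rec$annotations), 3)
  expect_equal(rec$annotations$sample, fx$ann$sample)
  expect_equal(rec$annotations$symbol, fx$ann$symbol)
  # physical values recovered up to ADC quantisation (gain 200)
  expect_lt(max(abs(rec$signal - fx$sig)), 1 / 200)
  # annotation indices are non-decreasing
  expect_true(all(diff(rec$annotations$sample) >= 0))
})

test_that("long annotation gaps survive the SKIP encoding", {
  dir <- tempfile("wfdb")
  dir.create(dir)
  path <- file.path(dir, "rec2")
  sig <- rnorm(10000) * 0.1
  ann <- data.frame(sample = c(100, 5000, 9800), symbol = c("N", "N", "A"))
  writeWfdbRecord(path, sig, 360, ann)
  rec <- readWfdbRecord(path, channel = 0)
  expect_equal(rec$annotations$sample, ann$sample)
  expect_equal(rec$annotations$symbol, ann$symbol)
})

test_that("missing files and bad channels are reported", {
  fx <- makeWfdbFixture()
  expect_error(readWfdbRecord(fx$path, channel = 1), "out of range")
  expect_error(readWfdbRecord(file.path(tempdir(), "nope"), 0), "not found")
  file.remove(paste0(fx$path, ".atr"))
  expect_error(readWfdbRecord(fx$path, 0), "annotation")
})

test_that("segmentation drops annotations violating the window rule", {
  sig <- rnorm(1000)
  ann <- data.frame(
    sample = c(50, 100, 500, 950),
    symbol = c("N", "N", "V", "N")
  )
  beats <- segmentBeats(sig, ann)
  # 50 < pre (90) is dropped; 950 + 144 >= 1000 is dropped
  expect_equal(nrow(beatMatrix(beats)), 2)
  expect_equal(rIndex(beats), c(100L, 500L))
  expect_equal(ncol(beatMatrix(beats)), 235)
  # window content: [r - 90, r + 144] inclusive
  expect_equal(beatMatrix(beats)[1, ], sig[(100 - 90 + 1):(100 + 144 + 1)])
})

test_that("segmentation agrees with a per-annotation brute-force check", {
  set.seed(12)
  sig <- rnorm(3000)
  ann <- data.frame(
    sample = sort(sample(0:2999, 40)),
    symbol = sample(c("N", "V", "L"), 40, replace = TRUE)
  )
  beats <- segmentBeats(sig, ann, pre = 90, post = 144)
  keepExpected <- ann$sample >= 90 & ann$sample + 144 < 3000
  expect_equal(nrow(beatMatrix(beats)), sum(keepExpected))
  expect_equal(rIndex(beats), as.integer(ann$sample[keepExpected]))
})

test_that("AAMI grouping matches the five-class taxonomy", {
  expect_equal(mapToAami("V"), "VentricularEctopic")
  expect_equal(mapToAami("P"), "Unknown")
  expect_equal(mapToAami("F"), "Fusion")
  expect_equal(mapToAami(c("N", "j")), rep("NonEctopic", 2))
  # total on the 15 AAMI symbols, partition sizes 5, 4, 2, 1, 3
  syms <- c(
    "N", "L", "R", "e", "j", "a", "A", "S", "J", "E", "V",
    "F", "Q", "P", "f"
  )
  grp <- mapToAami(syms)
  expect_equal(
    sort(unname(table(grp)), decreasing = TRUE),
    c(5, 4, 3, 2, 1),
    ignore_attr = TRUE
  )
  # ventricular flutter waves are not covered by the taxonomy
  expect_error(mapToAami("W"), "valid symbols")
  expect_error(mapToAami("x"), "valid symbols")
})

test_that("beat tables round-trip exactly and reject ragged rows", {
  beats <- simulateBeats(defaultBeatSpecs(), rep(5, 4), seed = 10)
  tf <- tempfile(fileext = ".csv")
  writeBeatTable(beats, tf)
  back <- readBeatTable(tf)
  expect_equal(beatMatrix(back), beatMatrix(beats), ignore_attr = TRUE)
  expect_equal(beatLabels(back), beatLabels(beats))

  # empty file -> empty set
  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_equal(nrow(beatMatrix(readBeatTable(empty))), 0)

  # a truncated row is an error naming the row
  lines <- readLines(tf)
  lines[3] <- sub(",[^,]*$", "", lines[3])
  writeLines(lines, tf)
  expect_error(readBeatTable(tf), "row 2")
  expect_error(
    {
      ok <- tempfile(fileext = ".csv")
      writeBeatTable(beats, ok)
      readBeatTable(ok, expectedLength = 234)
    },
    "expected 234"
  )
})
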