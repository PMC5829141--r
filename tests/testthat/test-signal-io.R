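test_that("CSV continuous recordings round-trip bit-identically", {
  fs <- 1000
  trace <- genPinkNoise(10 * fs, fs, scale = 25, seed = 41)
  path <- withr::local_tempfile(fileext = ".csv")
  writeContinuousCSV(trace, fs, path)
  rec <- readContinuous(path)
  expect_identical(rec$trace, trace)
  expect_equal(rec$fs, fs, tolerance = 1e-9)
})

test_that("CSV reader rejects broken time axes with a located error", {
  path <- withr::local_tempfile(fileext = ".csv")
  tt <- (0:99) / 1000
  x <- sin(tt)
  writeLines(c("time_s,voltage_uV",
               paste(sample(tt), x, sep = ",")), path)
  expect_error(readContinuous(path), "not strictly increasing")
  tt2 <- tt; tt2[51] <- tt2[51] + 5e-4   # 50% step glitch
  writeLines(c("time_s,voltage_uV", paste(tt2, x, sep = ",")), path)
  expect_error(readContinuous(path), "non-uniform")
  writeLines(c("t,v", paste(tt, x, sep = ",")), path)
  expect_error(readContinuous(path), "header")
})

test_that("EDF reader decodes a hand-constructed file and echoes header fs", {
  ## build a 2-record, fs = 1000 Hz EDF byte-by-byte, independent of writeEDF
  pad <- function(x, w) formatC(as.character(x), width = -w, flag = "-")
  hdr <- paste0(pad("0", 8), pad("p", 80), pad("r", 80), pad("01.01.26", 8),
                pad("00.00.00", 8), pad(512, 8), pad("", 44), pad(2, 8),
                pad(1, 8), pad(1, 4),
                pad("chan", 16), pad("tr", 80), pad("uV", 8), pad(-100, 8),
                pad(100, 8), pad(-32768, 8), pad(32767, 8), pad("", 80),
                pad(1000, 8), pad("", 32))
  dig <- as.integer(round(seq(-32768, 32767, length.out = 2000)))
  path <- withr::local_tempfile(fileext = ".edf")
  con <- file(path, "wb")
  writeBin(charToRaw(hdr), con)
  writeBin(dig, con, size = 2L, endian = "little")
  close(con)
  rec <- readContinuous(path)
  expect_equal(rec$fs, 1000)
  expected <- (dig + 32768) / 65535 * 200 - 100
  expect_equal(rec$trace, expected, tolerance = 1e-9)
})

test_that("EDF write/read round trip is exact to one digitisation step", {
  fs <- 500
  trace <- genPinkNoise(4 * fs, fs, scale = 40, seed = 42)
  path <- withr::local_tempfile(fileext = ".edf")
  writeEDF(trace, fs, path)
  rec <- readContinuous(path)
  expect_equal(rec$fs, fs)
  step <- diff(range(trace)) / 65535
  expect_lt(max(abs(rec$trace[seq_along(trace)] - trace)), step)
})

test_that("epoching slices the recording exactly (integer-indexing oracle)", {
  fs <- 1000
  trace <- genPinkNoise(700 * fs, fs, scale = 10, seed = 7)
  onsets <- seq(5, by = 5.8, length.out = 120)
  ev <- data.frame(onset_s = onsets, label = "C")
  es <- epochTrace(trace, fs, ev, span = c(-3.5, 1.1), alignLabel = "C")
  expect_equal(nTrials(es), 120L)
  expect_equal(ncol(epochData(es)), round(4.6 * fs) + 1L)
  expect_identical(epochData(es),
                   slice_oracle(trace, fs, onsets, c(-3.5, 1.1)))
  ## a second span and off-grid onsets (nearest-sample, ties earlier)
  on2 <- c(10.0004, 20.0005, 30.2503)
  ev2 <- data.frame(onset_s = on2, label = "C")
  es2 <- epochTrace(trace, fs, ev2, span = c(-3.2, 0.8))
  expect_identical(epochData(es2), slice_oracle(trace, fs, on2, c(-3.2, 0.8)))
})

test_that("epoching aligns events on the sample grid and handles edges", {
  fs <- 1000
  trace <- numeric(30 * fs)
  trace[10 * fs + 1] <- 1   # delta at exactly t = 10 s
  ev <- data.frame(onset_s = c(10, 0.2, 29.9), label = "x")
  expect_warning(
    es <- epochTrace(trace, fs, ev, span = c(-0.5, 1.0),
                     stimulus = "click_train"),
    "2 event\\(s\\)")
  expect_equal(nTrials(es), 1L)
  expect_equal(which.max(epochData(es)[1, ]), round(0.5 * fs) + 1L)
  ## zero trace, 3 clean events -> all-zero epochs
  ev3 <- data.frame(onset_s = c(5, 10, 15), label = "x")
  es3 <- epochTrace(numeric(30 * fs), fs, ev3, span = c(-0.5, 1.0),
                    stimulus = "click_train")
  expect_equal(nTrials(es3), 3L)
  expect_true(all(epochData(es3) == 0))
})

test_that("band-pass keeps in-band tones, rejects out-of-band, and is linear", {
  fs <- 2000
  t <- (0:(10 * fs - 1)) / fs
  mid <- (4 * fs):(6 * fs)
  x40 <- sin(2 * pi * 40 * t)
  y40 <- bandpass(x40, fs, 1, 300)
  expect_equal(sd(y40[mid]) / sd(x40[mid]), 1, tolerance = 0.01)
  x500 <- sin(2 * pi * 500 * t)
  y500 <- bandpass(x500, fs, 1, 300)
  atten_db <- 20 * log10(sd(y500[mid]) / sd(x500[mid]))
  expect_lt(atten_db, -20)
  expect_equal(bandpass(numeric(1000), fs, 1, 300), numeric(1000))
  ## linearity
  a <- genPinkNoise(5000, fs, 1, seed = 1)
  b <- genPinkNoise(5000, fs, 1, seed = 2)
  ## filtfilt estimates edge initial conditions from the data, so
  ## linearity holds to a small edge-transient tolerance, not to eps
  expect_equal(bandpass(3 * a - 2 * b, fs, 1, 300),
               3 * bandpass(a, fs, 1, 300) - 2 * bandpass(b, fs, 1, 300),
               tolerance = 1e-4)
  expect_error(bandpass(a, fs, 1, 1200), "Nyquist")
})

test_that("epoch containers round-trip bit-exactly and police their schema", {
  es <- genPairEpochs(presetPairParams("HP", "conscious", seed = 3,
                                       tweak = list(nTrials = 120)))
  path <- withr::local_tempfile(fileext = ".epochs")
  saveEpochs(es, path)
  expect_lt(file.size(path), 10 * 1024^2)
  back <- loadEpochs(path)
  expect_identical(epochData(back), epochData(es))
  expect_identical(
    lapply(c(samplingRate, region, condition, stimulus, sessionId),
           function(f) f(back)),
    lapply(c(samplingRate, region, condition, stimulus, sessionId),
           function(f) f(es)))
  ## metadata-only change alters the file bytes
  es2 <- EpochSet(epochData(es), samplingRate(es), es@t0, region(es),
                  condition(es), stimulus(es), sessionId = "other")
  path2 <- withr::local_tempfile(fileext = ".epochs")
  saveEpochs(es2, path2)
  expect_false(identical(readBin(path, "raw", file.size(path)),
                         readBin(path2, "raw", file.size(path2))))
  ## schema version bump must be refused explicitly
  raw <- readBin(path, "raw", file.size(path))
  raw[13] <- as.raw(99)   # version int32 little-endian starts after magic
  writeBin(raw, path)
  expect_error(loadEpochs(path), "incompatible")
})

test_that("event tables validate pairing structure", {
  ev <- data.frame(onset_s = c(1, 1.5, 9, 9.5), label = c("C", "T", "C", "T"),
                   pair_id = c(1, 1, 2, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEvents(ev, path)
  expect_equal(readEvents(path), ev)
  ev_bad <- ev; ev_bad$onset_s[2] <- 1.6
  expect_error(validateEvents(ev_bad), "expected 0.5")
  ev_dec <- ev; ev_dec$onset_s[3] <- 1.2
  expect_error(validateEvents(ev_dec), "increasing")
})

test_that("a continuous synthetic session re-epochs into the same analysis", {
  p <- presetPairParams("AC", "conscious", seed = 21)
  rec <- genContinuousSession(p)
  es <- epochTrace(rec$trace, rec$fs, rec$events, span = c(-3.5, 1.1),
                   alignLabel = "C", region = "AC", condition = "conscious",
                   stimulus = "sound_pair", sessionId = "cont")
  expect_equal(nTrials(es), 120L)
  ig <- computeIG(es)
  expect_equal(ig$tc_ratio[1], 0.75, tolerance = 0.12)
  expect_equal(ig$tc_ratio[2], 0.90, tolerance = 0.12)
})
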