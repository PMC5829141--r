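make_click_set <- function(mat, fs = 1000, t0 = -0.5) {
  EpochSet(mat, fs = fs, t0 = t0, region = "AC", condition = "conscious",
           stimulus = "click_train", sessionId = "tfr-test")
}

test_that("the wavelet normalisation reads out sinusoid amplitude at any frequency", {
  fs <- 1000; n <- 1501
  t <- -0.5 + (0:(n - 1)) / fs
  freqs <- c(10, 20, 40, 60, 80)
  mid <- which.min(abs(t - 0.25))
  for (f in freqs) {
    es <- make_click_set(matrix(3 * cos(2 * pi * f * t), 1))
    m <- mtp(morletTFR(es, freqGrid = freqs))
    expect_equal(mapValues(m)[match(f, freqs), mid], 9, tolerance = 1e-3)
  }
  ## equal-amplitude 20 + 60 Hz mixture decomposes into equal band powers
  es2 <- make_click_set(matrix(cos(2 * pi * 20 * t) + cos(2 * pi * 60 * t), 1))
  m2 <- mtp(morletTFR(es2, freqGrid = freqs))
  v <- rowMeans(mapValues(m2), na.rm = TRUE)
  expect_equal(v[2] / v[4], 1, tolerance = 0.02)
  ## argmax over frequency for a pure 40-Hz tone
  es3 <- make_click_set(matrix(cos(2 * pi * 40 * t), 1))
  m3 <- mtp(morletTFR(es3, freqGrid = seq(5, 95, 5)))
  expect_equal(seq(5, 95, 5)[which.max(rowMeans(mapValues(m3), na.rm = TRUE))],
               40)
})

test_that("morletTFR agrees with a direct time-domain convolution oracle", {
  fs <- 1000
  set.seed(11)
  mat <- matrix(rnorm(2 * 1501), 2)
  es <- make_click_set(mat)
  freqs <- c(20, 40, 70)
  tf <- morletTFR(es, freqGrid = freqs)
  for (i in 1:2) for (j in seq_along(freqs)) {
    got <- tf@coeffs[i, j, ]
    ref <- direct_morlet(mat[i, ], fs, freqs[j])
    ok <- !is.na(got)
    expect_gt(sum(ok), 0)
    expect_lt(max(Mod(got[ok] - ref[ok])) / max(Mod(ref[ok])), 1e-6)
  }
})

test_that("MTP obeys its exact identities", {
  fs <- 1000; n <- 1501
  t <- -0.5 + (0:(n - 1)) / fs
  es0 <- make_click_set(matrix(0, 2, n))
  m0 <- morletTFR(es0, freqGrid = c(20, 40))
  expect_true(all(m0@coeffs[!is.na(m0@coeffs)] == 0))
  x <- genPinkNoise(n, fs, 5, seed = 4) + cos(2 * pi * 40 * t)
  es1 <- make_click_set(matrix(x, 1))
  tf1 <- morletTFR(es1, freqGrid = c(35, 40, 45))
  expect_equal(mapValues(mtp(tf1)), Mod(tf1@coeffs[1, , ])^2)
  ## quadratic scaling: doubling voltages quadruples power
  es2 <- make_click_set(2 * epochData(es1))
  expect_equal(mapValues(mtp(morletTFR(es2, freqGrid = c(35, 40, 45)))),
               4 * mapValues(mtp(tf1)), tolerance = 1e-12)
  ## multi-trial MTP equals the brute-force per-trial power mean
  mat <- t(replicate(6, genPinkNoise(n, fs, 5) + cos(2 * pi * 40 * t)))
  tf <- morletTFR(make_click_set(mat), freqGrid = c(40))
  brute <- colMeans(t(vapply(1:6, function(i) Mod(tf@coeffs[i, 1, ])^2,
                             numeric(n))))
  expect_equal(mapValues(mtp(tf))[1, ], brute)
})

test_that("PLF is bounded, amplitude-invariant, and exact in closed cases", {
  fs <- 1000; n <- 1501
  t <- -0.5 + (0:(n - 1)) / fs
  ## perfect coherence
  es <- make_click_set(matrix(rep(cos(2 * pi * 40 * t), 4), 4, byrow = TRUE))
  tf <- morletTFR(es, freqGrid = c(40))
  v <- mapValues(plf(tf))
  expect_equal(v[!is.na(v)], rep(1, sum(!is.na(v))), tolerance = 1e-9)
  ## four phasors at 0, pi/2, pi, 3pi/2 cancel exactly
  ph <- c(0, pi / 2, pi, 3 * pi / 2)
  es4 <- make_click_set(t(sapply(ph, function(a) cos(2 * pi * 40 * t + a))))
  v4 <- mapValues(plf(morletTFR(es4, freqGrid = c(40))))
  mid <- which.min(abs(epochTimes(es4) - 0.25))
  expect_lt(v4[1, mid], 1e-10)
  ## invariant under per-trial positive rescaling; always within [0, 1]
  set.seed(9)
  mat <- t(replicate(6, genPinkNoise(n, fs, 5)))
  scales <- c(0.2, 1, 3, 7, 0.5, 10)
  p1 <- mapValues(plf(morletTFR(make_click_set(mat), freqGrid = c(20, 40))))
  p2 <- mapValues(plf(morletTFR(make_click_set(mat * scales),
                                freqGrid = c(20, 40))))
  expect_equal(p1, p2, tolerance = 1e-9)
  expect_true(all(p1[!is.na(p1)] >= 0 & p1[!is.na(p1)] <= 1))
  ## single trial has no trial-to-trial phase
  expect_error(plf(morletTFR(make_click_set(mat[1, , drop = FALSE]),
                             freqGrid = c(40))), "2 trials")
  ## zero-magnitude coefficients make the phase undefined, not zero
  matz <- rbind(mat[1:2, ], 0)
  vz <- mapValues(plf(morletTFR(make_click_set(matz), freqGrid = c(40))))
  expect_true(all(is.na(vz)))
})

test_that("assrMaps matches the full coefficient route", {
  p <- presetAssrParams("HP", "conscious", seed = 13,
                        tweak = list(nTrials = 10))
  es <- genAssrEpochs(p)
  tf <- morletTFR(es, freqGrid = 38:42)
  fast <- assrMaps(es, freqGrid = 38:42)
  expect_equal(mapValues(fast$mtp), mapValues(mtp(tf)), tolerance = 1e-12)
  expect_equal(mapValues(fast$plf), mapValues(plf(tf)), tolerance = 1e-12)
})

test_that("band/window summaries average exactly the requested cells", {
  vals <- matrix(7, 3, 100)
  map <- new("SpectralMap", values = vals, kind = "MTP", freqs = c(35, 40, 45),
             times = seq(0, 0.99, 0.01), nTrials = 1L)
  expect_equal(bandWindowMean(map, c(35, 45), c(0, 0.99)), 7)
  map@values[2, 51] <- 13
  expect_equal(bandWindowMean(map, c(40, 40), c(0.5, 0.5)), 13)
  expect_error(bandWindowMean(map, c(200, 300), c(0, 1)), "intersect")
  map@values[] <- NA_real_
  expect_error(bandWindowMean(map, c(35, 45), c(0, 0.99)), "valid")
})

test_that("edge samples inside the wavelet support are flagged, not faked", {
  es <- make_click_set(matrix(rnorm(1501), 1))
  tf <- morletTFR(es, freqGrid = c(2, 40))
  ## at 2 Hz the 7-cycle support exceeds the 1.5-s epoch: all invalid
  expect_true(all(is.na(tf@coeffs[1, 1, ])))
  ## at 40 Hz: NA within half support of the edges, valid inside
  h <- ceiling(3.5 * 7 / (2 * pi * 40) * 1000)
  expect_true(all(is.na(tf@coeffs[1, 2, 1:h])))
  expect_false(anyNA(tf@coeffs[1, 2, (h + 1):(1501 - h)]))
})
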