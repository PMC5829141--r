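test_that("trial averaging obeys its exact identities and 1/sqrt(N) scaling", {
  p <- pairParams(noiseAmp = 0, nTrials = 4, seed = 1)
  es <- genPairEpochs(p)
  erp <- averageERP(es)
  expect_equal(erp$uV, epochData(es)[1, ])
  ## cancellation
  mat <- rbind(epochData(es)[1, ], -epochData(es)[1, ])
  es2 <- EpochSet(mat, 1000, -3.5, "AC", "conscious", "sound_pair", "x")
  expect_equal(averageERP(es2)$uV, numeric(ncol(mat)))
  ## residual RMS around the noise-free kernel shrinks like 1/sqrt(N)
  kern <- pairKernel(p, averageERP(es)$time)
  rms <- function(N, seeds) vapply(seeds, function(s) {
    e <- genPairEpochs(pairParams(nTrials = N, seed = s))
    sqrt(mean((averageERP(e)$uV - kern)^2))
  }, numeric(1))
  r30 <- mean(rms(30, 501:510))
  r120 <- mean(rms(120, 601:610))
  expect_equal(r30 / r120, 2, tolerance = 0.35)
})

test_that("peak detection picks the deepest matching extremum, earliest on ties", {
  tt <- seq(0, 0.2, by = 0.001)
  ## two negative lobes, depths -8 and -5
  w <- -8 * exp(-(tt - 0.05)^2 / 2e-5) - 5 * exp(-(tt - 0.12)^2 / 2e-5)
  erp <- data.frame(time = tt, uV = w)
  pk <- detectPeak(erp, "negative", c(0.01, 0.19), stimOnset = 0)
  expect_equal(pk$latency, 0.05)
  expect_equal(pk$amplitude, min(w) - w[1])
  ## equal-depth twin lobes: earliest latency wins
  w2 <- -8 * exp(-(tt - 0.05)^2 / 2e-5) - 8 * exp(-(tt - 0.12)^2 / 2e-5)
  pk2 <- detectPeak(data.frame(time = tt, uV = w2), "negative",
                    c(0.01, 0.19), 0)
  expect_equal(pk2$latency, 0.05)
  ## flat waveform: boundary-flagged zero amplitude
  pk3 <- detectPeak(data.frame(time = tt, uV = rep(2, length(tt))),
                    "negative", c(0.01, 0.19), 0)
  expect_true(pk3$boundary)
  expect_equal(pk3$amplitude, 0)
  ## monotone ramp has no interior extremum either
  pk4 <- detectPeak(data.frame(time = tt, uV = tt), "positive",
                    c(0.01, 0.19), 0)
  expect_true(pk4$boundary)
  expect_equal(pk4$latency, 0.19)
  expect_error(detectPeak(erp, "negative", c(0.3, 0.4), 0), "empty")
})

test_that("peak significance separates real peaks from the control period", {
  ## noise-free large peak: maximally significant
  es <- genPairEpochs(pairParams(noiseAmp = 0, nTrials = 12, seed = 2))
  expect_equal(peakSignificance(es, latency = 0.025), 0)
  ## amplitude at 0.1x the noise SD: not significant in >= 95% of seeds
  ns <- vapply(1:20, function(i) {
    e <- genPairEpochs(pairParams(ampN = -3, ampP = 3, seed = 9500 + i))
    peakSignificance(e, latency = 0.025) >= 0.01
  }, logical(1))
  expect_gte(sum(ns), 19)
  ## too-short control period cannot build a null ensemble
  expect_error(peakSignificance(es, 0.025, controlPeriod = c(-2.05, -2)),
               "fewer than 10")
})

test_that("computeIG reproduces generative gating exactly without noise", {
  p <- presetPairParams("AC", "conscious", seed = 1,
                        tweak = list(noiseAmp = 0, nTrials = 2))
  ig <- computeIG(genPairEpochs(p))
  expect_equal(ig$label, c("N25", "P40"))
  ## the AC N25/P40 deflections are 15 ms apart, so the +/-5 ms amplitude
  ## windows pick up ~0.5% cross-talk from the neighbouring deflection
  expect_equal(ig$tc_ratio, c(0.75, 0.90), tolerance = 0.005)
  expect_equal(ig$C_lat, c(0.025, 0.040))
  expect_true(all(ig$significant))
  ## non-AC regions use the later N35/P70 windows
  p2 <- presetPairParams("PFC", "conscious", seed = 1,
                         tweak = list(noiseAmp = 0, nTrials = 2))
  ig2 <- computeIG(genPairEpochs(p2))
  expect_equal(ig2$label, c("N35", "P70"))
  expect_equal(ig2$tc_ratio, c(0.25, 0.28), tolerance = 1e-12)
  expect_equal(ig2$C_lat, c(0.035, 0.075))
})

test_that("T/C ratios are invariant under global amplitude rescaling", {
  es <- genPairEpochs(presetPairParams("HP", "conscious", seed = 5))
  es2 <- EpochSet(epochData(es) * 3.7, samplingRate(es), es@t0, region(es),
                  condition(es), stimulus(es), sessionId(es))
  ig1 <- computeIG(es)
  ig2 <- computeIG(es2)
  expect_equal(ig2$tc_ratio, ig1$tc_ratio, tolerance = 1e-12)
  expect_equal(ig2$C_amp, 3.7 * ig1$C_amp, tolerance = 1e-12)
})

test_that("conscious gating deepens from AC through HP and AMY to PFC", {
  mean_tc <- vapply(c("AC", "HP", "AMY", "PFC"), function(reg) {
    mean(vapply(1:5, function(i) {
      ig <- computeIG(genPairEpochs(presetPairParams(reg, "conscious",
                                                     seed = 800 + i)))
      ig$tc_ratio[1]
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_tc) < 0))
})

test_that("non-significant peaks yield NA ratios, never silent zeros", {
  ## no evoked response at all: both peaks are noise, the gate must close
  es <- genPairEpochs(pairParams(ampN = 0, ampP = 0, seed = 77))
  ig <- computeIG(es)
  expect_true(all(is.na(ig$tc_ratio) | ig$significant))
  expect_false(any(stats::na.omit(ig$tc_ratio) == 0))
})
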