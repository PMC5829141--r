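#' Generate 1/f (pink) background noise
#'
#' Spectral synthesis: Fourier amplitudes proportional to `f^(-1/2)` (power
#' spectral density slope -1 on a log-log plot) with independent Gaussian
#' quadratures per bin, zero DC, scaled to a target standard deviation.
#' Emulates the broadband background of an LFP recording.
#'
#' @param n number of samples (> 0).
#' @param fs sampling rate (Hz).
#' @param scale target standard deviation of the trace (microvolts);
#'   `scale = 0` returns an all-zero trace.
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @return numeric vector of length `n`, zero mean, sd = `scale`
#' @export
genPinkNoise <- function(n, fs, scale = 1, seed = NULL) {
  if (n <= 0) stop("n must be positive")
  if (scale < 0) stop("scale must be >= 0")
  if (scale == 0) return(numeric(n))
  .with_seed(seed, {
    nf <- floor(n / 2)
    f <- (1:nf) * fs / n
    a <- f^(-0.5)
    pos <- (stats::rnorm(nf) + 1i * stats::rnorm(nf)) * a
    if (n %% 2 == 0) pos[nf] <- Re(pos[nf])       # Nyquist bin must be real
    spec <- complex(n)
    spec[2:(nf + 1)] <- pos
    spec[n:(n - nf + 2)] <- Conj(pos[1:(nf - 1)])
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    x <- x - mean(x)
    x * scale / stats::sd(x)
  })
}

#' Parameters of the synthetic 40-Hz click-train (ASSR) generator
#'
#' @param fStim entrainment frequency (Hz).
#' @param trainDur click-train duration (s).
#' @param amp entrained oscillation amplitude (microvolts, >= 0).
#' @param phaseJitterSd per-trial phase jitter (radians, >= 0); the phase of
#'   each trial's oscillation is drawn from `Normal(0, phaseJitterSd^2)`.
#' @param noiseAmp pink-noise standard deviation (microvolts).
#' @param nTrials trials per session.
#' @param fs sampling rate (Hz); must exceed `2 * fStim`.
#' @param seed optional integer seed.
#' @param region,condition,sessionId metadata for the generated set.
#' @param span epoch extent (s) around train onset.
#' @return validated parameter list of class `AssrParams`
#' @export
assrParams <- function(fStim = 40, trainDur = 0.5, amp = 20,
                       phaseJitterSd = 0.4, noiseAmp = 30, nTrials = 120,
                       fs = 1000, seed = NULL, region = "AC",
                       condition = "conscious", sessionId = "synthetic",
                       span = c(-0.5, 1.0)) {
  if (amp < 0) stop("amp must be >= 0")
  if (phaseJitterSd < 0) stop("phaseJitterSd must be >= 0")
  if (nTrials < 1) stop("nTrials must be >= 1")
  if (fs <= 2 * fStim) stop("fs must exceed 2 * fStim")
  structure(as.list(environment()), class = "AssrParams")
}

## raised-cosine on/off ramp over `ramp` seconds, gating [0, dur]
.train_envelope <- function(t, dur, ramp = 0.010) {
  env <- numeric(length(t))
  inside <- t >= 0 & t <= dur
  env[inside] <- 1
  up <- t >= 0 & t < ramp
  env[up] <- 0.5 * (1 - cos(pi * t[up] / ramp))
  down <- t > dur - ramp & t <= dur
  env[down] <- 0.5 * (1 - cos(pi * (dur - t[down]) / ramp))
  env
}

#' Generate a synthetic ASSR (click-train) EpochSet
#'
#' Each trial is pink noise plus a 10-ms-ramped sinusoid
#' `amp * cos(2 * pi * fStim * t + phi_n)` gated on during the click train
#' (`t` in `[0, trainDur]`), with per-trial phase jitter
#' `phi_n ~ Normal(0, phaseJitterSd^2)` controlling how phase-locked the
#' entrained response is across trials.
#'
#' @param p an `AssrParams` list from [assrParams()].
#' @return an [EpochSet-class] with `stimulus = "click_train"`
#' @export
genAssrEpochs <- function(p) {
  stopifnot(inherits(p, "AssrParams"))
  n <- round(diff(p$span) * p$fs) + 1L
  t <- p$span[1] + (seq_len(n) - 1L) / p$fs
  env <- .train_envelope(t, p$trainDur)
  .with_seed(p$seed, {
    dat <- matrix(0, p$nTrials, n)
    for (i in seq_len(p$nTrials)) {
      phi <- stats::rnorm(1L, 0, p$phaseJitterSd)
      dat[i, ] <- genPinkNoise(n, p$fs, p$noiseAmp) +
        p$amp * env * cos(2 * pi * p$fStim * t + phi)
    }
    EpochSet(dat, fs = p$fs, t0 = p$span[1], region = p$region,
             condition = p$condition, stimulus = "click_train",
             sessionId = p$sessionId)
  })
}

#' Parameters of the synthetic paired-pulse (gating) generator
#'
#' The evoked response to each noise burst is modelled as two
#' raised-cosine deflections: a negative one of amplitude `ampN` peaking
#' `latN` seconds after the burst onset and a positive one (`ampP`, `latP`).
#' The test-burst response is the conditioning kernel scaled by `gateN`
#' (negative deflection) and `gateP` (positive deflection); `gate = 1`
#' means no gating, smaller values mean stronger suppression.
#'
#' @param latN,latP peak latencies (s), `0 < latN < latP < isi`.
#' @param ampN,ampP signed peak amplitudes (microvolts; `ampN` negative,
#'   `ampP` positive by convention).
#' @param width deflection half-width (s): each deflection is a raised
#'   cosine with compact support `[-width, width]` around its latency, so
#'   deflections further apart than `width` do not overlap at their peaks.
#' @param gateN,gateP multiplicative test-response scaling in `[0, 1.5]`.
#' @param isi conditioning-to-test interval (s).
#' @param noiseAmp pink-noise standard deviation (microvolts).
#' @param nTrials trials per session.
#' @param fs sampling rate (Hz).
#' @param seed optional integer seed.
#' @param region,condition,sessionId metadata.
#' @param span epoch extent (s) around the conditioning onset; must cover
#'   the control period and the test response.
#' @return validated parameter list of class `PairParams`
#' @export
pairParams <- function(latN = 0.025, latP = 0.040, ampN = -60, ampP = 45,
                       width = 0.012, gateN = 0.75, gateP = 0.90, isi = 0.5,
                       noiseAmp = 30, nTrials = 120, fs = 1000, seed = NULL,
                       region = "AC", condition = "conscious",
                       sessionId = "synthetic", span = c(-3.5, 1.1)) {
  if (gateN < 0 || gateN > 1.5 || gateP < 0 || gateP > 1.5)
    stop("gateN and gateP must lie in [0, 1.5]")
  if (!(0 < latN && latN < latP && latP < isi))
    stop("latencies must satisfy 0 < latN < latP < isi")
  if (nTrials < 1) stop("nTrials must be >= 1")
  if (span[1] > -3 || span[2] < isi + 0.2)
    stop("span must cover the control period and the test response")
  structure(as.list(environment()), class = "PairParams")
}

## compact raised-cosine deflection, unit peak, support [-w, w]
.bump <- function(t, w) {
  out <- numeric(length(t))
  inside <- abs(t) < w
  out[inside] <- 0.5 * (1 + cos(pi * t[inside] / w))
  out
}

#' Noise-free evoked kernel of a paired-pulse trial
#'
#' @param p a `PairParams` list.
#' @param t time points (s relative to conditioning onset).
#' @return numeric vector: conditioning plus gate-scaled test response
#' @export
pairKernel <- function(p, t) {
  p$ampN * .bump(t - p$latN, p$width) + p$ampP * .bump(t - p$latP, p$width) +
    p$gateN * p$ampN * .bump(t - p$isi - p$latN, p$width) +
    p$gateP * p$ampP * .bump(t - p$isi - p$latP, p$width)
}

#' Generate a synthetic paired-pulse (sound-pair) EpochSet
#'
#' Each trial is pink noise plus the deterministic evoked kernel of
#' [pairKernel()]: conditioning deflections at `latN`/`latP` and
#' gate-scaled test deflections `isi` seconds later.
#'
#' @param p a `PairParams` list from [pairParams()].
#' @return an [EpochSet-class] with `stimulus = "sound_pair"`
#' @export
genPairEpochs <- function(p) {
  stopifnot(inherits(p, "PairParams"))
  n <- round(diff(p$span) * p$fs) + 1L
  t <- p$span[1] + (seq_len(n) - 1L) / p$fs
  kern <- pairKernel(p, t)
  .with_seed(p$seed, {
    dat <- matrix(0, p$nTrials, n)
    for (i in seq_len(p$nTrials))
      dat[i, ] <- genPinkNoise(n, p$fs, p$noiseAmp) + kern
    EpochSet(dat, fs = p$fs, t0 = p$span[1], region = p$region,
             condition = p$condition, stimulus = "sound_pair",
             sessionId = p$sessionId)
  })
}

#' Region x condition generator presets
#'
#' One row per recording-site x condition cell (8 in total). Peak latencies
#' follow the nominal evoked deflections (AC: N25/P40; HP/AMY/PFC: negative
#' 39/37/35 ms, positive 65/65/75 ms), the gating factors are the
#' representative T/C ratios for each cell, and the ASSR amplitudes are
#' ordered AC > HP > AMY > PFC = 0, with anesthesia scaling the entrained
#' amplitude by 0.4 and doubling the phase jitter.
#'
#' @param path preset table; defaults to the TSV shipped with the package,
#'   which users may copy and override.
#' @return data.frame with one row per region x condition
#' @export
regionPresets <- function(path = system.file("extdata", "presets.tsv",
                                             package = "assrgating")) {
  pr <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region", "condition", "latN", "latP", "ampN", "ampP", "width",
            "gateN", "gateP", "isi", "noiseAmp", "nTrials", "fs", "assrAmp",
            "assrPhaseJitterSd", "assrNoiseAmp", "fStim", "trainDur")
  miss <- setdiff(need, names(pr))
  if (length(miss)) stop("preset table lacks column(s): ",
                         paste(miss, collapse = ", "))
  cells <- interaction(pr$region, pr$condition)
  if (length(unique(cells)) != nrow(pr)) stop("duplicate preset rows")
  for (r in .REGIONS) for (co in .CONDITIONS)
    if (!any(pr$region == r & pr$condition == co))
      stop("preset table lacks the ", r, " / ", co, " cell")
  pr
}

.preset_row <- function(region, condition, presets) {
  if (!region %in% .REGIONS)
    stop("unknown region '", region, "'; valid: ",
         paste(.REGIONS, collapse = ", "))
  if (!condition %in% .CONDITIONS)
    stop("unknown condition '", condition, "'; valid: ",
         paste(.CONDITIONS, collapse = ", "))
  presets[presets$region == region & presets$condition == condition, ]
}

#' Paired-pulse parameters for a preset cell
#'
#' @param region,condition preset cell.
#' @param seed optional integer seed.
#' @param presets preset table (see [regionPresets()]).
#' @param tweak named list of `PairParams` fields overriding the preset
#'   (used e.g. to add between-session variability in cohort simulations).
#' @param sessionId session label.
#' @return a `PairParams` list
#' @export
presetPairParams <- function(region, condition, seed = NULL,
                             presets = regionPresets(), tweak = list(),
                             sessionId = sprintf("%s_%s", region, condition)) {
  row <- .preset_row(region, condition, presets)
  args <- list(latN = row$latN, latP = row$latP, ampN = row$ampN,
               ampP = row$ampP, width = row$width, gateN = row$gateN,
               gateP = row$gateP, isi = row$isi, noiseAmp = row$noiseAmp,
               nTrials = row$nTrials, fs = row$fs, seed = seed,
               region = region, condition = condition, sessionId = sessionId)
  args[names(tweak)] <- tweak
  do.call(pairParams, args)
}

#' Click-train parameters for a preset cell
#'
#' @inheritParams presetPairParams
#' @return an `AssrParams` list
#' @export
presetAssrParams <- function(region, condition, seed = NULL,
                             presets = regionPresets(), tweak = list(),
                             sessionId = sprintf("%s_%s", region, condition)) {
  row <- .preset_row(region, condition, presets)
  args <- list(fStim = row$fStim, trainDur = row$trainDur, amp = row$assrAmp,
               phaseJitterSd = row$assrPhaseJitterSd,
               noiseAmp = row$assrNoiseAmp, nTrials = row$nTrials,
               fs = row$fs, seed = seed, region = region,
               condition = condition, sessionId = sessionId)
  args[names(tweak)] <- tweak
  do.call(assrParams, args)
}

#' Simulate one recording session (click trains + sound pairs)
#'
#' Mirrors one experimental session: an ASSR run of 120 click trains
#' followed by 120 sound pairs, both generated from the preset of the
#' requested region x condition cell. Deterministic for a fixed seed.
#'
#' @param region,condition preset cell; unknown values raise an error
#'   listing the valid ones.
#' @param seed integer seed; the click and pair sets use derived sub-seeds.
#' @param presets preset table.
#' @param tweakPair,tweakAssr named lists overriding preset fields.
#' @param sessionId session label carried by both sets.
#' @return list with elements `click` and `pair` ([EpochSet-class]s)
#' @export
makeSession <- function(region, condition, seed = 1L,
                        presets = regionPresets(),
                        tweakPair = list(), tweakAssr = list(),
                        sessionId = sprintf("%s_%s_s%03d", region, condition,
                                            seed %% 1000L)) {
  ap <- presetAssrParams(region, condition, seed = seed, presets = presets,
                         tweak = tweakAssr, sessionId = sessionId)
  pp <- presetPairParams(region, condition, seed = seed + 700000L,
                         presets = presets, tweak = tweakPair,
                         sessionId = sessionId)
  list(click = genAssrEpochs(ap), pair = genPairEpochs(pp))
}

#' Emit a session as a continuous recording plus an event sidecar
#'
#' Builds an uncut voltage trace with stimuli laid out at realistic
#' inter-trial intervals (click trains 2-4 s apart, sound pairs 8-10 s
#' apart, drawn uniformly) over a single pink-noise background, together
#' with the event table needed to re-epoch it with [epochTrace()].
#'
#' @param p an `AssrParams` or `PairParams` list.
#' @param seed optional integer seed (defaults to `p$seed`).
#' @return list with `trace` (microvolts), `fs` (Hz) and `events`
#'   (data.frame with `onset_s`, `label` and, for pairs, `pair_id`)
#' @export
genContinuousSession <- function(p, seed = p$seed) {
  .with_seed(seed, {
    if (inherits(p, "PairParams")) {
      gaps <- stats::runif(p$nTrials - 1L, 8, 10)
      onsets <- 5 + c(0, cumsum(gaps))
      total <- ceiling((onsets[p$nTrials] + 3) * p$fs)
      t <- (seq_len(total) - 1L) / p$fs
      trace <- genPinkNoise(total, p$fs, p$noiseAmp)
      for (on in onsets) trace <- trace + pairKernel(p, t - on)
      ev <- data.frame(
        onset_s = as.vector(rbind(onsets, onsets + p$isi)),
        label = rep(c("C", "T"), p$nTrials),
        pair_id = rep(seq_len(p$nTrials), each = 2L))
      list(trace = trace, fs = p$fs, events = ev)
    } else if (inherits(p, "AssrParams")) {
      gaps <- stats::runif(p$nTrials - 1L, 2, 4)
      onsets <- 2 + c(0, cumsum(gaps))
      total <- ceiling((onsets[p$nTrials] + 2) * p$fs)
      t <- (seq_len(total) - 1L) / p$fs
      trace <- genPinkNoise(total, p$fs, p$noiseAmp)
      for (on in onsets) {
        phi <- stats::rnorm(1L, 0, p$phaseJitterSd)
        trace <- trace + p$amp * .train_envelope(t - on, p$trainDur) *
          cos(2 * pi * p$fStim * (t - on) + phi)
      }
      ev <- data.frame(onset_s = onsets, label = "click_train")
      list(trace = trace, fs = p$fs, events = ev)
    } else stop("p must be AssrParams or PairParams")
  })
}
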