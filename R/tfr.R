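## Complex Morlet machinery shared by morletTFR() and assrMaps().
##
## The wavelet at frequency f is a complex exponential under a Gaussian
## envelope with sigma_t = nCycles / (2 pi f), normalised so that a
## unit-amplitude sinusoid at f yields |W| = 1 regardless of f (the
## coefficient magnitude reads out instantaneous amplitude in the input
## units). Convolution is done in the frequency domain; samples within
## half the wavelet support (3.5 sigma_t) of either epoch edge are flagged
## NA instead of being contaminated by the zero padding.
.morlet_plan <- function(freqs, fs, n, nCycles) {
  N <- stats::nextn(n + 1L)
  nf <- length(freqs)
  K <- matrix(0 + 0i, N, nf)
  half <- integer(nf)
  ok <- logical(nf)
  for (j in seq_len(nf)) {
    sigma <- nCycles / (2 * pi * freqs[j]) * fs     # samples
    h <- as.integer(ceiling(3.5 * sigma))
    half[j] <- h
    if (2L * h + 1L > min(n, N)) next               # support exceeds epoch
    ok[j] <- TRUE
    k <- -h:h
    g <- exp(-k^2 / (2 * sigma^2))
    w <- (2 / sum(g)) * g * exp(2i * pi * freqs[j] * k / fs)
    kern <- complex(N)
    kern[(k %% N) + 1L] <- w
    K[, j] <- stats::fft(kern)
  }
  list(N = N, K = K, half = half, ok = ok)
}

## coefficients of one trial: n x nf complex matrix (time in rows)
.morlet_trial <- function(x, plan) {
  X <- stats::fft(c(x, numeric(plan$N - length(x))))
  W <- stats::mvfft(plan$K * X, inverse = TRUE) / plan$N
  W[seq_along(x), , drop = FALSE]
}

.edge_na_idx <- function(n, h) c(seq_len(min(h, n)), seq.int(max(n - h + 1L, 1L), n))

#' Complex Morlet time-frequency decomposition
#'
#' Convolves every trial with L2-symmetric complex Morlet wavelets
#' (constant cycle count across frequencies) and returns the per-trial
#' complex coefficients. The wavelet is normalised so a unit-amplitude
#' sinusoid at frequency `f` gives `|W| = 1` at every `f`; squared
#' magnitudes are therefore power in amplitude-squared units. Edge samples
#' within half the wavelet support (3.5 temporal sigmas) of either epoch
#' boundary are `NA`; frequencies whose full support exceeds the epoch are
#' entirely `NA`.
#'
#' @param epochs an [EpochSet-class].
#' @param freqGrid strictly increasing frequencies (Hz), all below Nyquist.
#' @param nCycles Morlet cycles (default 7: ~11 ms temporal and ~6 Hz
#'   spectral resolution at 40 Hz).
#' @return a [TFRSet-class] (`trial x frequency x time`)
#' @export
morletTFR <- function(epochs, freqGrid = 1:100, nCycles = 7) {
  stopifnot(is(epochs, "EpochSet"))
  fs <- epochs@fs
  if (max(freqGrid) >= fs / 2)
    stop("freqGrid exceeds the Nyquist frequency ", fs / 2, " Hz")
  if (is.unsorted(freqGrid, strictly = TRUE))
    stop("freqGrid must be strictly increasing")
  x <- epochs@data
  n <- ncol(x); nt <- nrow(x); nf <- length(freqGrid)
  plan <- .morlet_plan(freqGrid, fs, n, nCycles)
  co <- array(NA_complex_, c(nt, nf, n))
  for (i in seq_len(nt)) co[i, , ] <- t(.morlet_trial(x[i, ], plan))
  for (j in seq_len(nf)) {
    if (!plan$ok[j]) { co[, j, ] <- NA_complex_; next }
    co[, j, .edge_na_idx(n, plan$half[j])] <- NA_complex_
  }
  new("TFRSet", coeffs = co, freqs = as.numeric(freqGrid),
      times = epochTimes(epochs), fs = fs,
      meta = list(region = epochs@region, condition = epochs@condition,
                  stimulus = epochs@stimulus, sessionId = epochs@sessionId))
}

.map_meta_from_tfr <- function(x, values, kind) {
  new("SpectralMap", values = values, kind = kind, freqs = x@freqs,
      times = x@times, nTrials = as.integer(dim(x@coeffs)[1]))
}

#' @rdname mtp
#' @export
setMethod("mtp", "TFRSet", function(x) {
  vals <- colMeans(Mod(x@coeffs)^2, dims = 1)
  .map_meta_from_tfr(x, vals, "MTP")
})

#' @rdname plf
#' @export
setMethod("plf", "TFRSet", function(x) {
  nt <- dim(x@coeffs)[1]
  if (nt < 2L) stop("PLF is undefined for fewer than 2 trials")
  m <- Mod(x@coeffs)
  zero <- !is.na(m) & m == 0
  ph <- x@coeffs / m
  ph[zero] <- NA_complex_
  vals <- Mod(colMeans(ph, dims = 1))
  vals[colSums(zero, dims = 1) > 0] <- NA_real_   # undefined phase in a trial
  .map_meta_from_tfr(x, pmin(vals, 1), "PLF")
})

#' Memory-light MTP and PLF of an EpochSet
#'
#' Computes the mean-trial-power and phase-locking-factor maps by
#' accumulating over trials without materialising the full per-trial
#' coefficient array; identical to `mtp(morletTFR(...))` and
#' `plf(morletTFR(...))`.
#'
#' @inheritParams morletTFR
#' @return list with elements `mtp` and `plf` ([SpectralMap-class]s)
#' @export
assrMaps <- function(epochs, freqGrid = 1:100, nCycles = 7) {
  stopifnot(is(epochs, "EpochSet"))
  fs <- epochs@fs
  if (max(freqGrid) >= fs / 2)
    stop("freqGrid exceeds the Nyquist frequency ", fs / 2, " Hz")
  x <- epochs@data
  n <- ncol(x); nt <- nrow(x); nf <- length(freqGrid)
  plan <- .morlet_plan(freqGrid, fs, n, nCycles)
  sumP <- matrix(0, nf, n)
  sumPh <- matrix(0 + 0i, nf, n)
  anyZero <- matrix(FALSE, nf, n)
  for (i in seq_len(nt)) {
    W <- t(.morlet_trial(x[i, ], plan))            # nf x n
    m <- Mod(W)
    anyZero <- anyZero | (m == 0)
    sumP <- sumP + m^2
    sumPh <- sumPh + ifelse(m == 0, 0 + 0i, W / m)
  }
  mtpv <- sumP / nt
  plfv <- Mod(sumPh / nt)
  plfv[anyZero] <- NA_real_
  for (j in seq_len(nf)) {
    idx <- if (plan$ok[j]) .edge_na_idx(n, plan$half[j]) else seq_len(n)
    mtpv[j, idx] <- NA_real_
    plfv[j, idx] <- NA_real_
  }
  tt <- epochTimes(epochs)
  list(
    mtp = new("SpectralMap", values = mtpv, kind = "MTP",
              freqs = as.numeric(freqGrid), times = tt,
              nTrials = as.integer(nt)),
    plf = if (nt >= 2L)
      new("SpectralMap", values = pmin(plfv, 1), kind = "PLF",
          freqs = as.numeric(freqGrid), times = tt,
          nTrials = as.integer(nt)) else NULL)
}

#' Band x window summary of a spectral map
#'
#' Arithmetic mean over all valid (non-`NA`) grid cells inside the closed
#' `band x window` rectangle; the canonical ASSR summary is the 35-45 Hz x
#' 50-550 ms mean.
#'
#' @param map a [SpectralMap-class].
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param window `c(t_lo, t_hi)` in s.
#' @return scalar mean
#' @export
bandWindowMean <- function(map, band = c(35, 45), window = c(0.05, 0.55)) {
  fi <- which(.in_closed(map@freqs, band[1], band[2]))
  ti <- which(.in_closed(map@times, window[1], window[2]))
  if (!length(fi) || !length(ti))
    stop("band x window does not intersect the map grid")
  v <- map@values[fi, ti]
  if (all(is.na(v)))
    stop("band x window contains no valid (non-edge) cells")
  mean(v, na.rm = TRUE)
}

#' Express an MTP map in dB relative to a pre-stimulus baseline
#'
#' Visualization aid: divides each frequency row by its mean over the
#' baseline interval and takes `10 * log10`. The quantitative summaries in
#' this package operate on raw power; no baseline normalisation is applied
#' anywhere else.
#'
#' @param map an MTP [SpectralMap-class].
#' @param baseline pre-stimulus interval (s).
#' @return list with `values` (dB matrix), `freqs`, `times`
#' @export
baselineNormalize <- function(map, baseline = c(-0.4, -0.1)) {
  stopifnot(map@kind == "MTP")
  ti <- which(.in_closed(map@times, baseline[1], baseline[2]))
  if (!length(ti)) stop("baseline interval outside the map")
  ref <- rowMeans(map@values[, ti, drop = FALSE], na.rm = TRUE)
  list(values = 10 * log10(sweep(map@values, 1, ref, "/")),
       freqs = map@freqs, times = map@times)
}
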