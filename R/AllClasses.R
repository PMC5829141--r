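#' @import methods
NULL

.REGIONS    <- c("AC", "HP", "AMY", "PFC")
.CONDITIONS <- c("conscious", "anesthetized")
.STIMULI    <- c("click_train", "sound_pair")

## Minimum epoch coverage (s, relative to the aligning stimulus onset) each
## stimulus type must provide so that downstream summaries are computable:
## sound pairs need the 1-s control period ending 2 s before C plus the test
## response, click trains need the full train and its wavelet neighbourhood.
.REQUIRED_SPAN <- list(
  sound_pair  = c(-3.0, 0.7),
  click_train = c(-0.5, 1.0)
)

#' EpochSet: aligned single-channel LFP trials
#'
#' Container for a trial-by-sample voltage matrix cut around a repeated
#' auditory stimulus, together with the sampling metadata and the labels
#' (brain region, consciousness condition, stimulus paradigm) that the
#' downstream ASSR and inhibitory-gating analyses key on.
#'
#' @slot data numeric matrix, trials in rows, samples in columns (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot t0 time of the first sample relative to the aligning stimulus onset
#'   (seconds; negative means pre-stimulus).
#' @slot region recording site, one of `"AC"`, `"HP"`, `"AMY"`, `"PFC"`.
#' @slot condition `"conscious"` or `"anesthetized"`.
#' @slot stimulus `"click_train"` (40-Hz click train, ASSR paradigm) or
#'   `"sound_pair"` (conditioning/test noise-burst pair, gating paradigm).
#' @slot sessionId opaque session label.
#'
#' @details Epochs for `sound_pair` must cover at least \[-3.0, 0.7\] s around
#' the conditioning onset (control period through test response);
#' `click_train` epochs must cover \[-0.5, 1.0\] s.
#'
#' @seealso [EpochSet()] for the user-facing constructor,
#'   [genPairEpochs()], [genAssrEpochs()] to simulate sets,
#'   [epochTrace()] to cut sets from a continuous recording.
#' @name EpochSet-class
#' @rdname EpochSet-class
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    data      = "matrix",
    fs        = "numeric",
    t0        = "numeric",
    region    = "character",
    condition = "character",
    stimulus  = "character",
    sessionId = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- object@data
  if (!is.numeric(d)) msg <- c(msg, "data must be a numeric matrix")
  if (nrow(d) < 1L) msg <- c(msg, "need at least one trial")
  if (anyNA(d)) msg <- c(msg, "data must not contain NA")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (!object@region %in% .REGIONS)
    msg <- c(msg, sprintf("region must be one of %s",
                          paste(.REGIONS, collapse = ", ")))
  if (!object@condition %in% .CONDITIONS)
    msg <- c(msg, sprintf("condition must be one of %s",
                          paste(.CONDITIONS, collapse = ", ")))
  if (!object@stimulus %in% .STIMULI)
    msg <- c(msg, sprintf("stimulus must be one of %s",
                          paste(.STIMULI, collapse = ", ")))
  if (length(msg) == 0L && object@stimulus %in% names(.REQUIRED_SPAN)) {
    need <- .REQUIRED_SPAN[[object@stimulus]]
    tol <- 1 / object@fs
    t_end <- object@t0 + (ncol(d) - 1L) / object@fs
    if (object@t0 > need[1] + tol || t_end < need[2] - tol)
      msg <- c(msg, sprintf(
        "%s epochs must cover [%.2f, %.2f] s around stimulus onset (got [%.3f, %.3f])",
        object@stimulus, need[1], need[2], object@t0, t_end))
  }
  if (length(msg)) msg else TRUE
})

#' TFRSet: per-trial complex wavelet coefficients
#'
#' Trial x frequency x time array of complex Morlet coefficients produced by
#' [morletTFR()]. Coefficients within half the wavelet support of either
#' epoch edge are `NA` (flagged invalid) rather than contaminated by
#' zero-padding.
#'
#' @slot coeffs complex array, `trial x frequency x time`. `NA` marks edge
#'   samples inside half the wavelet support at that frequency.
#' @slot freqs strictly increasing frequency grid (Hz).
#' @slot times time grid (s), aligned to the source `EpochSet` `t0`.
#' @slot fs sampling rate (Hz).
#' @slot meta list of labels copied from the source `EpochSet`.
#' @name TFRSet-class
#' @rdname TFRSet-class
#' @exportClass TFRSet
setClass("TFRSet",
  representation(
    coeffs = "array",
    freqs  = "numeric",
    times  = "numeric",
    fs     = "numeric",
    meta   = "list"
  )
)

setValidity("TFRSet", function(object) {
  msg <- character()
  if (length(dim(object@coeffs)) != 3L)
    msg <- c(msg, "coeffs must be a 3-d array (trial x frequency x time)")
  if (is.unsorted(object@freqs, strictly = TRUE))
    msg <- c(msg, "freqs must be strictly increasing")
  if (length(dim(object@coeffs)) == 3L) {
    if (dim(object@coeffs)[2] != length(object@freqs))
      msg <- c(msg, "second dim of coeffs must match length(freqs)")
    if (dim(object@coeffs)[3] != length(object@times))
      msg <- c(msg, "third dim of coeffs must match length(times)")
  }
  v <- object@coeffs[!is.na(object@coeffs)]
  if (length(v) && any(!is.finite(Mod(v))))
    msg <- c(msg, "non-NA coefficients must be finite")
  if (length(msg)) msg else TRUE
})

#' SpectralMap: frequency x time MTP or PLF surface
#'
#' Real-valued frequency-by-time matrix holding either the mean trial power
#' (MTP, microvolt-squared) or the phase-locking factor (PLF, dimensionless
#' in \[0, 1\]) of a [TFRSet-class]. Cells flagged invalid at the wavelet
#' edges are `NA`.
#'
#' @slot values numeric matrix, frequencies in rows, time points in columns.
#' @slot kind `"MTP"` or `"PLF"`.
#' @slot freqs frequency grid (Hz).
#' @slot times time grid (s).
#' @slot nTrials number of trials the map was computed from.
#' @name SpectralMap-class
#' @rdname SpectralMap-class
#' @exportClass SpectralMap
setClass("SpectralMap",
  representation(
    values  = "matrix",
    kind    = "character",
    freqs   = "numeric",
    times   = "numeric",
    nTrials = "integer"
  )
)

setValidity("SpectralMap", function(object) {
  msg <- character()
  if (!object@kind %in% c("MTP", "PLF"))
    msg <- c(msg, "kind must be 'MTP' or 'PLF'")
  if (nrow(object@values) != length(object@freqs))
    msg <- c(msg, "rows of values must match length(freqs)")
  if (ncol(object@values) != length(object@times))
    msg <- c(msg, "columns of values must match length(times)")
  v <- object@values[!is.na(object@values)]
  if (object@kind == "MTP" && length(v) && any(v < 0))
    msg <- c(msg, "MTP values must be >= 0")
  if (object@kind == "PLF" && length(v) && any(v < -1e-12 | v > 1 + 1e-12))
    msg <- c(msg, "PLF values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' RunConfig: analysis constants for the ASSR/IG pipeline
#'
#' Bundles every tunable the pipeline uses: the wavelet frequency grid and
#' cycle count, the ASSR summary band/window, the per-region evoked-peak
#' search windows, the pre-stimulus control period, the peak acceptance
#' level, and the sliding-window test geometry.
#'
#' @slot freqGrid ordered wavelet frequencies (Hz).
#' @slot nCycles Morlet cycle count (dimensionless).
#' @slot assrBand frequency interval for the ASSR summary (Hz).
#' @slot assrWindow time interval for the ASSR summary (s, post C onset).
#' @slot peakWindows named list: `AC` and `other`, each with `neg`/`pos`
#'   latency windows (s after stimulus onset) for the negative and positive
#'   evoked deflections.
#' @slot controlPeriod interval used as the null for peak significance
#'   (s relative to the conditioning onset); must precede the stimulus.
#' @slot alphaPeak significance level for accepting a peak (default 0.01).
#' @slot halfWin half-width of the amplitude measurement window (s).
#' @slot slideStep step between sliding null windows in the control period (s).
#' @slot seed integer seed recorded with the run (may be `NA`).
#' @seealso [runConfig()] for the constructor with defaults.
#' @name RunConfig-class
#' @rdname RunConfig-class
#' @exportClass RunConfig
setClass("RunConfig",
  representation(
    freqGrid      = "numeric",
    nCycles       = "numeric",
    assrBand      = "numeric",
    assrWindow    = "numeric",
    peakWindows   = "list",
    controlPeriod = "numeric",
    alphaPeak     = "numeric",
    halfWin       = "numeric",
    slideStep     = "numeric",
    seed          = "integer"
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  if (is.unsorted(object@freqGrid, strictly = TRUE))
    msg <- c(msg, "freqGrid must be strictly increasing")
  if (object@nCycles <= 0) msg <- c(msg, "nCycles must be positive")
  if (length(object@assrBand) != 2L || diff(object@assrBand) <= 0)
    msg <- c(msg, "assrBand must be an increasing interval")
  if (object@assrBand[1] < min(object@freqGrid) ||
      object@assrBand[2] > max(object@freqGrid))
    msg <- c(msg, "assrBand must lie within the freqGrid span")
  if (length(object@assrWindow) != 2L || diff(object@assrWindow) <= 0)
    msg <- c(msg, "assrWindow must be an increasing interval")
  if (length(object@controlPeriod) != 2L || diff(object@controlPeriod) <= 0)
    msg <- c(msg, "controlPeriod must be an increasing interval")
  if (object@controlPeriod[2] > 0)
    msg <- c(msg, "controlPeriod must precede the stimulus onset")
  if (object@alphaPeak <= 0 || object@alphaPeak >= 1)
    msg <- c(msg, "alphaPeak must be in (0, 1)")
  for (grp in c("AC", "other")) {
    pw <- object@peakWindows[[grp]]
    if (is.null(pw) || is.null(pw$neg) || is.null(pw$pos))
      msg <- c(msg, sprintf("peakWindows$%s must have neg and pos entries", grp))
  }
  if (object@halfWin <= 0 || object@slideStep <= 0)
    msg <- c(msg, "halfWin and slideStep must be positive")
  if (length(msg)) msg else TRUE
})
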