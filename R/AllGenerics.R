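#' Number of trials
#' @param x an [EpochSet-class] or [TFRSet-class]
#' @return integer trial count
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Sampling rate (Hz)
#' @param x an [EpochSet-class] or [TFRSet-class]
#' @return sampling rate in Hz
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Time grid of an object (seconds relative to stimulus onset)
#' @param x an [EpochSet-class], [TFRSet-class] or [SpectralMap-class]
#' @return numeric vector of sample times
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' Trial-by-sample voltage matrix
#' @param x an [EpochSet-class]
#' @return numeric matrix (trials x samples, microvolts)
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' Recording-site label
#' @param x an object carrying region metadata
#' @return one of `"AC"`, `"HP"`, `"AMY"`, `"PFC"`
#' @export
setGeneric("region", function(x) standardGeneric("region"))

#' Consciousness condition label
#' @param x an object carrying condition metadata
#' @return `"conscious"` or `"anesthetized"`
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' Stimulus paradigm label
#' @param x an object carrying stimulus metadata
#' @return `"click_train"` or `"sound_pair"`
#' @export
setGeneric("stimulus", function(x) standardGeneric("stimulus"))

#' Session identifier
#' @param x an object carrying session metadata
#' @return character session label
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))

#' Mean trial power (MTP)
#'
#' Averages the squared magnitude of the per-trial wavelet coefficients
#' across trials: `MTP(f, t) = mean_n |W_n(f, t)|^2`.
#'
#' @param x a [TFRSet-class]
#' @return a [SpectralMap-class] with `kind = "MTP"`
#' @export
setGeneric("mtp", function(x) standardGeneric("mtp"))

#' Phase-locking factor (PLF)
#'
#' Magnitude of the trial-averaged unit phasor of the wavelet coefficients:
#' `PLF(f, t) = | mean_n W_n(f, t) / |W_n(f, t)| |`. 1 means perfect phase
#' consistency across trials; values near `sqrt(pi) / (2 sqrt(N))` are the
#' chance level for `N` trials with random phases.
#'
#' @param x a [TFRSet-class] with at least 2 trials
#' @return a [SpectralMap-class] with `kind = "PLF"`
#' @export
setGeneric("plf", function(x) standardGeneric("plf"))

#' Trial-averaged evoked potential
#'
#' @param x an [EpochSet-class]
#' @return data.frame with columns `time` (s) and `uV` (microvolts): the
#'   pointwise mean across trials on the epoch time base.
#' @export
setGeneric("averageERP", function(x) standardGeneric("averageERP"))
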