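#' Construct an EpochSet
#'
#' @param data numeric matrix, trials in rows, samples in columns (microvolts).
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample relative to the aligning stimulus
#'   onset (s; negative = pre-stimulus).
#' @param region one of `"AC"`, `"HP"`, `"AMY"`, `"PFC"`.
#' @param condition `"conscious"` or `"anesthetized"`.
#' @param stimulus `"click_train"` or `"sound_pair"`.
#' @param sessionId opaque session label.
#' @return a validated [EpochSet-class]
#' @examples
#' es <- EpochSet(matrix(rnorm(3 * 1501), 3), fs = 1000, t0 = -0.5,
#'                region = "AC", condition = "conscious",
#'                stimulus = "click_train", sessionId = "demo")
#' nTrials(es)
#' @export
EpochSet <- function(data, fs, t0, region, condition, stimulus,
                     sessionId = "unlabeled") {
  new("EpochSet", data = as.matrix(data), fs = as.numeric(fs),
      t0 = as.numeric(t0), region = region, condition = condition,
      stimulus = stimulus, sessionId = as.character(sessionId))
}

#' @rdname nTrials
#' @export
setMethod("nTrials", "EpochSet", function(x) nrow(x@data))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)

#' @rdname epochTimes
#' @export
setMethod("epochTimes", "EpochSet",
          function(x) x@t0 + (seq_len(ncol(x@data)) - 1L) / x@fs)

#' @rdname epochData
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)

#' @rdname region
#' @export
setMethod("region", "EpochSet", function(x) x@region)

#' @rdname condition
#' @export
setMethod("condition", "EpochSet", function(x) x@condition)

#' @rdname stimulus
#' @export
setMethod("stimulus", "EpochSet", function(x) x@stimulus)

#' @rdname sessionId
#' @export
setMethod("sessionId", "EpochSet", function(x) x@sessionId)

#' @describeIn EpochSet-class subset trials (rows), keeping all metadata
#' @param x,i,j,...,drop see [base::Extract]; only trial subsetting is supported
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  new("EpochSet", data = x@data[i, , drop = FALSE], fs = x@fs, t0 = x@t0,
      region = x@region, condition = x@condition, stimulus = x@stimulus,
      sessionId = x@sessionId)
})

setMethod("show", "EpochSet", function(object) {
  tt <- epochTimes(object)
  cat(sprintf(
    "EpochSet: %d trials x %d samples @ %g Hz  [%g, %g] s\n  %s | %s | %s | session %s\n",
    nrow(object@data), ncol(object@data), object@fs,
    tt[1], tt[length(tt)],
    object@region, object@condition, object@stimulus, object@sessionId))
})

#' @rdname nTrials
#' @export
setMethod("nTrials", "TFRSet", function(x) dim(x@coeffs)[1])

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "TFRSet", function(x) x@fs)

#' @rdname epochTimes
#' @export
setMethod("epochTimes", "TFRSet", function(x) x@times)

#' @rdname epochTimes
#' @export
setMethod("epochTimes", "SpectralMap", function(x) x@times)

#' Frequency grid of a TFR or spectral map
#' @param x a [TFRSet-class] or [SpectralMap-class]
#' @return numeric vector of frequencies (Hz)
#' @export
frequencies <- function(x) x@freqs

#' Values matrix of a spectral map
#' @param map a [SpectralMap-class]
#' @return numeric matrix (frequency x time)
#' @export
mapValues <- function(map) map@values

setMethod("show", "TFRSet", function(object) {
  d <- dim(object@coeffs)
  cat(sprintf(
    "TFRSet: %d trials x %d freqs (%g-%g Hz) x %d times @ %g Hz\n",
    d[1], d[2], min(object@freqs), max(object@freqs), d[3], object@fs))
})

setMethod("show", "SpectralMap", function(object) {
  cat(sprintf(
    "SpectralMap[%s]: %d freqs (%g-%g Hz) x %d times, %d trials\n",
    object@kind, nrow(object@values), min(object@freqs), max(object@freqs),
    ncol(object@values), object@nTrials))
})

#' Export a spectral map as a long-format data.frame
#'
#' One row per (frequency, time) cell, suitable for TSV export or plotting.
#'
#' @param map a [SpectralMap-class]
#' @return data.frame with columns `freq`, `time`, `value`
#' @export
mapToLong <- function(map) {
  data.frame(
    freq  = rep(map@freqs, times = length(map@times)),
    time  = rep(map@times, each = length(map@freqs)),
    value = as.vector(map@values)
  )
}
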