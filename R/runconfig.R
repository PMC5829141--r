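#' Default pipeline configuration
#'
#' Builds a [RunConfig-class] with the defaults used throughout: a 1-100 Hz
#' wavelet grid with 7 cycles, the 35-45 Hz x 50-550 ms ASSR summary, the
#' region-specific evoked-peak search windows, the \[-3, -2\] s control
#' period and a 0.01 peak acceptance level.
#'
#' @param freqGrid wavelet frequency grid (Hz).
#' @param nCycles Morlet cycles.
#' @param assrBand ASSR summary band (Hz).
#' @param assrWindow ASSR summary window (s).
#' @param peakWindows per-region peak search windows; a list with entries
#'   `AC` and `other`, each a list with `neg` and `pos` intervals (s). The
#'   defaults bracket the nominal peak latencies (AC: 25/40 ms; other
#'   regions: 35-39/65-75 ms) with margin.
#' @param controlPeriod control interval for peak significance (s, relative
#'   to the conditioning onset).
#' @param alphaPeak peak acceptance significance level.
#' @param halfWin half-width of the +/-5 ms amplitude window (s).
#' @param slideStep step of the sliding null windows (s).
#' @param seed optional integer seed recorded with the run.
#' @return a validated [RunConfig-class]
#' @examples
#' cfg <- runConfig()
#' cfg@assrBand
#' @export
runConfig <- function(freqGrid = 1:100,
                      nCycles = 7,
                      assrBand = c(35, 45),
                      assrWindow = c(0.05, 0.55),
                      peakWindows = list(
                        AC    = list(neg = c(0.010, 0.040), pos = c(0.025, 0.060)),
                        other = list(neg = c(0.025, 0.055), pos = c(0.050, 0.095))
                      ),
                      controlPeriod = c(-3, -2),
                      alphaPeak = 0.01,
                      halfWin = 0.005,
                      slideStep = 0.010,
                      seed = NA_integer_) {
  new("RunConfig", freqGrid = as.numeric(freqGrid), nCycles = nCycles,
      assrBand = assrBand, assrWindow = assrWindow,
      peakWindows = peakWindows, controlPeriod = controlPeriod,
      alphaPeak = alphaPeak, halfWin = halfWin, slideStep = slideStep,
      seed = as.integer(seed))
}

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    "RunConfig: grid %g-%g Hz (%d freqs), %g cycles | ASSR %g-%g Hz x %g-%g s | alpha %g\n",
    min(object@freqGrid), max(object@freqGrid), length(object@freqGrid),
    object@nCycles, object@assrBand[1], object@assrBand[2],
    object@assrWindow[1], object@assrWindow[2], object@alphaPeak))
})

## flat key=value serialisation; numeric vectors are comma-separated and the
## four peak windows get one key each (peak_window_<AC|other>_<neg|pos>)
.config_keys <- function(cfg) {
  c(freq_grid     = paste(cfg@freqGrid, collapse = ","),
    n_cycles      = as.character(cfg@nCycles),
    assr_band     = paste(cfg@assrBand, collapse = ","),
    assr_window   = paste(cfg@assrWindow, collapse = ","),
    peak_window_AC_neg    = paste(cfg@peakWindows$AC$neg, collapse = ","),
    peak_window_AC_pos    = paste(cfg@peakWindows$AC$pos, collapse = ","),
    peak_window_other_neg = paste(cfg@peakWindows$other$neg, collapse = ","),
    peak_window_other_pos = paste(cfg@peakWindows$other$pos, collapse = ","),
    control_period = paste(cfg@controlPeriod, collapse = ","),
    alpha_peak    = as.character(cfg@alphaPeak),
    half_win      = as.character(cfg@halfWin),
    slide_step    = as.character(cfg@slideStep),
    seed          = as.character(cfg@seed))
}

#' Write a RunConfig as a flat key=value text file
#' @param cfg a [RunConfig-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeRunConfig <- function(cfg, path) {
  kv <- .config_keys(cfg)
  writeLines(paste0(names(kv), "=", kv), path)
  invisible(path)
}

#' Read a RunConfig from a flat key=value text file
#'
#' Unknown keys are rejected; missing keys fall back to the [runConfig()]
#' defaults, so a partial file overriding a single constant is valid.
#'
#' @param path file of `key=value` lines; `#` starts a comment.
#' @return a validated [RunConfig-class]
#' @export
readRunConfig <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  bad <- !grepl("=", ln, fixed = TRUE)
  if (any(bad))
    stop("malformed config line(s): ", paste(ln[bad], collapse = "; "))
  key <- sub("=.*$", "", ln)
  val <- sub("^[^=]*=", "", ln)
  known <- names(.config_keys(runConfig()))
  unknown <- setdiff(key, known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  get_num <- function(k, default) {
    if (!k %in% key) return(default)
    as.numeric(strsplit(val[match(k, key)], ",")[[1]])
  }
  pw <- list(
    AC = list(neg = get_num("peak_window_AC_neg", c(0.010, 0.040)),
              pos = get_num("peak_window_AC_pos", c(0.025, 0.060))),
    other = list(neg = get_num("peak_window_other_neg", c(0.025, 0.055)),
                 pos = get_num("peak_window_other_pos", c(0.050, 0.095))))
  runConfig(
    freqGrid = get_num("freq_grid", 1:100),
    nCycles = get_num("n_cycles", 7),
    assrBand = get_num("assr_band", c(35, 45)),
    assrWindow = get_num("assr_window", c(0.05, 0.55)),
    peakWindows = pw,
    controlPeriod = get_num("control_period", c(-3, -2)),
    alphaPeak = get_num("alpha_peak", 0.01),
    halfWin = get_num("half_win", 0.005),
    slideStep = get_num("slide_step", 0.010),
    seed = get_num("seed", NA_integer_))
}
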