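## Single-file epoch container.
##
## Layout (little-endian throughout):
##   bytes 1-12   magic "ASSRIGEPOCHS"
##   int32        schema version (currently 1)
##   int32        header length L in bytes
##   L bytes      UTF-8 JSON header: fs, t0, region, condition, stimulus,
##                session_id, n_trials, n_samples, dtype ("float64"),
##                order ("column-major")
##   then         n_trials * n_samples float64 voltages, column-major
##                (i.e. all trials' sample 1, then all trials' sample 2, ...)

.EPOCH_MAGIC <- "ASSRIGEPOCHS"
.EPOCH_SCHEMA_VERSION <- 1L

#' Save an EpochSet to a single binary container
#'
#' Lossless: voltages are stored as raw float64, so
#' `loadEpochs(saveEpochs(x, p))` reproduces `x` bit-exactly, metadata
#' included. See the source header for the documented byte layout.
#'
#' @param x an [EpochSet-class]
#' @param path output file path
#' @return `path`, invisibly
#' @seealso [loadEpochs()]
#' @export
saveEpochs <- function(x, path) {
  stopifnot(is(x, "EpochSet"))
  hdr <- jsonlite::toJSON(list(
    fs = x@fs, t0 = x@t0, region = x@region, condition = x@condition,
    stimulus = x@stimulus, session_id = x@sessionId,
    n_trials = nrow(x@data), n_samples = ncol(x@data),
    dtype = "float64", order = "column-major"), auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(hdr))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.EPOCH_MAGIC), con)
  writeBin(c(.EPOCH_SCHEMA_VERSION, length(hraw)), con, size = 4L,
           endian = "little")
  writeBin(hraw, con)
  writeBin(as.vector(x@data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Load an EpochSet saved by [saveEpochs()]
#'
#' @param path container file path
#' @return the stored [EpochSet-class]
#' @export
loadEpochs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(.EPOCH_MAGIC)))
  if (!identical(magic, .EPOCH_MAGIC))
    stop("not an epoch container: bad magic in ", path)
  ver <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(ver, .EPOCH_SCHEMA_VERSION))
    stop("incompatible epoch container: schema version ", ver,
         " (this package reads version ", .EPOCH_SCHEMA_VERSION, ")")
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  n <- hdr$n_trials * hdr$n_samples
  dat <- readBin(con, "double", n, size = 8L, endian = "little")
  if (length(dat) != n) stop("epoch container truncated: ", path)
  EpochSet(matrix(dat, nrow = hdr$n_trials, ncol = hdr$n_samples),
           fs = hdr$fs, t0 = hdr$t0, region = hdr$region,
           condition = hdr$condition, stimulus = hdr$stimulus,
           sessionId = hdr$session_id)
}
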