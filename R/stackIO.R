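#' Write / read a time-lapse stack as multi-page TIFF
#'
#' Pages are written channel-major (all frames of the first channel, then
#' the next channel) as 16-bit grayscale; a JSON sidecar file (same path
#' with extension \code{.json}) records the channel order, time grid, pixel
#' size and frame shape, and is required to read the stack back. Integer
#' stacks round-trip losslessly.
#'
#' @param stack a [TimeLapseStack-class] (integer counts in [0, 65535]).
#' @param path output TIFF path; the sidecar is written next to it.
#' @return \code{writeStack} returns \code{path} invisibly;
#'   \code{readStack} returns the [TimeLapseStack-class].
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "TimeLapseStack"))
  pages <- list()
  for (ch in names(stack@channels)) {
    arr <- stack@channels[[ch]]
    stopIf(max(arr) > 65535 || min(arr) < 0,
           "intensities must lie in [0, 65535] for 16-bit TIFF output")
    for (t in seq_len(dim(arr)[3]))
      pages[[length(pages) + 1L]] <- arr[, , t] / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    channels = names(stack@channels),
    framesPerChannel = dim(stack@channels[[1]])[3],
    shape = dim(stack@channels[[1]])[1:2],
    pixelSize = stack@pixelSize,
    timeGrid = stack@timeGrid,
    seed = stack@seed)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecarPath <- function(path) sub("\\.tiff?$", ".json", path)

#' @rdname writeStack
#' @param path TIFF path written by \code{writeStack}.
#' @export
readStack <- function(path) {
  side <- sidecarPath(path)
  stopIf(!file.exists(side),
         "stack metadata sidecar not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  stopIf(is.null(meta$channels) || is.null(meta$framesPerChannel),
         "malformed stack metadata: ", side)
  pages <- tiff::readTIFF(path, all = TRUE)
  nT <- meta$framesPerChannel
  stopIf(length(pages) != nT * length(meta$channels),
         "page count does not match metadata")
  channels <- list()
  k <- 0L
  for (ch in meta$channels) {
    arr <- array(0L, c(meta$shape[1], meta$shape[2], nT))
    for (t in seq_len(nT)) {
      k <- k + 1L
      arr[, , t] <- as.integer(round(pages[[k]] * 65535))
    }
    channels[[ch]] <- arr
  }
  new("TimeLapseStack", channels = channels, pixelSize = meta$pixelSize,
      timeGrid = as.numeric(meta$timeGrid),
      seed = if (is.null(meta$seed)) NA_real_ else as.numeric(meta$seed))
}

#' Write / read a ground-truth table
#'
#' Plain CSV round trip of the per-cell truth table produced by
#' [generatePopulation()]. An empty population writes a header-only file.
#'
#' @param truth truth data.frame.
#' @param path CSV path.
#' @return \code{writeTruth} returns \code{path} invisibly;
#'   \code{readTruth} the data.frame.
#' @export
writeTruth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  utils::read.csv(path, colClasses = c(
    cellId = "integer", anchorId = "integer", isHp = "logical",
    isViable = "logical"))
}
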