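#' Extract background-subtracted traces from a stack
#'
#' For each track and frame, \code{iCell} is the mean green intensity over
#' the cell's mask and \code{iBack} the mean green intensity over the
#' cell's own anchor disk excluding the mask (local background). Frames
#' with a missing detection are filled by linear interpolation between the
#' neighboring frames; tracks with an internal gap longer than
#' \code{maxGap} frames are discarded.
#'
#' @param tracks track-assigned detections from [trackCells()].
#' @param stack the [TimeLapseStack-class].
#' @param layout the [ChipLayout-class].
#' @param channel intensity channel (default green GFP).
#' @param maxGap longest internal run of missing frames tolerated.
#' @return a [CellTraceSet-class]; cellData records each track's anchor and
#'   frame-0 centroid, area and equivalent diameter.
#' @export
extractTraces <- function(tracks, stack, layout, channel = "green_gfp",
                          maxGap = 1L) {
  arr <- getChannel(stack, channel)
  h <- dim(arr)[1]; w <- dim(arr)[2]; nT <- dim(arr)[3]
  stopIf(nT != length(stack@timeGrid), "stack/time grid mismatch")
  tids <- sort(unique(tracks$trackId))
  n <- length(tids)
  iCell <- matrix(NA_real_, n, nT)
  iBack <- matrix(NA_real_, n, nT)
  cd <- data.frame(trackId = tids, anchorId = rep(NA_integer_, n),
                   x = rep(NA_real_, n), y = rep(NA_real_, n),
                   areaUm2 = rep(NA_real_, n),
                   eqDiameterUm = rep(NA_real_, n))
  anchorPx <- list()
  for (k in seq_len(n)) {
    tr <- tracks[tracks$trackId == tids[k], , drop = FALSE]
    a <- tr$anchorId[1]
    key <- as.character(a)
    if (is.null(anchorPx[[key]]))
      anchorPx[[key]] <- anchorPixelIndex(layout, a, h, w, stack@pixelSize)
    first <- which.min(tr$frame)
    cd$anchorId[k] <- a
    cd$x[k] <- tr$x[first]; cd$y[k] <- tr$y[first]
    cd$areaUm2[k] <- tr$areaUm2[first]
    cd$eqDiameterUm[k] <- tr$eqDiameterUm[first]
    for (r in seq_len(nrow(tr))) {
      t <- tr$frame[r]
      mask <- tr$pixels[[r]]
      backPx <- setdiff(anchorPx[[key]], mask)
      stopIf(length(backPx) == 0L,
             "anchor background region empty: anchor ", a)
      frame <- arr[, , t]
      iCell[k, t] <- mean(frame[mask])
      iBack[k, t] <- mean(frame[backPx])
    }
  }
  # interpolate short internal gaps; drop tracks with boundary or long gaps
  keep <- rep(TRUE, n)
  for (k in seq_len(n)) {
    miss <- is.na(iCell[k, ])
    if (!any(miss)) next
    runs <- rle(miss)
    missRuns <- which(runs$values)
    atEdge <- any(missRuns == 1L | missRuns == length(runs$lengths))
    if (atEdge || any(runs$lengths[missRuns] > maxGap)) {
      keep[k] <- FALSE
      next
    }
    ok <- which(!miss)
    iCell[k, miss] <- stats::approx(ok, iCell[k, ok], xout = which(miss))$y
    iBack[k, miss] <- stats::approx(ok, iBack[k, ok], xout = which(miss))$y
  }
  new("CellTraceSet", timeGrid = stack@timeGrid,
      iCell = iCell[keep, , drop = FALSE],
      iBack = iBack[keep, , drop = FALSE],
      cellData = cd[keep, , drop = FALSE])
}

#' @describeIn CellTraceSet-class Construct a trace set from matrices.
#' @param iCell,iBack cells x time matrices.
#' @param timeGrid acquisition times, hours.
#' @param cellData per-cell metadata (default: bare trackId).
#' @export
cellTraceSet <- function(iCell, iBack, timeGrid,
                         cellData = data.frame(trackId = seq_len(nrow(iCell)))) {
  new("CellTraceSet", timeGrid = timeGrid, iCell = as.matrix(iCell),
      iBack = as.matrix(iBack), cellData = cellData)
}

#' @rdname CellTraceSet-class
#' @export
setMethod("nCells", "CellTraceSet", function(x) nrow(x@iCell))

#' @rdname CellTraceSet-class
#' @export
setMethod("cellData", "CellTraceSet", function(x) x@cellData)

#' @rdname CellTraceSet-class
#' @export
setMethod("timeGrid", "CellTraceSet", function(x) x@timeGrid)

#' @rdname CellTraceSet-class
#' @export
setMethod("intensity", "CellTraceSet", function(x) x@iCell - x@iBack)

#' @rdname CellTraceSet-class
#' @export
setMethod("deltaIntensity", "CellTraceSet", function(x) {
  I <- x@iCell - x@iBack
  I - I[, 1]
})

setMethod("show", "CellTraceSet", function(object) {
  cat(sprintf("CellTraceSet: %d cells x %d time points (%g-%g h)\n",
              nCells(object), length(object@timeGrid),
              min(object@timeGrid), max(object@timeGrid)))
})

#' Delta-I of a single intensity series
#'
#' deltaI(t) = I(t) - I(0); the first element is 0 by construction.
#'
#' @param I background-subtracted intensity series.
#' @return numeric series of the same length.
#' @export
deltaTrace <- function(I) I - I[1]

#' Ordinary least-squares line fit of one trace
#'
#' Fits values ~ time by OLS and reports the slope, intercept and r^2 (the
#' squared Pearson correlation). A zero-variance series has slope 0 and,
#' by convention, r^2 = 0.
#'
#' @param time time points (>= 3).
#' @param values trace values.
#' @return list(slope, intercept, r2).
#' @export
fitLinear <- function(time, values) {
  stopIf(length(time) < 3L, "at least 3 time points are required")
  stopIf(length(time) != length(values), "time/values length mismatch")
  vt <- stats::var(time)
  vy <- stats::var(values)
  slope <- if (vy == 0) 0 else stats::cov(time, values) / vt
  intercept <- mean(values) - slope * mean(time)
  r2 <- if (vy == 0) 0 else stats::cor(time, values)^2
  list(slope = slope, intercept = intercept, r2 = r2)
}

#' Per-cell linear fits of delta-I traces
#'
#' Applies [fitLinear()] to every cell's delta-I series.
#'
#' @param traces a [CellTraceSet-class].
#' @return data.frame (trackId, slope, intercept, r2).
#' @export
fitKinetics <- function(traces) {
  stopifnot(is(traces, "CellTraceSet"))
  dI <- deltaIntensity(traces)
  tg <- traces@timeGrid
  fits <- t(vapply(seq_len(nrow(dI)), function(i) {
    f <- fitLinear(tg, dI[i, ])
    c(f$slope, f$intercept, f$r2)
  }, numeric(3)))
  data.frame(trackId = traces@cellData$trackId,
             slope = fits[, 1], intercept = fits[, 2], r2 = fits[, 3])
}

#' Population summary of delta-I traces
#'
#' At each time point: the mean delta-I over cells, the mean deviation
#' (mean absolute deviation from the mean, the dispersion statistic used
#' with these populations), the number of cells, and the bias-adjusted
#' sample skewness g1 (NA when fewer than 3 cells).
#'
#' @param traces a [CellTraceSet-class] with at least one cell.
#' @return data.frame (time, meanDeltaI, meanDeviation, n, skewness).
#' @export
summarizePopulation <- function(traces) {
  stopifnot(is(traces, "CellTraceSet"))
  stopIf(nCells(traces) == 0L, "empty trace set")
  dI <- deltaIntensity(traces)
  n <- nrow(dI)
  data.frame(
    time = traces@timeGrid,
    meanDeltaI = colMeans(dI),
    meanDeviation = apply(dI, 2, meanDeviation),
    n = n,
    skewness = if (n >= 3) apply(dI, 2, sampleSkewness) else NA_real_)
}
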