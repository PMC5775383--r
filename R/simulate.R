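#' Imaging and noise parameters for the synthetic generator
#'
#' Forward-model settings shared by [renderTimelapse()] and
#' [simulateTraceSet()]. Defaults emulate a 16-bit EM-CCD acquisition of the
#' anchor chip every 2 hours for 62 hours: cells are rendered as uniform
#' disks whose green level rises linearly in time on a flat background.
#'
#' @param pixelSize um per pixel.
#' @param timeGrid acquisition times, hours (default 0, 2, ..., 62).
#' @param background flat background level, counts.
#' @param readNoiseSd per-pixel Gaussian read noise sd, counts.
#' @param cellNoiseSd per-cell, per-frame intensity fluctuation sd, counts
#'   (spatially coherent across the cell mask; models biological and
#'   illumination flicker that pixel averaging cannot remove).
#' @param blurSigma Gaussian optical blur sd, pixels (0 disables).
#' @param quantize round intensities to integer counts (16-bit camera);
#'   disable for exact-arithmetic tests.
#' @param redIntensity,nucleiIntensity,deadIntensity disk levels of the
#'   cell-tracker, nuclei and dead-stain channels, counts.
#' @return a classed list of parameters.
#' @export
imagingParams <- function(pixelSize = 2, timeGrid = seq(0, 62, by = 2),
                          background = 100, readNoiseSd = 5,
                          cellNoiseSd = 8, blurSigma = 1, quantize = TRUE,
                          redIntensity = 5000, nucleiIntensity = 1500,
                          deadIntensity = 2000) {
  stopIf(pixelSize <= 0, "pixelSize must be positive")
  stopIf(length(timeGrid) == 0L, "timeGrid must be non-empty")
  structure(list(pixelSize = pixelSize, timeGrid = timeGrid,
                 background = background, readNoiseSd = readNoiseSd,
                 cellNoiseSd = cellNoiseSd, blurSigma = blurSigma,
                 quantize = quantize, redIntensity = redIntensity,
                 nucleiIntensity = nucleiIntensity,
                 deadIntensity = deadIntensity),
            class = "imagingParams")
}

#' @describeIn imagingParams Noise-free variant of a parameter set: no read
#'   noise, no cell flicker, no blur, no quantization. Under these settings
#'   trace extraction is exact arithmetic.
#' @param params an imagingParams list to strip of noise.
#' @export
noiseFree <- function(params = imagingParams()) {
  params$readNoiseSd <- 0
  params$cellNoiseSd <- 0
  params$blurSigma <- 0
  params$quantize <- FALSE
  params
}

#' Generate a ground-truth cell population on a chip
#'
#' Loads the chip by Poisson sampling ([poissonLoad()]) and draws per-cell
#' ground truth: position inside the anchor (cells are rejected-sampled to
#' avoid overlap where geometrically possible), diameter, HP membership,
#' GFP accumulation slope, baseline intensity and endpoint viability.
#' HP cells take an LP slope draw times \code{hpSlopeMultiplier} and an LP
#' diameter draw times \code{hpDiameterMultiplier}. Non-producers and
#' non-viable cells have slope 0. Cells are immobile: the generated position
#' holds in every frame (agarose-embedded cells are mechanically retained in
#' their anchors).
#'
#' @param layout a [ChipLayout-class]; rendering-oriented geometries such as
#'   \code{chipLayoutPreset("imaging")} are typical.
#' @param preset a [ConditionPreset-class].
#' @param seed optional integer seed.
#' @param occupancy optional [OccupancyTable-class] to reuse; drawn from
#'   \code{preset@lam} when NULL.
#' @param placementMargin minimum edge-to-edge distance between cells
#'   sharing an anchor, um. Gel-suspended cells do not touch; the default
#'   (4 um) also keeps neighboring cells optically resolvable under the
#'   default blur.
#' @return data.frame with one row per cell (cellId, anchorId, x, y,
#'   diameter, isHp, slope, baseline, isViable) and the occupancy table in
#'   \code{attr(, "occupancy")}.
#' @export
generatePopulation <- function(layout, preset, seed = NULL,
                               occupancy = NULL, placementMargin = 4) {
  stopifnot(is(layout, "ChipLayout"), is(preset, "ConditionPreset"))
  validObject(preset)
  withSeed(seed, {
    if (is.null(occupancy)) occupancy <- poissonLoad(layout, preset@lam)
    counts <- occupancyCounts(occupancy)
    n <- sum(counts)
    if (n == 0L) {
      truth <- data.frame(cellId = integer(), anchorId = integer(),
                          x = numeric(), y = numeric(), diameter = numeric(),
                          isHp = logical(), slope = numeric(),
                          baseline = numeric(), isViable = logical())
      attr(truth, "occupancy") <- occupancy
      return(truth)
    }
    anchorId <- rep(occupancy@anchorId, counts)
    isHp <- stats::runif(n) < preset@hpPrevalence
    diameter <- rtruncnorm(n, preset@lpDiameterMean, preset@lpDiameterSd,
                           preset@diameterRange[1], preset@diameterRange[2])
    diameter[isHp] <- pmin(diameter[isHp] * preset@hpDiameterMultiplier,
                           2 * anchorRadius(layout) - 1e-6)
    slope <- if (preset@lpSlopeMean > 0) {
      sdlog <- sqrt(log(1 + (preset@lpSlopeSd / preset@lpSlopeMean)^2))
      stats::rlnorm(n, log(preset@lpSlopeMean) - sdlog^2 / 2, sdlog)
    } else numeric(n)
    slope[isHp] <- slope[isHp] * preset@hpSlopeMultiplier
    nonproducer <- stats::runif(n) < preset@nonproducerFraction
    slope[nonproducer] <- 0
    isViable <- stats::runif(n) < preset@viability
    slope[!isViable] <- 0
    baseline <- stats::rnorm(n, preset@baselineMean, preset@baselineSd)

    # place cells inside their anchor, avoiding overlap where possible
    ctr <- anchorCenters(layout)[anchorId, , drop = FALSE]
    x <- numeric(n); y <- numeric(n)
    idxByAnchor <- split(seq_len(n), anchorId)
    for (idx in idxByAnchor) {
      placed <- matrix(numeric(0), ncol = 2)
      for (i in idx) {
        rmax <- max(anchorRadius(layout) - diameter[i] / 2, 0.5)
        for (try in seq_len(60L)) {
          rr <- rmax * sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
          px <- ctr[i, 1] + rr * cos(th); py <- ctr[i, 2] + rr * sin(th)
          ok <- !nrow(placed) ||
            all(sqrt((placed[, 1] - px)^2 + (placed[, 2] - py)^2) >
                  (diameter[i] + diameter[idx[seq_len(nrow(placed))]]) / 2 +
                  placementMargin)
          if (ok || try == 60L) break
        }
        x[i] <- px; y[i] <- py
        placed <- rbind(placed, c(px, py))
      }
    }
    truth <- data.frame(cellId = seq_len(n), anchorId = anchorId,
                        x = x, y = y, diameter = diameter, isHp = isHp,
                        slope = slope, baseline = baseline,
                        isViable = isViable)
    attr(truth, "occupancy") <- occupancy
    truth
  })
}

# linear pixel indices of the disk of the given center/diameter (um) in an
# h x w image at pixelSize um/px; pixel (i, j) center is ((j-.5), (i-.5)) px
diskPixels <- function(x0, y0, diameter, h, w, pixelSize) {
  r <- diameter / 2
  j0 <- max(1L, floor((x0 - r) / pixelSize)); j1 <- min(w, ceiling((x0 + r) / pixelSize) + 1L)
  i0 <- max(1L, floor((y0 - r) / pixelSize)); i1 <- min(h, ceiling((y0 + r) / pixelSize) + 1L)
  if (j1 < j0 || i1 < i0) return(integer(0))
  jj <- j0:j1; ii <- i0:i1
  px <- (jj - 0.5) * pixelSize; py <- (ii - 0.5) * pixelSize
  inside <- outer((py - y0)^2, (px - x0)^2, "+") <= r^2
  (rep(jj, each = length(ii))[inside] - 1L) * h + rep(ii, times = length(jj))[inside]
}

#' Render a ground-truth population as a time-lapse stack
#'
#' Forward model for on-chip imaging: each cell is a uniform disk at a fixed
#' position. Channel content: \code{red_tracker} constant disks (all cells);
#' \code{green_gfp} disks at baseline + slope x t plus a per-cell per-frame
#' fluctuation; \code{blue_nuclei} constant disks (all cells);
#' \code{red_dead} disks for non-viable cells only. Signal frames are
#' optionally Gaussian-blurred, then per-pixel read noise is added and the
#' result is quantized to non-negative integer counts.
#'
#' @param truth a truth table from [generatePopulation()].
#' @param layout the [ChipLayout-class] the truth was generated on.
#' @param params an [imagingParams()] list.
#' @param seed optional integer seed.
#' @return a [TimeLapseStack-class].
#' @export
renderTimelapse <- function(truth, layout, params = imagingParams(),
                            seed = NULL) {
  stopifnot(is(layout, "ChipLayout"), inherits(params, "imagingParams"))
  ps <- params$pixelSize
  h <- as.integer(round(layout@fieldOfView[2] / ps))
  w <- as.integer(round(layout@fieldOfView[1] / ps))
  tg <- params$timeGrid
  nT <- length(tg)
  n <- nrow(truth)
  if (n > 0) {
    out <- truth$x - truth$diameter / 2 < 0 |
      truth$x + truth$diameter / 2 > layout@fieldOfView[1] |
      truth$y - truth$diameter / 2 < 0 |
      truth$y + truth$diameter / 2 > layout@fieldOfView[2]
    stopIf(any(out), "invalid geometry: cell(s) outside the field of view: ",
           paste(truth$cellId[out], collapse = ", "))
  }
  disks <- if (n > 0)
    lapply(seq_len(n), function(i)
      diskPixels(truth$x[i], truth$y[i], truth$diameter[i], h, w, ps))
  else list()

  finish <- function(mat) {
    if (params$blurSigma > 0)
      mat <- EBImage::imageData(EBImage::gblur(EBImage::Image(mat),
                                               sigma = params$blurSigma))
    if (params$readNoiseSd > 0)
      mat <- mat + stats::rnorm(length(mat), 0, params$readNoiseSd)
    if (params$quantize) {
      m <- as.integer(round(pmax(mat, 0)))
      dim(m) <- dim(mat)
      m
    } else pmax(mat, 0)
  }
  staticSignal <- function(level, which) {
    mat <- matrix(params$background, h, w)
    for (i in which) mat[disks[[i]]] <- level
    mat
  }

  withSeed(seed, {
    jitter <- if (params$cellNoiseSd > 0 && n > 0)
      matrix(stats::rnorm(n * nT, 0, params$cellNoiseSd), n, nT)
    else matrix(0, max(n, 1), nT)

    mode0 <- if (params$quantize) 0L else 0
    green <- array(mode0, c(h, w, nT)); red <- array(mode0, c(h, w, nT))
    blue <- array(mode0, c(h, w, nT)); dead <- array(mode0, c(h, w, nT))
    redSig <- staticSignal(params$redIntensity, seq_len(n))
    blueSig <- staticSignal(params$nucleiIntensity, seq_len(n))
    deadSig <- staticSignal(params$deadIntensity, which(!truth$isViable))
    for (t in seq_len(nT)) {
      g <- matrix(params$background, h, w)
      for (i in seq_len(n))
        g[disks[[i]]] <- truth$baseline[i] + truth$slope[i] * tg[t] +
          jitter[i, t]
      green[, , t] <- finish(g)
      red[, , t] <- finish(redSig)
      blue[, , t] <- finish(blueSig)
      dead[, , t] <- finish(deadSig)
    }
    new("TimeLapseStack",
        channels = list(red_tracker = red, green_gfp = green,
                        blue_nuclei = blue, red_dead = dead),
        pixelSize = ps, timeGrid = tg,
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
  })
}

#' Simulate intensity traces directly from ground truth
#'
#' Trace-level counterpart of [renderTimelapse()] followed by
#' [extractTraces()]: draws each cell's mask-mean and background-mean green
#' intensities from the analytic marginal of the image forward model
#' (baseline + slope x t, plus the per-cell flicker and mask-averaged read
#' noise), skipping pixel rendering. Useful for statistical studies that
#' need many replicate chips.
#'
#' @param truth a truth table from [generatePopulation()].
#' @param params an [imagingParams()] list.
#' @param seed optional integer seed.
#' @param viableOnly drop non-viable cells first (mirrors the pipeline,
#'   which excludes dead-scored tracks).
#' @return a [CellTraceSet-class] whose cellData carries the truth columns.
#' @export
simulateTraceSet <- function(truth, params = imagingParams(), seed = NULL,
                             viableOnly = FALSE) {
  if (viableOnly) truth <- truth[truth$isViable, , drop = FALSE]
  n <- nrow(truth)
  tg <- params$timeGrid
  nT <- length(tg)
  withSeed(seed, {
    maskPx <- pmax(round(pi * (truth$diameter / 2)^2 / params$pixelSize^2), 1)
    iCell <- outer(truth$slope, tg) + truth$baseline +
      matrix(stats::rnorm(n * nT, 0, params$cellNoiseSd), n, nT) +
      matrix(stats::rnorm(n * nT), n, nT) * params$readNoiseSd / sqrt(maskPx)
    iBack <- matrix(params$background, n, nT)
    if (params$quantize) { iCell <- round(iCell); iBack <- round(iBack) }
    cd <- data.frame(trackId = truth$cellId, anchorId = truth$anchorId,
                     x = truth$x, y = truth$y,
                     areaUm2 = pi * (truth$diameter / 2)^2,
                     eqDiameterUm = truth$diameter,
                     isHp = truth$isHp, slope = truth$slope,
                     isViable = truth$isViable)
    new("CellTraceSet", timeGrid = tg, iCell = iCell, iBack = iBack,
        cellData = cd)
  })
}

setMethod("show", "TimeLapseStack", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf(
    "TimeLapseStack: %d x %d px, %d frames (%g-%g h), %g um/px\n  channels: %s\n",
    d[1], d[2], length(object@timeGrid), min(object@timeGrid),
    max(object@timeGrid), object@pixelSize,
    paste(names(object@channels), collapse = ", ")))
})

#' @rdname TimeLapseStack-class
#' @export
setMethod("timeGrid", "TimeLapseStack", function(x) x@timeGrid)

#' @rdname TimeLapseStack-class
#' @export
setMethod("channelNames", "TimeLapseStack", function(x) names(x@channels))

#' @rdname TimeLapseStack-class
#' @export
setMethod("getChannel", "TimeLapseStack", function(x, name) {
  stopIf(!name %in% names(x@channels), "unknown channel: ", name)
  x@channels[[name]]
})
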