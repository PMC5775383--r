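#' @import methods
NULL

#' Anchor-array chip layout
#'
#' Geometry of a rectangular anchor array: anchor centers on a regular grid,
#' a common anchor radius, the droplet volume trapped per anchor, and the
#' imaged field of view. Coordinates are in micrometers with the origin at
#' the top-left corner of the image; anchors are indexed row-major starting
#' at 1.
#'
#' @slot rows,cols integer grid dimensions.
#' @slot pitch center-to-center anchor spacing, um.
#' @slot anchorRadius anchor radius, um. Must satisfy pitch > 2 * radius so
#'   that anchors never overlap.
#' @slot dropletVolume trapped droplet volume, nL.
#' @slot centers numeric matrix (nAnchors x 2) of anchor centers (x, y) um.
#' @slot fieldOfView numeric length-2, image width and height in um.
#' @export
setClass("ChipLayout",
  representation(
    rows = "integer", cols = "integer",
    pitch = "numeric", anchorRadius = "numeric",
    dropletVolume = "numeric",
    centers = "matrix", fieldOfView = "numeric"
  )
)

setValidity("ChipLayout", function(object) {
  msg <- character()
  if (object@rows < 1L || object@cols < 1L)
    msg <- c(msg, "rows and cols must be >= 1")
  if (!is.finite(object@pitch) || object@pitch <= 0)
    msg <- c(msg, "pitch must be positive")
  if (object@pitch <= 2 * object@anchorRadius)
    msg <- c(msg, "pitch must exceed twice the anchor radius (overlapping anchors)")
  if (object@dropletVolume <= 0)
    msg <- c(msg, "dropletVolume must be positive")
  if (nrow(object@centers) != object@rows * object@cols)
    msg <- c(msg, "centers must have rows*cols rows")
  if (length(msg)) msg else TRUE
})

#' Per-anchor cell occupancy
#'
#' Integer cell counts per anchor, as produced by Poisson loading of a chip
#' or by counting detections per anchor in an image.
#'
#' @slot anchorId integer anchor identifiers (row-major, from 1).
#' @slot counts integer cells per anchor, same length as anchorId.
#' @slot lambda the generating mean cells/droplet when known, else NA.
#' @export
setClass("OccupancyTable",
  representation(anchorId = "integer", counts = "integer", lambda = "numeric")
)

setValidity("OccupancyTable", function(object) {
  msg <- character()
  if (length(object@anchorId) != length(object@counts))
    msg <- c(msg, "anchorId and counts lengths differ")
  if (length(object@counts) && any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Experimental condition preset for the synthetic generator
#'
#' Bundles the population parameters of one transfection condition: the
#' prevalence and effect sizes of the high-producer (HP) subpopulation,
#' low-producer (LP) GFP accumulation slopes, cell diameters, viability and
#' the Poisson loading mean. Shipping presets emulate the three lipoplex
#' charge-ratio conditions (R5, R3, R1.5) plus an untransfected-style null.
#'
#' @slot name preset label.
#' @slot hpPrevalence probability that a cell belongs to the HP subpopulation.
#' @slot lpSlopeMean,lpSlopeSd mean and sd of LP GFP slopes
#'   (intensity counts per hour; slopes are drawn lognormal).
#' @slot hpSlopeMultiplier HP slope = LP draw x multiplier (>= 1).
#' @slot hpDiameterMultiplier HP diameter = LP draw x multiplier (>= 1).
#' @slot nonproducerFraction fraction of cells with slope fixed at 0.
#' @slot viability probability a cell is alive at the endpoint.
#' @slot lam Poisson mean cells per droplet.
#' @slot lpDiameterMean,lpDiameterSd LP diameter distribution, um
#'   (normal, truncated to diameterRange).
#' @slot diameterRange allowed diameter interval, um.
#' @slot baselineMean,baselineSd per-cell baseline green intensity I0.
#' @export
setClass("ConditionPreset",
  representation(
    name = "character",
    hpPrevalence = "numeric",
    lpSlopeMean = "numeric", lpSlopeSd = "numeric",
    hpSlopeMultiplier = "numeric",
    hpDiameterMultiplier = "numeric",
    nonproducerFraction = "numeric",
    viability = "numeric",
    lam = "numeric",
    lpDiameterMean = "numeric", lpDiameterSd = "numeric",
    diameterRange = "numeric",
    baselineMean = "numeric", baselineSd = "numeric"
  )
)

setValidity("ConditionPreset", function(object) {
  msg <- character()
  fr <- c(object@hpPrevalence, object@nonproducerFraction, object@viability)
  if (any(fr < 0 | fr > 1))
    msg <- c(msg, "fractions (hpPrevalence, nonproducerFraction, viability) must lie in [0, 1]")
  if (object@hpSlopeMultiplier < 1 || object@hpDiameterMultiplier < 1)
    msg <- c(msg, "HP multipliers must be >= 1")
  if (object@lpSlopeMean < 0 || object@lpSlopeSd < 0)
    msg <- c(msg, "slope parameters must be non-negative")
  if (object@lam < 0)
    msg <- c(msg, "lam must be non-negative")
  if (length(object@diameterRange) != 2L || diff(object@diameterRange) <= 0)
    msg <- c(msg, "diameterRange must be an increasing length-2 interval")
  if (length(msg)) msg else TRUE
})

#' Multi-channel time-lapse image stack
#'
#' Time-ordered frames for the four acquisition channels used on chip:
#' \code{red_tracker} (whole-cell dye used for segmentation),
#' \code{green_gfp} (GFP production), \code{blue_nuclei} and
#' \code{red_dead} (viability stain pair). Each channel is a 3-D array
#' (height x width x time); all channels share the frame shape and time grid.
#'
#' @slot channels named list of 3-D numeric/integer arrays.
#' @slot pixelSize um per pixel.
#' @slot timeGrid acquisition times, hours.
#' @slot seed seed used at generation time (NA for imported stacks).
#' @export
setClass("TimeLapseStack",
  representation(channels = "list", pixelSize = "numeric",
                 timeGrid = "numeric", seed = "numeric")
)

setValidity("TimeLapseStack", function(object) {
  msg <- character()
  if (!length(object@channels) || is.null(names(object@channels)))
    msg <- c(msg, "channels must be a non-empty named list")
  dims <- lapply(object@channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    msg <- c(msg, "each channel must be a 3-D array (h x w x t)")
  else {
    hw <- vapply(dims, function(d) d[1:2], numeric(2))
    if (ncol(hw) > 1 && any(hw[, -1, drop = FALSE] != hw[, 1]))
      msg <- c(msg, "all channels must share the frame shape")
    if (any(vapply(dims, function(d) d[3], 1) != length(object@timeGrid)))
      msg <- c(msg, "third dimension must match the time grid length")
  }
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (is.unsorted(object@timeGrid, strictly = TRUE))
    msg <- c(msg, "timeGrid must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Per-cell background-subtracted intensity traces
#'
#' For each tracked cell and time point, the mask-mean green intensity
#' (\code{iCell}), the mean green intensity over the cell's anchor excluding
#' the mask (\code{iBack}), and derived quantities: the background-subtracted
#' signal I = iCell - iBack and its change from the first frame,
#' delta-I(t) = I(t) - I(0).
#'
#' @slot timeGrid acquisition times, hours.
#' @slot iCell,iBack numeric matrices (cells x time points).
#' @slot cellData data.frame of per-cell metadata (trackId, anchorId,
#'   frame-0 centroid/area/diameter, truth columns when available).
#' @export
setClass("CellTraceSet",
  representation(timeGrid = "numeric", iCell = "matrix", iBack = "matrix",
                 cellData = "data.frame")
)

setValidity("CellTraceSet", function(object) {
  msg <- character()
  if (!identical(dim(object@iCell), dim(object@iBack)))
    msg <- c(msg, "iCell and iBack must have identical dimensions")
  if (ncol(object@iCell) != length(object@timeGrid))
    msg <- c(msg, "trace length must match the time grid")
  if (nrow(object@iCell) != nrow(object@cellData))
    msg <- c(msg, "cellData must have one row per trace")
  if (length(msg)) msg else TRUE
})

#' High-producer classification of a cell population
#'
#' Result of thresholding the final-time delta-I distribution: the
#' asymmetry-derived threshold, per-cell HP/LP labels, the HP percentage and
#' the mean delta-I time course of each subgroup (the HP curve is the HP
#' specific productivity).
#'
#' @slot threshold delta-I threshold T.
#' @slot finalTime time point used for labeling, hours.
#' @slot timeGrid acquisition times, hours.
#' @slot labels data.frame (trackId, deltaIFinal, isHp).
#' @slot hpPercentage 100 x nHP / n.
#' @slot hpMeanDeltaI,lpMeanDeltaI per-time subgroup means (all-NA when a
#'   subgroup is empty).
#' @export
setClass("HPClassification",
  representation(threshold = "numeric", finalTime = "numeric",
                 timeGrid = "numeric", labels = "data.frame",
                 hpPercentage = "numeric",
                 hpMeanDeltaI = "numeric", lpMeanDeltaI = "numeric")
)

setValidity("HPClassification", function(object) {
  msg <- character()
  need <- c("trackId", "deltaIFinal", "isHp")
  if (!all(need %in% names(object@labels)))
    msg <- c(msg, "labels must contain trackId, deltaIFinal, isHp")
  else {
    pct <- 100 * mean(object@labels$isHp)
    if (nrow(object@labels) && abs(pct - object@hpPercentage) > 1e-8)
      msg <- c(msg, "hpPercentage inconsistent with labels")
  }
  if (length(msg)) msg else TRUE
})

#' Nonparametric group comparison result
#'
#' Container for the rank-based tests used to compare experimental groups
#' (Kruskal-Wallis for multiple groups, Wilcoxon rank-sum for pairs) and for
#' effect summaries such as the HP/LP mean-area ratio.
#'
#' @slot method test name.
#' @slot statistic named test statistic.
#' @slot pValue p value in [0, 1].
#' @slot effect named numeric effect summaries (possibly empty).
#' @slot groupSizes named integer group sizes.
#' @export
setClass("GroupComparison",
  representation(method = "character", statistic = "numeric",
                 pValue = "numeric", effect = "numeric",
                 groupSizes = "integer")
)

setValidity("GroupComparison", function(object) {
  if (length(object@pValue) == 1 && !is.na(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1))
    "pValue must lie in [0, 1]" else TRUE
})
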