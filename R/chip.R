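#' Build an anchor-array chip layout
#'
#' Places rows x cols anchors on a regular grid. The anchor at (row r,
#' column c) has center ((c - 0.5) pitch, (r - 0.5) pitch) um and id
#' (r - 1) * cols + c (row-major from 1). The field of view is the grid
#' bounding box.
#'
#' @param rows,cols grid dimensions.
#' @param pitch center-to-center spacing, um; must exceed 2 * anchorRadius.
#' @param anchorRadius anchor radius, um.
#' @param dropletVolume trapped droplet volume, nL.
#' @return a [ChipLayout-class].
#' @examples
#' nAnchors(chipLayout(65, 23))  # the 1495-anchor production chip
#' @export
chipLayout <- function(rows = 65, cols = 23, pitch = 300,
                       anchorRadius = 68.7, dropletVolume = 2) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  col <- rep(seq_len(cols), times = rows)
  row <- rep(seq_len(rows), each = cols)
  centers <- cbind(x = (col - 0.5) * pitch, y = (row - 0.5) * pitch)
  new("ChipLayout", rows = rows, cols = cols, pitch = pitch,
      anchorRadius = anchorRadius, dropletVolume = dropletVolume,
      centers = centers, fieldOfView = c(cols * pitch, rows * pitch))
}

#' Chip layout presets
#'
#' \code{"default"} is the physical production chip: 65 x 23 = 1495 anchors
#' at 300 um pitch, 68.7 um anchor radius, 2 nL droplets. \code{"imaging"}
#' keeps the 1495-anchor grid but compacts the raster (70 um pitch, 30 um
#' anchor radius) so that full-chip synthetic stacks stay tractable; it is
#' the default geometry of the synthetic time-lapse generator.
#'
#' @param name one of "default", "imaging".
#' @return a [ChipLayout-class].
#' @export
chipLayoutPreset <- function(name = c("default", "imaging")) {
  switch(match.arg(name),
    default = chipLayout(65, 23, pitch = 300, anchorRadius = 68.7),
    imaging = chipLayout(65, 23, pitch = 70, anchorRadius = 30))
}

#' @rdname ChipLayout-class
#' @export
setMethod("nAnchors", "ChipLayout", function(x) x@rows * x@cols)

#' @rdname ChipLayout-class
#' @export
setMethod("anchorCenters", "ChipLayout", function(x) x@centers)

#' @rdname ChipLayout-class
#' @export
setMethod("anchorRadius", "ChipLayout", function(x) x@anchorRadius)

#' @rdname ChipLayout-class
#' @export
setMethod("dropletVolume", "ChipLayout", function(x) x@dropletVolume)

setMethod("show", "ChipLayout", function(object) {
  cat(sprintf(
    "ChipLayout: %d x %d grid (%d anchors), pitch %g um, radius %g um, %g nL droplets\n",
    object@rows, object@cols, nAnchors(object), object@pitch,
    object@anchorRadius, object@dropletVolume))
})

#' @describeIn OccupancyTable-class Construct an occupancy table from counts.
#' @param counts integer cells per anchor.
#' @param lambda generating Poisson mean, if known.
#' @export
occupancyTable <- function(counts, lambda = NA_real_) {
  new("OccupancyTable", anchorId = seq_along(counts),
      counts = as.integer(counts), lambda = lambda)
}

#' @rdname OccupancyTable-class
#' @export
setMethod("occupancyCounts", "OccupancyTable", function(x) x@counts)

setMethod("show", "OccupancyTable", function(object) {
  cat(sprintf("OccupancyTable: %d anchors, %d cells (mean %.3f)\n",
              length(object@counts), sum(object@counts),
              mean(object@counts)))
})

#' @rdname OccupancyTable-class
#' @param row.names,optional,... passed on conventions of as.data.frame.
#' @export
as.data.frame.OccupancyTable <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(anchorId = x@anchorId, nCells = x@counts)
}

#' Poisson loading of a chip
#'
#' Draws i.i.d. Poisson(lam) cell counts, one per anchor, emulating random
#' encapsulation of suspension cells into the trapped droplets.
#'
#' @param layout a [ChipLayout-class].
#' @param lam mean cells per droplet (the production condition is 0.45).
#' @param seed optional integer for reproducibility.
#' @return an [OccupancyTable-class].
#' @export
poissonLoad <- function(layout, lam = 0.45, seed = NULL) {
  stopifnot(is(layout, "ChipLayout"))
  assertScalarNumber(lam, "lam", 0)
  counts <- withSeed(seed, stats::rpois(nAnchors(layout), lam))
  occupancyTable(counts, lambda = lam)
}

#' Fit a Poisson law to droplet occupancies
#'
#' Maximum-likelihood fit of the cells-per-droplet distribution: the MLE of
#' the Poisson mean is the sample mean. Returns the estimate together with
#' the observed histogram and fitted probabilities.
#'
#' @param x an [OccupancyTable-class] or integer vector of counts.
#' @return list with \code{lambdaHat} and a data.frame \code{table}
#'   (k, observed, expected) covering 0..max(count).
#' @export
fitPoisson <- function(x) {
  counts <- if (is(x, "OccupancyTable")) occupancyCounts(x) else as.integer(x)
  stopIf(length(counts) == 0L, "empty occupancy table")
  stopIf(any(counts < 0L), "counts must be non-negative")
  lambdaHat <- mean(counts)
  k <- 0:max(counts, 1L)
  tab <- data.frame(
    k = k,
    observed = as.integer(tabulate(counts + 1L, nbins = length(k))),
    expected = length(counts) * stats::dpois(k, lambdaHat))
  list(lambdaHat = lambdaHat, table = tab)
}

#' Poisson occupancy probability
#'
#' P(k cells in a droplet) = exp(-lam) lam^k / k! under Poisson loading.
#' At the production loading lam = 0.45, P(1) = 0.287 -- the "about 30\%"
#' of droplets containing exactly one cell that enter single-cell analysis.
#'
#' @param lam mean cells per droplet, >= 0.
#' @param k cell count(s), non-negative integer(s).
#' @return probability vector.
#' @export
occupancyProbability <- function(lam, k) {
  assertScalarNumber(lam, "lam", 0)
  stopIf(any(k < 0) || any(k != round(k)), "k must be non-negative integer")
  stats::dpois(round(k), lam)
}

#' Select droplets containing exactly one cell
#'
#' Returns the ids of anchors whose droplet holds a single cell; only these
#' enter the downstream single-cell analysis.
#'
#' @param x an [OccupancyTable-class], or an integer vector of per-anchor
#'   counts (detection-derived counts work equally).
#' @return integer anchor ids.
#' @export
selectSingleCellDroplets <- function(x) {
  if (is(x, "OccupancyTable")) x@anchorId[x@counts == 1L]
  else which(as.integer(x) == 1L)
}
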