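# nearest-anchor assignment: anchor id containing each centroid, NA when the
# point lies outside every anchor disk
assignAnchor <- function(x, y, layout) {
  col <- pmin(pmax(ceiling(x / layout@pitch), 1L), layout@cols)
  row <- pmin(pmax(ceiling(y / layout@pitch), 1L), layout@rows)
  id <- (row - 1L) * layout@cols + col
  ctr <- anchorCenters(layout)[id, , drop = FALSE]
  inside <- (x - ctr[, 1])^2 + (y - ctr[, 2])^2 <= anchorRadius(layout)^2
  ifelse(inside, id, NA_integer_)
}

# linear pixel indices of one anchor disk
anchorPixelIndex <- function(layout, anchorId, h, w, pixelSize) {
  ctr <- anchorCenters(layout)[anchorId, ]
  diskPixels(ctr[1], ctr[2], 2 * anchorRadius(layout), h, w, pixelSize)
}

# logical h x w mask of pixels outside every anchor disk
outsideAnchorMask <- function(layout, h, w, pixelSize) {
  mask <- matrix(TRUE, h, w)
  for (a in seq_len(nAnchors(layout)))
    mask[anchorPixelIndex(layout, a, h, w, pixelSize)] <- FALSE
  mask
}

#' Size gate for segmented objects
#'
#' Objects with an equivalent diameter between \code{minDiameter} and
#' \code{maxDiameter} um (inclusive at both bounds) are considered cells.
#'
#' @param eqDiameter equivalent diameter(s), um.
#' @param minDiameter,maxDiameter gate bounds, um (defaults 10 and 25).
#' @return logical vector.
#' @export
withinSizeGate <- function(eqDiameter, minDiameter = 10, maxDiameter = 25) {
  eqDiameter >= minDiameter & eqDiameter <= maxDiameter
}

#' Detect cells in one tracker-channel frame
#'
#' The red (cell tracker) frame is thresholded (global Otsu by default),
#' connected components are extracted, and components are kept when their
#' equivalent diameter -- the diameter of the circle with the component's
#' area -- lies within the size gate and their centroid falls inside an
#' anchor. Components outside every anchor are dropped.
#'
#' @param frame numeric/integer matrix (one red-channel frame).
#' @param layout the [ChipLayout-class].
#' @param pixelSize um per pixel.
#' @param minDiameter,maxDiameter size gate, um.
#' @param threshold fixed global threshold in counts, or NULL for Otsu.
#' @return data.frame (label, x, y, areaUm2, eqDiameterUm, anchorId) with a
#'   \code{pixels} list-column of linear pixel indices per cell. A blank or
#'   saturated frame yields zero rows with a warning.
#' @export
detectCells <- function(frame, layout, pixelSize = 2,
                        minDiameter = 10, maxDiameter = 25,
                        threshold = NULL) {
  empty <- data.frame(label = integer(), x = numeric(), y = numeric(),
                      areaUm2 = numeric(), eqDiameterUm = numeric(),
                      anchorId = integer())
  empty$pixels <- list()
  rng <- range(frame)
  if (diff(rng) < 1e-8) {
    warning("blank or saturated frame: no detections")
    return(empty)
  }
  if (is.null(threshold)) {
    im <- EBImage::Image((frame - rng[1]) / diff(rng))
    threshold <- rng[1] + diff(rng) *
      EBImage::otsu(im, range = c(0, 1), levels = 256L)
  }
  bw <- frame > threshold
  if (!any(bw) || all(bw)) {
    warning("thresholding left no foreground/background: no detections")
    return(empty)
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
  nLab <- max(lab)
  if (nLab == 0) return(empty)
  idx <- which(lab > 0)
  lv <- lab[idx]
  areaPx <- tabulate(lv, nbins = nLab)
  h <- nrow(frame)
  ii <- (idx - 1L) %% h + 1L
  jj <- (idx - 1L) %/% h + 1L
  cx <- (rowsum(jj, lv)[, 1] / areaPx - 0.5) * pixelSize
  cy <- (rowsum(ii, lv)[, 1] / areaPx - 0.5) * pixelSize
  areaUm2 <- areaPx * pixelSize^2
  eqD <- 2 * sqrt(areaUm2 / pi)
  keep <- withinSizeGate(eqD, minDiameter, maxDiameter)
  anchorId <- assignAnchor(cx, cy, layout)
  keep <- keep & !is.na(anchorId)
  out <- data.frame(label = seq_len(nLab), x = cx, y = cy,
                    areaUm2 = areaUm2, eqDiameterUm = eqD,
                    anchorId = anchorId)[keep, , drop = FALSE]
  out$pixels <- unname(split(idx, lv))[keep]
  rownames(out) <- NULL
  out
}

#' Detect cells in every frame of a stack
#'
#' Runs [detectCells()] on each red-tracker frame and binds the results
#' with a \code{frame} index column.
#'
#' @param stack a [TimeLapseStack-class].
#' @param layout the [ChipLayout-class].
#' @param channel channel used for detection.
#' @param ... passed to [detectCells()].
#' @return data.frame of per-frame detections.
#' @export
detectCellsStack <- function(stack, layout, channel = "red_tracker", ...) {
  arr <- getChannel(stack, channel)
  res <- lapply(seq_len(dim(arr)[3]), function(t) {
    d <- detectCells(arr[, , t], layout, pixelSize = stack@pixelSize, ...)
    if (nrow(d)) d$frame <- t
    else d$frame <- integer(0)
    d
  })
  do.call(rbind, res)
}

#' Track detections across frames
#'
#' Cells are agarose-immobilized, so tracking is greedy nearest-centroid
#' matching within each anchor: for every frame, detections are matched to
#' existing tracks in ascending order of distance to the track's last
#' centroid, accepting matches within \code{matchRadius}; ties go to the
#' smaller distance, then to the smaller track id. Unmatched detections
#' start new tracks. Tracks detected in fewer than
#' \code{minCompleteness} x nFrames frames are discarded.
#'
#' @param detections multi-frame detections from [detectCellsStack()].
#' @param nFrames total number of frames in the acquisition.
#' @param matchRadius maximum centroid displacement, um.
#' @param minCompleteness minimum fraction of frames with a detection.
#' @return data.frame of track-assigned detections (columns of
#'   \code{detections} plus trackId and completeness).
#' @export
trackCells <- function(detections, nFrames, matchRadius = 10,
                       minCompleteness = 0.9) {
  stopIf(nFrames < 1, "nFrames must be >= 1")
  if (!nrow(detections)) {
    out <- detections
    out$trackId <- integer(0)
    out$completeness <- numeric(0)
    return(out)
  }
  detections$trackId <- NA_integer_
  nextId <- 1L
  lastPos <- list()  # trackId -> c(x, y, anchorId)
  for (f in sort(unique(detections$frame))) {
    rows <- which(detections$frame == f)
    if (length(lastPos)) {
      tids <- as.integer(names(lastPos))
      pos <- do.call(rbind, lastPos)
      # candidate pairs within the same anchor and radius
      cand <- NULL
      for (k in seq_along(rows)) {
        r <- rows[k]
        same <- which(pos[, 3] == detections$anchorId[r])
        if (!length(same)) next
        d <- sqrt((pos[same, 1] - detections$x[r])^2 +
                    (pos[same, 2] - detections$y[r])^2)
        ok <- d <= matchRadius
        if (any(ok))
          cand <- rbind(cand, cbind(row = r, tid = tids[same[ok]],
                                    dist = d[ok]))
      }
      if (!is.null(cand)) {
        cand <- cand[order(cand[, "dist"], cand[, "tid"]), , drop = FALSE]
        usedRow <- integer(0); usedTid <- integer(0)
        for (k in seq_len(nrow(cand))) {
          r <- cand[k, "row"]; tid <- cand[k, "tid"]
          if (r %in% usedRow || tid %in% usedTid) next
          detections$trackId[r] <- tid
          usedRow <- c(usedRow, r); usedTid <- c(usedTid, tid)
        }
      }
    }
    for (r in rows) {
      if (is.na(detections$trackId[r])) {
        detections$trackId[r] <- nextId
        nextId <- nextId + 1L
      }
      lastPos[[as.character(detections$trackId[r])]] <-
        c(detections$x[r], detections$y[r], detections$anchorId[r])
    }
  }
  compl <- table(detections$trackId) / nFrames
  detections$completeness <- as.numeric(compl[as.character(detections$trackId)])
  out <- detections[detections$completeness >= minCompleteness, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score cell viability from the Live/Dead channel pair
#'
#' A cell is scored dead when the mean dead-stain signal over its mask
#' exceeds the dead-channel background mean plus 3 background standard
#' deviations; the background is measured over pixels outside every anchor.
#' Viability is 1 - dead/total.
#'
#' @param deadFrame dead-stain channel frame (matrix).
#' @param detections single-frame detections (with \code{pixels} masks),
#'   typically at the endpoint acquisition.
#' @param layout the [ChipLayout-class].
#' @param pixelSize um per pixel.
#' @param nSd threshold in background standard deviations.
#' @return list with \code{viability} (NA when there are no detections) and
#'   \code{flags} data.frame (label/trackId columns carried over, isDead).
#' @export
scoreViability <- function(deadFrame, detections, layout, pixelSize = 2,
                           nSd = 3) {
  if (!nrow(detections))
    return(list(viability = NA_real_,
                flags = data.frame(isDead = logical())))
  bg <- deadFrame[outsideAnchorMask(layout, nrow(deadFrame),
                                    ncol(deadFrame), pixelSize)]
  thr <- mean(bg) + nSd * stats::sd(bg)
  sig <- vapply(detections$pixels, function(px) mean(deadFrame[px]), 0)
  isDead <- sig > thr
  flags <- detections[, setdiff(names(detections), "pixels"), drop = FALSE]
  flags$deadSignal <- sig
  flags$isDead <- isDead
  list(viability = 1 - mean(isDead), flags = flags)
}
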