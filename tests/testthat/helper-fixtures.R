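# Shared fixtures: small chips and fast parameter sets used across tests.

smallLayout <- function(rows = 10, cols = 10)
  chipLayout(rows, cols, pitch = 70, anchorRadius = 30)

# single-frame imaging for segmentation-only tests
snapshotParams <- function(...) imagingParams(timeGrid = 0, ...)

# match detections to truth cells by nearest centroid within `radius` um;
# returns logical vectors (truth matched, detection matched)
matchToTruth <- function(det, truth, radius = 5) {
  matchedTruth <- rep(FALSE, nrow(truth))
  matchedDet <- rep(FALSE, nrow(det))
  if (!nrow(det) || !nrow(truth))
    return(list(truth = matchedTruth, det = matchedDet))
  for (k in seq_len(nrow(det))) {
    d <- sqrt((truth$x - det$x[k])^2 + (truth$y - det$y[k])^2)
    i <- which.min(d)
    if (d[i] <= radius && !matchedTruth[i]) {
      matchedTruth[i] <- TRUE
      matchedDet[k] <- TRUE
    }
  }
  list(truth = matchedTruth, det = matchedDet)
}

# truth cells the size gate should retain
inGate <- function(truth, lo = 10, hi = 25)
  truth$diameter >= lo & truth$diameter <= hi
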