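test_that("blank frames yield no detections, with a warning", {
  lay <- smallLayout(2, 2)
  expect_warning(d <- detectCells(matrix(100, 70, 70), lay), "blank")
  expect_equal(nrow(d), 0L)
})

test_that("noise-free detection recovers every in-gate cell exactly", {
  lay <- smallLayout(4, 4)
  truth <- generatePopulation(lay, conditionPreset("R5", lam = 0.6,
                                                   viability = 1),
                              seed = 21)
  stack <- renderTimelapse(truth, lay, noiseFree(snapshotParams()))
  det <- detectCells(getChannel(stack, "red_tracker")[, , 1], lay,
                     pixelSize = 2)
  keep <- inGate(truth)
  expect_equal(nrow(det), sum(keep))
  m <- matchToTruth(det, truth[keep, ], radius = 2)  # centroids within 1 px
  expect_true(all(m$truth))
  expect_true(all(m$det))
})

test_that("the size gate is inclusive at 10 and 25 um and rejects outside", {
  expect_true(withinSizeGate(10))
  expect_true(withinSizeGate(25))
  expect_false(withinSizeGate(10 - 1e-9))
  expect_false(withinSizeGate(25 + 1e-9))

  # rendered disks: 8 um is excluded, 26 um (above gate) excluded, 13 kept
  lay <- smallLayout(1, 3)
  truth <- data.frame(cellId = 1:3, anchorId = 1:3,
                      x = c(35, 105, 175), y = 35,
                      diameter = c(8, 13, 26), isHp = FALSE, slope = 1,
                      baseline = 150, isViable = TRUE)
  stack <- renderTimelapse(truth, lay, noiseFree(snapshotParams()))
  det <- detectCells(getChannel(stack, "red_tracker")[, , 1], lay,
                     pixelSize = 2)
  expect_equal(nrow(det), 1L)
  expect_equal(det$anchorId, 2L)
  expect_equal(det$eqDiameterUm, 13, tolerance = 0.1)
})

test_that("segmentation precision and recall exceed 0.95 at default noise", {
  tp <- fp <- fn <- 0
  for (s in 1:5) {
    lay <- smallLayout(10, 10)
    truth <- generatePopulation(lay, conditionPreset("R5", viability = 1),
                                seed = 400 + s)
    stack <- renderTimelapse(truth, lay, snapshotParams(), seed = 500 + s)
    det <- detectCells(getChannel(stack, "red_tracker")[, , 1], lay,
                       pixelSize = 2)
    gated <- truth[inGate(truth), ]
    m <- matchToTruth(det, gated, radius = 5)
    tp <- tp + sum(m$det)
    fp <- fp + sum(!m$det)
    fn <- fn + sum(!m$truth)
  }
  expect_gte(tp / (tp + fp), 0.95)  # precision
  expect_gte(tp / (tp + fn), 0.95)  # recall
})

test_that("per-anchor detected counts remain Poisson", {
  counts <- integer(0)
  for (s in 1:3) {
    lay <- smallLayout(10, 10)
    truth <- generatePopulation(lay, conditionPreset("R5", viability = 1),
                                seed = 600 + s)
    stack <- renderTimelapse(truth, lay, snapshotParams(), seed = 700 + s)
    det <- detectCells(getChannel(stack, "red_tracker")[, , 1], lay,
                       pixelSize = 2)
    perAnchor <- integer(nAnchors(lay))
    tab <- table(det$anchorId)
    perAnchor[as.integer(names(tab))] <- as.integer(tab)
    counts <- c(counts, perAnchor)
  }
  lam <- mean(counts)
  kmax <- 3
  obs <- c(tabulate(pmin(counts, kmax) + 1L, nbins = kmax + 1L))
  p <- c(dpois(0:(kmax - 1), lam), 1 - ppois(kmax - 1, lam))
  chi2 <- sum((obs - length(counts) * p)^2 / (length(counts) * p))
  pval <- pchisq(chi2, df = kmax - 1, lower.tail = FALSE)  # lambda estimated
  expect_gt(pval, 0.01)
})

test_that("tracking keeps static cells and tolerates one missing frame", {
  lay <- smallLayout(3, 3)
  truth <- generatePopulation(lay, conditionPreset("R5", lam = 0.5,
                                                   viability = 1),
                              seed = 31)
  prm <- imagingParams(timeGrid = seq(0, 62, 2))
  stack <- renderTimelapse(truth, lay, prm, seed = 31)
  det <- detectCellsStack(stack, lay)
  tracks <- trackCells(det, nFrames = 32)

  # one track per in-gate cell, all complete, no cross-anchor merges
  gated <- truth[inGate(truth), ]
  singles <- names(which(table(gated$anchorId) == 1))
  tr1 <- tracks[tracks$anchorId %in% as.integer(singles), ]
  expect_equal(length(unique(tr1$trackId)),
               length(singles))
  expect_true(all(tr1$completeness == 1))
  byTrack <- tapply(tr1$anchorId, tr1$trackId, function(a)
    length(unique(a)))
  expect_true(all(byTrack == 1))

  # drop one frame of one track: completeness 31/32 >= 0.9, still kept
  tid <- tr1$trackId[1]
  det2 <- det[!(det$anchorId == tr1$anchorId[1] & det$frame == 16L), ]
  tracks2 <- trackCells(det2, nFrames = 32)
  kept <- tracks2[tracks2$anchorId == tr1$anchorId[1], ]
  expect_equal(unique(kept$completeness), 31 / 32)

  # remove 5 frames: completeness 27/32 < 0.9, discarded
  det3 <- det[!(det$anchorId == tr1$anchorId[1] & det$frame %in% 10:14), ]
  tracks3 <- trackCells(det3, nFrames = 32)
  expect_equal(nrow(tracks3[tracks3$anchorId == tr1$anchorId[1], ]), 0L)
})

test_that("viability scoring recovers the generator truth", {
  lay <- smallLayout(18, 18)
  truth <- generatePopulation(lay, conditionPreset("R5", viability = 0.8,
                                                   lam = 0.8),
                              seed = 41)
  stack <- renderTimelapse(truth, lay, snapshotParams(), seed = 41)
  det <- detectCells(getChannel(stack, "red_tracker")[, , 1], lay,
                     pixelSize = 2)
  vs <- scoreViability(getChannel(stack, "red_dead")[, , 1], det, lay,
                       pixelSize = 2)
  # compare to the truth viability of gated cells
  gated <- truth[inGate(truth), ]
  n <- nrow(gated)
  p <- mean(gated$isViable)
  expect_gt(n, 150)
  expect_lt(abs(vs$viability - p), 2.58 * sqrt(p * (1 - p) / n) + 0.02)

  # degenerate inputs
  lay1 <- smallLayout(1, 1)
  stack1 <- renderTimelapse(
    data.frame(cellId = 1L, anchorId = 1L, x = 35, y = 35, diameter = 15,
               isHp = FALSE, slope = 1, baseline = 150, isViable = TRUE),
    lay1, noiseFree(snapshotParams()))
  det1 <- detectCells(getChannel(stack1, "red_tracker")[, , 1], lay1,
                      pixelSize = 2)
  vsAlive <- scoreViability(matrix(rnorm(35 * 35, 100, 1), 35, 35),
                            det1, lay1, pixelSize = 2)
  expect_equal(vsAlive$viability, 1)

  none <- scoreViability(matrix(100, 35, 35), det1[0, ], lay1,
                         pixelSize = 2)
  expect_true(is.na(none$viability))
})
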