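# builds a rendered one-cell stack plus its tracks, for trace arithmetic
oneCellRun <- function(baseline = 250, slope = 0, timeGrid = c(0, 2, 4),
                       params = NULL) {
  lay <- smallLayout(1, 1)
  truth <- data.frame(cellId = 1L, anchorId = 1L, x = 35, y = 35,
                      diameter = 16, isHp = FALSE, slope = slope,
                      baseline = baseline, isViable = TRUE)
  if (is.null(params)) params <- noiseFree(imagingParams(timeGrid = timeGrid))
  stack <- renderTimelapse(truth, lay, params)
  det <- detectCellsStack(stack, lay)
  tracks <- trackCells(det, nFrames = length(params$timeGrid))
  list(lay = lay, truth = truth, stack = stack, tracks = tracks)
}

test_that("trace extraction does the background-subtraction arithmetic", {
  # disk at 250 counts over a 100-count background: I = 150 at every frame
  r <- oneCellRun(baseline = 250, slope = 0)
  traces <- extractTraces(r$tracks, r$stack, r$lay)
  expect_equal(nCells(traces), 1L)
  expect_equal(as.vector(intensity(traces)), rep(150, 3))
  expect_equal(as.vector(deltaIntensity(traces)), rep(0, 3))

  # uniform frame: mask mean equals background mean, I = 0
  u <- r$stack
  u@channels$green_gfp[] <- 500L
  tu <- extractTraces(r$tracks, u, r$lay)
  expect_equal(as.vector(intensity(tu)), rep(0, 3))
})

test_that("zero-noise slopes are recovered exactly", {
  lay <- smallLayout(4, 4)
  truth <- generatePopulation(lay, conditionPreset("R5", viability = 1,
                                                   lam = 0.5), seed = 51)
  prm <- noiseFree(imagingParams(timeGrid = seq(0, 62, 2)))
  stack <- renderTimelapse(truth, lay, prm)
  det <- detectCellsStack(stack, lay)
  tracks <- trackCells(det, nFrames = 32)
  traces <- extractTraces(tracks, stack, lay)
  fits <- fitKinetics(traces)

  # delta-I(0) = 0 identically; I(t) - I(0) = slope * t exactly
  dI <- deltaIntensity(traces)
  expect_true(all(dI[, 1] == 0))
  # single-cell anchors only: another producer in the same anchor would
  # (correctly) contribute to that anchor's background
  cd <- cellData(traces)
  singles <- as.integer(names(which(table(truth$anchorId) == 1)))
  ks <- which(cd$anchorId %in% singles)
  expect_gt(length(ks), 2)
  for (k in ks) {
    cand <- truth[truth$anchorId == cd$anchorId[k], ]
    expect_equal(fits$slope[k], cand$slope, tolerance = 1e-9)
    expect_equal(dI[k, ], cand$slope * timeGrid(traces),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("a global additive offset leaves I, delta-I and slopes unchanged", {
  r <- oneCellRun(baseline = 250, slope = 4,
                  params = imagingParams(timeGrid = c(0, 2, 4, 6)))
  traces <- extractTraces(r$tracks, r$stack, r$lay)
  shifted <- r$stack
  shifted@channels$green_gfp <- shifted@channels$green_gfp + 500L
  traces2 <- extractTraces(r$tracks, shifted, r$lay)
  expect_equal(intensity(traces2), intensity(traces))
  expect_equal(deltaIntensity(traces2), deltaIntensity(traces))
  expect_equal(fitKinetics(traces2)$slope, fitKinetics(traces)$slope)
})

test_that("delta-trace arithmetic", {
  expect_equal(deltaTrace(c(10, 30, 70)), c(0, 20, 60))
  expect_equal(deltaTrace(rep(7, 5)), rep(0, 5))
  expect_equal(deltaTrace(c(3, 1))[1], 0)
})

test_that("linear fitting: exact lines, degenerate traces, input checks", {
  t <- seq(0, 62, 2)
  f <- fitLinear(t, 5 * t)
  expect_equal(f$slope, 5, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)

  fc <- fitLinear(t, rep(3, length(t)))
  expect_equal(fc$slope, 0)
  expect_equal(fc$r2, 0)

  expect_error(fitLinear(c(0, 2), c(1, 2)), "at least 3")
})

test_that("population summaries: means, mean deviation, mixture identity", {
  tg <- c(0, 2)
  one <- cellTraceSet(iCell = matrix(c(100, 110), 1),
                      iBack = matrix(100, 1, 2), timeGrid = tg)
  s1 <- summarizePopulation(one)
  expect_equal(s1$meanDeltaI, c(0, 10))
  expect_equal(s1$meanDeviation, c(0, 0))

  two <- cellTraceSet(iCell = rbind(c(100, 110), c(100, 130)),
                      iBack = matrix(100, 2, 2), timeGrid = tg)
  s2 <- summarizePopulation(two)
  expect_equal(s2$meanDeltaI, c(0, 20))
  expect_equal(s2$meanDeviation, c(0, 10))

  expect_error(summarizePopulation(cellTraceSet(
    matrix(0, 0, 2), matrix(0, 0, 2), tg,
    cellData = data.frame(trackId = integer()))), "empty")

  # whole-population mean is the prevalence-weighted subgroup mixture
  lay <- smallLayout(14, 14)
  truth <- generatePopulation(lay, conditionPreset("R5", viability = 1),
                              seed = 61)
  traces <- simulateTraceSet(truth, seed = 61)
  cls <- classifyHP(traces)
  labs <- hpLabels(cls)
  p <- mean(labs$isHp)
  mixture <- p * cls@hpMeanDeltaI + (1 - p) * cls@lpMeanDeltaI
  expect_equal(mixture, summarizePopulation(traces)$meanDeltaI,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("default-noise traces are near-linear (median r2 > 0.9)", {
  lay <- smallLayout(14, 14)
  truth <- generatePopulation(lay, conditionPreset("R5", viability = 1),
                              seed = 71)
  traces <- simulateTraceSet(truth, seed = 71)
  fits <- fitKinetics(traces)
  expect_gt(median(fits$r2), 0.9)
})

test_that("short gaps are interpolated, long or edge gaps drop the track", {
  r <- oneCellRun(baseline = 200, slope = 5, timeGrid = seq(0, 20, 2),
                  params = noiseFree(imagingParams(timeGrid = seq(0, 20, 2))))
  # knock out an interior frame: linear interpolation restores the line
  tr <- r$tracks[r$tracks$frame != 5L, ]
  traces <- extractTraces(tr, r$stack, r$lay, maxGap = 1L)
  expect_equal(nCells(traces), 1L)
  expect_equal(fitKinetics(traces)$slope, 5, tolerance = 1e-9)

  # a 2-frame interior gap exceeds maxGap = 1: track discarded
  tr2 <- r$tracks[!r$tracks$frame %in% c(5L, 6L), ]
  expect_equal(nCells(extractTraces(tr2, r$stack, r$lay, maxGap = 1L)), 0L)

  # missing first frame cannot be interpolated: track discarded
  tr3 <- r$tracks[r$tracks$frame != 1L, ]
  expect_equal(nCells(extractTraces(tr3, r$stack, r$lay)), 0L)
})
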