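#' Pipeline run configuration
#'
#' Bundles everything one reproducible run needs: the condition preset, the
#' chip geometry, imaging parameters, analysis settings and the seed. The
#' configuration round-trips losslessly through YAML
#' ([writeRunConfig()] / [readRunConfig()]), and a short content hash of the
#' serialized configuration plus the seed forms the run id stamped into
#' every output filename.
#'
#' @param preset a [ConditionPreset-class] or shipped preset name.
#' @param seed integer seed driving every random stage.
#' @param outDir output directory (created on run).
#' @param layout a [ChipLayout-class]; the compact imaging preset by default.
#' @param imaging an [imagingParams()] list.
#' @param minDiameter,maxDiameter segmentation size gate, um.
#' @param matchRadius tracking match radius, um.
#' @param minCompleteness minimum track completeness.
#' @param thresholdMultiplier HP threshold multiplier.
#' @param excludeDead drop dead-scored tracks before kinetics.
#' @param writeStackFile also write the rendered stack as TIFF (large).
#' @return a classed configuration list.
#' @export
runConfig <- function(preset = "R5", seed = 1L, outDir = tempfile("run"),
                      layout = chipLayoutPreset("imaging"),
                      imaging = imagingParams(),
                      minDiameter = 10, maxDiameter = 25,
                      matchRadius = 10, minCompleteness = 0.9,
                      thresholdMultiplier = 3, excludeDead = TRUE,
                      writeStackFile = FALSE) {
  if (is.character(preset)) preset <- conditionPreset(preset)
  structure(list(preset = preset, seed = as.integer(seed), outDir = outDir,
                 layout = layout, imaging = imaging,
                 minDiameter = minDiameter, maxDiameter = maxDiameter,
                 matchRadius = matchRadius,
                 minCompleteness = minCompleteness,
                 thresholdMultiplier = thresholdMultiplier,
                 excludeDead = excludeDead,
                 writeStackFile = writeStackFile),
            class = "runConfig")
}

configAsList <- function(config) {
  p <- config$preset
  l <- config$layout
  list(
    preset = list(name = p@name, hpPrevalence = p@hpPrevalence,
                  lpSlopeMean = p@lpSlopeMean, lpSlopeSd = p@lpSlopeSd,
                  hpSlopeMultiplier = p@hpSlopeMultiplier,
                  hpDiameterMultiplier = p@hpDiameterMultiplier,
                  nonproducerFraction = p@nonproducerFraction,
                  viability = p@viability, lam = p@lam,
                  lpDiameterMean = p@lpDiameterMean,
                  lpDiameterSd = p@lpDiameterSd,
                  diameterRange = p@diameterRange,
                  baselineMean = p@baselineMean, baselineSd = p@baselineSd),
    layout = list(rows = l@rows, cols = l@cols, pitch = l@pitch,
                  anchorRadius = l@anchorRadius,
                  dropletVolume = l@dropletVolume),
    imaging = unclass(config$imaging),
    seed = config$seed,
    minDiameter = config$minDiameter, maxDiameter = config$maxDiameter,
    matchRadius = config$matchRadius,
    minCompleteness = config$minCompleteness,
    thresholdMultiplier = config$thresholdMultiplier,
    excludeDead = config$excludeDead,
    writeStackFile = config$writeStackFile)
}

#' @rdname runConfig
#' @param config a runConfig.
#' @param path YAML path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(configAsList(config), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  preset <- do.call(conditionPreset, c(list(name = x$preset$name),
                                       x$preset[-1]))
  layout <- chipLayout(x$layout$rows, x$layout$cols, x$layout$pitch,
                       x$layout$anchorRadius, x$layout$dropletVolume)
  imaging <- do.call(imagingParams, x$imaging)
  runConfig(preset = preset, seed = x$seed, outDir = dirname(path),
            layout = layout, imaging = imaging,
            minDiameter = x$minDiameter, maxDiameter = x$maxDiameter,
            matchRadius = x$matchRadius,
            minCompleteness = x$minCompleteness,
            thresholdMultiplier = x$thresholdMultiplier,
            excludeDead = x$excludeDead,
            writeStackFile = x$writeStackFile)
}

#' @rdname runConfig
#' @export
configHash <- function(config) {
  fnv1a32(yaml::as.yaml(configAsList(config)))
}

logStage <- function(quiet, ...) if (!quiet) message("[anchorTrack] ", ...)

#' Run the full simulate-segment-trace-classify pipeline
#'
#' Executes one reproducible synthetic experiment: Poisson loading and
#' ground-truth generation, time-lapse rendering, per-frame segmentation
#' with the size gate, restriction to anchors holding exactly one detected
#' cell at the first frame, tracking, viability scoring at the endpoint,
#' delta-I trace extraction and per-cell linear fits, population summary
#' and skewness series, asymmetry-threshold HP classification, and an
#' HP-vs-LP morphology comparison. All tables are written to
#' \code{config$outDir} with the run id (config hash + seed) in every
#' filename; the same configuration reproduces every output exactly.
#'
#' @param config a [runConfig()].
#' @param quiet suppress stage messages.
#' @return the run report (invisible list, also written as JSON): occupancy
#'   fit, single-cell droplet fraction, viability, fit quality, threshold,
#'   HP percentage, skewness series, group statistics, truth-recovery
#'   metrics, and output file paths.
#' @export
runPipeline <- function(config = runConfig(), quiet = FALSE) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  runId <- paste0(configHash(config), "-s", config$seed)
  fp <- function(name, ext) file.path(config$outDir,
                                      sprintf("%s-%s.%s", name, runId, ext))
  files <- list(config = fp("config", "yaml"))
  writeRunConfig(config, files$config)
  tg <- config$imaging$timeGrid
  nT <- length(tg)

  withSeed(config$seed, {
    logStage(quiet, "generating population (preset ", config$preset@name, ")")
    truth <- generatePopulation(config$layout, config$preset)
    occ <- attr(truth, "occupancy")
    pois <- fitPoisson(occ)
    files$occupancy <- fp("occupancy", "csv")
    utils::write.csv(as.data.frame(occ), files$occupancy, row.names = FALSE)
    files$truth <- fp("truth", "csv")
    writeTruth(truth, files$truth)

    logStage(quiet, "rendering ", nrow(truth), " cells, ", nT, " frames")
    stack <- renderTimelapse(truth, config$layout, config$imaging)
    if (config$writeStackFile) {
      files$stack <- fp("stack", "tif")
      writeStack(stack, files$stack)
    }

    logStage(quiet, "segmenting")
    det <- detectCellsStack(stack, config$layout,
                            minDiameter = config$minDiameter,
                            maxDiameter = config$maxDiameter)
    # single-cell droplet selection: anchors with exactly one frame-0 object
    det0 <- det[det$frame == 1L, , drop = FALSE]
    anchorCounts <- integer(nAnchors(config$layout))
    t0 <- table(det0$anchorId)
    anchorCounts[as.integer(names(t0))] <- as.integer(t0)
    singleAnchors <- selectSingleCellDroplets(anchorCounts)
    det <- det[det$anchorId %in% singleAnchors, , drop = FALSE]
    files$detections <- fp("detections", "csv")
    utils::write.csv(det[, setdiff(names(det), "pixels")],
                     files$detections, row.names = FALSE)

    logStage(quiet, "tracking ", length(singleAnchors),
             " single-cell anchors")
    tracks <- trackCells(det, nFrames = nT,
                         matchRadius = config$matchRadius,
                         minCompleteness = config$minCompleteness)

    viability <- NA_real_
    if (nrow(tracks)) {
      lastFrame <- max(tracks$frame)
      endDet <- tracks[tracks$frame == lastFrame, , drop = FALSE]
      vs <- scoreViability(getChannel(stack, "red_dead")[, , nT], endDet,
                           config$layout, pixelSize = stack@pixelSize)
      viability <- vs$viability
      if (config$excludeDead) {
        deadIds <- vs$flags$trackId[vs$flags$isDead]
        tracks <- tracks[!tracks$trackId %in% deadIds, , drop = FALSE]
      }
    }
    files$tracks <- fp("tracks", "csv")
    utils::write.csv(tracks[, setdiff(names(tracks), "pixels")],
                     files$tracks, row.names = FALSE)

    logStage(quiet, "extracting traces")
    traces <- extractTraces(tracks, stack, config$layout)
    n <- nCells(traces)

    report <- list(
      runId = runId, seed = config$seed, preset = config$preset@name,
      nAnchors = nAnchors(config$layout),
      lambdaHat = pois$lambdaHat,
      singleCellFraction = mean(occupancyCounts(occ) == 1L),
      nSingleCellAnchors = length(singleAnchors),
      viability = viability,
      nTraces = n)

    if (n == 0L) {
      logStage(quiet, "no analyzable droplets; writing empty results")
      report$hpPercentage <- NA_real_
      files$report <- fp("report", "json")
      jsonlite::write_json(report, files$report, auto_unbox = TRUE,
                           digits = NA, na = "null")
      report$files <- files
      return(invisible(report))
    }

    fits <- fitKinetics(traces)
    popSummary <- summarizePopulation(traces)
    report$medianR2 <- stats::median(fits$r2)
    report$skewnessSeries <- popSummary[, c("time", "skewness")]
    report$meanDeltaIFinal <- popSummary$meanDeltaI[nT]

    classification <- NULL
    if (n >= 30L) {
      logStage(quiet, "classifying high producers (", n, " traces)")
      thr <- computeThreshold(deltaIntensity(traces)[, nT],
                              multiplier = config$thresholdMultiplier)
      classification <- classifyHP(traces, threshold = thr)
      report$threshold <- hpThreshold(classification)
      report$hpPercentage <- hpPercentage(classification)
      report$nHp <- sum(hpLabels(classification)$isHp)
      report$hpSpecificProductivityFinal <-
        classification@hpMeanDeltaI[nT]
      labs <- hpLabels(classification)
      if (any(labs$isHp) && any(!labs$isHp)) {
        morph <- compareMorphology(labs$isHp, cellData(traces)$areaUm2)
        report$groupStats <- list(
          areaRatio = unname(morph@effect["areaRatio"]),
          areaWilcoxonP = morph@pValue)
      }
      # truth recovery: match traces to truth cells by anchor + centroid
      rec <- recoverTruthLabels(traces, truth, labs)
      report$recovery <- rec
    } else {
      report$hpPercentage <- NA_real_
    }

    # long-format traces with labels merged
    I <- intensity(traces); dI <- deltaIntensity(traces)
    cd <- cellData(traces)
    long <- data.frame(
      trackId = rep(cd$trackId, each = nT),
      anchorId = rep(cd$anchorId, each = nT),
      t_h = rep(tg, times = n),
      iCell = as.vector(t(traces@iCell)),
      iBack = as.vector(t(traces@iBack)),
      I = as.vector(t(I)), dI = as.vector(t(dI)))
    if (!is.null(classification)) {
      labMap <- stats::setNames(hpLabels(classification)$isHp,
                                hpLabels(classification)$trackId)
      long$isHp <- unname(labMap[as.character(long$trackId)])
    }
    files$traces <- fp("traces", "csv")
    utils::write.csv(long, files$traces, row.names = FALSE)
    files$fits <- fp("fits", "csv")
    utils::write.csv(fits, files$fits, row.names = FALSE)

    if (!is.null(classification)) {
      files$classification <- fp("classification", "json")
      jsonlite::write_json(
        list(threshold = report$threshold, n = n, n_hp = report$nHp,
             hp_percentage = report$hpPercentage,
             skewness_series = report$skewnessSeries,
             group_stats = report$groupStats),
        files$classification, auto_unbox = TRUE, digits = NA, na = "null",
        dataframe = "columns")
    }
    files$report <- fp("report", "json")
    jsonlite::write_json(report, files$report, auto_unbox = TRUE,
                         digits = NA, na = "null", dataframe = "columns")
    report$files <- files
    logStage(quiet, "done: ", report$nTraces, " traces, HP% = ",
             signif(report$hpPercentage, 4))
    invisible(report)
  })
}

# match analyzed traces back to ground-truth cells (nearest truth cell in
# the same anchor within 10 um) and score HP recall/precision
recoverTruthLabels <- function(traces, truth, labels, radius = 10) {
  cd <- cellData(traces)
  truthHp <- rep(NA, nrow(cd))
  for (k in seq_len(nrow(cd))) {
    cand <- which(truth$anchorId == cd$anchorId[k])
    if (!length(cand)) next
    d <- sqrt((truth$x[cand] - cd$x[k])^2 + (truth$y[cand] - cd$y[k])^2)
    if (min(d) <= radius) truthHp[k] <- truth$isHp[cand[which.min(d)]]
  }
  ok <- !is.na(truthHp)
  called <- labels$isHp[ok]; actual <- as.logical(truthHp[ok])
  list(nMatched = sum(ok),
       truthHpPercentage = 100 * mean(actual),
       hpRecall = if (any(actual)) mean(called[actual]) else NA_real_,
       hpPrecision = if (any(called)) mean(actual[called]) else NA_real_)
}
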