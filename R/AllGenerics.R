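#' @rdname ChipLayout-class
#' @param object,x an object.
#' @export
setGeneric("nAnchors", function(x) standardGeneric("nAnchors"))

#' @rdname ChipLayout-class
#' @export
setGeneric("anchorCenters", function(x) standardGeneric("anchorCenters"))

#' @rdname ChipLayout-class
#' @export
setGeneric("anchorRadius", function(x) standardGeneric("anchorRadius"))

#' @rdname ChipLayout-class
#' @export
setGeneric("dropletVolume", function(x) standardGeneric("dropletVolume"))

#' @rdname OccupancyTable-class
#' @export
setGeneric("occupancyCounts", function(x) standardGeneric("occupancyCounts"))

#' @rdname TimeLapseStack-class
#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))

#' @rdname TimeLapseStack-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname TimeLapseStack-class
#' @param name channel name.
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' @rdname CellTraceSet-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname CellTraceSet-class
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))

#' @rdname CellTraceSet-class
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname CellTraceSet-class
#' @export
setGeneric("deltaIntensity", function(x) standardGeneric("deltaIntensity"))

#' @rdname HPClassification-class
#' @export
setGeneric("hpThreshold", function(x) standardGeneric("hpThreshold"))

#' @rdname HPClassification-class
#' @export
setGeneric("hpPercentage", function(x) standardGeneric("hpPercentage"))

#' @rdname HPClassification-class
#' @export
setGeneric("hpLabels", function(x) standardGeneric("hpLabels"))
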