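#' @rdname MarkerPanel-accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname MarkerPanel-accessors
#' @export
setGeneric("markerScores", function(x) standardGeneric("markerScores"))

#' @rdname MarkerPanel-accessors
#' @export
setGeneric("ampliconSizes", function(x) standardGeneric("ampliconSizes"))

#' @rdname MarkerPanel-accessors
#' @export
setGeneric("multiplexSets", function(x) standardGeneric("multiplexSets"))

#' @rdname MarkerPanel-accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname patternCapacity
#' @export
setGeneric("patternCapacity", function(x) standardGeneric("patternCapacity"))

#' @rdname DiscriminationTable-accessors
#' @export
setGeneric("tableEntries", function(x) standardGeneric("tableEntries"))

#' @rdname DiscriminationTable-accessors
#' @export
setGeneric("domesticEntries", function(x) standardGeneric("domesticEntries"))

#' @rdname DiscriminationTable-accessors
#' @export
setGeneric("foreignEntries", function(x) standardGeneric("foreignEntries"))

#' @rdname DiscriminationTable-accessors
#' @export
setGeneric("resolvedValues", function(x) standardGeneric("resolvedValues"))

#' @rdname DiscriminationTable-accessors
#' @export
setGeneric("resolvedValues<-",
           function(x, value) standardGeneric("resolvedValues<-"))

#' @rdname DiscriminationTable-accessors
#' @export
setGeneric("totalSamples", function(x, ...) standardGeneric("totalSamples"))

#' @rdname overlappingValues
#' @export
setGeneric("overlappingValues",
           function(x, ...) standardGeneric("overlappingValues"))

#' @rdname confusionCounts
#' @export
setGeneric("confusionCounts", function(x, ...) standardGeneric("confusionCounts"))

#' @rdname performance-metrics
#' @export
setGeneric("sensitivity", function(x, ...) standardGeneric("sensitivity"))

#' @rdname performance-metrics
#' @export
setGeneric("selectivity", function(x, ...) standardGeneric("selectivity"))

#' @rdname performance-metrics
#' @export
setGeneric("efficiency", function(x, ...) standardGeneric("efficiency"))

#' @rdname overlapStats
#' @export
setGeneric("overlapStats", function(x, ...) standardGeneric("overlapStats"))
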