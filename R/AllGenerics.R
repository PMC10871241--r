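#' @rdname queryIntervals
#' @export
setGeneric("queryIntervals", function(x, chrom, start = NULL, end = NULL, ...)
  standardGeneric("queryIntervals"))

#' @rdname bwValues
#' @export
setGeneric("bwValues", function(x, chrom, start = NULL, end = NULL, ...)
  standardGeneric("bwValues"))

#' @rdname zoomQuery
#' @export
setGeneric("zoomQuery", function(x, chrom, start, end, reduction, ...)
  standardGeneric("zoomQuery"))

#' @rdname bbiStats
#' @export
setGeneric("bbiStats", function(x, chrom, start = NULL, end = NULL, ...)
  standardGeneric("bbiStats"))

#' @rdname chromSizes
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @rdname accessors
#' @export
setGeneric("totalSummary", function(x) standardGeneric("totalSummary"))

#' @rdname accessors
#' @export
setGeneric("zoomLevels", function(x) standardGeneric("zoomLevels"))

#' @rdname accessors
#' @export
setGeneric("autoSqlText", function(x) standardGeneric("autoSqlText"))

#' @rdname mergeSummaries
#' @export
setGeneric("mergeSummaries", function(a, b) standardGeneric("mergeSummaries"))
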