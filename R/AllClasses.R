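#' Chromosome name/length table
#'
#' An ordered table of chromosome names and lengths, as read from a
#' two-column `chrom.sizes` file.  The order of entries is meaningful: it
#' defines the chromosome ids (0-based, dense) used inside a BBI file and
#' the order in which a writer expects its input sorted.
#'
#' @slot chrom character vector of unique chromosome names.
#' @slot size numeric vector of lengths in base pairs (integral,
#'   `0 < size <= 2^32 - 1`).
#' @export
setClass("ChromSizes",
  representation(chrom = "character", size = "numeric"))

setValidity("ChromSizes", function(object) {
  if (length(object@chrom) != length(object@size))
    return("chrom and size must have equal length")
  if (anyDuplicated(object@chrom))
    return(sprintf("duplicate chromosome name: %s",
                   object@chrom[anyDuplicated(object@chrom)]))
  if (length(object@size)) {
    if (any(is.na(object@size)) || any(object@size <= 0))
      return("chromosome lengths must be positive")
    if (any(object@size != floor(object@size)))
      return("chromosome lengths must be integral")
    if (any(object@size > 4294967295))
      return("chromosome lengths must fit in 32 bits")
  }
  TRUE
})

#' Construct a ChromSizes table
#'
#' @param x a named numeric vector of lengths, or a data.frame with columns
#'   name and length.
#' @return a [ChromSizes-class] object preserving input order.
#' @examples
#' cs <- ChromSizes(c(chr1 = 1000, chr2 = 500))
#' names(cs); chromLength(cs, "chr2")
#' @export
ChromSizes <- function(x) {
  if (is.data.frame(x)) {
    new("ChromSizes", chrom = as.character(x[[1L]]), size = as.double(x[[2L]]))
  } else {
    nm <- names(x)
    if (is.null(nm)) nm <- character(length(x))
    new("ChromSizes", chrom = nm, size = as.double(unname(x)))
  }
}

#' @describeIn ChromSizes number of chromosomes
#' @param x a ChromSizes
#' @export
setMethod("length", "ChromSizes", function(x) length(x@chrom))

#' @describeIn ChromSizes chromosome names, in file order
#' @export
setMethod("names", "ChromSizes", function(x) x@chrom)

setMethod("show", "ChromSizes", function(object) {
  cat(sprintf("ChromSizes with %d sequence(s)\n", length(object)))
  n <- min(length(object), 6L)
  if (n) cat(paste0("  ", object@chrom[seq_len(n)], ": ",
                    format(object@size[seq_len(n)], big.mark = ","),
                    collapse = "\n"), "\n")
  if (length(object) > n) cat("  ...\n")
})

#' Length of one chromosome
#' @param x a [ChromSizes-class]
#' @param chrom chromosome name
#' @return length in bp, or `NA` if the name is absent (a not-found signal,
#'   not an error).
#' @export
chromLength <- function(x, chrom) {
  i <- match(chrom, x@chrom)
  ifelse(is.na(i), NA_real_, x@size[i])
}

setAs("ChromSizes", "data.frame", function(from)
  data.frame(chrom = from@chrom, size = from@size))


#' autoSql schema
#'
#' Parsed form of an autoSql table definition: the record schema language
#' BigBed files embed to describe their extra columns.
#'
#' @slot name table name.
#' @slot comment table comment.
#' @slot fields data.frame with columns `type`, `name`, `comment`, one row
#'   per field, in declaration order.  Type tokens are kept verbatim.
#' @export
setClass("AutoSql",
  representation(name = "character", comment = "character",
                 fields = "data.frame"))

setValidity("AutoSql", function(object) {
  f <- object@fields
  if (!all(c("type", "name", "comment") %in% names(f)))
    return("fields must have columns type, name, comment")
  if (nrow(f) < 3L)
    return("an autoSql schema needs at least 3 fields (chrom, start, end)")
  if (anyDuplicated(f$name))
    return(sprintf("duplicate field name: %s", f$name[anyDuplicated(f$name)]))
  TRUE
})

setMethod("show", "AutoSql", function(object) {
  cat(sprintf("AutoSql table '%s' (%d fields): %s\n",
              object@name, nrow(object@fields),
              paste(object@fields$name, collapse = ", ")))
})


#' Five-field summary statistics
#'
#' The mergeable aggregate stored in zoom records and the file-wide total
#' summary: count of bases with data, min, max, sum and sum of squares of
#' the per-base value.  Sufficient for mean, coverage and standard
#' deviation.  The empty (neutral) summary has `validCount = 0`,
#' `minVal = Inf`, `maxVal = -Inf` and zero sums.
#'
#' @slot validCount number of bases with data.
#' @slot minVal,maxVal extrema of the per-base value.
#' @slot sumData sum of per-base values.
#' @slot sumSquares sum of squared per-base values.
#' @export
setClass("SummaryStats",
  representation(validCount = "numeric", minVal = "numeric",
                 maxVal = "numeric", sumData = "numeric",
                 sumSquares = "numeric"))

setValidity("SummaryStats", function(object) {
  if (object@validCount < 0) return("validCount must be >= 0")
  if (object@validCount > 0 && object@minVal > object@maxVal)
    return("minVal must be <= maxVal when validCount > 0")
  TRUE
})

#' @rdname SummaryStats-class
#' @param validCount,minVal,maxVal,sumData,sumSquares field values; the
#'   default arguments give the neutral element.
#' @export
SummaryStats <- function(validCount = 0, minVal = Inf, maxVal = -Inf,
                         sumData = 0, sumSquares = 0) {
  new("SummaryStats", validCount = as.double(validCount),
      minVal = as.double(minVal), maxVal = as.double(maxVal),
      sumData = as.double(sumData), sumSquares = as.double(sumSquares))
}

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf(
    "SummaryStats: validCount=%.0f min=%g max=%g sum=%g sumSquares=%g\n",
    object@validCount, object@minVal, object@maxVal, object@sumData,
    object@sumSquares))
})


#' An open BBI file
#'
#' Handle to an open BigWig or BigBed file with its parsed metadata.
#' Create with [openBBI()] (or the kind-checked [BigWigHandle()] /
#' [BigBedHandle()] constructors); query with [queryIntervals()],
#' [bwValues()], [zoomQuery()] and [bbiStats()].
#'
#' @slot source the underlying byte source (file or in-memory buffer).
#' @slot littleEndian logical; byte order the file was written with.
#' @slot version format version.
#' @slot chromTable data.frame (`chrom`, `id`, `size`) enumerated from the
#'   chromosome B+ tree (name order).
#' @slot zoomHeaders data.frame (`reduction`, `dataOffset`, `indexOffset`),
#'   sorted by increasing reduction level.
#' @slot totalSummary [SummaryStats-class] over the whole file.
#' @slot uncompressBufSize decompression buffer size in bytes; 0 means the
#'   data blocks are stored uncompressed.
#' @slot fullDataOffset,fullIndexOffset,dataCount primary data region
#'   bookkeeping; `dataCount` is the number of data sections (BigWig) or
#'   records (BigBed).
#' @slot fieldCount,definedFieldCount BED column counts (BigBed; 0 for
#'   BigWig).
#' @slot autoSqlText embedded autoSql schema text, or `NA`.
#' @slot stats environment tallying blocks/sections read, for access
#'   instrumentation.
#' @aliases BigWigHandle-class BigBedHandle-class
#' @export
setClass("BBIFile",
  representation(source = "ANY", littleEndian = "logical",
                 version = "numeric", chromTable = "data.frame",
                 zoomHeaders = "data.frame", totalSummary = "SummaryStats",
                 uncompressBufSize = "numeric", fullDataOffset = "numeric",
                 fullIndexOffset = "numeric", dataCount = "numeric",
                 fieldCount = "numeric", definedFieldCount = "numeric",
                 autoSqlText = "character", stats = "environment"))

#' @export
setClass("BigWigHandle", contains = "BBIFile")

#' @export
setClass("BigBedHandle", contains = "BBIFile")

setValidity("BBIFile", function(object) {
  zh <- object@zoomHeaders
  if (nrow(zh) > 1L && any(diff(zh$reduction) <= 0))
    return("zoom levels must have strictly increasing reduction levels")
  ct <- object@chromTable
  if (nrow(ct) && !setequal(ct$id, seq_len(nrow(ct)) - 1))
    return("chromosome ids must be dense 0..n-1")
  TRUE
})

setMethod("show", "BBIFile", function(object) {
  kind <- if (is(object, "BigWigHandle")) "BigWig" else "BigBed"
  cat(sprintf("%sFile: %s\n", kind, object@source$desc))
  cat(sprintf("  version %d | %d chromosome(s) | %d zoom level(s) | %s\n",
              object@version, nrow(object@chromTable),
              nrow(object@zoomHeaders),
              if (object@uncompressBufSize > 0) "compressed"
              else "uncompressed"))
  ts <- object@totalSummary
  cat(sprintf("  basesCovered %.0f | min %g | max %g | mean %g\n",
              ts@validCount, ts@minVal, ts@maxVal,
              if (ts@validCount > 0) ts@sumData / ts@validCount else NaN))
  if (is(object, "BigBedHandle"))
    cat(sprintf("  items %.0f | fieldCount %d (defined %d)%s\n",
                object@dataCount, object@fieldCount,
                object@definedFieldCount,
                if (!is.na(object@autoSqlText)) " | autoSql embedded" else ""))
})
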