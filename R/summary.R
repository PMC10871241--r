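# Summary-statistic arithmetic.  A SummaryStats describes the per-base
# value distribution over a span: counts and sums add under merging, min
# and max take extrema, and the neutral element (validCount 0) is the
# identity, which makes folds over zoom records well defined in any order.

#' Merge two summaries
#'
#' Field-wise monoid operation: counts and sums add, min/max take extrema;
#' the neutral [SummaryStats()] is the identity.  Associative and
#' commutative.
#'
#' @param a,b [SummaryStats-class] objects.
#' @return the merged [SummaryStats-class].
#' @export
setMethod("mergeSummaries", signature("SummaryStats", "SummaryStats"),
  function(a, b) {
    if (a@validCount == 0) return(b)
    if (b@validCount == 0) return(a)
    SummaryStats(validCount = a@validCount + b@validCount,
                 minVal = min(a@minVal, b@minVal),
                 maxVal = max(a@maxVal, b@maxVal),
                 sumData = a@sumData + b@sumData,
                 sumSquares = a@sumSquares + b@sumSquares)
  })

#' Summarize a sorted interval set over one genomic bin
#'
#' Aggregates the step function described by `intervals` over
#' `[start, end)` of `chrom`: `validCount` counts covered bases inside the
#' bin, sums weight each value by its overlap length, min/max range over
#' values of overlapping intervals.  Disjoint bins give the neutral
#' summary.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`, `value`;
#'   sorted, non-overlapping per chromosome.
#' @param chrom,start,end the bin.
#' @return a [SummaryStats-class].
#' @export
summarizeIntervals <- function(intervals, chrom, start, end) {
  sel <- intervals$chrom == chrom & intervals$end > start &
    intervals$start < end
  if (!any(sel)) return(SummaryStats())
  v <- intervals$value[sel]
  len <- pmin(intervals$end[sel], end) - pmax(intervals$start[sel], start)
  SummaryStats(validCount = sum(len), minVal = min(v), maxVal = max(v),
               sumData = sum(v * len), sumSquares = sum(v * v * len))
}

# ---- vectorized "zoom frame" helpers ------------------------------------
# Internally, collections of per-bin summaries travel as plain data.frames
# ("zoom frames") with columns chrom (or id), start, end, validCount, min,
# max, sum, sumSquares -- one row per ZoomRecord.

emptyZoomFrame <- function(withChrom = TRUE) {
  base <- data.frame(start = double(), end = double(),
                     validCount = double(), min = double(), max = double(),
                     sum = double(), sumSquares = double())
  if (withChrom) cbind(data.frame(chrom = character()), base)
  else cbind(data.frame(id = double()), base)
}

# fold all rows of a zoom frame into one SummaryStats
foldZoomFrame <- function(z) {
  if (!nrow(z)) return(SummaryStats())
  SummaryStats(validCount = sum(z$validCount), minVal = min(z$min),
               maxVal = max(z$max), sumData = sum(z$sum),
               sumSquares = sum(z$sumSquares))
}

# sample standard deviation from the five summary fields
summaryStd <- function(s) {
  n <- s@validCount
  if (n < 2) return(0)
  var <- (s@sumSquares - s@sumData^2 / n) / (n - 1)
  sqrt(max(var, 0))
}

# split intervals (id,start,end,value) at multiples of `level` and
# aggregate per (id, bin): the vectorized core of zoom reduction.
# Returns a data.table keyed/sorted by (id, binStart).
binAggregate <- function(id, start, end, value, level) {
  firstBin <- floor(start / level)
  lastBin <- floor((end - 1) / level)
  nb <- lastBin - firstBin + 1
  i <- rep.int(seq_along(start), nb)
  bin <- (rep.int(firstBin, nb) + sequence(nb) - 1) * level
  s <- pmax(start[i], bin)
  e <- pmin(end[i], bin + level)
  len <- e - s
  v <- value[i]
  dt <- data.table::data.table(id = id[i], bin = bin, len = len, v = v)
  out <- dt[, list(validCount = sum(len), min = min(v), max = max(v),
                   sum = sum(v * len), sumSquares = sum(v * v * len)),
            by = c("id", "bin")]
  data.table::setorder(out, id, bin)
  out
}
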