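# Reading BBI files: header/metadata parsing and the query surface.
# Accepts any seekable byte source (file path, raw vector, or a bbi_source
# object); byte order is detected from the magic number so both
# little-endian files (the common case and what this package writes) and
# big-endian files are readable.

BIGWIG_MAGIC <- 2291137574   # 0x888FFC26
BIGBED_MAGIC <- 2273964779   # 0x8789F2EB

swapU32 <- function(x) {
  r <- u32ToRaw(x, "little")
  rawToU32(r, 1, "big")
}

#' Open a BigWig or BigBed file
#'
#' Parses the header, chromosome B+ tree, zoom-level table and total
#' summary of a BBI file and returns a query handle.  The kind (BigWig vs
#' BigBed) and byte order are inferred from the magic number.
#'
#' @param x file path, raw vector of file bytes, or a byte-source object.
#' @return a [BigWigHandle-class] or [BigBedHandle-class].
#' @seealso [queryIntervals()], [bwValues()], [zoomQuery()], [bbiStats()]
#' @export
openBBI <- function(x) {
  src <- asByteSource(x)
  ok <- FALSE
  on.exit(if (!ok) src$close())   # release the source if opening fails
  hdr <- src$read(0, 64)
  if (length(hdr) < 64)
    bbiFormatError("not a BBI file: truncated header")
  magicLE <- rawToU32(hdr[1:4], 1, "little")
  if (magicLE %in% c(BIGWIG_MAGIC, BIGBED_MAGIC)) {
    endian <- "little"
    magic <- magicLE
  } else if (swapU32(magicLE) %in% c(BIGWIG_MAGIC, BIGBED_MAGIC)) {
    endian <- "big"
    magic <- swapU32(magicLE)
  } else {
    bbiFormatError("not a BBI file: unrecognized magic number")
  }
  kind <- if (magic == BIGWIG_MAGIC) "BigWigHandle" else "BigBedHandle"
  version <- rawToU16(hdr[5:6], 1, endian)
  nZoom <- rawToU16(hdr[7:8], 1, endian)
  chromTreeOffset <- rawToU64(hdr[9:16], 1, endian)
  fullDataOffset <- rawToU64(hdr[17:24], 1, endian)
  fullIndexOffset <- rawToU64(hdr[25:32], 1, endian)
  fieldCount <- rawToU16(hdr[33:34], 1, endian)
  definedFieldCount <- rawToU16(hdr[35:36], 1, endian)
  autoSqlOffset <- rawToU64(hdr[37:44], 1, endian)
  totalSummaryOffset <- rawToU64(hdr[45:52], 1, endian)
  uncompressBufSize <- rawToU32(hdr[53:56], 1, endian)

  zoom <- data.frame(reduction = double(), dataOffset = double(),
                     indexOffset = double())
  if (nZoom > 0) {
    zr <- sourceReadExact(src, 64, 24 * nZoom)
    m <- matrix(zr, nrow = 24)
    zoom <- data.frame(
      reduction = rawToU32(as.raw(m[1:4, ]), nZoom, endian),
      dataOffset = rawToU64(as.raw(m[9:16, ]), nZoom, endian),
      indexOffset = rawToU64(as.raw(m[17:24, ]), nZoom, endian))
  }
  ts <- SummaryStats()
  if (totalSummaryOffset > 0) {
    tr <- sourceReadExact(src, totalSummaryOffset, 40)
    vc <- rawToU64(tr[1:8], 1, endian)
    d <- rawToF64(tr[9:40], 4, endian)
    ts <- if (vc == 0) SummaryStats()
          else SummaryStats(vc, d[1L], d[2L], d[3L], d[4L])
  }
  chromTable <- readChromBTree(src, chromTreeOffset, endian)
  autoSqlText <- NA_character_
  if (autoSqlOffset > 0) {
    # NUL-terminated text; read in chunks until the terminator
    bytes <- raw(); at <- autoSqlOffset
    repeat {
      chunk <- src$read(at, 4096)
      if (!length(chunk))
        bbiFormatError("unterminated autoSql text", offset = autoSqlOffset)
      z <- which(chunk == as.raw(0))
      if (length(z)) { bytes <- c(bytes, chunk[seq_len(z[1L] - 1L)]); break }
      bytes <- c(bytes, chunk); at <- at + length(chunk)
    }
    autoSqlText <- rawToChar(bytes)
  }
  dataCount <- rawToU32(sourceReadExact(src, fullDataOffset, 4), 1, endian)
  statsEnv <- new.env(parent = emptyenv())
  statsEnv$sectionsRead <- 0
  statsEnv$blockBytesRead <- 0
  ok <- TRUE
  new(kind, source = src, littleEndian = endian == "little",
      version = version, chromTable = chromTable, zoomHeaders = zoom,
      totalSummary = ts, uncompressBufSize = uncompressBufSize,
      fullDataOffset = fullDataOffset, fullIndexOffset = fullIndexOffset,
      dataCount = dataCount, fieldCount = fieldCount,
      definedFieldCount = definedFieldCount, autoSqlText = autoSqlText,
      stats = statsEnv)
}

#' @rdname openBBI
#' @export
BigWigHandle <- function(x) {
  f <- openBBI(x)
  if (!is(f, "BigWigHandle")) {
    close(f)
    bbiKindError("file is a BigBed, not a BigWig")
  }
  f
}

#' @rdname openBBI
#' @export
BigBedHandle <- function(x) {
  f <- openBBI(x)
  if (!is(f, "BigBedHandle")) {
    close(f)
    bbiKindError("file is a BigWig, not a BigBed")
  }
  f
}

#' Close a BBI file handle
#' @param con a [BBIFile-class]
#' @param ... ignored
#' @export
setMethod("close", "BBIFile", function(con, ...) {
  con@source$close()
  invisible(NULL)
})

.endian <- function(x) if (x@littleEndian) "little" else "big"

#' Chromosome table of an open BBI file
#'
#' @param x a [BBIFile-class].
#' @return a [ChromSizes-class] (in the file's chromosome-id order).
#' @export
setMethod("chromSizes", "BBIFile", function(x) {
  ct <- x@chromTable[order(x@chromTable$id), ]
  new("ChromSizes", chrom = ct$chrom, size = ct$size)
})

#' Metadata accessors
#'
#' `totalSummary()` returns the file-wide [SummaryStats-class];
#' `zoomLevels()` the zoom-level table (`reduction`, `dataOffset`,
#' `indexOffset`); `autoSqlText()` the embedded autoSql schema text
#' (`NA` when absent).
#'
#' @param x a [BBIFile-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("totalSummary", "BBIFile", function(x) x@totalSummary)

#' @rdname accessors
#' @export
setMethod("zoomLevels", "BBIFile", function(x) x@zoomHeaders)

#' @rdname accessors
#' @export
setMethod("autoSqlText", "BBIFile", function(x) x@autoSqlText)

# resolve a query region; chrom must exist.  end=NULL means chrom end.
resolveRegion <- function(x, chrom, start, end) {
  hit <- bptLookup(x@chromTable, chrom)
  if (is.null(hit))
    bbiNotFoundError(sprintf("chromosome '%s' not present in file", chrom))
  if (is.null(start)) start <- 0
  if (is.null(end)) end <- hit$size
  if (start < 0 || start >= end)
    bbiValidationError(sprintf("invalid region [%.0f, %.0f)", start, end))
  list(id = hit$id, size = hit$size, start = start, end = end)
}

# fetch + decompress the data blocks listed in `blocks` (offset/size df),
# tallying access statistics on the handle
readBlocks <- function(x, blocks) {
  lapply(seq_len(nrow(blocks)), function(i) {
    r <- sourceReadExact(x@source, blocks$offset[i], blocks$size[i])
    x@stats$sectionsRead <- x@stats$sectionsRead + 1
    x@stats$blockBytesRead <- x@stats$blockBytesRead + length(r)
    decompressSection(r, x@uncompressBufSize)
  })
}

#' Query records overlapping a region
#'
#' Returns exactly the records overlapping `[start, end)` of `chrom`,
#' whole (unclipped) unless `clip = TRUE`, sorted by start.  Only the data
#' blocks selected by the R-tree index are read and decompressed.
#'
#' @param x a [BBIFile-class].
#' @param chrom chromosome name.
#' @param start,end region bounds (0-based half-open); default to the
#'   whole chromosome.
#' @param clip return record coordinates clipped to the query region.
#' @param ... unused.
#' @return for BigWig: data.frame `chrom`/`start`/`end`/`value`; for
#'   BigBed: data.frame `chrom`/`start`/`end`/`rest`.
#' @export
setMethod("queryIntervals", "BBIFile",
  function(x, chrom, start = NULL, end = NULL, clip = FALSE, ...) {
    q <- resolveRegion(x, chrom, start, end)
    blocks <- queryRTree(x@source, x@fullIndexOffset, q$id, q$start, q$end,
                         .endian(x))
    isWig <- is(x, "BigWigHandle")
    decoded <- lapply(readBlocks(x, blocks), function(r)
      if (isWig) decodeBigWigSections(r, .endian(x))
      else decodeBigBedSection(r, .endian(x)))
    d <- if (length(decoded)) as.data.frame(data.table::rbindlist(decoded))
         else if (isWig) data.frame(id = double(), start = double(),
                                    end = double(), value = double())
         else data.frame(id = double(), start = double(), end = double(),
                         rest = character())
    keep <- d$id == q$id & d$end > q$start & d$start < q$end
    d <- d[keep, , drop = FALSE]
    # stable: records sharing a start keep their file order
    d <- d[order(d$start), , drop = FALSE]
    if (clip) {
      d$start <- pmax(d$start, q$start)
      d$end <- pmin(d$end, q$end)
    }
    d$id <- NULL
    rownames(d) <- NULL
    cbind(data.frame(chrom = rep.int(chrom, nrow(d))), d)
  })

#' Per-base (or binned) values from a BigWig
#'
#' Expands the step function over `[start, end)` into a dense numeric
#' vector, one element per base, with `NA` marking bases without data
#' (missing is distinct from zero).  Bases beyond the chromosome end are
#' missing.  With `bins`, each bin's value is the mean over covered bases
#' in the bin (`NA` if none).
#'
#' @inheritParams queryIntervals
#' @param bins optional number of equal-width bins.
#' @return numeric vector of length `end - start` (or `bins`).
#' @export
setMethod("bwValues", "BigWigHandle",
  function(x, chrom, start = NULL, end = NULL, bins = NULL, ...) {
    q <- resolveRegion(x, chrom, start, end)
    fetchEnd <- min(q$end, q$size)
    d <- if (q$start < fetchEnd)
      queryIntervals(x, chrom, q$start, fetchEnd, clip = TRUE)
    else data.frame(chrom = character(), start = double(), end = double(),
                    value = double())
    width <- q$end - q$start
    if (is.null(bins)) {
      out <- rep(NA_real_, width)
      if (nrow(d)) {
        len <- d$end - d$start
        idx <- rep.int(d$start - q$start, len) + sequence(len)
        out[idx] <- rep.int(d$value, len)
      }
      out
    } else {
      bins <- as.integer(bins)
      if (bins < 1L) bbiValidationError("bins must be >= 1")
      edges <- q$start + floor((0:bins) * width / bins)
      out <- rep(NA_real_, bins)
      if (nrow(d)) {
        agg <- binnedMeans(d$start, d$end, d$value, edges)
        out[agg$bin] <- agg$mean
      }
      out
    }
  })

#' @rdname bwValues
#' @export
setMethod("bwValues", "BigBedHandle", function(x, chrom, start, end, ...)
  bbiKindError("values() needs a BigWig; this is a BigBed"))

# mean of covered bases per bin, given clipped intervals and bin edges
binnedMeans <- function(start, end, value, edges) {
  nb <- length(edges) - 1L
  firstBin <- findInterval(start, edges, rightmost.closed = FALSE)
  lastBin <- findInterval(end - 1, edges, rightmost.closed = FALSE)
  nbins <- pmax(lastBin - firstBin + 1L, 1L)
  i <- rep.int(seq_along(start), nbins)
  bin <- rep.int(firstBin, nbins) + sequence(nbins) - 1L
  ok <- bin >= 1L & bin <= nb
  i <- i[ok]; bin <- bin[ok]
  s <- pmax(start[i], edges[bin])
  e <- pmin(end[i], edges[bin + 1L])
  len <- e - s
  ok <- len > 0
  dt <- data.table::data.table(bin = bin[ok], len = len[ok],
                               v = value[i[ok]])
  agg <- dt[, list(sum = sum(len * v), n = sum(len)), by = "bin"]
  data.frame(bin = agg$bin, mean = agg$sum / agg$n)
}

#' Query zoom (summary) records
#'
#' Fetches the precomputed summary records of one reduction level that
#' overlap the query region, via that level's own R-tree index.
#'
#' @inheritParams queryIntervals
#' @param reduction the reduction level (bp per bin); must equal one of
#'   the file's levels (see [zoomLevels()]).
#' @return data.frame with `chrom`, `start`, `end`, `validCount`, `min`,
#'   `max`, `sum`, `sumSquares`.
#' @export
setMethod("zoomQuery", "BBIFile",
  function(x, chrom, start, end, reduction, ...) {
    zh <- x@zoomHeaders
    li <- match(reduction, zh$reduction)
    if (is.na(li))
      bbiNotFoundError(sprintf(
        "no zoom level with reduction %.0f; available: %s", reduction,
        if (nrow(zh)) paste(zh$reduction, collapse = ", ") else "none"))
    q <- resolveRegion(x, chrom, start, end)
    blocks <- queryRTree(x@source, zh$indexOffset[li], q$id, q$start, q$end,
                         .endian(x))
    decoded <- lapply(readBlocks(x, blocks), decodeZoomSection,
                      endian = .endian(x))
    z <- if (length(decoded)) as.data.frame(data.table::rbindlist(decoded))
         else emptyZoomFrame(withChrom = FALSE)
    z <- z[z$id == q$id & z$end > q$start & z$start < q$end, , drop = FALSE]
    z <- z[order(z$start), , drop = FALSE]
    z$id <- NULL
    rownames(z) <- NULL
    cbind(data.frame(chrom = rep.int(chrom, nrow(z))), z)
  })

#' Region statistics from a BigWig
#'
#' Computes one statistic per bin over `[start, end)`.  With
#' `exact = TRUE` the full-resolution data are used.  With
#' `exact = FALSE`, the largest zoom level whose reduction is at most half
#' the bin width serves as a fast approximation (zoom records overlapping
#' each bin are folded with [mergeSummaries()]); when no level qualifies
#' the exact path is used.
#'
#' @inheritParams queryIntervals
#' @param stat one of `"mean"`, `"min"`, `"max"`, `"coverage"`, `"sum"`.
#'   `mean = sum / validCount`; `coverage = validCount / bin width`.
#' @param bins number of equal-width bins (default 1).
#' @param exact compute from full-resolution data.
#' @return numeric vector of length `bins`; `NA` where a bin has no data
#'   (for `mean`/`min`/`max`; `coverage` and `sum` give 0 there).
#' @export
setMethod("bbiStats", "BigWigHandle",
  function(x, chrom, start = NULL, end = NULL,
           stat = c("mean", "min", "max", "coverage", "sum"), bins = 1L,
           exact = TRUE, ...) {
    stat <- match.arg(stat)
    bins <- as.integer(bins)
    if (bins < 1L) bbiValidationError("bins must be >= 1")
    q <- resolveRegion(x, chrom, start, end)
    width <- q$end - q$start
    binWidth <- width / bins
    if (binWidth <= 0) bbiValidationError("zero-length bin")
    edges <- q$start + floor((0:bins) * width / bins)

    zh <- x@zoomHeaders
    useZoom <- !exact && nrow(zh) > 0 &&
      any(zh$reduction <= binWidth / 2)
    frame <- if (useZoom) {
      red <- max(zh$reduction[zh$reduction <= binWidth / 2])
      z <- zoomQuery(x, chrom, q$start, q$end, red)
      data.frame(start = z$start, end = z$end, validCount = z$validCount,
                 min = z$min, max = z$max, sum = z$sum)
    } else {
      fetchEnd <- min(q$end, q$size)
      d <- if (q$start < fetchEnd)
        queryIntervals(x, chrom, q$start, fetchEnd, clip = TRUE)
      else data.frame(start = double(), end = double(), value = double())
      len <- d$end - d$start
      data.frame(start = d$start, end = d$end, validCount = len,
                 min = d$value, max = d$value, sum = d$value * len)
    }
    out <- rep(NA_real_, bins)
    if (nrow(frame)) {
      if (useZoom) {
        # whole zoom records are folded into every bin they overlap
        firstBin <- pmax(findInterval(frame$start, edges), 1L)
        lastBin <- pmin(findInterval(frame$end - 1, edges), bins)
        nb <- pmax(lastBin - firstBin + 1L, 0L)
        i <- rep.int(seq_len(nrow(frame)), nb)
        bin <- rep.int(firstBin, nb) + sequence(nb) - 1L
        dt <- data.table::data.table(
          bin = bin, vc = frame$validCount[i], mn = frame$min[i],
          mx = frame$max[i], sm = frame$sum[i])
      } else {
        firstBin <- pmax(findInterval(frame$start, edges), 1L)
        lastBin <- pmin(findInterval(frame$end - 1, edges), bins)
        nb <- pmax(lastBin - firstBin + 1L, 0L)
        i <- rep.int(seq_len(nrow(frame)), nb)
        bin <- rep.int(firstBin, nb) + sequence(nb) - 1L
        s <- pmax(frame$start[i], edges[bin])
        e <- pmin(frame$end[i], edges[bin + 1L])
        len <- e - s
        v <- frame$min[i]   # = the interval value on the exact path
        dt <- data.table::data.table(bin = bin, vc = len, mn = v, mx = v,
                                     sm = v * len)[vc > 0]
      }
      agg <- dt[, list(vc = sum(vc), mn = min(mn), mx = max(mx),
                       sm = sum(sm)), by = "bin"]
      val <- switch(stat,
        mean = agg$sm / agg$vc,
        min = agg$mn,
        max = agg$mx,
        coverage = agg$vc / diff(edges)[agg$bin],
        sum = agg$sm)
      out[agg$bin] <- val
    }
    if (stat %in% c("coverage", "sum")) out[is.na(out)] <- 0
    out
  })

#' @rdname bbiStats
#' @export
setMethod("bbiStats", "BigBedHandle", function(x, chrom, start, end, ...)
  bbiKindError("stats() needs a BigWig; this is a BigBed"))
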