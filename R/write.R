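# Streaming single-pass BBI writer.  The input record stream is consumed
# exactly once, in order: data sections are compressed and written as they
# fill, while a staging area (a temporary file by default, an in-memory
# buffer when disabled) retains what zoom building needs.  Headers and
# counts are back-patched at the end, so the sink must be seekable even
# when the source is a pipe.  Both staging modes, any thread count, and
# file-vs-pipe input produce byte-identical output.

#' Writer options
#'
#' @param itemsPerSlot records per data section (the compression unit).
#' @param blockSize R-tree and B+ tree branching factor.
#' @param compress zlib-compress data sections.
#' @param zoomLevels `"auto"` (see [planZoomLevels()]) or an explicit
#'   strictly increasing numeric vector of reduction levels.
#' @param useTempFiles stage zoom inputs in a temporary file instead of
#'   memory; output bytes are identical either way.
#' @param maxZoomLevels cap on the number of zoom levels.
#' @param threads worker processes for section compression; output bytes
#'   are identical for any value.
#' @param clip drop/truncate records extending past the chromosome end
#'   instead of raising an error.
#' @param endian byte order written; `"little"` matches the mainstream
#'   tools and is what the drop-in CLI always uses (`"big"` exists to
#'   exercise readers).
#' @return an options list used by [writeBigWig()] / [writeBigBed()].
#' @export
bbiWriteOptions <- function(itemsPerSlot = 1024L, blockSize = 256L,
                            compress = TRUE, zoomLevels = "auto",
                            useTempFiles = TRUE, maxZoomLevels = 10L,
                            threads = 1L, clip = FALSE,
                            endian = c("little", "big")) {
  itemsPerSlot <- as.integer(itemsPerSlot)
  blockSize <- as.integer(blockSize)
  if (itemsPerSlot < 1L) bbiValidationError("itemsPerSlot must be >= 1")
  if (blockSize < 2L) bbiValidationError("blockSize must be >= 2")
  if (!identical(zoomLevels, "auto")) {
    zoomLevels <- as.double(zoomLevels)
    if (length(zoomLevels) && any(diff(zoomLevels) <= 0))
      bbiValidationError("explicit zoom levels must be strictly increasing")
  }
  structure(list(itemsPerSlot = itemsPerSlot, blockSize = blockSize,
                 compress = isTRUE(compress), zoomLevels = zoomLevels,
                 useTempFiles = isTRUE(useTempFiles),
                 maxZoomLevels = as.integer(maxZoomLevels),
                 threads = max(1L, as.integer(threads)),
                 clip = isTRUE(clip), endian = match.arg(endian)),
            class = "bbi_write_options")
}

#' Plan zoom reduction levels
#'
#' The automatic rule: the first level is `max(10, ceiling(10 * mean
#' record length))`; each subsequent level is 4x the previous; levels stop
#' at the longest chromosome length or after `maxZoomLevels`, whichever
#' comes first.  An explicit `zoomLevels` vector in `opts` overrides the
#' rule.
#'
#' @param recordCount,meanLength input stream statistics.
#' @param chromSizes a [ChromSizes-class].
#' @param opts a [bbiWriteOptions()] list.
#' @return numeric vector of reduction levels (possibly empty).
#' @export
planZoomLevels <- function(recordCount, meanLength, chromSizes,
                           opts = bbiWriteOptions()) {
  if (!identical(opts$zoomLevels, "auto"))
    return(opts$zoomLevels[opts$zoomLevels < 4294967296])
  if (recordCount < 1) return(double())
  longest <- max(chromSizes@size)
  level <- max(10, ceiling(10 * meanLength))
  out <- double()
  while (level < longest && length(out) < opts$maxZoomLevels &&
         level < 4294967296) {
    out <- c(out, level)
    level <- level * 4
  }
  out
}

## ---- sink ---------------------------------------------------------------

newSink <- function(path) {
  con <- file(path, "w+b")
  pos <- 0
  list(
    append = function(r) {
      at <- pos
      writeBin(r, con)
      pos <<- pos + length(r)
      at
    },
    patch = function(offset, r) {
      seek(con, where = offset, rw = "write")
      writeBin(r, con)
      seek(con, where = pos, rw = "write")
    },
    pos = function() pos,
    close = function() close(con)
  )
}

## ---- zoom staging -------------------------------------------------------
# Retains the (chromId, start, end, value) runs that zoom reduction will
# re-read.  Temp-file mode keeps a bounded number of records resident;
# memory mode buffers them.  Both replay identical record sequences.

newStaging <- function(useTempFiles) {
  count <- 0
  if (useTempFiles) {
    path <- tempfile("bbi-staging-")
    con <- file(path, "w+b")
    list(
      append = function(id, start, end, value) {
        writeBin(as.double(rbind(id, start, end, value)), con, size = 8L)
        count <<- count + length(id)
      },
      scan = function(fun, chunkRows = 65536L) {
        seek(con, 0, rw = "read")
        done <- 0
        while (done < count) {
          n <- min(chunkRows, count - done)
          m <- matrix(readBin(con, "double", n = 4L * n, size = 8L),
                      nrow = 4L)
          done <- done + n
          fun(data.frame(id = m[1L, ], start = m[2L, ], end = m[3L, ],
                         value = m[4L, ]))
        }
      },
      count = function() count,
      destroy = function() { close(con); unlink(path) }
    )
  } else {
    buf <- list(); k <- 0L
    list(
      append = function(id, start, end, value) {
        k <<- k + 1L
        buf[[k]] <<- data.frame(id = id, start = start, end = end,
                                value = value)
        count <<- count + length(id)
      },
      scan = function(fun, chunkRows = 65536L) {
        # replay with the same chunk geometry as the temp-file path so
        # downstream section boundaries are identical
        pend <- NULL
        flushPend <- function(final = FALSE) {
          while (!is.null(pend) &&
                 (nrow(pend) >= chunkRows || (final && nrow(pend) > 0))) {
            n <- min(chunkRows, nrow(pend))
            fun(pend[seq_len(n), , drop = FALSE])
            pend <<- if (n < nrow(pend))
              pend[(n + 1L):nrow(pend), , drop = FALSE] else NULL
          }
        }
        for (b in buf) {
          pend <- if (is.null(pend)) b else rbind(pend, b)
          flushPend()
        }
        flushPend(final = TRUE)
      },
      count = function() count,
      destroy = function() invisible(NULL)
    )
  }
}

## ---- summary accumulator ------------------------------------------------

newSummaryAcc <- function() {
  e <- new.env(parent = emptyenv())
  e$vc <- 0; e$mn <- Inf; e$mx <- -Inf; e$sm <- 0; e$ssq <- 0
  e
}

accAdd <- function(e, value, len) {
  e$vc <- e$vc + sum(len)
  e$mn <- min(e$mn, min(value))
  e$mx <- max(e$mx, max(value))
  e$sm <- e$sm + sum(value * len)
  e$ssq <- e$ssq + sum(value * value * len)
}

accToSummary <- function(e)
  if (e$vc == 0) SummaryStats() else SummaryStats(e$vc, e$mn, e$mx, e$sm,
                                                  e$ssq)

## ---- section spooler ----------------------------------------------------
# Collects per-section record groups, compresses them (optionally in
# parallel) and writes them out in input order, recording R-tree leaf
# bookkeeping and the largest uncompressed section size.

newSpooler <- function(sink, opts, encodeFun) {
  queue <- list(); qn <- 0L
  leaves <- list(); ln <- 0L
  maxRaw <- 0
  flushQueue <- function() {
    if (!qn) return(invisible(NULL))
    raws <- lapply(queue[seq_len(qn)], encodeFun)
    maxRaw <<- max(maxRaw, vapply(raws, length, 1L))
    enc <- encodeSectionBatch(raws, opts$compress, opts$threads)
    for (i in seq_len(qn)) {
      g <- queue[[i]]
      off <- sink$append(enc[[i]])
      ln <<- ln + 1L
      leaves[[ln]] <<- data.frame(
        id = g$id[1L], start = g$start[1L], end = max(g$end),
        offset = off, size = length(enc[[i]]))
    }
    queue <<- list(); qn <<- 0L
  }
  list(
    push = function(group) {
      qn <<- qn + 1L
      queue[[qn]] <<- group
      if (qn >= max(32L, opts$threads * 8L)) flushQueue()
    },
    finish = function() {
      flushQueue()
      list(leaves = if (ln) as.data.frame(data.table::rbindlist(
             leaves[seq_len(ln)])) else NULL,
           count = ln, maxRaw = maxRaw)
    }
  )
}

# split a same-chromosome record accumulator into full sections
drainSections <- function(pend, spooler, ips, final = FALSE) {
  while (!is.null(pend) && (nrow(pend) >= ips || (final && nrow(pend)))) {
    n <- min(ips, nrow(pend))
    spooler$push(pend[seq_len(n), , drop = FALSE])
    pend <- if (n < nrow(pend)) pend[(n + 1L):nrow(pend), , drop = FALSE]
            else NULL
  }
  pend
}

## ---- zoom level writing -------------------------------------------------

writeOneZoomLevel <- function(sink, staging, level, sizesById, opts) {
  endian <- opts$endian
  ips <- opts$itemsPerSlot
  dataOffset <- sink$pos()
  sink$append(u32ToRaw(0, endian))  # record count, patched below
  totalRecs <- 0
  maxRaw <- 0
  leaves <- list(); ln <- 0L
  pend <- NULL     # completed zoom records awaiting a full section
  carry <- NULL    # last (id,bin) aggregate; may continue in next chunk

  flushPend <- function(final = FALSE) {
    while (!is.null(pend) && (nrow(pend) >= ips || (final && nrow(pend)))) {
      n <- min(ips, nrow(pend))
      # keep one section on one chromosome
      n <- min(n, which(pend$id[seq_len(n)] != pend$id[1L])[1L] - 1L,
               na.rm = TRUE)
      g <- pend[seq_len(n), , drop = FALSE]
      raw <- encodeZoomSection(g, endian)
      maxRaw <<- max(maxRaw, length(raw))
      enc <- compressSection(raw, opts$compress)
      off <- sink$append(enc)
      ln <<- ln + 1L
      leaves[[ln]] <<- data.frame(id = g$id[1L], start = g$start[1L],
                                  end = max(g$end), offset = off,
                                  size = length(enc))
      totalRecs <<- totalRecs + n
      pend <<- if (n < nrow(pend)) pend[(n + 1L):nrow(pend), , drop = FALSE]
               else NULL
    }
  }
  emit <- function(agg) {
    # agg: data.table(id, bin, validCount, min, max, sum, sumSquares)
    z <- data.frame(id = agg$id, start = agg$bin,
                    end = pmin(agg$bin + level, sizesById[agg$id + 1L]),
                    validCount = agg$validCount, min = agg$min,
                    max = agg$max, sum = agg$sum,
                    sumSquares = agg$sumSquares)
    pend <<- if (is.null(pend)) z else rbind(pend, z)
    flushPend()
  }

  staging$scan(function(df) {
    agg <- binAggregate(df$id, df$start, df$end, df$value, level)
    if (!is.null(carry)) {
      if (agg$id[1L] == carry$id && agg$bin[1L] == carry$bin) {
        agg$validCount[1L] <- agg$validCount[1L] + carry$validCount
        agg$min[1L] <- min(agg$min[1L], carry$min)
        agg$max[1L] <- max(agg$max[1L], carry$max)
        agg$sum[1L] <- agg$sum[1L] + carry$sum
        agg$sumSquares[1L] <- agg$sumSquares[1L] + carry$sumSquares
      } else {
        emit(carry)
      }
      carry <<- NULL
    }
    n <- nrow(agg)
    carry <<- as.data.frame(agg[n, ])
    if (n > 1L) emit(agg[seq_len(n - 1L), ])
  })
  if (!is.null(carry)) emit(carry)
  flushPend(final = TRUE)
  if (!ln) return(NULL)   # no records at this level (empty input guard)
  lv <- as.data.frame(data.table::rbindlist(leaves[seq_len(ln)]))
  indexOffset <- sink$pos()
  sink$append(buildRTree(lv, atOffset = indexOffset,
                         blockSize = opts$blockSize, itemsPerSlot = ips,
                         endFileOffset = indexOffset, endian = endian))
  sink$patch(dataOffset, u32ToRaw(totalRecs, endian))
  list(reduction = level, dataOffset = dataOffset,
       indexOffset = indexOffset, maxRaw = maxRaw)
}

## ---- header assembly ----------------------------------------------------

writeMainHeader <- function(sink, magic, version, zoomHeaders, chromTreeOffset,
                            fullDataOffset, fullIndexOffset, fieldCount,
                            definedFieldCount, autoSqlOffset,
                            totalSummaryOffset, uncompressBufSize, endian) {
  sink$patch(0, c(
    u32ToRaw(magic, endian), u16ToRaw(version, endian),
    u16ToRaw(nrow(zoomHeaders), endian),
    u64ToRaw(chromTreeOffset, endian), u64ToRaw(fullDataOffset, endian),
    u64ToRaw(fullIndexOffset, endian), u16ToRaw(fieldCount, endian),
    u16ToRaw(definedFieldCount, endian), u64ToRaw(autoSqlOffset, endian),
    u64ToRaw(totalSummaryOffset, endian),
    u32ToRaw(uncompressBufSize, endian), u64ToRaw(0, endian)))
  if (nrow(zoomHeaders))
    sink$patch(64, unlist(lapply(seq_len(nrow(zoomHeaders)), function(i)
      c(u32ToRaw(zoomHeaders$reduction[i], endian), u32ToRaw(0, endian),
        u64ToRaw(zoomHeaders$dataOffset[i], endian),
        u64ToRaw(zoomHeaders$indexOffset[i], endian)))))
}

writeTotalSummary <- function(sink, offset, s, endian) {
  zeroIfEmpty <- function(v) if (s@validCount == 0) 0 else v
  sink$patch(offset, c(
    u64ToRaw(s@validCount, endian),
    f64ToRaw(zeroIfEmpty(s@minVal), endian),
    f64ToRaw(zeroIfEmpty(s@maxVal), endian),
    f64ToRaw(s@sumData, endian), f64ToRaw(s@sumSquares, endian)))
}

## ---- BigWig -------------------------------------------------------------

#' Write a BigWig file
#'
#' Creates a complete BigWig — header, chromosome B+ tree, compressed data
#' sections, full-resolution R-tree, zoom levels each with its own R-tree,
#' and total summary — from a single forward pass over the input.
#'
#' @param x intervals: a data.frame with columns `chrom`, `start`, `end`,
#'   `value` (0-based half-open), or a lazy stream such as
#'   [parseBedGraph()] output.  Must be sorted by (chromosome in
#'   `chromSizes` order, start) and non-overlapping per chromosome; values
#'   are stored as 32-bit floats.
#' @param chromSizes a [ChromSizes-class]; defines the coordinate space
#'   and the chromosome order.
#' @param path output file path.
#' @param opts a [bbiWriteOptions()] list.
#' @return invisibly, a metadata list (`kind`, `version`, `dataCount`,
#'   `zoomHeaders`, `totalSummary`, `uncompressBufSize`, `path`).
#' @examples
#' cs <- ChromSizes(c(chr1 = 1000))
#' iv <- data.frame(chrom = "chr1", start = c(0, 10), end = c(10, 20),
#'                  value = c(1, 3))
#' bw <- tempfile(fileext = ".bw")
#' writeBigWig(iv, cs, bw)
#' f <- openBBI(bw)
#' queryIntervals(f, "chr1")
#' close(f)
#' @export
writeBigWig <- function(x, chromSizes, path, opts = bbiWriteOptions()) {
  writeBbiFile(x, chromSizes, path, opts, kind = "BigWig")
}

#' Write a BigBed file
#'
#' Like [writeBigWig()] but for BED-like features, which may overlap.
#' Zoom levels and the total summary aggregate per-base coverage depth
#' (the number of records covering each base), making zoomed-out views a
#' density track.
#'
#' @inheritParams writeBigWig
#' @param x records: data.frame with columns `chrom`, `start`, `end`,
#'   `rest` (tab-joined fields 4..N, `""` when none), or a [parseBed()]
#'   stream.  Sorted by (chromosome order, start); constant column count.
#' @param autoSql optional [AutoSql-class] schema to embed; its field
#'   count must match the records'.
#' @param definedFieldCount how many leading columns follow the standard
#'   BED definitions (defaults to all of them, capped at 12).
#' @export
writeBigBed <- function(x, chromSizes, path, autoSql = NULL,
                        definedFieldCount = NULL,
                        opts = bbiWriteOptions()) {
  writeBbiFile(x, chromSizes, path, opts, kind = "BigBed",
               autoSql = autoSql, definedFieldCount = definedFieldCount)
}

writeBbiFile <- function(x, chromSizes, path, opts, kind,
                         autoSql = NULL, definedFieldCount = NULL) {
  stopifnot(is(chromSizes, "ChromSizes"))
  if (!length(chromSizes))
    bbiValidationError("chrom.sizes is empty; cannot write a BBI file")
  isWig <- kind == "BigWig"
  endian <- opts$endian
  s <- asStream(x)
  sink <- newSink(path)
  staging <- newStaging(opts$useTempFiles)
  ok <- FALSE
  on.exit({
    if (!ok) finishStream(s)
    staging$destroy()
    sink$close()
    if (!ok) unlink(path)
  })

  # fixed front matter: header | zoom reserve | [autoSql] | total summary
  # | chromosome B+ tree | data count | sections...  (autoSql precedes the
  # total summary so readers that infer its length from the gap agree)
  zoomReserve <- 24 * max(opts$maxZoomLevels,
                          if (identical(opts$zoomLevels, "auto")) 0L
                          else length(opts$zoomLevels))
  autoSqlOffset <- 0
  autoSqlRaw <- raw()
  if (!isWig && !is.null(autoSql)) {
    stopifnot(is(autoSql, "AutoSql"))
    autoSqlOffset <- 64 + zoomReserve
    autoSqlRaw <- c(charToRaw(formatAutoSql(autoSql)), as.raw(0L))
  }
  totalSummaryOffset <- 64 + zoomReserve + length(autoSqlRaw)
  chromTreeOffset <- totalSummaryOffset + 40
  bpt <- buildChromBTree(chromSizes, atOffset = chromTreeOffset,
                         blockSize = opts$blockSize, endian = endian)
  fullDataOffset <- chromTreeOffset + length(bpt)
  sink$append(raw(64 + zoomReserve))
  sink$append(autoSqlRaw)
  sink$append(raw(40))
  sink$append(bpt)
  sink$append(u32ToRaw(0, endian))   # data count, patched at the end

  sizesById <- chromSizes@size
  spooler <- newSpooler(sink, opts, function(g)
    if (isWig) encodeBigWigSection(g$id, g$start, g$end, g$value,
                                   endian = endian)
    else encodeBigBedSection(g$id, g$start, g$end, g$rest, endian = endian))
  sortState <- newSortState()
  acc <- newSummaryAcc()
  nRecords <- 0
  sumLen <- 0
  fieldCount <- if (isWig) 0L else NA_integer_
  pend <- NULL          # records of the current chromosome
  curId <- NA_real_
  bedChromStarts <- NULL; bedChromEnds <- NULL  # depth events (BigBed)

  flushBedChrom <- function() {
    # depth profile of the finished chromosome -> staging + total summary
    if (!length(bedChromStarts)) return(invisible(NULL))
    ev <- data.table::data.table(
      pos = c(bedChromStarts, bedChromEnds),
      d = rep(c(1, -1), c(length(bedChromStarts), length(bedChromEnds))))
    ev <- ev[, list(d = sum(d)), by = "pos"]
    data.table::setorder(ev, pos)
    depth <- cumsum(ev$d)
    n <- nrow(ev)
    keep <- depth > 0 & seq_len(n) < n
    if (any(keep)) {
      rs <- ev$pos[keep]
      re <- ev$pos[which(keep) + 1L]
      rd <- depth[keep]
      staging$append(rep.int(curId, length(rs)), rs, re, rd)
      accAdd(acc, rd, re - rs)
    }
    bedChromStarts <<- NULL; bedChromEnds <<- NULL
  }

  while (!is.null(b <- s$nextBatch())) {
    if (!nrow(b)) next
    checkSortedIntervals(b, sortState, chromOrder = chromSizes,
                         requireDisjoint = isWig)
    id <- match(b$chrom, chromSizes@chrom) - 1
    size <- sizesById[id + 1L]
    if (opts$clip) {
      b$end <- pmin(b$end, size)
      keep <- b$start < size
      b <- b[keep, , drop = FALSE]; id <- id[keep]; size <- size[keep]
      if (!nrow(b)) next
    } else if (any(b$end > size)) {
      i <- which(b$end > size)[1L]
      bbiValidationError(sprintf(
        "record %s:[%.0f,%.0f) extends past chromosome end (%.0f)",
        b$chrom[i], b$start[i], b$end[i], size[i]))
    }
    if (isWig) {
      if (any(!is.finite(b$value)))
        bbiValidationError("values must be finite")
      b$value <- asFloat32(b$value)
      recs <- data.frame(id = id, start = b$start, end = b$end,
                         value = b$value)
    } else {
      nf <- 3L + ifelse(nzchar(b$rest),
                        1L + nchar(gsub("[^\t]", "", b$rest)), 0L)
      if (is.na(fieldCount)) fieldCount <- nf[1L]
      if (any(nf != fieldCount))
        bbiValidationError(sprintf(
          "field count drift: expected %d columns, got %d",
          fieldCount, nf[nf != fieldCount][1L]))
      recs <- data.frame(id = id, start = b$start, end = b$end,
                         rest = b$rest)
    }
    nRecords <- nRecords + nrow(recs)
    sumLen <- sumLen + sum(recs$end - recs$start)
    # route records into per-chromosome sections
    for (g in split(seq_len(nrow(recs)), cumsum(c(TRUE, diff(recs$id) != 0)))) {
      gid <- recs$id[g[1L]]
      if (!is.na(curId) && gid != curId) {
        pend <- drainSections(pend, spooler, opts$itemsPerSlot, final = TRUE)
        if (!isWig) flushBedChrom()
      }
      curId <- gid
      part <- recs[g, , drop = FALSE]
      pend <- if (is.null(pend)) part else rbind(pend, part)
      pend <- drainSections(pend, spooler, opts$itemsPerSlot)
      if (isWig) {
        staging$append(part$id, part$start, part$end, part$value)
        accAdd(acc, part$value, part$end - part$start)
      } else {
        bedChromStarts <- c(bedChromStarts, part$start)
        bedChromEnds <- c(bedChromEnds, part$end)
      }
    }
  }
  pend <- drainSections(pend, spooler, opts$itemsPerSlot, final = TRUE)
  if (!isWig) flushBedChrom()
  if (nRecords == 0)
    bbiValidationError("no data: refusing to write an empty BBI file")

  sp <- spooler$finish()
  fullIndexOffset <- sink$pos()
  sink$append(buildRTree(sp$leaves, atOffset = fullIndexOffset,
                         blockSize = opts$blockSize,
                         itemsPerSlot = opts$itemsPerSlot,
                         endFileOffset = fullIndexOffset, endian = endian))

  levels <- planZoomLevels(nRecords, sumLen / nRecords, chromSizes, opts)
  levels <- levels[seq_len(min(length(levels), zoomReserve / 24))]
  zoomHeaders <- data.frame(reduction = double(), dataOffset = double(),
                            indexOffset = double())
  maxZoomRaw <- 0
  for (lv in levels) {
    z <- writeOneZoomLevel(sink, staging, lv, sizesById, opts)
    if (is.null(z)) next
    zoomHeaders <- rbind(zoomHeaders, data.frame(
      reduction = z$reduction, dataOffset = z$dataOffset,
      indexOffset = z$indexOffset))
    maxZoomRaw <- max(maxZoomRaw, z$maxRaw)
  }

  magic <- if (isWig) BIGWIG_MAGIC else BIGBED_MAGIC
  total <- accToSummary(acc)
  uncompressBufSize <- if (opts$compress) max(sp$maxRaw, maxZoomRaw) else 0
  dataCount <- if (isWig) sp$count else nRecords
  dfc <- if (isWig) 0L else {
    if (is.null(definedFieldCount)) min(fieldCount, 12L)
    else as.integer(definedFieldCount)
  }
  if (!isWig && !is.null(autoSql) && nrow(autoSql@fields) != fieldCount)
    bbiValidationError(sprintf(
      "autoSql schema has %d fields but records have %d columns",
      nrow(autoSql@fields), fieldCount))
  if (!isWig && dfc > fieldCount)
    bbiValidationError(sprintf(
      "definedFieldCount %d exceeds the %d columns present", dfc,
      fieldCount))
  sink$append(u32ToRaw(magic, endian))   # trailing magic
  writeMainHeader(sink, magic, 4, zoomHeaders, chromTreeOffset,
                  fullDataOffset, fullIndexOffset,
                  if (isWig) 0L else fieldCount, dfc, autoSqlOffset,
                  totalSummaryOffset, uncompressBufSize, endian)
  writeTotalSummary(sink, totalSummaryOffset, total, endian)
  sink$patch(fullDataOffset, u32ToRaw(dataCount, endian))
  ok <- TRUE
  invisible(list(kind = kind, version = 4, dataCount = dataCount,
                 zoomHeaders = zoomHeaders, totalSummary = total,
                 uncompressBufSize = uncompressBufSize, path = path))
}

#' Reduce a sorted record stream to zoom records
#'
#' One summary per non-empty aligned bin of width `level`, per chromosome;
#' bins with no data are omitted.  This is the in-memory counterpart of
#' the reduction the writer streams to disk, exposed for testing and
#' ad-hoc use.
#'
#' @param x data.frame with `chrom`, `start`, `end`, `value` (sorted).
#' @param level bin width in bp.
#' @param chromSizes a [ChromSizes-class] (bins are clipped to chromosome
#'   ends).
#' @return a zoom-record data.frame (`chrom`, `start`, `end`,
#'   `validCount`, `min`, `max`, `sum`, `sumSquares`).
#' @export
reduceToZoom <- function(x, level, chromSizes) {
  if (!nrow(x)) return(emptyZoomFrame())
  id <- match(x$chrom, chromSizes@chrom) - 1
  if (anyNA(id))
    bbiValidationError(sprintf("unknown chromosome '%s'",
                               x$chrom[is.na(id)][1L]))
  agg <- binAggregate(id, x$start, x$end, x$value, level)
  data.frame(chrom = chromSizes@chrom[agg$id + 1L], start = agg$bin,
             end = pmin(agg$bin + level, chromSizes@size[agg$id + 1L]),
             validCount = agg$validCount, min = agg$min, max = agg$max,
             sum = agg$sum, sumSquares = agg$sumSquares)
}
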