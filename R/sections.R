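# Data-section codecs.  A section is the unit of storage and compression:
# for BigWig, a 24-byte header plus packed items in one of three layouts
# (bedgraph = explicit start/end/value, variableStep = start/value with a
# shared span, fixedStep = values only); for BigBed, a run of
# (chromId, start, end, rest\0) records; for zoom levels, packed 32-byte
# summary records.  Sections never span chromosomes.  Compression is
# zlib (RFC 1950) DEFLATE when enabled.

SECTION_TYPES <- c(bedgraph = 1, variable = 2, fixed = 3)

bwSectionHeader <- function(id, chromStart, chromEnd, itemStep, itemSpan,
                            type, count, endian) {
  c(u32ToRaw(id, endian), u32ToRaw(chromStart, endian),
    u32ToRaw(chromEnd, endian), u32ToRaw(itemStep, endian),
    u32ToRaw(itemSpan, endian), u8ToRaw(type), u8ToRaw(0),
    u16ToRaw(count, endian))
}

# Encode one BigWig section (uncompressed bytes).  The writer always emits
# the bedgraph layout; the variable/fixed layouts are encodable too so the
# codec round-trips everything it can decode.
encodeBigWigSection <- function(id, start, end, value, type = "bedgraph",
                                itemStep = 0, itemSpan = 0,
                                endian = "little") {
  n <- length(start)
  stopifnot(n >= 1L, n <= 65535L)
  id <- id[1L]   # one chromosome per section
  tcode <- SECTION_TYPES[[type]]
  if (type == "bedgraph") {
    payload <- as.raw(rbind(matrix(u32ToRaw(start, endian), nrow = 4),
                            matrix(u32ToRaw(end, endian), nrow = 4),
                            matrix(f32ToRaw(value, endian), nrow = 4)))
    itemStep <- 0; itemSpan <- 0
  } else if (type == "variable") {
    span <- unique(end - start)
    if (length(span) != 1L)
      bbiValidationError("variableStep sections need a constant span")
    itemSpan <- span; itemStep <- 0
    payload <- as.raw(rbind(matrix(u32ToRaw(start, endian), nrow = 4),
                            matrix(f32ToRaw(value, endian), nrow = 4)))
  } else if (type == "fixed") {
    if (itemSpan <= 0 || itemStep <= 0)
      bbiValidationError("fixedStep sections need itemStep and itemSpan")
    payload <- f32ToRaw(value, endian)
  } else bbiValidationError(sprintf("unknown section type '%s'", type))
  c(bwSectionHeader(id, start[1L], end[n], itemStep, itemSpan, tcode, n,
                    endian),
    payload)
}

# Decode a run of concatenated BigWig sections from uncompressed bytes.
# Returns data.frame(id, start, end, value).
decodeBigWigSections <- function(r, endian = "little") {
  out <- list(); k <- 0L
  p <- 0L
  total <- length(r)
  while (p < total) {
    if (p + 24 > total)
      bbiFormatError("truncated BigWig section header", offset = p)
    hdr <- r[(p + 1):(p + 24)]
    id <- rawToU32(hdr[1:4], 1, endian)
    chromStart <- rawToU32(hdr[5:8], 1, endian)
    itemStep <- rawToU32(hdr[13:16], 1, endian)
    itemSpan <- rawToU32(hdr[17:20], 1, endian)
    type <- rawToU8(hdr[21L])
    cnt <- rawToU16(hdr[23:24], 1, endian)
    p <- p + 24L
    k <- k + 1L
    if (type == 1) {
      body <- r[(p + 1):(p + 12 * cnt)]
      if (length(body) < 12 * cnt)
        bbiFormatError("truncated bedgraph section", offset = p)
      m <- matrix(body, nrow = 12)
      out[[k]] <- data.frame(
        id = rep.int(id, cnt),
        start = rawToU32(as.raw(m[1:4, ]), cnt, endian),
        end = rawToU32(as.raw(m[5:8, ]), cnt, endian),
        value = rawToF32(as.raw(m[9:12, ]), cnt, endian))
      p <- p + 12L * cnt
    } else if (type == 2) {
      body <- r[(p + 1):(p + 8 * cnt)]
      if (length(body) < 8 * cnt)
        bbiFormatError("truncated variableStep section", offset = p)
      m <- matrix(body, nrow = 8)
      s <- rawToU32(as.raw(m[1:4, ]), cnt, endian)
      out[[k]] <- data.frame(id = rep.int(id, cnt), start = s,
                             end = s + itemSpan,
                             value = rawToF32(as.raw(m[5:8, ]), cnt, endian))
      p <- p + 8L * cnt
    } else if (type == 3) {
      body <- r[(p + 1):(p + 4 * cnt)]
      if (length(body) < 4 * cnt)
        bbiFormatError("truncated fixedStep section", offset = p)
      s <- chromStart + (seq_len(cnt) - 1) * itemStep
      out[[k]] <- data.frame(id = rep.int(id, cnt), start = s,
                             end = s + itemSpan,
                             value = rawToF32(body, cnt, endian))
      p <- p + 4L * cnt
    } else {
      bbiFormatError(sprintf("unknown BigWig section type %d", type),
                     offset = p - 24)
    }
  }
  if (!k) return(data.frame(id = double(), start = double(),
                            end = double(), value = double()))
  as.data.frame(data.table::rbindlist(out))
}

# Encode one BigBed section: records packed as chromId/start/end (u32 each)
# followed by the NUL-terminated tab-joined rest string.
encodeBigBedSection <- function(id, start, end, rest, endian = "little") {
  n <- length(start)
  hdrBytes <- as.raw(rbind(matrix(u32ToRaw(id, endian), nrow = 4),
                           matrix(u32ToRaw(start, endian), nrow = 4),
                           matrix(u32ToRaw(end, endian), nrow = 4)))
  strBytes <- writeBin(as.character(rest), raw())  # NUL-terminated each
  strLens <- nchar(rest, type = "bytes") + 1L
  recLens <- 12L + strLens
  recStart <- cumsum(c(0L, head(recLens, -1L)))
  out <- raw(sum(recLens))
  out[rep(recStart, each = 12L) + seq_len(12L)] <- hdrBytes
  out[rep(recStart + 12L, times = strLens) + sequence(strLens)] <- strBytes
  out
}

# Decode a run of BigBed records from uncompressed bytes.
decodeBigBedSection <- function(r, endian = "little") {
  nulls <- which(r == as.raw(0))
  ids <- double(); starts <- double(); ends <- double(); rests <- character()
  k <- 0L
  p <- 0L
  total <- length(r)
  # record boundaries: first NUL at or after p+12 ends each record
  while (p < total) {
    if (p + 12 > total)
      bbiFormatError("truncated BigBed record header", offset = p)
    z <- nulls[nulls > p + 12]
    # NUL may sit inside the 12-byte header of the NEXT record, so the
    # terminator is the first NUL strictly after the header we just read
    if (!length(z))
      bbiFormatError("unterminated BigBed record", offset = p)
    z <- z[1L]
    k <- k + 1L
    hdr <- r[(p + 1):(p + 12)]
    ids[k] <- rawToU32(hdr[1:4], 1, endian)
    starts[k] <- rawToU32(hdr[5:8], 1, endian)
    ends[k] <- rawToU32(hdr[9:12], 1, endian)
    rests[k] <- if (z > p + 13) rawToChar(r[(p + 13):(z - 1)]) else ""
    p <- z
  }
  data.frame(id = ids, start = starts, end = ends, rest = rests)
}

# zoom records: 32 bytes each; note min/max/sum/sumSquares are 32-bit
# floats in this layout (only the file-wide total summary uses doubles)
encodeZoomSection <- function(z, endian = "little") {
  as.raw(rbind(matrix(u32ToRaw(z$id, endian), nrow = 4),
               matrix(u32ToRaw(z$start, endian), nrow = 4),
               matrix(u32ToRaw(z$end, endian), nrow = 4),
               matrix(u32ToRaw(z$validCount, endian), nrow = 4),
               matrix(f32ToRaw(z$min, endian), nrow = 4),
               matrix(f32ToRaw(z$max, endian), nrow = 4),
               matrix(f32ToRaw(z$sum, endian), nrow = 4),
               matrix(f32ToRaw(z$sumSquares, endian), nrow = 4)))
}

decodeZoomSection <- function(r, endian = "little") {
  if (length(r) %% 32 != 0)
    bbiFormatError("zoom section length is not a multiple of 32")
  cnt <- length(r) %/% 32
  m <- matrix(r, nrow = 32)
  data.frame(id = rawToU32(as.raw(m[1:4, ]), cnt, endian),
             start = rawToU32(as.raw(m[5:8, ]), cnt, endian),
             end = rawToU32(as.raw(m[9:12, ]), cnt, endian),
             validCount = rawToU32(as.raw(m[13:16, ]), cnt, endian),
             min = rawToF32(as.raw(m[17:20, ]), cnt, endian),
             max = rawToF32(as.raw(m[21:24, ]), cnt, endian),
             sum = rawToF32(as.raw(m[25:28, ]), cnt, endian),
             sumSquares = rawToF32(as.raw(m[29:32, ]), cnt, endian))
}

compressSection <- function(r, compress = TRUE)
  if (compress) memCompress(r, type = "gzip") else r

# uncompressBufSize > 0 declares the maximum inflated size; exceeding it
# (or undecodable bytes) is a typed format error, never a wrong answer
decompressSection <- function(r, uncompressBufSize) {
  if (uncompressBufSize <= 0) return(r)
  out <- tryCatch(memDecompress(r, type = "gzip"),
                  error = function(e)
                    bbiFormatError(paste("corrupt compressed section:",
                                         conditionMessage(e))))
  if (length(out) > uncompressBufSize)
    bbiFormatError(sprintf(
      "inflated section size %d exceeds declared buffer size %.0f",
      length(out), uncompressBufSize))
  out
}

# compress a list of uncompressed section byte blocks, optionally on
# several worker processes; results are returned in input order and are
# byte-identical to the serial result whatever the thread count.
encodeSectionBatch <- function(rawList, compress = TRUE, threads = 1L) {
  if (!compress || !length(rawList)) return(rawList)
  if (threads > 1L && length(rawList) > 1L &&
      .Platform$OS.type == "unix") {
    parallel::mclapply(rawList, memCompress, type = "gzip",
                       mc.cores = threads, mc.preschedule = TRUE)
  } else {
    lapply(rawList, memCompress, type = "gzip")
  }
}
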