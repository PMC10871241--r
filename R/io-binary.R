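# Low-level binary packing/unpacking.  All integer fields travel as doubles
# on the R side (exact below 2^53, which comfortably covers u32 coordinates
# and u64 file offsets); raw bytes are assembled by explicit byte
# decomposition so unsigned 32/64-bit ranges are handled without relying on
# R's signed integer type.

u8ToRaw <- function(x) as.raw(x)

u16ToRaw <- function(x, endian = "little") {
  x <- as.double(x)
  m <- rbind(x %% 256, x %/% 256)
  if (endian == "big") m <- m[2:1, , drop = FALSE]
  as.raw(m)
}

u32ToRaw <- function(x, endian = "little") {
  x <- as.double(x)
  b0 <- x %% 256; x <- x %/% 256
  b1 <- x %% 256; x <- x %/% 256
  m <- rbind(b0, b1, x %% 256, x %/% 256)
  if (endian == "big") m <- m[4:1, , drop = FALSE]
  as.raw(m)
}

u64ToRaw <- function(x, endian = "little") {
  x <- as.double(x)
  m <- matrix(0, 8, length(x))
  for (i in 1:8) { m[i, ] <- x %% 256; x <- x %/% 256 }
  if (endian == "big") m <- m[8:1, , drop = FALSE]
  as.raw(m)
}

f32ToRaw <- function(x, endian = "little")
  writeBin(as.double(x), raw(), size = 4L, endian = endian)

f64ToRaw <- function(x, endian = "little")
  writeBin(as.double(x), raw(), size = 8L, endian = endian)

rawToU8 <- function(r) as.double(as.integer(r))

rawToU16 <- function(r, n = length(r) %/% 2L, endian = "little")
  as.double(readBin(r, "integer", n = n, size = 2L, signed = FALSE,
                    endian = endian))

rawToU32 <- function(r, n = length(r) %/% 4L, endian = "little") {
  v <- readBin(r, "integer", n = n, size = 4L, endian = endian)
  v <- as.double(v)
  neg <- v < 0
  if (any(neg)) v[neg] <- v[neg] + 4294967296
  v
}

rawToU64 <- function(r, n = length(r) %/% 8L, endian = "little") {
  w <- rawToU32(r, 2L * n, endian = endian)
  odd <- seq(1L, by = 2L, length.out = n)
  if (endian == "little") w[odd] + w[odd + 1L] * 4294967296
  else                    w[odd] * 4294967296 + w[odd + 1L]
}

rawToF32 <- function(r, n = length(r) %/% 4L, endian = "little")
  readBin(r, "numeric", n = n, size = 4L, endian = endian)

rawToF64 <- function(r, n = length(r) %/% 8L, endian = "little")
  readBin(r, "numeric", n = n, size = 8L, endian = endian)

#' Round values through IEEE-754 single precision
#'
#' BigWig values and zoom statistics are stored as 32-bit floats; this
#' applies that rounding, so expected values can be prepared for exact
#' comparison with what a file will return.
#'
#' @param x numeric vector.
#' @return `x` with each element rounded to the nearest single-precision
#'   value.
#' @export
asFloat32 <- function(x)
  readBin(writeBin(as.double(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)

# gather `width` consecutive bytes starting at each (0-based) offset `off`
# of raw vector r -- used to deinterleave packed record arrays
gatherBytes <- function(r, off, width)
  r[rep(off, each = width) + seq_len(width)]


## ---- byte sources -------------------------------------------------------
# A "byte source" abstracts a seekable, readable sequence of bytes: local
# files and in-memory raw vectors are provided; anything honoring the same
# three closures (read(offset, n), size(), close()) plugs in.  Reads past
# the end return fewer bytes than requested; callers that need an exact
# count use sourceReadExact(), which raises a typed format error on
# truncation.

newRawSource <- function(bytes, desc = "<raw>") {
  force(bytes)
  structure(list(
    read = function(offset, n) {
      if (n <= 0) return(raw())
      from <- offset + 1
      to <- min(offset + n, length(bytes))
      if (from > to) raw() else bytes[from:to]
    },
    size = function() length(bytes),
    close = function() invisible(NULL),
    desc = desc
  ), class = "bbi_source")
}

newFileSource <- function(path) {
  con <- file(path, "rb")
  sz <- file.size(path)
  structure(list(
    read = function(offset, n) {
      if (n <= 0) return(raw())
      seek(con, where = offset, origin = "start")
      readBin(con, raw(), n = n)
    },
    size = function() sz,
    close = function() close(con),
    desc = path
  ), class = "bbi_source")
}

# wrap a source so that reads are tallied; `stats()` returns the counters.
# Used to verify the sparse-index access contract.
countingSource <- function(src) {
  bytesRead <- 0
  readCalls <- 0L
  structure(list(
    read = function(offset, n) {
      out <- src$read(offset, n)
      bytesRead <<- bytesRead + length(out)
      readCalls <<- readCalls + 1L
      out
    },
    size = src$size,
    close = src$close,
    desc = paste0("counting(", src$desc, ")"),
    stats = function() list(bytesRead = bytesRead, readCalls = readCalls)
  ), class = "bbi_source")
}

asByteSource <- function(x) {
  if (inherits(x, "bbi_source")) return(x)
  if (is.raw(x)) return(newRawSource(x))
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) bbiFormatError(sprintf("file not found: %s", x))
    return(newFileSource(x))
  }
  bbiFormatError("cannot interpret object as a byte source")
}

sourceReadExact <- function(src, offset, n) {
  r <- src$read(offset, n)
  if (length(r) < n)
    bbiFormatError(sprintf("truncated file: wanted %.0f bytes, got %d",
                           n, length(r)), offset = offset)
  r
}
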