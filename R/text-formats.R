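# Text precursors of the BBI formats: bedGraph, Wiggle (fixedStep /
# variableStep), BED and chrom.sizes.  All parsers are chunked single-pass
# streams over a connection: peak resident record count is bounded by the
# chunk size, independent of file length.  Fields may be separated by any
# run of tabs/spaces on input; emitters produce tabs only.

# turn path ("-" = stdin) / connection / raw text into a line-chunk puller
lineChunker <- function(input, chunkSize = 65536L) {
  if (inherits(input, "connection")) {
    con <- input
    if (!isOpen(con)) open(con, "r")
  } else if (is.character(input) && length(input) == 1L) {
    con <- if (identical(input, "-")) file("stdin", "r")
           else file(input, "r")
  } else {
    bbiParseError("text input must be a file path, \"-\", or a connection")
  }
  owned <- TRUE   # the chunker consumes (and closes) its input
  lineNo <- 0L
  done <- FALSE
  list(
    nextChunk = function() {
      if (done) return(NULL)
      lines <- readLines(con, n = chunkSize, warn = FALSE)
      if (!length(lines)) {
        done <<- TRUE
        if (owned) close(con)
        return(NULL)
      }
      first <- lineNo + 1L
      lineNo <<- lineNo + length(lines)
      list(lines = lines, first = first)
    },
    finish = function() {
      if (!done && owned) close(con)
      done <<- TRUE
    }
  )
}

# lines that carry no data in any of the UCSC text formats
isSkipLine <- function(lines)
  !nzchar(trimws(lines)) | grepl("^(track|browser)([ \t]|$)|^#", lines)

splitFields <- function(lines)
  strsplit(sub("^[ \t]+", "", lines), "[ \t]+")

strictNumeric <- function(x, what, lineNos) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & !is.na(x)
  if (any(bad))
    bbiParseError(sprintf("malformed %s '%s'", what, x[which(bad)[1L]]),
                  line = lineNos[which(bad)[1L]])
  v
}

strictCoord <- function(x, what, lineNos) {
  v <- strictNumeric(x, what, lineNos)
  bad <- is.na(v) | v < 0 | v != floor(v)
  if (any(bad))
    bbiParseError(sprintf("%s must be a non-negative integer, got '%s'",
                          what, x[which(bad)[1L]]),
                  line = lineNos[which(bad)[1L]])
  v
}

emptyIntervals <- function()
  data.frame(chrom = character(), start = double(), end = double(),
             value = double())

#' Parse bedGraph text lazily
#'
#' Yields `chrom start end value` intervals (0-based half-open) in file
#' order as a chunked stream; `track`, `browser`, comment and blank lines
#' are skipped.
#'
#' @param input file path, `"-"` for standard input, or a connection.
#' @param chunkSize lines per batch (bounds resident memory).
#' @return a stream (see [collectStream()]) of data.frames with columns
#'   `chrom`, `start`, `end`, `value`.
#' @examples
#' s <- parseBedGraph(textConnection("chr1\t0\t100\t1.5"))
#' collectStream(s)
#' @export
parseBedGraph <- function(input, chunkSize = 65536L) {
  ch <- lineChunker(input, chunkSize)
  newStream(function() {
    repeat {
      chunk <- ch$nextChunk()
      if (is.null(chunk)) return(NULL)
      lines <- chunk$lines
      lineNos <- chunk$first + seq_along(lines) - 1L
      keep <- !isSkipLine(lines)
      if (!any(keep)) return(emptyIntervals())
      lines <- lines[keep]; lineNos <- lineNos[keep]
      f <- splitFields(lines)
      nf <- lengths(f)
      if (any(nf != 4L))
        bbiParseError(sprintf("expected 4 fields, got %d", nf[nf != 4L][1L]),
                      line = lineNos[nf != 4L][1L])
      m <- matrix(unlist(f, use.names = FALSE), nrow = 4L)
      start <- strictCoord(m[2L, ], "start", lineNos)
      end <- strictCoord(m[3L, ], "end", lineNos)
      value <- strictNumeric(m[4L, ], "value", lineNos)
      bad <- start >= end
      if (any(bad))
        bbiValidationError(
          sprintf("empty or inverted interval [%s, %s)",
                  m[2L, bad][1L], m[3L, bad][1L]),
          line = lineNos[bad][1L])
      return(data.frame(chrom = m[1L, ], start = start, end = end,
                        value = value))
    }
  }, desc = "bedGraph", finish = ch$finish)
}

#' Parse Wiggle (fixedStep / variableStep) text lazily
#'
#' Converts Wiggle's 1-based starts to the 0-based half-open convention
#' used everywhere else in this package.  `span` defaults to 1; adjacent
#' equal-valued steps are preserved, never coalesced.
#'
#' @inheritParams parseBedGraph
#' @return a stream of `chrom`/`start`/`end`/`value` data.frames.
#' @export
parseWiggle <- function(input, chunkSize = 65536L) {
  ch <- lineChunker(input, chunkSize)
  # declaration state carried across chunks
  st <- new.env(parent = emptyenv())
  st$mode <- NA_character_   # "fixed" | "variable"
  st$chrom <- NA_character_
  st$pos <- NA_real_         # next start (0-based) for fixedStep
  st$step <- NA_real_
  st$span <- 1

  parseDecl <- function(line, lineNo) {
    mode <- if (grepl("^fixedStep", line)) "fixed" else "variable"
    toks <- splitFields(line)[[1L]][-1L]
    kv <- strsplit(toks, "=", fixed = TRUE)
    if (any(lengths(kv) != 2L))
      bbiParseError("malformed declaration attribute", line = lineNo)
    keys <- vapply(kv, `[`, "", 1L)
    vals <- vapply(kv, `[`, "", 2L)
    att <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    chrom <- att("chrom")
    if (is.na(chrom))
      bbiParseError("declaration missing required chrom=", line = lineNo)
    span <- att("span")
    st$span <- if (is.na(span)) 1 else strictCoord(span, "span", lineNo)
    if (st$span < 1) bbiParseError("span must be >= 1", line = lineNo)
    st$chrom <- chrom
    st$mode <- mode
    if (mode == "fixed") {
      start <- att("start"); step <- att("step")
      if (is.na(start) || is.na(step))
        bbiParseError("fixedStep declaration missing start= or step=",
                      line = lineNo)
      start <- strictCoord(start, "start", lineNo)
      if (start < 1)
        bbiParseError("Wiggle starts are 1-based; start must be >= 1",
                      line = lineNo)
      st$pos <- start - 1       # to 0-based
      st$step <- strictCoord(step, "step", lineNo)
      if (st$step < 1) bbiParseError("step must be >= 1", line = lineNo)
    }
  }

  segToIntervals <- function(lines, lineNos) {
    if (is.na(st$mode))
      bbiParseError("data line before any fixedStep/variableStep declaration",
                    line = lineNos[1L])
    if (st$mode == "fixed") {
      value <- strictNumeric(lines, "value", lineNos)
      start <- st$pos + (seq_along(value) - 1) * st$step
      st$pos <- st$pos + length(value) * st$step
      data.frame(chrom = st$chrom, start = start, end = start + st$span,
                 value = value)
    } else {
      f <- splitFields(lines)
      nf <- lengths(f)
      if (any(nf != 2L))
        bbiParseError("variableStep data lines need 2 fields (start value)",
                      line = lineNos[nf != 2L][1L])
      m <- matrix(unlist(f, use.names = FALSE), nrow = 2L)
      start <- strictCoord(m[1L, ], "start", lineNos)
      if (any(start < 1))
        bbiParseError("Wiggle starts are 1-based; start must be >= 1",
                      line = lineNos[start < 1][1L])
      value <- strictNumeric(m[2L, ], "value", lineNos)
      data.frame(chrom = st$chrom, start = start - 1,
                 end = start - 1 + st$span, value = value)
    }
  }

  newStream(function() {
    chunk <- ch$nextChunk()
    if (is.null(chunk)) return(NULL)
    lines <- chunk$lines
    lineNos <- chunk$first + seq_along(lines) - 1L
    keep <- !isSkipLine(lines)
    lines <- lines[keep]; lineNos <- lineNos[keep]
    if (!length(lines)) return(emptyIntervals())
    isDecl <- grepl("^(fixedStep|variableStep)([ \t]|$)", lines)
    # split into runs of data lines between declarations, in order
    seg <- cumsum(isDecl)
    out <- list(); k <- 0L
    for (g in split(seq_along(lines), seg)) {
      if (isDecl[g[1L]]) {
        parseDecl(lines[g[1L]], lineNos[g[1L]])
        g <- g[-1L]
      }
      if (length(g)) {
        k <- k + 1L
        out[[k]] <- segToIntervals(lines[g], lineNos[g])
      }
    }
    if (!k) return(emptyIntervals())
    as.data.frame(data.table::rbindlist(out))
  }, desc = "wiggle", finish = ch$finish)
}

#' Parse BED text lazily
#'
#' Yields records with the first three columns parsed and all remaining
#' columns preserved verbatim, tab-joined, in `rest`.  The column count
#' must be constant across the file.
#'
#' @inheritParams parseBedGraph
#' @param fieldCount expected number of columns; inferred from the first
#'   record when `NULL`.
#' @return a stream of data.frames with columns `chrom`, `start`, `end`,
#'   `rest`.
#' @export
parseBed <- function(input, fieldCount = NULL, chunkSize = 65536L) {
  ch <- lineChunker(input, chunkSize)
  nfExpect <- if (is.null(fieldCount)) NA_integer_ else as.integer(fieldCount)
  newStream(function() {
    chunk <- ch$nextChunk()
    if (is.null(chunk)) return(NULL)
    lines <- chunk$lines
    lineNos <- chunk$first + seq_along(lines) - 1L
    keep <- !isSkipLine(lines)
    lines <- lines[keep]; lineNos <- lineNos[keep]
    if (!length(lines))
      return(data.frame(chrom = character(), start = double(),
                        end = double(), rest = character()))
    f <- splitFields(lines)
    nf <- lengths(f)
    if (is.na(nfExpect)) {
      if (nf[1L] < 3L)
        bbiParseError(sprintf("BED needs >= 3 columns, got %d", nf[1L]),
                      line = lineNos[1L])
      nfExpect <<- nf[1L]
    }
    if (any(nf != nfExpect)) {
      i <- which(nf != nfExpect)[1L]
      bbiValidationError(
        sprintf("column count drift: expected %d columns, got %d",
                nfExpect, nf[i]), line = lineNos[i])
    }
    m <- matrix(unlist(f, use.names = FALSE), nrow = nfExpect)
    start <- strictCoord(m[2L, ], "start", lineNos)
    end <- strictCoord(m[3L, ], "end", lineNos)
    bad <- start >= end
    if (any(bad))
      bbiValidationError(sprintf("empty or inverted interval [%s, %s)",
                                 m[2L, bad][1L], m[3L, bad][1L]),
                         line = lineNos[bad][1L])
    rest <- if (nfExpect > 3L)
      do.call(paste, c(lapply(4:nfExpect, function(i) m[i, ]), sep = "\t"))
    else character(length(start)) # ""
    data.frame(chrom = m[1L, ], start = start, end = end, rest = rest)
  }, desc = "bed", finish = ch$finish)
}

#' Read a chrom.sizes file
#'
#' @param input file path or connection with two whitespace-delimited
#'   columns: chromosome name and length.
#' @return a [ChromSizes-class] preserving line order.
#' @export
parseChromSizes <- function(input) {
  ch <- lineChunker(input)
  nm <- character(); sz <- double()
  while (!is.null(chunk <- ch$nextChunk())) {
    lines <- chunk$lines
    lineNos <- chunk$first + seq_along(lines) - 1L
    keep <- !isSkipLine(lines)
    lines <- lines[keep]; lineNos <- lineNos[keep]
    if (!length(lines)) next
    f <- splitFields(lines)
    nf <- lengths(f)
    if (any(nf != 2L))
      bbiParseError(sprintf("chrom.sizes needs 2 columns, got %d",
                            nf[nf != 2L][1L]), line = lineNos[nf != 2L][1L])
    m <- matrix(unlist(f, use.names = FALSE), nrow = 2L)
    len <- strictCoord(m[2L, ], "length", lineNos)
    dup <- m[1L, ] %in% nm | duplicated(m[1L, ])
    if (any(dup))
      bbiValidationError(sprintf("duplicate chromosome name '%s'",
                                 m[1L, dup][1L]), line = lineNos[dup][1L])
    nm <- c(nm, m[1L, ]); sz <- c(sz, len)
  }
  new("ChromSizes", chrom = nm, size = sz)
}

## ---- emission -----------------------------------------------------------

#' Render values as bedGraph text numbers
#'
#' Shortest decimal representation that round-trips through a 32-bit float,
#' so emitted text re-parses to the exact stored value and output is stable
#' across runs.
#'
#' @param v numeric vector.
#' @return character vector.
#' @export
formatBbiValue <- function(v) {
  v32 <- asFloat32(v)
  out <- character(length(v32))
  todo <- rep(TRUE, length(v32))
  special <- !is.finite(v32)
  if (any(special)) {
    out[special] <- as.character(v32[special])
    todo[special] <- FALSE
  }
  for (d in 1:9) {
    if (!any(todo)) break
    cand <- sprintf("%.*g", d, v32[todo])
    ok <- asFloat32(as.numeric(cand)) == v32[todo]
    out[todo][ok] <- cand[ok]
    todo[todo] <- !ok
  }
  if (any(todo)) out[todo] <- sprintf("%.9g", v32[todo])
  out
}

#' Write intervals as bedGraph text
#'
#' @param x data.frame or stream of `chrom`/`start`/`end`/`value` records,
#'   sorted and non-overlapping per chromosome.
#' @param dest file path, `"-"` for standard output, or a connection.
#' @return number of lines written, invisibly.
#' @export
emitBedGraph <- function(x, dest) {
  s <- asStream(x)
  if (inherits(dest, "connection")) {
    con <- dest
    owned <- !isOpen(con)
    if (owned) open(con, "w")
  } else {
    con <- if (identical(dest, "-")) stdout() else file(dest, "w")
    owned <- !identical(dest, "-")
  }
  on.exit({
    if (owned) close(con)
    finishStream(s)
  })
  st <- newSortState()
  total <- 0
  while (!is.null(b <- s$nextBatch())) {
    if (!nrow(b)) next
    checkSortedIntervals(b, st, chromOrder = NULL, requireDisjoint = TRUE)
    writeLines(paste(b$chrom, format(b$start, scientific = FALSE, trim = TRUE),
                     format(b$end, scientific = FALSE, trim = TRUE),
                     formatBbiValue(b$value), sep = "\t"), con)
    total <- total + nrow(b)
  }
  invisible(total)
}

newSortState <- function() {
  e <- new.env(parent = emptyenv())
  e$lastChrom <- NA_character_
  e$lastStart <- -Inf
  e$lastEnd <- -Inf
  e$seen <- character()
  e
}

# shared sortedness validation for interval/record batches, carrying state
# across batches in `st` (see newSortState).  With requireDisjoint, records
# on one chromosome must be non-overlapping (start >= previous end);
# without, only start order is required (BED records may overlap).
# chromOrder (a ChromSizes or NULL) additionally pins chromosome order to
# the chrom.sizes line order and rejects unknown chromosomes; with NULL any
# chromosome order is accepted but each chromosome must form a single run.
checkSortedIntervals <- function(b, st, chromOrder = NULL,
                                 requireDisjoint = TRUE) {
  chrom <- b$chrom
  n <- length(chrom)
  runs <- rle(chrom)
  runChroms <- runs$values
  contin <- !is.na(st$lastChrom) && runChroms[1L] == st$lastChrom
  newNames <- if (contin) runChroms[-1L] else runChroms
  if (anyDuplicated(runChroms) || any(newNames %in% st$seen)) {
    d <- c(runChroms[duplicated(runChroms)], newNames[newNames %in% st$seen])
    bbiValidationError(sprintf(
      "chromosome '%s' appears in more than one run; input must be sorted",
      d[1L]))
  }
  if (!is.null(chromOrder)) {
    idx <- match(runChroms, names(chromOrder))
    if (anyNA(idx))
      bbiValidationError(sprintf("unknown chromosome '%s'",
                                 runChroms[is.na(idx)][1L]))
    prev <- c(if (contin) idx[1L] else
                if (is.na(st$lastChrom)) -Inf else
                  match(st$lastChrom, names(chromOrder)),
              idx[-length(idx)])
    if (any(idx < prev))
      bbiValidationError(sprintf(
        "chromosomes out of chrom.sizes order: '%s' after '%s'",
        runChroms[which(idx < prev)[1L]],
        c(st$lastChrom, runChroms)[which(idx < prev)[1L]]))
  }
  newChrom <- c(!contin, chrom[-1L] != chrom[-n])
  bound <- if (requireDisjoint) c(st$lastEnd, b$end[-n])
           else c(st$lastStart, b$start[-n])
  bound[newChrom] <- -Inf
  bad <- b$start < bound
  if (any(bad)) {
    i <- which(bad)[1L]
    prev <- if (i == 1L)
      sprintf("%s:[%.0f,%.0f)", st$lastChrom, st$lastStart, st$lastEnd)
    else sprintf("%s:[%.0f,%.0f)", chrom[i - 1L], b$start[i - 1L],
                 b$end[i - 1L])
    bbiValidationError(sprintf(
      "intervals unsorted%s: %s followed by %s:[%.0f,%.0f)",
      if (requireDisjoint) " or overlapping" else "",
      prev, chrom[i], b$start[i], b$end[i]))
  }
  st$seen <- c(st$seen, setdiff(newNames, st$seen))
  st$lastChrom <- chrom[n]
  st$lastStart <- b$start[n]
  st$lastEnd <- max(b$end[chrom == chrom[n]],
                    if (contin && runChroms[length(runChroms)] == runChroms[1L])
                      st$lastEnd else -Inf)
  invisible(TRUE)
}
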