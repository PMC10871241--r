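# Streaming multi-way BigWig merge and region averaging.  Both operate
# through bounded windows backed by the R-tree block lists, so peak
# resident interval count scales with (number of inputs x items per
# section), independent of chromosome length.

# sequential per-chromosome block reader for one BigWig: returns closures
# to pull one data block's intervals at a time, plus the coordinate up to
# which the stream is fully known (the next unread block's start)
bwChromBlockCursor <- function(file, id) {
  leaves <- rtreeLeaves(file@source, file@fullIndexOffset, .endian(file))
  leaves <- leaves[leaves$id == id, , drop = FALSE]
  i <- 0L
  list(
    frontier = function() if (i < nrow(leaves)) leaves$start[i + 1L] else Inf,
    nextBlock = function() {
      if (i >= nrow(leaves)) return(NULL)
      i <<- i + 1L
      r <- sourceReadExact(file@source, leaves$offset[i], leaves$size[i])
      file@stats$sectionsRead <- file@stats$sectionsRead + 1
      d <- decodeBigWigSections(decompressSection(r, file@uncompressBufSize),
                                .endian(file))
      d[d$id == id, c("start", "end", "value"), drop = FALSE]
    }
  )
}

#' Merge BigWig files into a combined step function
#'
#' Computes, per base, the sum (or maximum) of the input files' values
#' plus `adjust`, and emits maximal runs of constant value as a lazy
#' stream of bedGraph-style intervals.  Runs with value `<= threshold` are
#' omitted; bases covered by no input produce no output.  The merge is a
#' windowed ordered sweep over the inputs' data blocks: memory is
#' independent of chromosome length.
#'
#' @param files list of [BigWigHandle-class] handles or file paths.
#' @param op `"sum"` or `"max"`.
#' @param threshold omit runs with value at or below this (default 0).
#' @param adjust added to every output value.
#' @param clipValue if non-`NULL`, values above this are clipped to it.
#' @param tally optional environment collecting residency statistics
#'   (`peakResident`).
#' @return a stream (see [collectStream()]) of `chrom`/`start`/`end`/
#'   `value` data.frames; chromosomes appear in name order.
#' @export
mergeBigWigs <- function(files, op = c("sum", "max"), threshold = 0,
                         adjust = 0, clipValue = NULL, tally = NULL) {
  op <- match.arg(op)
  opened <- list()   # handles this function opened (closed at stream end)
  closeOpened <- function() {
    lapply(opened, close)
    opened <<- list()
  }
  files <- tryCatch({
    files <- lapply(files, function(f) {
      if (is(f, "BigWigHandle")) return(f)
      h <- BigWigHandle(f)
      opened[[length(opened) + 1L]] <<- h
      h
    })
    if (length(files) < 2L)
      bbiValidationError("merging needs at least two BigWig inputs")
    files
  }, error = function(e) { closeOpened(); stop(e) })
  # chromosome universe: union, consistent lengths required where shared
  tabs <- lapply(files, function(f) f@chromTable)
  all <- as.data.frame(data.table::rbindlist(
    lapply(tabs, function(t) t[, c("chrom", "size")])))
  chk <- unique(all)
  if (anyDuplicated(chk$chrom)) {
    closeOpened()
    bbiValidationError(sprintf(
      "conflicting lengths for chromosome '%s' across inputs",
      chk$chrom[duplicated(chk$chrom)][1L]))
  }
  chroms <- sort(unique(all$chrom), method = "radix")

  ci <- 0L          # current chromosome index
  state <- NULL     # per-chromosome sweep state
  if (is.null(tally)) tally <- newStreamTally()
  tally$peakResident <- 0L

  initChrom <- function(chrom) {
    members <- which(vapply(tabs, function(t) chrom %in% t$chrom, TRUE))
    state <<- list(
      chrom = chrom,
      cursors = lapply(members, function(i)
        bwChromBlockCursor(files[[i]],
                           tabs[[i]]$id[match(chrom, tabs[[i]]$chrom)])),
      buffers = rep(list(NULL), length(members)),
      cur = 0,
      pending = NULL)   # held-back last run: c(start, end, value)
  }

  stepWindow <- function() {
    # advance every cursor that blocks the frontier, then sweep the window
    st <- state
    fr <- vapply(st$cursors, function(cu) cu$frontier(), 1)
    while (any(fr <= st$cur + 0)) {
      for (i in which(fr <= st$cur)) {
        b <- st$cursors[[i]]$nextBlock()
        if (!is.null(b))
          st$buffers[[i]] <- if (is.null(st$buffers[[i]])) b
                             else rbind(st$buffers[[i]], b)
      }
      fr <- vapply(st$cursors, function(cu) cu$frontier(), 1)
    }
    safe <- min(fr)
    resident <- sum(vapply(st$buffers, function(b)
      if (is.null(b)) 0L else nrow(b), 1L))
    tally$peakResident <- max(tally$peakResident, resident)
    # clipped pieces inside [cur, safe)
    pieces <- lapply(st$buffers, function(b) {
      if (is.null(b)) return(NULL)
      sel <- b$end > st$cur & b$start < safe
      if (!any(sel)) return(NULL)
      data.frame(start = pmax(b$start[sel], st$cur),
                 end = pmin(b$end[sel], safe), value = b$value[sel])
    })
    pc <- data.table::rbindlist(pieces)
    runs <- NULL
    if (nrow(pc)) {
      cuts <- sort(unique(c(pc$start, pc$end)))
      seg <- findInterval(pc$start, cuts)
      segLast <- findInterval(pc$end - 1e-9, cuts)  # end lands on a cut
      nb <- segLast - seg + 1L
      i <- rep.int(seq_len(nrow(pc)), nb)
      sidx <- rep.int(seg, nb) + sequence(nb) - 1L
      dt <- data.table::data.table(s = sidx, v = pc$value[i])
      agg <- if (op == "sum") dt[, list(v = sum(v)), by = "s"]
             else dt[, list(v = max(v)), by = "s"]
      data.table::setorder(agg, s)
      v <- asFloat32(asFloat32(agg$v) + adjust)
      if (!is.null(clipValue)) v <- pmin(v, clipValue)
      runs <- data.frame(start = cuts[agg$s], end = cuts[agg$s + 1L],
                         value = v)
      # coalesce contiguous equal-valued runs
      brk <- cumsum(c(TRUE, !(runs$value[-1L] == runs$value[-nrow(runs)] &
                              runs$start[-1L] == runs$end[-nrow(runs)])))
      runs <- data.frame(start = runs$start[!duplicated(brk)],
                         end = tapply(runs$end, brk, max),
                         value = runs$value[!duplicated(brk)],
                         row.names = NULL)
    }
    # splice with the held-back run from the previous window
    done <- is.infinite(safe)
    if (!is.null(st$pending)) {
      p <- st$pending
      if (!is.null(runs) && nrow(runs) && runs$start[1L] == p[2L] &&
          runs$value[1L] == p[3L]) {
        runs$start[1L] <- p[1L]
      } else {
        runs <- rbind(data.frame(start = p[1L], end = p[2L], value = p[3L]),
                      runs)
      }
      st$pending <- NULL
    }
    if (!done && !is.null(runs) && nrow(runs) &&
        runs$end[nrow(runs)] == safe) {
      st$pending <- c(runs$start[nrow(runs)], runs$end[nrow(runs)],
                      runs$value[nrow(runs)])
      runs <- runs[-nrow(runs), , drop = FALSE]
    }
    st$buffers <- lapply(st$buffers, function(b) {
      if (is.null(b)) return(NULL)
      b <- b[b$end > safe, , drop = FALSE]
      if (nrow(b)) b else NULL
    })
    st$cur <- safe
    state <<- st
    list(runs = runs, done = done)
  }

  newStream(function() {
    repeat {
      if (is.null(state)) {
        if (ci >= length(chroms)) {
          closeOpened()
          return(NULL)
        }
        ci <<- ci + 1L
        initChrom(chroms[ci])
      }
      res <- stepWindow()
      if (res$done) state <<- NULL
      runs <- res$runs
      if (!is.null(runs) && nrow(runs)) {
        keep <- runs$value > threshold
        if (any(keep)) {
          out <- runs[keep, , drop = FALSE]
          rownames(out) <- NULL
          chromName <- if (is.null(state)) chroms[ci] else state$chrom
          return(cbind(data.frame(chrom = rep.int(chromName, nrow(out))),
                       out))
        }
      }
    }
  }, desc = sprintf("merge(%d BigWigs, %s)", length(files), op),
  finish = closeOpened)
}

#' Average a BigWig over BED regions
#'
#' For each region, aggregates the signal restricted to it; output mirrors
#' the classic six-column report: `name`, `size` (bp), `covered` (bases
#' with data), `sum`, `mean0` (sum/size) and `mean` (sum/covered, 0 when
#' nothing is covered).  Regions are processed one at a time through the
#' index, so memory is independent of chromosome length.
#'
#' @param bw a [BigWigHandle-class] or path.
#' @param regions data.frame/stream of BED records (see [parseBed()]).
#'   Column 4, when present, supplies the (unique) region names; otherwise
#'   names are synthesized as `chrom:start-end`.
#' @param tally optional environment collecting residency statistics.
#' @return data.frame with columns `name`, `size`, `covered`, `sum`,
#'   `mean0`, `mean`.
#' @export
bigWigAverageOverBed <- function(bw, regions, tally = NULL) {
  openedHere <- !is(bw, "BigWigHandle")
  f <- if (openedHere) BigWigHandle(bw) else bw
  s <- asStream(regions)
  on.exit({
    finishStream(s)
    if (openedHere) close(f)
  })
  if (is.null(tally)) tally <- newStreamTally()
  tally$peakResident <- 0L
  seen <- new.env(parent = emptyenv())
  out <- list(); k <- 0L
  while (!is.null(b <- s$nextBatch())) {
    if (!nrow(b)) next
    hasName <- "rest" %in% names(b) & any(nzchar(b$rest))
    nm <- if (hasName) vapply(strsplit(b$rest, "\t"), `[`, "", 1L)
          else sprintf("%s:%.0f-%.0f", b$chrom, b$start, b$end)
    for (i in seq_len(nrow(b))) {
      if (!is.null(seen[[nm[i]]]))
        bbiValidationError(sprintf("duplicate region name '%s'", nm[i]))
      seen[[nm[i]]] <- TRUE
      size <- b$end[i] - b$start[i]
      hit <- bptLookup(f@chromTable, b$chrom[i])
      if (is.null(hit)) {
        warning(sprintf("chromosome '%s' absent from BigWig; region '%s' reported uncovered",
                        b$chrom[i], nm[i]), call. = FALSE)
        d <- data.frame(start = double(), end = double(), value = double())
      } else {
        qe <- min(b$end[i], hit$size)
        d <- if (b$start[i] < qe)
          queryIntervals(f, b$chrom[i], b$start[i], qe, clip = TRUE)
        else data.frame(start = double(), end = double(), value = double())
      }
      tally$peakResident <- max(tally$peakResident, nrow(d))
      len <- d$end - d$start
      covered <- sum(len)
      total <- sum(d$value * len)
      k <- k + 1L
      out[[k]] <- data.frame(
        name = nm[i], size = size, covered = covered, sum = total,
        mean0 = total / size,
        mean = if (covered > 0) total / covered else 0)
    }
  }
  if (!k) return(data.frame(name = character(), size = double(),
                            covered = double(), sum = double(),
                            mean0 = double(), mean = double()))
  as.data.frame(data.table::rbindlist(out))
}
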