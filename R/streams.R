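# Record streams.  A BbiStream is a one-shot pull iterator: an object whose
# nextBatch() returns a data.frame of records (possibly zero rows) or NULL
# when exhausted.  Parsers produce streams so files larger than memory can
# be converted in a single pass; writers consume them; a plain data.frame
# is accepted anywhere a stream is and is chunked transparently.

newStream <- function(nextBatch, desc = "stream", finish = NULL) {
  structure(list(nextBatch = nextBatch, desc = desc, finish = finish),
            class = "bbi_stream")
}

# release a stream's underlying resources (no-op for plain streams);
# consumers call this when abandoning a stream early (e.g. on error)
finishStream <- function(s) {
  if (inherits(s, "bbi_stream") && is.function(s$finish)) s$finish()
  invisible(NULL)
}

#' @export
print.bbi_stream <- function(x, ...) {
  cat("BbiStream:", x$desc, "\n")
  invisible(x)
}

# chunk a materialized data.frame into a stream
chunkStream <- function(df, chunkSize = 65536L) {
  i <- 0L
  n <- nrow(df)
  newStream(function() {
    if (i >= n) return(NULL)
    j <- min(i + chunkSize, n)
    out <- df[(i + 1L):j, , drop = FALSE]
    i <<- j
    rownames(out) <- NULL
    out
  }, desc = sprintf("data.frame[%d rows]", n))
}

asStream <- function(x, chunkSize = 65536L) {
  if (inherits(x, "bbi_stream")) return(x)
  if (is.data.frame(x)) return(chunkStream(x, chunkSize))
  bbiValidationError("expected a data.frame or a record stream")
}

#' Materialize a record stream
#'
#' Drains a stream produced by one of the lazy parsers ([parseBedGraph()],
#' [parseWiggle()], [parseBed()]) into a single data.frame.
#'
#' @param x a stream or data.frame.
#' @return a data.frame of all records.
#' @export
collectStream <- function(x) {
  if (is.data.frame(x)) return(x)
  out <- list()
  i <- 0L
  while (!is.null(b <- x$nextBatch())) {
    i <- i + 1L
    out[[i]] <- b
  }
  if (!i) return(NULL)
  as.data.frame(data.table::rbindlist(out))
}

# pull from a stream while recording the peak resident batch size; used by
# the laziness/memory-contract tests
instrumentStream <- function(s, tally) {
  newStream(function() {
    b <- s$nextBatch()
    if (!is.null(b)) {
      tally$batches <- tally$batches + 1L
      tally$peakRows <- max(tally$peakRows, nrow(b))
      tally$totalRows <- tally$totalRows + nrow(b)
    }
    b
  }, desc = paste0("instrumented(", s$desc, ")"))
}

newStreamTally <- function() {
  e <- new.env(parent = emptyenv())
  e$batches <- 0L
  e$peakRows <- 0L
  e$totalRows <- 0L
  e
}
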