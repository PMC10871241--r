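# Seeded synthetic data: random step-function signal tracks, BED feature
# sets and minimally corrupted BBI files, so every part of the package is
# testable without downloads.  Generators are pure functions of their spec
# (seed included) and restore the caller's RNG state.

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic signal track
#'
#' Defaults emulate a modest read-pileup-style track: two chromosomes in
#' the tens of kilobases, step lengths of 10-200 bp, non-negative
#' coverage-like values, and occasional gaps of geometric length
#' (mean 50 bp).
#'
#' @param seed RNG seed.
#' @param chromSizes a [ChromSizes-class].
#' @param n number of intervals.
#' @param lengthRange min/max interval length (bp).
#' @param valueRange min/max value (rounded through 32-bit float, as the
#'   format stores them).
#' @param gapProb probability of a gap before each interval.
#' @return a spec list for [genSignalTrack()].
#' @export
trackSpec <- function(seed = 1L,
                      chromSizes = ChromSizes(c(chr1 = 50000, chr2 = 30000)),
                      n = 500L, lengthRange = c(10, 200),
                      valueRange = c(0, 50), gapProb = 0.1) {
  stopifnot(is(chromSizes, "ChromSizes"), n >= 1,
            lengthRange[1L] >= 1, lengthRange[2L] >= lengthRange[1L],
            valueRange[2L] >= valueRange[1L], gapProb >= 0, gapProb <= 1)
  list(seed = as.integer(seed), chromSizes = chromSizes, n = as.integer(n),
       lengthRange = lengthRange, valueRange = valueRange,
       gapProb = gapProb)
}

#' Generate a synthetic signal track
#'
#' Places `spec$n` sorted, non-overlapping intervals across the
#' chromosomes in order, with random lengths, values and gaps.  For
#' chromosomes up to 10 kb an independent per-base oracle map (value per
#' base, `NA` where uncovered) is returned alongside, built directly from
#' the placement, for cross-checking summaries and queries.
#'
#' @param spec a [trackSpec()].
#' @return `list(intervals = data.frame(chrom, start, end, value),
#'   oracle = named list of per-base vectors or NULL entries)`.
#' @export
genSignalTrack <- function(spec) {
  withSeed(spec$seed, {
    n <- spec$n
    cs <- spec$chromSizes
    gaps <- ifelse(runif(n) < spec$gapProb, rgeom(n, 1 / 50) + 1, 0)
    lens <- floor(runif(n, spec$lengthRange[1L], spec$lengthRange[2L] + 1))
    vals <- asFloat32(runif(n, spec$valueRange[1L], spec$valueRange[2L]))
    chrom <- character(n); start <- double(n); end <- double(n)
    placed <- 0L
    for (ci in seq_along(cs@chrom)) {
      if (placed >= n) break
      idx <- (placed + 1L):n
      need <- cumsum(gaps[idx] + lens[idx])
      fits <- which(need <= cs@size[ci])
      if (!length(fits)) next
      take <- idx[seq_len(max(fits))]
      s <- cumsum(gaps[take] + lens[take]) - lens[take]
      chrom[take] <- cs@chrom[ci]
      start[take] <- s
      end[take] <- s + lens[take]
      placed <- placed + length(take)
    }
    if (placed < n)
      bbiValidationError(sprintf(
        "infeasible track spec: only %d of %d intervals fit the genome",
        placed, n))
    intervals <- data.frame(chrom = chrom, start = start, end = end,
                            value = vals)
    oracle <- setNames(lapply(seq_along(cs@chrom), function(ci) {
      if (cs@size[ci] > 10000) return(NULL)
      v <- rep(NA_real_, cs@size[ci])
      sel <- intervals$chrom == cs@chrom[ci]
      if (any(sel)) {
        len <- intervals$end[sel] - intervals$start[sel]
        pos <- rep.int(intervals$start[sel], len) + sequence(len)
        v[pos] <- rep.int(intervals$value[sel], len)
      }
      v
    }), cs@chrom)
    stopifnot(all(intervals$end <= cs@size[match(intervals$chrom,
                                                 cs@chrom)]))
    list(intervals = intervals, oracle = oracle)
  })
}

#' Specification of a synthetic BED feature set
#'
#' @inheritParams trackSpec
#' @param n number of records.
#' @param layout `"bedN"` or `"bedN+P"` column layout (N in 3..9).
#' @param lengthRange min/max feature length (bp).
#' @param overlap whether features may overlap.
#' @return a spec list for [genFeatures()].
#' @export
featureSpec <- function(seed = 1L,
                        chromSizes = ChromSizes(c(chr1 = 50000,
                                                  chr2 = 30000)),
                        n = 200L, layout = "bed6",
                        lengthRange = c(50, 500), overlap = TRUE) {
  m <- regmatches(layout, regexec("^bed([0-9]+)(\\+([0-9]+))?$", layout))[[1L]]
  if (!length(m)) bbiValidationError(sprintf("bad layout '%s'", layout))
  defined <- as.integer(m[2L])
  extra <- if (m[4L] == "") 0L else as.integer(m[4L])
  stopifnot(defined >= 3L, defined <= 9L)
  list(seed = as.integer(seed), chromSizes = chromSizes, n = as.integer(n),
       defined = defined, extra = extra, lengthRange = lengthRange,
       overlap = isTRUE(overlap))
}

#' Generate synthetic BED features
#'
#' Deterministic for a given spec; sorted by (chromosome order, start);
#' pairwise disjoint per chromosome when `overlap = FALSE`.
#'
#' @param spec a [featureSpec()].
#' @return data.frame with `chrom`, `start`, `end`, `rest` (tab-joined
#'   columns 4..N, `""` for bed3).
#' @export
genFeatures <- function(spec) {
  withSeed(spec$seed, {
    n <- spec$n
    cs <- spec$chromSizes
    lens <- floor(runif(n, spec$lengthRange[1L], spec$lengthRange[2L] + 1))
    if (spec$overlap) {
      ci <- sample.int(length(cs@chrom), n, replace = TRUE,
                       prob = cs@size / sum(cs@size))
      maxStart <- cs@size[ci] - lens
      if (any(maxStart < 0))
        bbiValidationError("infeasible feature spec: feature longer than chromosome")
      start <- floor(runif(n) * (maxStart + 1))
      ord <- order(ci, start)
      ci <- ci[ord]; start <- start[ord]; lens <- lens[ord]
    } else {
      gaps <- rgeom(n, 1 / 100) + 1
      ci <- integer(n); start <- double(n)
      placed <- 0L
      for (c0 in seq_along(cs@chrom)) {
        if (placed >= n) break
        idx <- (placed + 1L):n
        need <- cumsum(gaps[idx] + lens[idx])
        fits <- which(need <= cs@size[c0])
        if (!length(fits)) next
        take <- idx[seq_len(max(fits))]
        start[take] <- cumsum(gaps[take] + lens[take]) - lens[take]
        ci[take] <- c0
        placed <- placed + length(take)
      }
      if (placed < n)
        bbiValidationError(sprintf(
          "infeasible feature spec: only %d of %d features fit", placed, n))
    }
    end <- start + lens
    cols <- list()
    nf <- spec$defined + spec$extra
    if (spec$defined >= 4L)
      cols$name <- sprintf("feat%0*d", nchar(n), seq_len(n))
    if (spec$defined >= 5L)
      cols$score <- as.character(sample(0:1000, n, replace = TRUE))
    if (spec$defined >= 6L)
      cols$strand <- sample(c("+", "-", "."), n, replace = TRUE)
    if (spec$defined >= 7L) cols$thickStart <-
        format(start, scientific = FALSE, trim = TRUE)
    if (spec$defined >= 8L) cols$thickEnd <-
        format(end, scientific = FALSE, trim = TRUE)
    if (spec$defined >= 9L) cols$reserved <- rep("0", n)
    if (spec$extra > 0L)
      for (j in seq_len(spec$extra))
        cols[[paste0("x", j)]] <- sprintf("extra%d_%d", j, seq_len(n))
    rest <- if (length(cols)) do.call(paste, c(cols, sep = "\t"))
            else character(n)
    data.frame(chrom = cs@chrom[ci], start = start, end = end, rest = rest)
  })
}

#' Minimally corrupt a BBI file, for exercising reader error paths
#'
#' @param bytes raw vector of a valid (little-endian) BBI file.
#' @param mode one of `"bad_magic"` (clobber the magic number),
#'   `"truncated"` (keep the first half), `"bad_section_size"` (declare a
#'   tiny decompression buffer so inflated sections exceed it),
#'   `"bad_node_magic"` (clobber the R-tree magic).
#' @return the corrupted raw vector.
#' @export
genCorruptBBI <- function(bytes,
                          mode = c("bad_magic", "truncated",
                                   "bad_section_size", "bad_node_magic")) {
  mode <- match.arg(mode)
  stopifnot(is.raw(bytes), length(bytes) >= 64)
  switch(mode,
    bad_magic = { bytes[1:4] <- as.raw(c(0xde, 0xad, 0xbe, 0xef)); bytes },
    truncated = bytes[seq_len(length(bytes) %/% 2L)],
    bad_section_size = { bytes[53:56] <- u32ToRaw(4); bytes },
    bad_node_magic = {
      idx <- rawToU64(bytes[25:32], 1)
      bytes[(idx + 1):(idx + 4)] <- as.raw(c(0, 0, 0, 0))
      bytes
    })
}
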