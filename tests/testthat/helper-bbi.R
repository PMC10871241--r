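# Shared fixtures and brute-force oracles.  Oracles work on per-base value
# maps (numeric vector per chromosome, NA = no data) built independently
# of the code under test.

tinyChroms <- function(...) {
  v <- c(...)
  if (!length(v)) v <- c(chrA = 9000, chrB = 6000)
  ChromSizes(v)
}

# per-base map from an interval data.frame (independent expansion)
mapFromIntervals <- function(iv, cs) {
  setNames(lapply(seq_along(names(cs)), function(ci) {
    v <- rep(NA_real_, cs@size[ci])
    sel <- iv$chrom == cs@chrom[ci]
    for (i in which(sel)) {
      v[(iv$start[i] + 1):iv$end[i]] <- iv$value[i]
    }
    v
  }), names(cs))
}

# SummaryStats over [start, end) of a per-base map
oracleSummary <- function(map, start, end) {
  v <- map[(start + 1):min(end, length(map))]
  v <- v[!is.na(v)]
  if (!length(v)) return(SummaryStats())
  SummaryStats(length(v), min(v), max(v), sum(v), sum(v^2))
}

expectSummaryEqual <- function(a, b, tol = 1e-6, label = NULL) {
  expect_equal(a@validCount, b@validCount, info = label)
  if (a@validCount > 0) {
    expect_equal(a@minVal, b@minVal, info = label)
    expect_equal(a@maxVal, b@maxVal, info = label)
    expect_equal(a@sumData, b@sumData, tolerance = tol, info = label)
    expect_equal(a@sumSquares, b@sumSquares, tolerance = tol, info = label)
  }
}

statsFromFrameRow <- function(z, i)
  SummaryStats(z$validCount[i], z$min[i], z$max[i], z$sum[i],
               z$sumSquares[i])

writeTempBigWig <- function(iv, cs, opts = bbiWriteOptions(), name = NULL) {
  path <- if (is.null(name)) tempfile(fileext = ".bw")
          else file.path(tempdir(), name)
  writeBigWig(iv, cs, path, opts)
  path
}

fileBytes <- function(path) readBin(path, raw(), file.size(path))

# a bedGraph text rendering of intervals (for CLI fixtures)
bedGraphLines <- function(iv)
  paste(iv$chrom, iv$start, iv$end, formatBbiValue(iv$value), sep = "\t")

writeTempText <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

foldZoomFrameT <- function(z) bigbits:::foldZoomFrame(z)

writeTempBigBedFixture <- function() {
  path <- tempfile(fileext = ".bb")
  writeBigBed(data.frame(chrom = "chr1", start = c(0, 5), end = c(10, 20),
                         rest = ""),
              ChromSizes(c(chr1 = 100)), path)
  path
}

chromSizesLines <- function(cs)
  paste(names(cs), format(cs@size, scientific = FALSE, trim = TRUE),
        sep = "\t")
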