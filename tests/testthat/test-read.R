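cs0 <- ChromSizes(c(chr1 = 1000, chr2 = 500))
iv0 <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                  start = c(0, 10, 100, 4), end = c(10, 20, 150, 25),
                  value = c(1.5, 2.5, 3, 7))

test_that("openBBI round-trips metadata of files this package writes", {
  bw <- writeTempBigWig(iv0, cs0)
  f <- openBBI(bw)
  on.exit(close(f))
  expect_s4_class(f, "BigWigHandle")
  expect_equal(f@version, 4)
  got <- chromSizes(f)
  expect_equal(names(got), names(cs0))
  expect_equal(got@size, cs0@size)
  expect_gt(nrow(zoomLevels(f)), 0)
  expect_true(all(diff(zoomLevels(f)$reduction) > 0))
  expectSummaryEqual(totalSummary(f),
                     mergeSummaries(summarizeIntervals(iv0, "chr1", 0, 1000),
                                    summarizeIntervals(iv0, "chr2", 0, 500)))
})

test_that("random bytes and truncations are rejected as 'not a BBI file'", {
  set.seed(1)
  expect_error(openBBI(as.raw(sample(0:255, 64, TRUE))),
               class = "bbi_format_error")
  expect_error(openBBI(as.raw(1:10)), class = "bbi_format_error")
  expect_error(openBBI(tempfile()), class = "bbi_format_error")
})

test_that("byte order is detected from the magic and both orders read back", {
  le <- writeTempBigWig(iv0, cs0)
  be <- writeTempBigWig(iv0, cs0, bbiWriteOptions(endian = "big"))
  fle <- openBBI(le); fbe <- openBBI(be)
  on.exit({ close(fle); close(fbe) })
  expect_true(fle@littleEndian)
  expect_false(fbe@littleEndian)
  expect_equal(queryIntervals(fbe, "chr1"), queryIntervals(fle, "chr1"))
  expect_equal(names(chromSizes(fbe)), names(chromSizes(fle)))
  expectSummaryEqual(totalSummary(fbe), totalSummary(fle))
})

test_that("queryIntervals returns whole overlapping records, or clipped on request", {
  f <- openBBI(writeTempBigWig(iv0, cs0))
  on.exit(close(f))
  expect_equal(queryIntervals(f, "chr1")[, c("start", "end", "value")],
               data.frame(start = c(0, 10, 100), end = c(10, 20, 150),
                          value = c(1.5, 2.5, 3)))
  q <- queryIntervals(f, "chr1", 15, 120)
  expect_equal(q$start, c(10, 100))   # whole records
  expect_equal(q$end, c(20, 150))
  qc <- queryIntervals(f, "chr1", 15, 120, clip = TRUE)
  expect_equal(qc$start, c(15, 100))
  expect_equal(qc$end, c(20, 120))
  expect_equal(nrow(queryIntervals(f, "chr1", 300, 400)), 0L)
  expect_error(queryIntervals(f, "chrX"), class = "bbi_notfound_error")
  expect_error(queryIntervals(f, "chr1", 50, 50),
               class = "bbi_validation_error")
})

test_that("query results match a linear-scan oracle on synthetic tracks", {
  cs <- tinyChroms()
  tr <- genSignalTrack(trackSpec(seed = 31, chromSizes = cs, n = 400,
                                 lengthRange = c(5, 25)))
  f <- openBBI(writeTempBigWig(tr$intervals, cs))
  on.exit(close(f))
  set.seed(32)
  for (i in 1:20) {
    chrom <- sample(names(cs), 1)
    w <- sort(sample(0:chromLength(cs, chrom), 2))
    if (w[1L] == w[2L]) next
    got <- queryIntervals(f, chrom, w[1L], w[2L])
    iv <- tr$intervals
    want <- iv[iv$chrom == chrom & iv$end > w[1L] & iv$start < w[2L], ]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("bwValues expands the step function with NA for missing data", {
  f <- openBBI(writeTempBigWig(
    data.frame(chrom = "chr1", start = 0, end = 10, value = 2), cs0))
  on.exit(close(f))
  expect_equal(bwValues(f, "chr1", 0, 10), rep(2, 10))
  expect_equal(bwValues(f, "chr1", 5, 15), c(rep(2, 5), rep(NA_real_, 5)))
  expect_error(bwValues(f, "chrZ", 0, 5), class = "bbi_notfound_error")
})

test_that("bases beyond the chromosome end are missing, not zero", {
  csTiny <- ChromSizes(c(mini = 10))
  f <- openBBI(writeTempBigWig(
    data.frame(chrom = "mini", start = 0, end = 10, value = 1), csTiny))
  on.exit(close(f))
  v <- bwValues(f, "mini", 5, 15)
  expect_equal(v, c(rep(1, 5), rep(NA_real_, 5)))
})

test_that("binned bwValues averages covered bases per bin", {
  f <- openBBI(writeTempBigWig(
    data.frame(chrom = "chr1", start = c(0, 10), end = c(10, 20),
               value = c(1, 3)), cs0))
  on.exit(close(f))
  expect_equal(bwValues(f, "chr1", 0, 20, bins = 2), c(1, 3))
  expect_equal(bwValues(f, "chr1", 0, 40, bins = 2), c(2, NA_real_))
  fbb <- openBBI(writeTempBigBedFixture())
  expect_error(bwValues(fbb, "chr1", 0, 5), class = "bbi_kind_error")
  close(fbb)
})

test_that("values and intervals are mutually consistent per base", {
  cs <- tinyChroms()
  tr <- genSignalTrack(trackSpec(seed = 41, chromSizes = cs, n = 300,
                                 lengthRange = c(5, 30)))
  f <- openBBI(writeTempBigWig(tr$intervals, cs))
  on.exit(close(f))
  for (chrom in names(cs)) {
    v <- bwValues(f, chrom, 0, chromLength(cs, chrom))
    expect_equal(v, tr$oracle[[chrom]])
  }
})

test_that("zoom records reproduce raw-data summaries over their bins", {
  cs <- tinyChroms()
  tr <- genSignalTrack(trackSpec(seed = 51, chromSizes = cs, n = 250,
                                 lengthRange = c(5, 30)))
  f <- openBBI(writeTempBigWig(tr$intervals, cs))
  on.exit(close(f))
  zl <- zoomLevels(f)
  expect_gt(nrow(zl), 0)
  for (li in seq_len(nrow(zl))) {
    z <- zoomQuery(f, "chrA", 0, chromLength(cs, "chrA"),
                   zl$reduction[li])
    expect_true(all(z$end - z$start <= zl$reduction[li]))
    expect_true(all(z$start %% zl$reduction[li] == 0))
    for (i in seq_len(nrow(z)))
      expectSummaryEqual(statsFromFrameRow(z, i),
                         oracleSummary(tr$oracle$chrA, z$start[i], z$end[i]),
                         tol = 1e-5,
                         label = sprintf("level %d bin %d", li, i))
  }
  # query before any data
  first <- min(tr$intervals$start[tr$intervals$chrom == "chrA"])
  if (first > zl$reduction[1L])
    expect_equal(nrow(zoomQuery(f, "chrA", 0, zl$reduction[1L] *
                                  (first %/% zl$reduction[1L]),
                                zl$reduction[1L])), 0L)
  expect_error(zoomQuery(f, "chrA", 0, 100, reduction = 12345),
               class = "bbi_notfound_error")
})

test_that("folding the coarsest zoom level approximates the total summary", {
  cs <- tinyChroms()
  tr <- genSignalTrack(trackSpec(seed = 61, chromSizes = cs, n = 300,
                                 lengthRange = c(5, 30)))
  f <- openBBI(writeTempBigWig(tr$intervals, cs))
  on.exit(close(f))
  red <- max(zoomLevels(f)$reduction)
  fold <- SummaryStats()
  for (chrom in names(cs)) {
    z <- zoomQuery(f, chrom, 0, chromLength(cs, chrom), red)
    fold <- mergeSummaries(fold, foldZoomFrameT(z))
  }
  ts <- totalSummary(f)
  expect_equal(fold@validCount, ts@validCount)
  expect_equal(fold@sumData, ts@sumData, tolerance = 1e-6)
  expect_equal(fold@sumSquares, ts@sumSquares, tolerance = 1e-6)
})

test_that("exact stats match the per-base oracle for every statistic", {
  cs <- tinyChroms()
  tr <- genSignalTrack(trackSpec(seed = 71, chromSizes = cs, n = 300,
                                 lengthRange = c(5, 30)))
  f <- openBBI(writeTempBigWig(tr$intervals, cs))
  on.exit(close(f))
  f1 <- openBBI(writeTempBigWig(
    data.frame(chrom = "chr1", start = c(0, 10), end = c(10, 20),
               value = c(1, 3)), cs0))
  expect_equal(bbiStats(f1, "chr1", 0, 20, stat = "mean"), 2)
  close(f1)
  f2 <- openBBI(writeTempBigWig(
    data.frame(chrom = "chr1", start = 0, end = 10, value = 1), cs0))
  expect_equal(bbiStats(f2, "chr1", 0, 100, stat = "coverage"), 0.1)
  close(f2)
  set.seed(72)
  for (i in 1:12) {
    chrom <- sample(names(cs), 1)
    w <- sort(sample(0:chromLength(cs, chrom), 2))
    if (diff(w) < 10) next
    bins <- sample(1:7, 1)
    edges <- w[1L] + floor((0:bins) * diff(w) / bins)
    o <- lapply(seq_len(bins), function(b)
      oracleSummary(tr$oracle[[chrom]], edges[b], edges[b + 1L]))
    toNA <- function(x) ifelse(is.nan(x), NA_real_, x)
    expect_equal(bbiStats(f, chrom, w[1L], w[2L], "mean", bins),
                 toNA(vapply(o, function(s) s@sumData / s@validCount, 1)),
                 tolerance = 1e-6)
    expect_equal(bbiStats(f, chrom, w[1L], w[2L], "min", bins),
                 vapply(o, function(s)
                   if (s@validCount) s@minVal else NA_real_, 1))
    expect_equal(bbiStats(f, chrom, w[1L], w[2L], "max", bins),
                 vapply(o, function(s)
                   if (s@validCount) s@maxVal else NA_real_, 1))
    expect_equal(bbiStats(f, chrom, w[1L], w[2L], "sum", bins),
                 vapply(o, function(s) s@sumData, 1), tolerance = 1e-6)
    expect_equal(bbiStats(f, chrom, w[1L], w[2L], "coverage", bins),
                 vapply(o, function(s) s@validCount, 1) / diff(edges),
                 tolerance = 1e-6)
  }
})

test_that("zoom-backed stats stay within the documented error bound", {
  cs <- ChromSizes(c(chrA = 100000))
  tr <- genSignalTrack(trackSpec(seed = 81, chromSizes = cs, n = 900,
                                 lengthRange = c(20, 120),
                                 valueRange = c(0, 10), gapProb = 0.2))
  f <- openBBI(writeTempBigWig(tr$intervals, cs))
  on.exit(close(f))
  bins <- 10L
  exact <- bbiStats(f, "chrA", 0, 100000, "mean", bins, exact = TRUE)
  approx <- bbiStats(f, "chrA", 0, 100000, "mean", bins, exact = FALSE)
  binWidth <- 100000 / bins
  red <- max(zoomLevels(f)$reduction[zoomLevels(f)$reduction <=
                                       binWidth / 2])
  bound <- max(tr$intervals$value) * red / binWidth
  expect_true(all(abs(approx - exact) <= bound + 1e-9, na.rm = TRUE))
  fbb <- openBBI(writeTempBigBedFixture())
  expect_error(bbiStats(fbb, "chr1", 0, 10), class = "bbi_kind_error")
  close(fbb)
})

test_that("files written by the reference C implementation read back identically", {
  gr <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2"),
    IRanges::IRanges(c(1, 51, 11), c(50, 70, 40)),
    score = c(0.5, -1.25, 4), seqlengths = c(chr1 = 2000, chr2 = 1000))
  ref <- tempfile(fileext = ".bw")
  rtracklayer::export.bw(gr, ref)
  f <- openBBI(ref)
  on.exit(close(f))
  got <- queryIntervals(f, "chr1")
  expect_equal(got$start, c(0, 50))
  expect_equal(got$end, c(50, 70))
  expect_equal(got$value, c(0.5, -1.25))
  expect_equal(queryIntervals(f, "chr2")$value, 4)
  expect_equal(totalSummary(f)@validCount, 100)
})
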