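test_that("a written BigWig reopens with identical records and totals", {
  cs <- ChromSizes(c(chr1 = 1000))
  iv <- data.frame(chrom = "chr1", start = c(0, 10, 50),
                   end = c(10, 20, 60), value = asFloat32(c(1.5, 2.5, -3)))
  f <- openBBI(writeTempBigWig(iv, cs))
  on.exit(close(f))
  expect_equal(queryIntervals(f, "chr1"), iv)
  expectSummaryEqual(totalSummary(f), summarizeIntervals(iv, "chr1", 0, 1000))
})

test_that("an empty input stream is refused ('no data')", {
  e <- expect_error(
    writeBigWig(bigbits:::emptyIntervals(), ChromSizes(c(chr1 = 100)),
                tempfile()),
    class = "bbi_validation_error")
  expect_match(conditionMessage(e), "no data")
  expect_error(writeBigWig(bigbits:::emptyIntervals(), ChromSizes(double()),
                           tempfile()),
               class = "bbi_validation_error")
})

test_that("writer output is a pure function of input, chrom sizes and options", {
  cs <- ChromSizes(setNames(c(2e5, 1.5e5, 1e5), paste0("c", 1:3)))
  tr <- genSignalTrack(trackSpec(seed = 77, chromSizes = cs, n = 10000,
                                 lengthRange = c(5, 40)))
  ref <- writeTempBigWig(tr$intervals, cs)
  variants <- list(
    tempOff = bbiWriteOptions(useTempFiles = FALSE),
    threads4 = bbiWriteOptions(threads = 4L),
    both = bbiWriteOptions(useTempFiles = FALSE, threads = 4L))
  for (nm in names(variants)) {
    p <- writeTempBigWig(tr$intervals, cs, variants[[nm]])
    expect_identical(fileBytes(p), fileBytes(ref), info = nm)
  }
  # pipe-style (non-seekable text stream) input vs data.frame input
  piped <- writeTempBigWig(
    parseBedGraph(textConnection(bedGraphLines(tr$intervals))), cs)
  expect_identical(fileBytes(piped), fileBytes(ref))
})

test_that("the input stream is consumed exactly once, forward only", {
  cs <- tinyChroms()
  tr <- genSignalTrack(trackSpec(seed = 78, chromSizes = cs, n = 500,
                                 lengthRange = c(5, 20)))
  tally <- bigbits:::newStreamTally()
  s <- bigbits:::instrumentStream(bigbits:::chunkStream(tr$intervals, 100L),
                                  tally)
  writeBigWig(s, cs, tempfile())
  expect_equal(tally$totalRows, 500L)   # each record seen exactly once
  expect_equal(tally$batches, 5L)
})

test_that("unsorted, overlapping or out-of-bounds input is named in the error", {
  cs <- ChromSizes(c(chr1 = 1000, chr2 = 500))
  e <- expect_error(writeBigWig(
    data.frame(chrom = "chr1", start = c(0, 5), end = c(10, 15),
               value = 1), cs, tempfile()),
    class = "bbi_validation_error")
  expect_match(conditionMessage(e), "chr1:\\[0,10\\)")
  expect_match(conditionMessage(e), "chr1:\\[5,15\\)")
  expect_error(writeBigWig(
    data.frame(chrom = c("chr2", "chr1"), start = c(0, 0),
               end = c(10, 10), value = 1), cs, tempfile()),
    class = "bbi_validation_error")
  expect_error(writeBigWig(
    data.frame(chrom = "chrX", start = 0, end = 10, value = 1), cs,
    tempfile()), class = "bbi_validation_error")
  e2 <- expect_error(writeBigWig(
    data.frame(chrom = "chr2", start = 490, end = 520, value = 1), cs,
    tempfile()), class = "bbi_validation_error")
  expect_match(conditionMessage(e2), "past chromosome end")
  # same record accepted with the clip option
  p <- tempfile()
  writeBigWig(data.frame(chrom = "chr2", start = 490, end = 520, value = 1),
              cs, p, bbiWriteOptions(clip = TRUE))
  f <- openBBI(p)
  expect_equal(queryIntervals(f, "chr2")$end, 500)
  close(f)
})

test_that("automatic zoom planning follows the 10x mean / 4x progression rule", {
  csBig <- ChromSizes(c(chr1 = 1e8))
  # levels stop strictly below the longest chromosome: 1000 * 4^9 >= 1e8
  expect_equal(planZoomLevels(1000, 100, csBig),
               1000 * 4^(0:8))
  csSmall <- ChromSizes(c(chr1 = 500))
  expect_equal(planZoomLevels(1000, 1, csSmall), c(10, 40, 160))
  expect_equal(planZoomLevels(1000, 1, csSmall,
                              bbiWriteOptions(zoomLevels = 100)), 100)
  expect_equal(planZoomLevels(5, 80, csSmall), double())  # 800 >= 500
  expect_equal(planZoomLevels(0, 0, csSmall), double())
})

test_that("reduceToZoom emits one summary per non-empty aligned bin", {
  cs <- ChromSizes(c(c = 100))
  iv <- data.frame(chrom = "c", start = c(0, 10), end = c(10, 20),
                   value = c(1, 3))
  z20 <- reduceToZoom(iv, 20, cs)
  expect_equal(nrow(z20), 1L)
  expect_equal(c(z20$validCount, z20$min, z20$max, z20$sum, z20$sumSquares),
               c(20, 1, 3, 40, 100))
  z10 <- reduceToZoom(iv, 10, cs)
  expect_equal(nrow(z10), 2L)
  expect_equal(z10$sum, c(10, 30))
  expect_equal(nrow(reduceToZoom(iv[0, ], 10, cs)), 0L)
})

test_that("every zoom level in a written file equals brute-force aggregation", {
  cs <- tinyChroms()
  tr <- genSignalTrack(trackSpec(seed = 91, chromSizes = cs, n = 350,
                                 lengthRange = c(5, 25),
                                 valueRange = c(-4, 4)))
  f <- openBBI(writeTempBigWig(tr$intervals, cs))
  on.exit(close(f))
  for (red in zoomLevels(f)$reduction) {
    for (chrom in names(cs)) {
      z <- zoomQuery(f, chrom, 0, chromLength(cs, chrom), red)
      want <- reduceToZoom(tr$intervals[tr$intervals$chrom == chrom, ],
                           red, cs)
      want <- want[want$chrom == chrom, ]
      expect_equal(z$start, want$start)
      expect_equal(z$validCount, want$validCount)
      expect_equal(z$min, asFloat32(want$min))
      expect_equal(z$max, asFloat32(want$max))
      expect_equal(z$sum, want$sum, tolerance = 1e-6)
      expect_equal(z$sumSquares, want$sumSquares, tolerance = 1e-6)
    }
  }
})

test_that("overlapping BigBed records reopen whole and summarize by depth", {
  cs <- ChromSizes(c(chr1 = 100))
  bed <- data.frame(chrom = "chr1", start = c(0, 5), end = c(10, 20),
                    rest = "")
  p <- tempfile(fileext = ".bb")
  writeBigBed(bed, cs, p)
  f <- openBBI(p)
  on.exit(close(f))
  expect_equal(queryIntervals(f, "chr1", 0, 100)[, 1:3],
               bed[, 1:3])
  expect_equal(f@dataCount, 2)
  # depth oracle: [0,5)=1, [5,10)=2, [10,20)=1 -> 20 covered, sum 25
  ts <- totalSummary(f)
  expect_equal(ts@validCount, 20)
  expect_equal(ts@minVal, 1)
  expect_equal(ts@maxVal, 2)
  expect_equal(ts@sumData, 25)
  expect_equal(ts@sumSquares, 35)
})

test_that("BigBed zoom levels aggregate per-base coverage depth", {
  cs <- tinyChroms()
  feats <- genFeatures(featureSpec(seed = 93, chromSizes = cs, n = 300,
                                   layout = "bed6", overlap = TRUE))
  p <- tempfile(fileext = ".bb")
  writeBigBed(feats, cs, p)
  f <- openBBI(p)
  on.exit(close(f))
  # independent per-base depth map
  for (chrom in names(cs)) {
    depth <- rep(0, chromLength(cs, chrom))
    sel <- feats$chrom == chrom
    for (i in which(sel))
      depth[(feats$start[i] + 1):feats$end[i]] <-
        depth[(feats$start[i] + 1):feats$end[i]] + 1
    red <- zoomLevels(f)$reduction[1L]
    z <- zoomQuery(f, chrom, 0, chromLength(cs, chrom), red)
    for (i in seq_len(nrow(z))) {
      d <- depth[(z$start[i] + 1):z$end[i]]
      d <- d[d > 0]
      expect_equal(z$validCount[i], length(d))
      expect_equal(z$min[i], min(d))
      expect_equal(z$max[i], max(d))
      expect_equal(z$sum[i], sum(d), tolerance = 1e-6)
    }
  }
})

test_that("BigBed embeds autoSql and validates it against the records", {
  cs <- ChromSizes(c(chr1 = 1000))
  feats <- genFeatures(featureSpec(seed = 94, chromSizes = cs, n = 20))
  p <- tempfile(fileext = ".bb")
  writeBigBed(feats, cs, p, autoSql = autoSqlForBed(6))
  f <- openBBI(p)
  got <- parseAutoSql(autoSqlText(f))
  expect_equal(got@fields, autoSqlForBed(6)@fields)
  expect_equal(f@fieldCount, 6)
  expect_equal(f@definedFieldCount, 6)
  close(f)
  expect_error(
    writeBigBed(feats, cs, tempfile(), autoSql = autoSqlForBed(4)),
    class = "bbi_validation_error")
  expect_error(
    writeBigBed(feats, cs, tempfile(), definedFieldCount = 9),
    class = "bbi_validation_error")
  expect_error(
    writeBigBed(feats[c(2, 1), ], cs, tempfile()),
    class = "bbi_validation_error")
  expect_error(
    writeBigBed(data.frame(chrom = "chr1", start = c(0, 5),
                           end = c(10, 20), rest = c("a\tb", "c")),
                cs, tempfile()),
    class = "bbi_validation_error")
})

test_that("BigBed round-trips synthetic feature sets exactly", {
  cs <- tinyChroms()
  for (layout in c("bed3", "bed4", "bed6", "bed6+2")) {
    feats <- genFeatures(featureSpec(seed = 95, chromSizes = cs, n = 150,
                                     layout = layout))
    p <- tempfile(fileext = ".bb")
    writeBigBed(feats, cs, p)
    f <- openBBI(p)
    got <- do.call(rbind, lapply(names(cs), function(chrom)
      queryIntervals(f, chrom, 0, chromLength(cs, chrom))))
    rownames(got) <- NULL
    expect_equal(got, feats, info = layout)
    close(f)
  }
})

test_that("uncompressed output is honored and reads back identically", {
  cs <- tinyChroms()
  tr <- genSignalTrack(trackSpec(seed = 96, chromSizes = cs, n = 200,
                                 lengthRange = c(5, 30)))
  p <- writeTempBigWig(tr$intervals, cs, bbiWriteOptions(compress = FALSE))
  f <- openBBI(p)
  on.exit(close(f))
  expect_equal(f@uncompressBufSize, 0)
  expect_equal(queryIntervals(f, "chrA"),
               tr$intervals[tr$intervals$chrom == "chrA", ],
               ignore_attr = TRUE)
})

test_that("explicit zoom levels override the automatic rule", {
  cs <- ChromSizes(c(chr1 = 100000))
  tr <- genSignalTrack(trackSpec(seed = 97, chromSizes = cs, n = 300))
  p <- writeTempBigWig(tr$intervals, cs,
                       bbiWriteOptions(zoomLevels = c(100, 1000)))
  f <- openBBI(p)
  on.exit(close(f))
  expect_equal(zoomLevels(f)$reduction, c(100, 1000))
})
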