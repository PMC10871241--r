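test_that("bedGraph parsing maps fields and skips metadata lines", {
  txt <- c("track type=bedGraph name=x", "# a comment", "",
           "browser position chr1", "chr1\t0\t100\t1.5",
           "chr1  200   300   -2.25", "chr2\t5\t10\t1e3")
  d <- collectStream(parseBedGraph(textConnection(txt)))
  expect_equal(d$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(d$start, c(0, 200, 5))
  expect_equal(d$end, c(100, 300, 10))
  expect_equal(d$value, c(1.5, -2.25, 1000))
})

test_that("bedGraph parser rejects malformed and empty intervals with line numbers", {
  e <- expect_error(
    collectStream(parseBedGraph(textConnection(c(
      "chr1\t0\t10\t1", "chr1\t100\t100\t2.0")))),
    class = "bbi_validation_error")
  expect_match(conditionMessage(e), "line 2")
  expect_error(
    collectStream(parseBedGraph(textConnection("chr1\t0\tten\t1"))),
    class = "bbi_parse_error")
  expect_error(
    collectStream(parseBedGraph(textConnection("chr1\t0\t10"))),
    class = "bbi_parse_error")
  expect_error(
    collectStream(parseBedGraph(textConnection("chr1\t0\t10\tNotANumber"))),
    class = "bbi_parse_error")
})

test_that("bedGraph parsing is chunked and lazy with bounded batches", {
  n <- 10000L
  lines <- sprintf("chr1\t%d\t%d\t%g", 0:(n - 1) * 10, 0:(n - 1) * 10 + 5,
                   sin(1:n))
  s <- parseBedGraph(textConnection(lines), chunkSize = 512L)
  tally <- bigbits:::newStreamTally()
  d <- collectStream(bigbits:::instrumentStream(s, tally))
  expect_equal(nrow(d), n)
  expect_lte(tally$peakRows, 512L)
  expect_gte(tally$batches, n %/% 512L)
  # whole-file split-and-parse oracle
  parts <- strsplit(lines, "\t", fixed = TRUE)
  expect_equal(d$start, as.numeric(vapply(parts, `[`, "", 2L)))
  expect_equal(d$value, as.numeric(vapply(parts, `[`, "", 4L)))
})

test_that("wiggle fixedStep and variableStep convert 1-based starts", {
  d <- collectStream(parseWiggle(textConnection(c(
    "fixedStep chrom=chr1 start=1 step=5 span=5", "1.0", "2.0"))))
  expect_equal(d, data.frame(chrom = "chr1", start = c(0, 5),
                             end = c(5, 10), value = c(1, 2)))
  d2 <- collectStream(parseWiggle(textConnection(c(
    "variableStep chrom=chr2 span=2", "11 3.5"))))
  expect_equal(d2, data.frame(chrom = "chr2", start = 10, end = 12,
                              value = 3.5))
  # span defaults to 1
  d3 <- collectStream(parseWiggle(textConnection(c(
    "variableStep chrom=chr1", "7 1.25"))))
  expect_equal(d3$end - d3$start, 1)
})

test_that("wiggle parser enforces declarations and attributes", {
  expect_error(collectStream(parseWiggle(textConnection("1.0"))),
               class = "bbi_parse_error")
  expect_error(collectStream(parseWiggle(textConnection(c(
    "fixedStep chrom=chr1 start=1", "1.0")))),
    class = "bbi_parse_error")
  expect_error(collectStream(parseWiggle(textConnection(c(
    "fixedStep start=1 step=1", "1.0")))),
    class = "bbi_parse_error")
})

test_that("randomized fixedStep blocks match a per-base expansion oracle", {
  set.seed(11)
  lines <- character()
  oracle <- rep(NA_real_, 10000)
  pos <- 1
  for (b in 1:20) {
    step <- sample(1:10, 1)
    span <- sample(seq_len(step), 1)  # span <= step: no overlap
    nvals <- sample(5:30, 1)
    vals <- round(runif(nvals, -5, 5), 3)
    lines <- c(lines,
               sprintf("fixedStep chrom=chrA start=%d step=%d span=%d",
                       pos, step, span),
               formatC(vals, format = "g"))
    for (i in seq_len(nvals)) {
      at <- pos + (i - 1) * step
      oracle[at:(at + span - 1)] <- vals[i]   # 1-based per-base fill
    }
    pos <- pos + nvals * step + sample(0:50, 1)
  }
  d <- collectStream(parseWiggle(textConnection(lines), chunkSize = 64L))
  got <- rep(NA_real_, 10000)
  for (i in seq_len(nrow(d))) got[(d$start[i] + 1):d$end[i]] <- d$value[i]
  expect_equal(got, oracle)
})

test_that("BED parsing keeps fields 4..N verbatim and fixes the column count", {
  d <- collectStream(parseBed(textConnection("chr1\t10\t20\tfeatA\t960\t+")))
  expect_equal(d$rest, "featA\t960\t+")
  e <- expect_error(
    collectStream(parseBed(textConnection(c("chr1\t10\t20",
                                            "chr1\t30\t40\tx")))),
    class = "bbi_validation_error")
  expect_match(conditionMessage(e), "3")
  expect_match(conditionMessage(e), "4")
  expect_match(conditionMessage(e), "line 2")
  expect_error(
    collectStream(parseBed(textConnection("chr1\t10\t20"), fieldCount = 6)),
    class = "bbi_validation_error")
})

test_that("generated BED6 parses with rest splitting into exactly 3 fields", {
  feats <- genFeatures(featureSpec(seed = 3, n = 5000,
                                   chromSizes = tinyChroms(c(c1 = 1e6))))
  lines <- paste(feats$chrom, feats$start, feats$end, feats$rest, sep = "\t")
  d <- collectStream(parseBed(textConnection(lines)))
  expect_equal(nrow(d), 5000L)
  expect_true(all(lengths(strsplit(d$rest, "\t", fixed = TRUE)) == 3L))
  # independent text-processing oracle: column counts straight off the text
  expect_true(all(lengths(strsplit(lines, "\t", fixed = TRUE)) == 6L))
})

test_that("chrom.sizes parsing preserves order and rejects duplicates", {
  cs <- parseChromSizes(textConnection("chr1\t1000\nchr2\t500"))
  expect_equal(names(cs), c("chr1", "chr2"))
  expect_equal(chromLength(cs, "chr2"), 500)
  expect_error(parseChromSizes(textConnection("chr1 1000\nchr1 900")),
               class = "bbi_validation_error")
  expect_error(parseChromSizes(textConnection("chr1 many")),
               class = "bbi_parse_error")
  empty <- parseChromSizes(textConnection(character()))
  expect_equal(length(empty), 0L)
})

test_that("bedGraph emission round-trips values through 32-bit floats", {
  set.seed(5)
  iv <- data.frame(chrom = "chr1", start = seq(0, 990, 10),
                   end = seq(5, 995, 10),
                   value = asFloat32(runif(100, -1e4, 1e4)))
  out <- textConnection("buf", "w", local = TRUE)
  n <- emitBedGraph(iv, out)
  close(out)
  expect_equal(n, 100)
  back <- collectStream(parseBedGraph(textConnection(buf)))
  expect_identical(asFloat32(back$value), iv$value)
  expect_equal(back$start, iv$start)
  # integral values render without an exponent or trailing zeros
  expect_equal(formatBbiValue(c(1, 2.5, 0)), c("1", "2.5", "0"))
})

test_that("bedGraph emission rejects unsorted input and passes empty through", {
  bad <- data.frame(chrom = "chr1", start = c(10, 0), end = c(20, 5),
                    value = 1)
  expect_error(emitBedGraph(bad, tempfile()),
               class = "bbi_validation_error")
  out <- textConnection("buf2", "w", local = TRUE)
  expect_equal(emitBedGraph(bigbits:::emptyIntervals(), out), 0)
  close(out)
})

test_that("autoSql schemas parse, render and re-parse to equal structures", {
  sch <- parseAutoSql(formatAutoSql(autoSqlForBed(3)))
  expect_equal(sch@fields$name, c("chrom", "chromStart", "chromEnd"))
  sch9 <- autoSqlForBed(9)
  expect_equal(sch9@fields$type[5L], "uint")
  expect_equal(sch9@fields$name[5L], "score")
  back <- parseAutoSql(formatAutoSql(sch9))
  expect_equal(back@name, sch9@name)
  expect_equal(back@fields, sch9@fields)
  # unbalanced quote / paren carry an offset in the message
  e <- expect_error(parseAutoSql('table t\n"comment\n(\n)'),
                    class = "bbi_parse_error")
  expect_match(conditionMessage(e), "offset")
  expect_error(parseAutoSql('table t\n"c"\n(\nuint a ; "x"\n'),
               class = "bbi_parse_error")
})

test_that("bedGraph and wiggle renderings of the same track agree per base", {
  tr <- genSignalTrack(trackSpec(seed = 21, chromSizes = tinyChroms(),
                                 n = 150, lengthRange = c(1, 1)))
  iv <- tr$intervals
  wig <- unlist(lapply(split(iv, iv$chrom), function(d) c(
    sprintf("variableStep chrom=%s span=1", d$chrom[1L]),
    sprintf("%d %s", d$start + 1, formatBbiValue(d$value)))))
  fromWig <- collectStream(parseWiggle(textConnection(wig)))
  fromBg <- collectStream(parseBedGraph(textConnection(bedGraphLines(iv))))
  cs <- tinyChroms()
  expect_equal(mapFromIntervals(fromWig[order(match(fromWig$chrom, names(cs)),
                                              fromWig$start), ], cs),
               mapFromIntervals(fromBg, cs))
})
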