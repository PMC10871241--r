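# bigbits

Read, write and query **BigWig** and **BigBed** files — the Big Binary
Indexed (BBI) container formats — in pure R.

Processed sequencing data overwhelmingly travels as BigWig (per-base
quantitative signal: read pileups, conservation scores, methylation
levels) and BigBed (indexed interval features: peak calls, annotations).
These containers pack the primary records, a sparse R-tree spatial
index, and multi-resolution "zoom" summaries into one block-compressed,
random-access file.  `bigbits` implements the whole format from first
principles for R users and pipeline authors: parsing and emitting the
text precursors (bedGraph, Wiggle, BED, chrom.sizes, autoSql schemas),
memory-efficient single-pass creation of indexed files — including from
standard input — and indexed queries for intervals, per-base values,
zoom records and region statistics, plus drop-in command-line tools
mirroring the classic UCSC utilities.

## The model in brief

A BigWig encodes a step function: disjoint intervals `[start, end)` with
32-bit float values and explicit *missing* data (gaps are not zeros).  A
BigBed encodes BED features, possibly overlapping, with extra columns
optionally described by an embedded autoSql schema.  Every span of data
reduces to the mergeable five-field summary

```
(validCount, min, max, sum, sumSquares)
```

over per-base values (coverage depth, for BigBed), from which
`mean = sum / validCount`, `coverage = validCount / width` and the
sample standard deviation follow.  Zoom level *k* stores one such
summary per aligned bin of `L_k` base pairs, with
`L_1 = max(10, ceiling(10 × mean record length))` and `L_{k+1} = 4 L_k`,
each level carrying its own R-tree so coarse views never touch
full-resolution data.  Coordinates are 0-based half-open throughout.

## Worked example

```r
library(bigbits)

cs <- parseChromSizes(textConnection("chr1\t20000\nchr2\t10000"))
iv <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                 start  = c(100, 150, 500, 0),
                 end    = c(150, 300, 900, 250),
                 value  = c(4, 7.5, 2, 1.25))
bw <- tempfile(fileext = ".bw")
writeBigWig(iv, cs, bw)

f <- openBBI(bw)
f
#> BigWigFile: /tmp/.../file...bw
#>   version 4 | 2 chromosome(s) | 2 zoom level(s) | compressed
#>   basesCovered 850 | min 1.25 | max 7.5 | mean 2.86765
```

`basesCovered` is the number of bases with data (50+150+400+250 = 850);
the mean is per covered base.  Queries go through the index:

```r
queryIntervals(f, "chr1", 120, 600)   # overlapping records, whole
#>   chrom start end value
#> 1  chr1   100 150   4.0
#> 2  chr1   150 300   7.5
#> 3  chr1   500 900   2.0

bwValues(f, "chr1", 140, 160)         # one value per base; NA = no data
#>  [1] 4.0 4.0 4.0 4.0 4.0 4.0 4.0 4.0 4.0 4.0 7.5 7.5 7.5 7.5 7.5 7.5 7.5
#> [18] 7.5 7.5 7.5

bbiStats(f, "chr1", 0, 1000, stat = "mean")
#> [1] 3.541667                         # (50*4 + 150*7.5 + 400*2) / 600

bbiStats(f, "chr1", 0, 1000, stat = "coverage", bins = 2)
#> [1] 0.4 0.8                          # 200/500 and 400/500 bases covered

zoomQuery(f, "chr1", 0, 20000, reduction = zoomLevels(f)$reduction[1])
#>   chrom start  end validCount min max  sum sumSquares
#> 1  chr1     0 2125        600   2 7.5 2125    10837.5
close(f)
```

The same surface exists for BigBed (`writeBigBed()`, overlapping
records, autoSql schemas via `parseAutoSql()` / `autoSqlForBed()`), and
`mergeBigWigs()` / `bigWigAverageOverBed()` provide streaming
combination and per-region aggregation.

## Command-line tools

One multitool and seven per-tool entry points are installed under the
package's `exec/` directory, with the familiar flag spellings:

```sh
bigbits bedgraphtobigwig in.bedGraph chrom.sizes out.bw   # "-" reads stdin
bigbits bedtobigbed -type=bed6 -as=bed6.as in.bed chrom.sizes out.bb
bigbits bigwigaverageoverbed in.bw regions.bed out.tab
bigbits bigwigmerge -threshold=0 a.bw b.bw out.bedGraph
bigbits bigwiginfo in.bw
bigbits bigwigtobedgraph -chrom=chr1 in.bw out.bedGraph
```

Exit codes: 0 success, 1 usage/validation error, 2 broken file.  The
same functionality is callable in-process via `cliMain()` and the
`cmd*()` functions.

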