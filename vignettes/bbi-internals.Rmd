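---
title: "Inside bigbits: the BBI formats, their summaries, and this implementation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inside bigbits: the BBI formats, their summaries, and this implementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bigbits)
```

## The data model

A BigWig file stores a quantitative step function over a reference
genome: disjoint intervals `[start, end)` on each chromosome, each with
one 32-bit float value, and gaps where there is *no data* (which is
distinct from a value of zero).  A BigBed file stores BED-like features
— intervals plus an arbitrary tab-separated payload — which, unlike
signal steps, may overlap.  Both live in the same container layout
("Big Binary Indexed", BBI):

* a fixed 64-byte header with offsets to every other component;
* a **chromosome B+ tree** mapping fixed-width, NUL-padded chromosome
  names to dense integer ids and lengths;
* the primary data, cut into **sections** of at most `itemsPerSlot`
  records (never spanning a chromosome), each section independently
  zlib-compressed;
* an **R-tree** over `(chromosome id, base range)` bounding boxes whose
  leaves point at the byte offset and size of each section — this is
  what makes a 1 kb query on a multi-gigabase file touch a handful of
  blocks instead of all of them;
* a ladder of **zoom levels**: pre-aggregated summaries at
  progressively coarser resolutions, each with its own data sections
  and its own R-tree;
* a 40-byte **total summary** over the whole file, and the magic number
  repeated at the end of the file.

All coordinates inside the container (and in BED/bedGraph text) are
0-based half-open; Wiggle text is 1-based and is converted on parse.
Everything in this package uses the 0-based convention.

## The five-field summary

Zoom records, the total summary, and region statistics all reduce to one
mergeable aggregate over a span of bases:

`(validCount, min, max, sum, sumSquares)`

where `validCount` counts bases with data and the sums are over
*per-base* values (an interval of width `w` and value `v` contributes
`w·v` to `sum` and `w·v²` to `sumSquares`).  For BigBed, the summarized
quantity is the per-base **coverage depth** — the number of records
covering each base — which is the convention that makes a zoomed-out
BigBed renderable as a density track, and matches what the reference C
implementation writes.

Merging two summaries adds counts and sums and takes extrema; the empty
summary (`validCount = 0`, `min = +Inf`, `max = -Inf`) is the identity,
and the operation is associative and commutative, so folds over zoom
records are well defined in any order.  From the five fields one gets
`mean = sum/validCount`, `coverage = validCount/width`, and the sample
standard deviation `sqrt((sumSquares − sum²/n)/(n−1))` with
`n = validCount`.

Two serialization details matter numerically.  First, zoom-record
statistics are stored as 32-bit floats (only the total summary uses
doubles), so folds over many zoom records agree with exact aggregation
only to single precision; tests and the acceptance script use a 1e-6
relative tolerance on sums for this reason, while counts, minima and
maxima are compared exactly.  Second, the empty summary's infinite
sentinels are serialized as zeros with `validCount = 0`; consumers must
gate on `validCount`, and this package's readers do.

## Tunable parameters

* `itemsPerSlot` (records per section; default **1024**) is the
  compression unit and the granularity of random access: larger slots
  compress better, smaller slots decompress less per query.  The default
  is the long-standing convention of the reference tools.
* `blockSize` (tree branching; default **256**) bounds children per
  B+/R-tree node.  At 256, even million-section files need only two or
  three levels, so a query reads a handful of index nodes.
* `compress` (default on) toggles zlib.  The header's
  `uncompressBufSize` is written as the largest uncompressed section
  actually produced; a stored value of 0 marks an uncompressed file.
* `zoomLevels = "auto"`: the first reduction level is
  `max(10, ceiling(10 × mean record length))` base pairs per bin, each
  subsequent level is 4× the previous, and planning stops at the longest
  chromosome length or after `maxZoomLevels` (default 10) levels.  The
  10×/4× progression mirrors the reference tools: the finest level only
  pays off once a bin summarizes several records, and quadrupling keeps
  the whole ladder within ~33% extra space.  Note the stop rule is
  strict (`level < longest chromosome`), so a first level at or beyond
  the longest chromosome yields a file with no zoom levels at all —
  valid, and handled by the readers.
* `threads` parallelizes section *compression* only; the output is
  defined to be byte-identical for any thread count, which is tested.
* `useTempFiles` (default on) stages the records needed for zoom
  building in a temporary file instead of memory; again byte-identical
  by construction.
* `endian`: the writer emits little-endian, matching every mainstream
  producer; the reader auto-detects byte order from the magic number.
  A big-endian writing mode exists so the byte-swapped read path is
  honestly exercised by tests rather than dead code.

## Single-pass streaming creation

The writer consumes its input — a data.frame or a lazy parser stream,
including standard input — exactly once, in order.  As records arrive
they are validated (chromosome order per the `chrom.sizes` file,
sortedness, non-overlap for signal, bounds), packed into sections,
compressed (optionally on worker processes, in deterministic order) and
appended to the output; section bookkeeping (bounds, offset, size) is
retained for the R-tree.  What zoom building needs — the signal
intervals, or for BigBed the per-chromosome depth runs computed by an
event sweep at each chromosome boundary — is spilled to a staging area.
After the data pass, the full-resolution R-tree is written, then each
planned zoom level is produced by a chunked scan of the staging area
(binning at that level, flushing full zoom sections as they complete,
then that level's R-tree), and finally the header, zoom header table,
total summary, and record count are back-patched.  The sink therefore
must be seekable even when the source is a pipe.

Zoom records are aligned to multiples of their reduction level and
clipped at chromosome ends; empty bins are simply absent.  (Third-party
files whose zoom bins straddle chromosome ends are tolerated and
clipped on read; this writer never emits them.)

The header region reserves `maxZoomLevels` zoom-header slots up front
(they are fixed-size), so the number of levels need not be known until
the end of the pass — this is what makes single-pass writing possible
even though the auto zoom rule depends on the mean record length.

## Query semantics and numerical choices

* `queryIntervals()` returns records overlapping the region **whole**;
  `clip = TRUE` clips coordinates instead.  Both behaviors exist in the
  ecosystem; whole records are the natural default for feature
  retrieval.  Results are sorted by start with a *stable* sort, so
  BigBed records sharing a start keep their file order.
* `bwValues()` returns one value per base with `NA` for missing data —
  missing is never conflated with zero.  Bases beyond the chromosome
  end are missing too (regions may extend past the end; the out-of-range
  part simply contributes no data).  With `bins`, each bin reports the
  mean over covered bases only.
* `bbiStats(..., exact = FALSE)` answers from the largest zoom level
  whose reduction is at most **half** the bin width, guaranteeing at
  least two zoom bins per output bin; zoom records overlapping a bin are
  folded in whole, so bin edges carry an error bounded by roughly
  `max value × reduction / bin width`.  When no level qualifies the
  exact path runs instead.
* Values are rounded through 32-bit floats at write time, and
  `formatBbiValue()` renders them with the shortest decimal string that
  round-trips through single precision — so emitted bedGraph re-parses
  to the exact stored value and text output is stable run to run.
* Adjacent equal-valued bedGraph intervals are preserved as given, never
  coalesced, on both import and export; `bigwigmerge` output, by
  contrast, is defined as maximal runs of constant value, so there
  coalescing is part of the tool's contract.
* Degenerate inputs fail fast with typed conditions: empty intervals
  (`start >= end`), column-count drift in BED, unsorted or overlapping
  writer input (the offending pair is named), records past the
  chromosome end (unless `clip`), empty record streams (a data-free BBI
  file is refused), and structurally broken files (bad magic,
  truncation, inflated sections exceeding the declared buffer) raise
  `bbi_format_error` rather than returning wrong answers.

## Streaming merge and averaging

`mergeBigWigs()` is a windowed ordered sweep: each input contributes a
per-chromosome cursor over its data sections (in coordinate order); the
sweep advances to the smallest "frontier" (the next unread section
boundary across inputs), combines the buffered intervals inside the
window segment-by-segment (sum or max, then `adjust`, value clipping
and thresholding), emits maximal constant-value runs, and holds back a
run touching the window edge so it can coalesce across windows.  Peak
resident interval count is bounded by inputs × section size — on the
order of a few thousand records — independent of chromosome length.
The multi-way sweep is inherently sequential, so this one tool has no
multi-threaded mode.  `bigWigAverageOverBed()` touches, per region,
only the sections the index selects, so its memory is likewise
independent of chromosome length.

## What the synthetic data emulates — and what it does not

`genSignalTrack()` places sorted, non-overlapping steps with uniform
lengths (default 10–200 bp), uniform non-negative values rounded to
float32 (default 0–50, coverage-like), and occasional geometric gaps
(mean 50 bp, default probability 0.1) — a caricature of a read-pileup
track.  `genFeatures()` draws BED features with standard column
content, optionally disjoint.  For chromosomes up to 10 kb the track
generator also returns a per-base oracle map built directly from the
placement, which the tests use as an independent ground truth for every
query path.

Passing tests on these data demonstrate format correctness, index
selectivity, summary arithmetic and determinism.  They do not
demonstrate behavior on real NGS artifacts — multimodal value
distributions, megabase chromosomes with billions of covered bases,
extreme record counts — nor performance at that scale; an R
implementation will not match compiled ones on wall time, and no claim
to that effect is made.  Interoperability is instead checked directly:
the test suite cross-reads files against the UCSC C code (via
rtracklayer) in both directions.

Test problem sizes were chosen as the smallest that still exercise
multi-section, multi-level structure: round trips run over 100 seeded
genome specs up to 10 chromosomes × 100 kb and up to 2 000 records
each; determinism and index-efficiency checks use a single 100 000
record file; oracle comparisons run on genomes of at most 10 kb per
chromosome, where per-base brute force is cheap.  Three tiny golden
files (committed as base64 text) pin the writer's byte-level output
against accidental format drift.

## Known limitations

* Format version 4 only; the extended header and extra indices
  (`extraIndex`, name indexes) of later versions are neither written
  nor interpreted.
* The reader accepts any seekable byte source (paths and in-memory raw
  vectors are provided); remote transports satisfy the same three-closure
  contract but none is bundled.
* autoSql schemas are tokenized and round-tripped, but field types are
  not validated against record contents.
* `bigwigmerge` holds one section's worth of intervals per input; an
  adversarial file with one enormous interval per section still bounds
  residency, but per-*record* payloads (BigBed) are not merged at all —
  merging is a signal-track operation.
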