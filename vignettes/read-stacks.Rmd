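---
title: "Methods: cell-type-stratified read stacks for single-cell long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-stratified read stacks for single-cell long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-cell long-read RNA sequencing resolves complete transcript structures
read by read, each read carrying a cell-type label assigned upstream. For a
single gene, the scientifically interesting questions — which cassette exons
are differentially included across cell types, whether neighboring
alternative exons co-occur, where reads disagree with the reference — are
best answered by *looking at every read at once*. This package computes that
picture: per-cell-type stacks of reads clustered by intron chain, on an axis
that preserves exon geometry while collapsing the introns that would
otherwise make the plot unreadable.

The package consumes pre-processed data: reads already mapped, assigned to a
gene and a cell type, with optional TSS/polyA assignments made upstream.
Mapping, barcode demultiplexing and TSS/polyA peak calling are out of scope.

## Coordinate compression

Introns are commonly one to two orders of magnitude longer than exons. The
coordinate map unions **all** exonic evidence — annotation exons and every
read's exon blocks — into maximal blocks, keeps those blocks at real scale,
and assigns each maximal exon-free gap a plot length of
`min(gap length, compressed_width)` with `compressed_width = 100` bases by
default. Consequences worth stating explicitly:

* A retained intron observed in *any* read is exonic evidence, so that
  region stays at real scale for every read. Short introns retained in some
  read are therefore drawn to scale; very large introns, which long reads
  essentially never retain, are compressed.
* Gaps no longer than `compressed_width` keep their genomic length:
  compression never enlarges. The rule is applied at the
  `compressed_width` boundary itself (a 100-base gap is drawn at 100), and
  the width is a user option rather than a second hard-coded threshold.
* The flanks before the first and after the last exonic block are treated
  as compressible gaps like any other.
* Within a real-scale segment the transform is an exact shift (an isometry);
  within a compressed gap, positions are interpolated linearly. The
  transform is globally non-decreasing, and plot positions are real-valued —
  rounding happens only at render time.

```{r}
library(splicestack)
m <- build_coordinate_map(
  tibble::tibble(start = c(0, 10200), end = c(200, 10400)))
tidy(m)        # the 10,000-base gap receives plot length 100
```

## Intron-chain clustering

A read's intron chain is the ordered list of gaps between its exon blocks;
mono-exonic reads have the empty chain and form one cluster per cell type.
Chain equality is exact coordinate equality — no fuzz window — because
TSS/polyA values and splice sites are taken as already binned/assigned by
the upstream pipeline; softening splice-site matching is deliberately not
this package's job. Under modes that include TSS and/or polyA, reads lacking
the key are excluded from the plot and reported per cell type; under the
default chain mode every read is retained.

The display order of clusters is not dictated by the method itself, so the
package fixes a deterministic comparator and exposes it as an option:
descending size, then more introns first, then elementwise chain-coordinate
order (`by = "size"`, the default), or chain-coordinate order first
(`by = "position"`). Reads within a cluster are ordered by alignment start,
end, then read id. Cell types are stacked in the order the user supplies,
falling back to factor levels and then lexicographic order.

## Alternative exons (Ψ)

Candidates are the exact `(start, end)` exon variants pooled from the
annotation and all reads; overlapping variants are scored independently
rather than merged into bins, keeping the call at read resolution. For a
candidate exon:

* **overlapping** — reads whose genomic footprint (first exon start to last
  exon end) intersects the exon by at least one base, pooled across *all*
  cell types. A read that splices the exon out counts in the denominator;
  that is what makes Ψ an inclusion fraction.
* **included** — overlapping reads with one exon block fully containing the
  candidate. A retained-intron read containing the exon region inside a
  larger block counts as including; exact-splice-site inclusion would be a
  stricter dialect and is not the default.
* Ψ = included / overlapping; with no overlapping reads Ψ is undefined and
  the exon is never flagged.

An exon is *alternative* when 100·Ψ lies in the closed window
`[lower_pct, upper_pct]`, default `[5, 95]` ("at least ... at most ...", both
boundaries inclusive). For higher-error chemistries such as current Oxford
Nanopore data, a `[20, 80]` window gives a cleaner picture and is available
as the `--ont` preset of the command-line tool. The degenerate window
`[0, 100]` flags every covered exon. Differential-inclusion testing across
cell types and formal mutually-exclusive-exon calls are out of scope: the
plot shows those patterns, the package does not test them.

## Mismatch finding

Alignments are walked along their CIGAR strings against the reference:
aligned-base disagreements yield SNV observations; `I`/`D` operations yield
one observation per event per read, keyed by position plus allele string
(one biological event, one dot — not per-base events). Intron skips (`N`)
and soft clips consume coordinates but produce nothing.

Filtering has two stages, both with documented conventions:

* **End exclusion.** Observations within `margin` (default 20) reference
  bases of either alignment end are removed. Distances are measured along
  the reference within the read's own alignment, 1-based from each end;
  an insertion is anchored on the base to its left. The boundary is
  inclusive: an observation exactly 20 bases from an end is removed.
* **Frequency window.** Observations are aggregated by (position, kind,
  alleles); `support` counts distinct reads and the denominator is per-site
  alignment coverage — the deleted interval for deletions, both flanking
  bases for insertions — pooled across all cell types, mirroring the Ψ
  pooling. (A per-gene denominator is the other conceivable convention; the
  per-site one is implemented because coverage varies across a gene.) A
  site passes when its frequency lies in the closed `[5, 95]` percent
  window: the lower bound suppresses random sequencing errors, the upper
  bound suppresses near-fixed genome differences, which users can surface
  with `upper_pct = 100`, or surface everything with `(0, 100)` and
  `margin = 0`.

## Input dialects

GFF/GTF input is 1-based inclusive, BED output 0-based half-open; everything
internal is 0-based half-open, converted only at the I/O boundary.
Book-ended exon blocks (zero gap) are merged on input — a zero-length gap is
a representation artifact, not a splice — while gaps of one base or more are
introns.

The combined per-read ("AllInfo") record has no published column layout, so
this package documents its own 10-column schema (see `?read_allinfo`):
`read_id gene_id cell_type barcode chrom strand tss polya intron_chain
exons`, tab-delimited, 1-based inclusive coordinates, `.` for missing
TSS/polyA. Files from other pipelines may need a column-order shim; the
parser offers a strict mode (inconsistent intron chain vs exon gaps is an
error naming the reads) and a lenient mode (skip and count). The barcode is
optional; the cell type is mandatory.

## The synthetic generator

The generator is the package's study system: a 5-exon toy gene
(exons 200/150/120/150/200 bases; introns 1,500/10,000/80/2,000 bases, so
one gap compresses hard and one stays at real scale), three isoforms
(full-length, skip-exon-3, skip-exon-4) at fixed per-cell-type proportions
across three cell types, 120 reads per cell type by default, TSS/polyA
assigned with probability 0.8 each, and three injected mismatch sites in the
constitutive flanking exons — a substitution at frequency 0.10, a 2-base
insertion at 0.30, a 3-base deletion at 0.25 — all chosen as plausible
desk-scale analogues of a real single-cell long-read locus. All sampling is
Mersenne-Twister under an explicit seed and the previous RNG state is
restored, so fixtures are fully deterministic; alternative alleles are the
next base in a fixed cyclic order rather than random draws.

What the generator does *not* emulate: realistic ONT/PacBio error profiles
(errors appear only at injected sites), truncated or internally clipped
reads (every simulated read is full length for its isoform), ambiguous gene
assignment, and doublets. Tests passing on these fixtures therefore
establish the correctness of the computations — coordinate conversion,
counting, filtering, ordering, rendering — not robustness to real-data
artifacts upstream of this package's contract.

Test and acceptance problem sizes are desk-scale by design: 120 reads per
cell type for pipeline checks, 1,000 draws for multinomial envelopes, 2,000
overlapping reads for Ψ and frequency recovery (3-standard-error bands),
100 random layouts for transform properties.

## Rendering

The layout assigns one row per read, clusters contiguous within cell type.
Mismatch dots are drawn on every read row carrying the observation (matching
how such figures distribute dots among reads); without read-level
observations, passing sites fall back to a single summary row. Alternative
exons recolor blocks that exactly equal the flagged interval; a containing
block (retained intron) keeps the cell-type color with only the matching
sub-interval overlaid, and that overlay is togglable. Intron connectors are
thin horizontal lines, not sashimi arcs. Colors are fixed defaults — SNV
blue, insertion green, deletion red, alternative exon orange, annotation
black — and user-overridable. Figure height grows linearly with the row
count; width scales with the compressed axis length.

Static SVG comes from the package's own emitter, which writes exactly one
SVG element per glyph — this is what makes the rendering tests exact
(element counts equal glyph counts) and reruns byte-identical. PDF/PNG
render the `autoplot()` ggplot. The interactive output is a standalone HTML
page embedding that SVG with native `<title>` hover tooltips (read id, cell
type, cluster size; site kind and frequency) and one SVG group per cell
type; it needs no JavaScript runtime or external assets.

The annotation section draws transcripts overlapping the read-covered span,
unclipped; clipping transcripts to the covered interval is the other
defensible reading and was not chosen because partial transcript glyphs are
easy to misread as short isoforms.

## Numerical and degenerate-input choices

* Empty exonic evidence: the coordinate map keeps the whole span at real
  scale with a warning rather than failing.
* An exon candidate with zero overlapping reads has undefined Ψ and is never
  alternative.
* A cell type whose reads are all excluded under a TSS/polyA mode is omitted
  with a warning; an empty retained set overall is an error.
* Window parameters are validated (`lower <= upper`, within `[0, 100]`);
  boundaries are always inclusive.
* Cluster-order ties end at the read-id comparison, so output order is a
  deterministic function of the input set, independent of input order.

## Limitations

* Chain equality is exact; reads with one-base splice-site wobble form
  separate clusters. That is faithful to the clustering definition but
  means error-prone data benefit from upstream splice-site correction.
* Ψ pools all cell types, so an exon fully included in one cell type and
  absent in another is flagged (that is the point), but an exon at 97 %
  everywhere is not — the window is a display filter, not a test.
* The mismatch finder is not a variant caller: no base qualities, no
  genotypes, no phasing.
* One gene, one chromosome per figure; multi-gene figures are loops over
  genes.
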