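---
title: "Characterizing transgene insertions in repetitive genomic regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing transgene insertions in repetitive genomic regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insertra)
```

## The problem

piggyBac transposons integrate semi-randomly at TTAA motifs, duplicating
the motif on both flanks of the cargo (the target-site duplication, TSD).
When the landing site falls in pericentromeric heterochromatin — regions
rich in retroelements and tandem repeats — the short flanking sequence
recovered by inverse PCR or split short reads matches many near-identical
loci across the genome, and the insertion cannot be assigned to a single
chromosome position. A strain can then carry a perfectly characterized
*construct* while its *location* stays ambiguous, which matters whenever
a transgenic line must be exhaustively described (e.g. ahead of a field
release of a modified disease vector).

`insertra` implements the complete computational workflow for this
situation on fully synthetic data with planted ground truth:

1. a forward simulator (genome with repeat families, a piggyBac-style
   construct, the TTAA/TSD insertion model, Illumina-like and
   Nanopore-like reads);
2. a self-contained seed-and-extend read mapper and a BLAST-like local
   similarity search, so the pipeline has no external aligner
   dependencies and every alignment is reproducible;
3. junction evidence: split reads, discordant pairs, junction-anchored
   flank consensus, TSD calls;
4. read-depth copy-number estimation against single-copy reference loci;
5. in-silico molecular assays (restriction digestion + Southern probing,
   inverse PCR, dot plots);
6. a locus resolver that ranks candidate sites from flank evidence and
   breaks ties with long-read contigs.

## The insertion model

For a chromosome `x = left + TTAA + right` and construct `C`, the
modified haplotype is

```
left + TTAA + C + TTAA + right
```

i.e. the motif is duplicated on both sides of the insert. A heterozygous
event modifies haplotype A only. `insert_transgene()` enforces the motif
precondition and `excise_transgene()` inverts the operation byte-exactly;
this round-trip identity is the anchor for all downstream truth checks.

Coordinates are 0-based half-open everywhere in the package; BED output
uses the same dialect and SAM output is 1-based, as those formats
require.

## The repeat model and the study conditions

`make_repeat_family()` derives `n` copies from one random ancestor by
independent per-base substitutions at rate `d`. Two copies then differ at
a site with probability `2d(1-d) + (2/3)d^2`, so the expected pairwise
identity is `1 - 2d(1-d) - (2/3)d^2`. An interval of the ancestor can be
`protect`ed from substitutions: the scenarios use this to keep the
central TTAA intact in every copy, reflecting the empirical situation in
which all ambiguous candidate loci still carry the target motif.

The headline scenario (`ambiguity_scenario()`) builds a ~2 Mb
two-chromosome haploid genome (a ~4 Mb diploid) with:

* 12 copies of a 750 bp repeat family at divergence 0.035 (expected
  pairwise identity ~0.93; this value keeps *every* sampled pair above
  the 90% identity regime that defines the ambiguity problem),
* each copy embedded in 500 bp "filler" repeats, so that alignments of a
  junction flank extend beyond the copy itself (~1.2 kb at >90%
  identity),
* a heterozygous insertion at the protected TTAA of one chr2R copy,
* a 563 bp unique island ~1.4 kb upstream of the junction — the only
  unique sequence within reach of a long-read contig arm — with every
  other repeat copy at least 30 kb away,
* an endogenous promoter/terminator donor gene on the other chromosome.

The default construct (~8.7 kb) is ITR5 – spacer – marker cassette
(1.5 kb, dosage class *n*) – promoter (1.2 kb, class *3n*, copied
verbatim from the host donor) – payload (4 kb, class *n*) – terminator
(0.8 kb, *3n*) – spacer – ITR3. Two spacers carry planted DraI sites so
inverse PCR releases junction fragments of amplifiable size; the payload
(the Southern probe source) is kept free of DraI/ScaI sites, as a real
construct designer would.

The copy-number scenario uses the same families on a ~70 kb genome so a
30x simulation stays cheap; its junction-adjacent filler repeats are
nearly identical (divergence 0.002, a "young" tandem family). That
choice reproduces the multi-mapping coverage inflation observed in the
immediate transgene-flanking sequence, which with diverged (3.5%)
copies would not occur because 150 bp reads can already distinguish
them.

## Alignment engine

One scoring scheme is shared by every identity computation: match +2,
mismatch −3, gap open 5, gap extend 2, with a gap of length L costing
`open + L·extend`. This is exactly the affine-gap convention of
`Biostrings::pairwiseAlignment`, which the test suite uses as an
independent full-dynamic-programming oracle: mapper best scores are
checked for *equality* against it on random instances.

`map_reads()` seeds with exact 15-mers (forward-strand index, both read
orientations), clusters seeds by diagonal, and extends each candidate
locus with banded affine Smith–Waterman (band 50 by default). All loci
tying the best score are reported; `mapq` is 40 for a unique best locus
and 0 otherwise — the pipeline only ever consumes the unique/ambiguous
distinction, so a calibrated error probability would be spurious
precision. `local_search()` is the BLAST-like variant that reports every
locus above a score threshold, with deterministic ordering (score
descending, then reference name, then position).

For the substitution-only short-read simulations the copy-number runs
narrow the band to 25 and sample every second seed; this changes no
result (reads have no indels) and roughly halves mapping time. Defaults
are untouched.

## Junction evidence

A split read has a primary alignment on one reference class (construct
vs genome) and a soft clip of ≥ 20 bp that maps to the other class;
clips shorter than that cannot be placed reliably with a 15-mer seed.
The flank consensus is anchored at the junction and built only from
construct-anchored tails: their clip boundary coincides structurally
with the construct terminus, whereas genome-anchored alignments can
overrun the junction by a few chance-matching bases and would blur the
anchoring. Columns with fewer than 2 supporting reads are trimmed;
2-vs-2 ties are broken alphabetically and flagged. With error-free
reads the consensus is byte-identical to the planted flank, and the TSD
call (`flank5` ends with TTAA, `flank3` starts with it) is exact.

## Copy number

Dosage classes follow the heterozygous-transgenic logic: *n* = once in
the diploid (transgene-unique features), *2n* = a normal locus, *3n* =
once in the construct plus two endogenous alleles. The normalizer is the
**median** depth of 15 random 20 bp single-copy loci (median rather than
mean: robust to a locus accidentally overlapping unannotated repeats).

Two depth subtleties are handled explicitly:

* *Shared features multi-map.* Reads from the interior of the promoter
  cannot be assigned between its construct and endogenous copies; every
  best-scoring placement is therefore counted, which makes each
  reference copy see the reads of all three diploid copies — the dosage
  signal itself. A mapq>0-only filter would instead zero out feature
  interiors; it remains available (`feature_depth(min_mapq = )`) for
  unique intervals.
* *Feature edges are depleted.* Reads overlapping a feature boundary
  carry unique context and map to one copy only, so edge positions
  undercount. Features longer than ~2 read lengths are measured over
  their core (interval trimmed by `read_len − 1`), where every covering
  read is fully internal. Short 20 bp loci are unique and unbiased, so
  they are measured untrimmed. ITR arms abut the insertion junctions and
  are depressed by split mapping however they are measured; they are
  reported but excluded from the class-consistency set (marker and
  payload carry the *n* verdict, as the fluorescent marker did in the
  motivating analysis).

At 30x with this design the per-seed class estimates have a standard
deviation around 0.1–0.2 copies, dominated by the 20 bp normalizer loci
(each is a single read-length window, so its depth estimate has
sd ≈ √30). Accuracy statements are therefore made about means over 10
seeded replicates (observed mean absolute error ~0.12 copies), not about
single features in single replicates, where ±0.4 excursions are expected
statistics, not method error.

Repeat-flank flagging uses the opposite depth convention — *all*
alignments including mapq 0 — since multi-mapping inflation is exactly
the signal: maximal runs above `2 ×` the 2n baseline, merged across
< 10 bp gaps.

## Assays

Restriction enzymes are (motif, cut-offset) pairs; non-palindromic
motifs are searched on both strands. Digestion preserves the template
(fragment lengths sum to the input; in-order concatenation restores it),
which is asserted over random sequences. A Southern "band" is a fragment
with ≥ 100 aligned bp of probe homology at ≥ 90% identity: a single
insertion gives one band per digest, wild type none, a double insertion
two. Inverse PCR digests the haplotype, circularizes the junction
fragment and walks the circle from the forward primer through the
ligated ends to the reverse primer; the construct-derived portions of
the amplicon are computable from the construct sequence and the enzyme
alone, so the genomic flank is recovered without consulting the truth.
Products above `max_product` (default 10 kb) raise an assay-failure
condition, as a real PCR would simply not amplify.

## Long-read resolution

Reads containing a construct anchor (searched at ≥ 0.75 identity, since
raw long reads carry ~8% error: 40% substitutions, 30% insertions, 30%
deletions by default) are oriented and greedily merged by the
best-scoring dovetail overlap (≥ 500 bp, ≥ 80% identity), then polished
by two rounds of majority-vote pileup. At ~10x local depth the polished
contig exceeds 98% identity to the truth haplotype over the construct
span; below ~7x, 2-vote ties (broken toward the draft) leave residual
error — the practical lower bound for this consensus scheme.

`integrate_long_read_evidence()` aligns the contig arms to the genome
and derives *unique islands*: maximal arm intervals covered by exactly
one hit at ≥ 90% identity, at least 500 bp long. A candidate is resolved
when an island maps within 25 kb of it (the resolving region in the
motivating case sat ~1.5 kb plus a repeat span from the junction; 25 kb
bounds the linkage without assuming a chromosome-scale assembly — it is
configurable, and implies the scenario design rule that decoy copies
must be farther than the linkage window from any island). Exactly one
resolved candidate clears the ambiguity flag; zero or several leave it
standing, with resolved candidates flagged rather than silently chosen,
and an island that links to *no* flank candidate is reported as a novel
locus with an explicit flank-discordant flag.

## Determinism and numerical choices

Every generator draws from a child seed derived from one top-level seed
by a 31-bit polynomial hash of a stage tag, so stages are independent
but the whole pipeline is reproducible: identical configs give
byte-identical FASTQ and JSON reports. Tie-breaks are deterministic
everywhere (alphabetical consensus ties, lexicographic hit ordering,
draft-base preference in polish ties). Degenerate inputs are contracts,
not surprises: empty sequences, missing TTAA, out-of-range intervals,
insufficient read support and over-long PCR products each raise a typed
condition (`insertra_*_error`).

## Problem sizes

The shipped analyses are sized for a laptop-scale run: the ambiguity
scenario uses a ~4 Mb diploid with 300 long reads per replicate
(~0.6x genome-wide, <10x local — the low-coverage regime the method is
designed for); copy number uses a ~150 kb diploid at 30x (about 18,000
read pairs); junction/TSD analyses resequence a 6 kb window around the
junction at 60x. Ten-seed replicate sets of the two simulation-heavy
analyses complete in a few minutes each.

## What the synthetic data does and does not show

The simulator reproduces the *structural* features that make insertion
mapping hard: near-identical repeat families spanning more than the
recoverable flank, a TSD-bearing junction, dosage-classed features, and
error-prone long reads. It deliberately omits GC bias, quality-score
structure, PCR duplicates, chimeric library artifacts and structural
variants other than the single insertion. Passing tests therefore
demonstrate that the algorithms are correct under their stated models —
not that a real genome's repeat landscape, assembly gaps, or collapsed
reference regions (which this package emulates only through its young
filler family) would behave as cleanly. The percentages reported for
signal tallies are pure arithmetic on supplied counts; no imaging or
cytogenetics is modeled.
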