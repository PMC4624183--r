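---
title: "Mapping mitochondrial 3' transcript ends: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mitochondrial 3' transcript ends: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mitotail)
library(dplyr)
```

## The biological problem

Mammalian mitochondrial DNA is a ~16.5-kb circle transcribed as long
polycistronic precursors from both strands. Under the tRNA punctuation
model, the tRNAs interspersed between genes are excised from the
precursor and the mRNA/rRNA ends are thereby defined by the tRNA
endpoints. Mature mRNAs are polyadenylated, and for several genes the
genome encodes only a partial stop codon — a solitary `T` or a `TA` at
the processing site — which polyadenylation completes to `TAA`.

Poly(A)-enriched RNA-Seq makes these mature 3' ends directly
observable: a read crossing a transcript end carries non-template
adenines that cannot be aligned to the genome and remain as a
soft-clipped terminal segment. This package implements the complete
inference chain from reads to biological verdicts:

1. **Mapping** (`map_reads()`, `map_pairs()`): local alignment of each
   read and its reverse complement against the circular genome
   (doubled-sequence technique; positions reported modulo the genome
   length), accepting a read only when at least 90% of it aligns at
   95% or higher identity. Both thresholds are inclusive. Unaligned
   read ends are retained as soft clips.
2. **Site calling** (`detect_tails()`, `aggregate_sites()`): a
   transcript-3'-side clip starting with three or more adenines (on
   the transcript strand) is poly(A) evidence; evidence is aggregated
   per exact genomic position and strand into sites with read-support
   counts.
3. **Annotation** (`classify_stop()`, `call_utr()`,
   `detect_bicistronic()`, `predict_punctuation_ends()`,
   `check_punctuation_conformance()`, `stemloop_scan()`): sites plus
   the gene annotation yield stop-codon completion calls, 3' UTRs,
   bicistronic transcripts, and a gene-by-gene audit against the
   punctuation model.

## Coordinate and site conventions

External files (GenBank, GFF3, TSV reports) use 1-based inclusive
coordinates; BED output is 0-based half-open; all internal arithmetic
is 0-based half-open with one conversion layer (`seq_slice()` /
`seq_slice1()`). A **poly(A) site** is the genomic coordinate of the
*first non-template base* in transcript orientation; the mature
transcript's last base is the preceding template position. On the
light (L) strand, transcript orientation runs against genomic
coordinates, so an L-strand site at genomic position *p* means the
transcript ends at *p + 1*.

"Completed by polyadenylation" requires the site at distance 0 from
the last template-encoded stop base. A site one base away instead
implies a 1-bp UTR after a genomic stop — the two situations are never
conflated.

## Alignment model and its parameters

The aligner is a seeded Gotoh local aligner (Rcpp): match +1, mismatch
−2, affine gaps costing 3 + L for a gap of length L. These scores are
stated in `mapper_params()` and all acceptance decisions are
*threshold-based* (length and similarity fractions), not score-based,
because the published analysis used a commercial mapper whose scoring
scheme is not public. 13-mer seeds place candidate windows; a read
with no seed on either strand falls back to an exhaustive scan, and
small genomes are always scanned exhaustively, so the seeded path is
an optimisation, not an approximation (the test suite asserts score
equality against `Biostrings::pairwiseAlignment()` as an independent
oracle).

Two tie-break rules matter biologically:

* **Template-maximal alignment**: a terminal read adenine that matches
  a genomic adenine extends the aligned core rather than joining the
  clip (extension through a match strictly increases the score, so the
  maximum-score alignment implements this automatically). This biases
  *against* false poly(A) calls at A-rich junctions.
* Placement ties go to the smallest genomic start, then the forward
  strand, keeping results deterministic.

## Site-calling parameters

| parameter | default | meaning |
|---|---|---|
| `min_tail` | 3 | minimum leading clip adenines (transcript strand) |
| `min_purity` | 0.8 | minimum A fraction over the whole clip |
| `min_support` | 3 | reads required for a primary site |
| `merge_window` | 0 bp | positional merging (0 = exact) |

The three-adenine rule is the published evidence criterion. The purity
parameter is this package's explicit knob for a question the published
criterion leaves open — whether non-A bases later in the clip
disqualify a read; the first three bases must always be A. Support of
3 is deliberately lower than the 40+ reads the published sites
enjoyed: one gene there was supported by only seven reads, so a low
default with a reported support column lets users apply any stricter
lens afterwards. Duplicate reads are counted individually, matching
raw read-count reporting. Sites failing `min_support` are kept in a
low-confidence sidecar rather than discarded.

## The punctuation auditor

`predict_punctuation_ends()` walks each protein-coding gene to the
next *sense* (same-strand) tRNA; antisense features are transparent —
they end up inside 3' UTRs, which is exactly how long UTRs arise (a
UTR can carry a full antisense gene and tRNA). Genes overlapping the
next same-strand gene tail-to-head are predicted bicistronic and have
no 3' end of their own. Two abutting same-strand genes with no
intervening tRNA are deliberately reported as a model *deviation*
(some other cleavage mechanism must act there), never silently merged.
`check_punctuation_conformance()` classifies each deviation by the
junction at the observed end: gene/gene junction without tRNA,
IGS/gene boundary, or other.

A bicistronic call (`detect_bicistronic()`) needs both lines of
evidence: the tail-to-head ORF overlap *and* the absence of any
supported site between the upstream ORF's end and the downstream ORF's
end.

## Stem-loop scanning

`stemloop_scan()` is a structural capacity screen for
replication-origin-like spacers: it enumerates every contiguous-stem
hairpin (loop ≥ 3 nt) and scores stems by a weighted pair count
(GC = 3, AT = 2, GU = 1), returning the maximum. Candidacy requires
five or more stem pairs. This is intentionally *not* a thermodynamic
folding model — reproducing a specific free-energy figure would tie
the package to one vendor's nearest-neighbour parameterisation — and
the tests therefore assert structural properties (planted palindromes
always pass; random 31-mers pass well under half the time) rather than
energies.

The IGS classifier (`derive_igs()`) calls an uncovered run of 100 bp
or more (or one abutting an annotated D-loop feature) a control
region; shorter runs that pass the stem-loop screen are
origin-of-light-strand candidates; the rest are short non-coding
spacers. The 100-bp rule is a pragmatic choice: in real mitogenomes
the control region is two orders of magnitude longer than any other
spacer.

## What the synthetic generator emulates

`build_toy_genome()` packs the archetypes of a mammalian mitogenome
into ~5 kb: a gene ending in a solitary `T` before a sense tRNA; a
full-stop gene with a 2-bp UTR; an abutting gene pair (upstream ends
`TA`) with no intervening tRNA; bicistronic pairs overlapping 43 and
7 bp tail-to-head with the upstream stop pinned inside the downstream
ORF's frame; a heavy/light tail-to-tail 4-bp overlap whose antisense
gene and tRNA sit inside a long UTR; a 31-bp palindromic spacer inside
a light-strand tRNA cluster; and a long control-region-like block.
ORFs are stop-free in frame under the vertebrate mitochondrial code
(stops `TAA`, `TAG`, `AGA`, `AGG`), including the shifted frames of
overlap regions, which the generator enforces by pinning and rejection
sampling.

`transcribe_and_process()` applies the punctuation model to the
heavy-strand precursor, with a derived cleavage at the start of any
gene directly preceded by a non-overlapping same-strand gene (the
abutting-pair and IGS/gene-boundary archetypes). `simulate_reads()`
draws 250–400-bp fragments, 100-bp paired ends in FR orientation,
substitution errors at 0.2% per base, per-transcript poly(A) tails
from a truncated geometric distribution (mean 30 nt, minimum 3 — no
tail-length data exist for this system, and a geometric keeps short
tails common so the three-adenine detection threshold is exercised
near its boundary), 5% enrichment leak-through for untailed
transcripts, and 10% unprocessed-precursor background. By default the
three genomic bases immediately downstream of every true site are
A-depleted so that called coordinates are unambiguous; a switch
(`deplete_A_after_sites = FALSE`) forces genomic adenines there
instead, to exercise the template-maximal tie-break (where a genomic
A follows the site, the first tail adenine is absorbed into the
template and the called coordinate shifts by design).

What it does **not** emulate: indels and PCR duplicates, quality-score
structure (qualities are constant and unused), rRNA transcript ends
(the published analysis states these need targeted assays),
promoter-specific transcription rates, and 5'-end processing (mature
transcripts may carry upstream antisense sequence on their 5' side;
only 3' ends are analysed). Passing tests on synthetic data therefore
demonstrate the *inference machinery* under known truth — not
robustness to every artefact of real libraries.

The light-strand mRNA is emitted without a stable poly(A) site,
mirroring the finding that the one L-strand gene's transcript end
could not be located; the pipeline reports it as unresolved rather
than guessing.

## Problem sizes and determinism

The default study conditions are a 4–6-kb toy genome at 200× mean
transcript coverage (~4,000 read pairs), at which every planted site
is recovered with support in the tens; the full-size 16,353-bp
reconstruction is used for coordinate arithmetic only. All randomness
flows from a single integer seed through isolated RNG scopes
(`withr::with_seed`), so identical configurations produce
byte-identical FASTQ, SAM and report files; the run manifest records
seed, parameters and input checksums.

A full-size synthetic reconstruction of the reference annotation
(`vole_like_fixture()`) pins every published coordinate — the fourteen
intergenic spacers, the 43/7/4-bp overlaps, the 69-bp and 595-bp UTR
budgets, 13 protein-coding genes totalling 11,390 bp in a 16,353-bp
circle — while its sequence is synthetic and seeded. Gene boundaries
that no published number pins are filled with realistic gene lengths.

```{r}
fx <- vole_like_fixture()
derive_igs(fx$annotation, fx$genome) |> count(igs_class, wt = length)
```

## Degenerate inputs and numerical choices

* Reads shorter than 20 bp and sequences outside `{A,C,G,T,N}` are
  rejected with errors; `N` never matches anything.
* Fraction thresholds are compared with a 1e-9 tolerance so that exact
  boundary cases (90 aligned bases of a 100-bp read) pass the
  inclusive contract regardless of floating-point representation.
* A CDS whose length modulo 3 is inconsistent with its terminal bases
  (e.g. one trailing base that is not `T`) is a hard error — it means
  the annotation's frame is wrong, and silently classifying it would
  corrupt the stop-codon table.
* An annotation covering the whole genome yields an empty IGS table;
  an empty site set yields a report stating that no 3' ends were
  resolved.
* One tRNA isoacceptor naming wrinkle is handled explicitly:
  duplicated tRNA names are number-suffixed in file order
  (`trnS1`/`trnS2`), because serine and leucine each have two
  mitochondrial tRNAs and published tables are inconsistent about
  which suffix the light-strand serine tRNA carries.

## Known limitations

* The aligner targets the mitochondrial use case: one short circular
  reference, substitution-dominated error profiles, soft-clip
  semantics. It is not a general-purpose spliced or multi-chromosome
  mapper.
* Minor/alternative poly(A) sites are not modelled; the strongest site
  per gene wins the UTR and stop-codon calls (the support column and
  the low-confidence sidecar preserve the evidence for finer
  analyses).
* Internal template-encoded priming artefacts are not simulated, so
  the precision measured on synthetic data is an upper bound for real
  libraries.
* The punctuation auditor consumes tRNA coordinates as annotated;
  tRNA structure prediction is out of scope.
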