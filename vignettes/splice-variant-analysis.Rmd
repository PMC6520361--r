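---
title: "Detecting splice-site mutation consequences in RNA-seq with splicetx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting splice-site mutation consequences in RNA-seq with splicetx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicetx)
```

## The problem

A mutation at or near a splice site can destroy the spliceosome's recognition
of an exon boundary. The transcriptional outcomes are heterogeneous: the exon
may be skipped, the intron may be retained in the mature mRNA, or a normally
silent ("cryptic") GT/AG site nearby may take over, shifting the junction into
the exon or the intron. At the protein level these events divide into in-frame
losses of a few amino acids and — far more often — reading-frame disturbance
or premature termination codons (PTCs) that predict a truncated protein.
splicetx implements this analysis as a reusable pipeline for a single gene of
interest (the canonical use case is *TP53* in tumour cohorts): classify the
DNA-level mutation, find and quantify the aberrant transcripts in aligned
RNA-seq reads, and predict each variant's protein consequence.

## Mutation classification

Mutations enter as HGVS coding-DNA (c.) descriptions. Intronic positions are
written relative to the flanking exon boundary: `c.X+n` is the n-th base of
the intron after the exon ending at coding position X (donor side), `c.X-n`
the n-th base before the exon starting at X (acceptor side). The parser
accepts the dialects that clinical tables actually print — en-dashes, spaces,
and length suffixes such as `del14` or `ins6`.

The classifier anchors each mutation on an exon boundary of the transcript
model. Donor-side mutations belong to the exon they terminate, acceptor-side
mutations to the exon they precede. Site classes are:

* **consensus** — a single-base substitution *or single-base deletion* at
  intronic offset ±1/±2, the invariant GT/AG dinucleotides. Treating a
  single-base deletion at +1 as a consensus point mutation is deliberate:
  it is a point event at the invariant site.
* **splice region** — a single-base event at offsets ±3..±10. The splice
  region is defined as the first ten and last ten bases of each intron,
  matching the breadth of targeted splice-region sequencing panels.
* **boundary spanning** — any multi-base event (a deletion running from the
  intron into the exon, an insertion/duplication near the boundary). These
  are never counted as consensus point mutations, but they do count towards
  per-exon tallies.

Events deeper than ten intronic bases are rejected as out of scope, and
purely exonic events are rejected outright; splice-altering exonic mutations
are a separate problem this package does not address.

## Junction evidence and event calling

Aberrant transcripts are detected from gap (CIGAR `N`) operations of primary
alignments. Each gap operation of each counted read contributes one
supporting read to its junction, so a read spanning two junctions counts for
both — exactly the arc-label semantics of a genome-browser Sashimi view.
Alignments below mapping quality 1, duplicates, and secondary/supplementary
records are excluded by default; these defaults mirror common browser
behaviour and are recorded in every report's configuration snapshot.

A junction is annotated against the canonical intron chain as *canonical*,
*exon skipping* (canonical donor of one intron joined to the canonical
acceptor of a downstream intron), *cryptic donor* or *cryptic acceptor* (one
canonical end, the other within the search window), or *unrelated*.

An aberrant junction is reported as expressed only when

1. it is supported by **≥ 5 reads** (`min_reads`),
2. it accounts for **≥ 5 %** of all *relevant* junction reads
   (`min_fraction`), and
3. it is **absent from the control sample**, "present" meaning it passes the
   same two filters there.

*Relevant reads* are all junction reads — canonical included — with either
splice end inside the affected intron. This is the package's own definition
(the evidence filters themselves do not pin down a denominator): it is what a
Sashimi view drawn over the mutated intron displays, every junction caused by
a mutated splice site keeps at least one end in that intron, and unlike a
fixed base-pair window it does not let the canonical junctions of unrelated
neighbouring introns dilute the fraction. The `search_window_bp` parameter
(default 500 bp, comfortably containing reported cryptic sites tens of bases
away) governs the extraction region and cryptic-site scanning only.
Intron-retention depth is deliberately kept out of this denominator —
retention has its own thresholds.

`scan_cryptic_sites()` enumerates candidate AG (acceptor) or GT (donor)
dinucleotides around the canonical site in transcript orientation. Distances
follow the junction-shift convention: for an acceptor, positive distances
move the junction into the exon (bases lost) and negative distances into the
intron (bases retained); donors mirror the signs.

## Intron retention

Retention is quantified from gap-aware per-base depth: a read splicing across
the intron contributes nothing to intronic depth. The retention ratio is

$$\mathrm{IR} = \frac{\text{median intronic depth}}
{\text{median intronic depth} + \text{canonical junction reads}},$$

the estimated fraction of transcripts retaining the intron. Retention is
called when the ratio **strictly exceeds 0.1** and **every measurable base is
covered by ≥ 3 reads**. External retention callers do not publish their exact
formula; this definition is fixed here, stated in all outputs, and recovers
simulated retention fractions (see below). Numerical conventions: the median
uses the lower-median rule, so integer depths give integer medians and the
0.1 boundary cannot be crossed by interpolation; a zero denominator yields
ratio 0, not called; ratio exactly 0.1 is not called.

Nonmeasurable bases (low-complexity or multi-mapping regions) are supplied as
a BED mask and leave the measurable set; mappability is not computed here.
A fully masked intron triggers the coverage-only fallback, which applies the
same thresholds to depth over all bases and records `method =
"coverage_fallback"` so reports distinguish such calls.

## Relative expression of variants

Per sample, the canonical variant (junction reads on the affected intron),
each passing aberrant junction (its supporting reads) and each called
retention (its median depth) are normalised jointly:
`relative_expression_i = evidence_i / Σ evidence_j`. Junction counts and
median depth are treated as commensurate. That is an explicit assumption, and
it is exactly what per-base sampling of an RNA-seq library justifies: both
quantities estimate the coverage depth a variant contributes at an
informative position. The table also reports each aberrant variant's
evidence ratio against the canonical variant, since "relative expression"
can mean either normalised fraction or aberrant:canonical ratio; both
readings are served. When a sample's events affect two introns, the mean of
the two canonical junction counts is used as canonical evidence.

## Consequence prediction

Each event is applied to the exon chain: skipping removes the exon(s),
retention merges the two flanking exons with the intron, a cryptic site moves
one junction end. The variant mRNA is assembled in transcript orientation and
translated from the canonical start codon.

* **Frame disturbance** — the net coding-length change is not a multiple
  of 3.
* **Premature termination codon** — the first in-frame stop is not the
  canonical termination codon (identified by position, so an in-frame
  deletion that merely shifts the canonical stop is not a PTC).
* **Amino acids lost** — canonical codons destroyed by the event: codons
  with a base removed, plus hybrid codons whose bases are no longer
  contiguous in the variant transcript. Counting destroyed hybrid codons is
  what makes a junction shift that removes a multiple of three bases
  starting mid-codon lose one more amino acid than the naive `bases/3`.
* **Protein class** — `truncated` when a PTC exists; `inframe_loss` when
  frame and stop are intact but codons were lost; `frameshift_no_ptc` for
  the rare frame shift that reaches the canonical stop without an earlier
  stop; `full_length` otherwise.

Degradation of PTC transcripts by nonsense-mediated decay is deliberately not
modelled; predictions are about the encoded protein if the transcript is
translated. Named isoforms are recognised by exact event match against a
small JSON catalogue; the shipped entry is p53ψ, the truncated TP53 isoform
arising from a cryptic acceptor 49 bp upstream of the canonical intron 6
acceptor.

One declared fixture variant is knowingly non-reproducible from arithmetic:
the cryptic acceptor 24 bases into exon 8 removes a multiple of three bases,
so the computed frame is intact, while the published table marks the frame
as disturbed even though its own amino-acid count (nine lost) matches the
in-frame computation. The package reports the sequence-derived values and
flags the discordance rather than forcing the printed flag.

## The synthetic reference and read simulator

All validation runs on data generated in code; no external sequence is
shipped. `tp53_synthetic_fixture()` builds a minus-strand gene whose coding
exon architecture follows the TP53 reference transcript NM_000546.4
(noncoding exon 1, coding exons 2–11, CDS boundaries c.96/97, 375/376,
559/560, 672/673, 782/783, 919/920 at the mutated junctions). The nucleotide
sequence is *synthetic*: a pyrimidine-only filler carries deterministic
patches that place the start/stop codons, canonical GT/AG dinucleotides, the
cryptic sites (+21 into exon 5, +24 into exon 8, −49 in intron 6, a donor GT
at c.550–551) and early in-frame stop codons inside each retainable intron.
Intron lengths (i4 = 300, i5 = 250, i6 = 150, i7 = 200, i8 = 180) are chosen
so that retention preserves or disturbs the frame exactly as each fixture
variant requires. Because the filler contains no other AG/GT dinucleotides,
cryptic-site scans on the fixture are fully deterministic. Exon numbering
anchors the first coding exon as exon 2, following the convention of the
TP53 literature.

What the fixture does *not* emulate: real TP53 sequence content (hotspot
codons, GC structure), real intron lengths, sequencing errors, coverage
biases, or mappability problems. Tests passing on this fixture therefore
demonstrate the correctness of the coordinate arithmetic, filters, and
translation logic — not robustness to alignment artefacts in real tumour
RNA-seq.

`simulate_reads()` emits pre-aligned single-end reads for a mixture of the
canonical transcript and aberrant variants. Each variant is tiled at a
coverage depth proportional to its mixture fraction — per-base sampling of a
library does the same — so junction counts and intronic depth land on a
common scale, which is precisely the assumption the quantification relies
on. The default coverage model is systematic tiling with a random phase
(uniform coverage taken literally; recovery error is then dominated by
rounding rather than sampling noise); a `"random"`-starts model is available
where Poisson-like variability is wanted. Reads are written as SAM text and
converted to sorted, indexed BAM through Rsamtools.

## Validation problem sizes

The shipped test-suite exercises, among others: round-trip coordinate
conversion over every base of a five-exon toy gene on both strands; 100
random cohorts re-tallied by brute force; exhaustive consequence checks of
all single-exon skips and all intron retentions against an independent
string-level translation oracle; junction counts and intronic depth against
direct SAM-text recounts; and parameter recovery for two-variant mixtures at
aberrant fractions 0.1/0.3/0.5 across ten seeds per event type at ~220
informative reads, with estimates required to land within ±0.05 of truth.
These sizes were chosen as the smallest at which the checks are exhaustive
or statistically stable.

## Coordinate conventions

All coordinates, internal and external, are 1-based closed intervals — the
Bioconductor convention shared by GRanges, Rsamtools and rtracklayer. Using a
single convention end to end (rather than 0-based internally and 1-based at
the edges) removes the usual source of off-by-one errors on the minus
strand, where this gene lives. Exons are stored in transcript order, so
"exon 1" of a minus-strand gene sits at the genomic right end; junction and
coverage operations receive genomic coordinates and convert once.

## Known limitations

* Single-transcript gene models only; no liftover, no alternative builds.
* Events are searched around the mutated intron of one gene, not discovered
  genome-wide, and no statistical test of differential splicing is offered.
* The 5 %-of-relevant-reads denominator includes junction reads only.
* Full-transcript isoform deconvolution (EM over shared reads), TPM/FPKM
  normalisation and cross-sample normalisation are out of scope.
* NMD is not modelled, so "truncated" means "PTC present", not "protein
  necessarily produced".
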