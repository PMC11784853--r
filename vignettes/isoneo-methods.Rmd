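---
title: "Methods: transcript-variant neoepitope discovery with isoneo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript-variant neoepitope discovery with isoneo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoneo)
```

## The problem

Tumors with few point mutations offer few classical neoantigens, but
full-length transcript sequencing of actively translated mRNA reveals a
second source: large-scale transcript variants (LSTVs) — isoforms arising
from intron retention, alternative splice-site use, exon exchange, or
intergenic transcription that are present in tumor tissue but absent from
matched normal tissue and the reference annotation. Because an LSTV can
insert tens to hundreds of amino acids of sequence never seen by the
thymus, a single variant can seed far more candidate MHC ligands than a
single missense mutation, whose mutant peptide space is limited to windows
around one substituted residue.

`isoneo` implements the full desk side of this strategy: variant calling
at the splice-chain level, event classification, translation and
proteome-novelty filtering, candidate tiling for MHC class I and II,
presentation scoring with a convolutional classifier, self-antigen
screening, and tandem-minigene assembly — plus a synthetic-locus generator
so the whole cascade is testable without external data.

## Isoform comparison and event classification

Transcripts are compared by their *splice chain* — the ordered set of
introns. Two design choices follow from the failure modes of long reads:

* **Tumor-specificity is junction identity, not exon identity.** Terminal
  exon ends wobble with 5'/3' degradation, so a tumor transcript is
  "novel" only if its exact intron chain occurs in neither the normal set
  nor the annotation. Mono-exonic transcripts have no junctions and fall
  back to exact exon-interval identity; they count as variants only when
  intergenic or fully intronic, which avoids calling fragments of
  annotated exons.
* **Support threshold.** `min_support = 2` full-length reads by default:
  it removes singleton artifacts while keeping the filter transparent and
  monotone (the variant count can only fall as the threshold rises).
  Transcripts without a recorded support count are retained, since a
  missing count is not evidence of low support.

Classification proceeds: (1) no overlap with any gene span (either
strand) is *intergenic*; (2) an exact chain match is a *full splice
match* (FSM), never a variant; (3) otherwise the query is compared
against the best-matching annotated transcript — most shared introns,
ties broken by closest exon count, then smallest identifier — and events
are read off the interval algebra:

| event | rule |
|---|---|
| intron retention | a query exon fully contains a reference intron, **or** a query exon lies entirely within a reference intron |
| exon skipping | a query intron fully contains an internal reference exon |
| mutually exclusive exons | exactly one query-only and one reference-only exon, non-overlapping, between the same pair of shared introns |
| alt 5' / alt 3' | a query intron shares exactly one boundary with a reference intron; donor-side change is 5', acceptor-side 3', resolved by strand |

The second intron-retention clause encodes a deliberate taxonomy choice:
a novel exon carved entirely out of annotated intronic sequence is
classed *intron retention* — the new coding material is intron-derived —
rather than as a separate "novel exon" category.

One interaction needs care. A mutually exclusive replacement exon
necessarily lies inside a reference intron (it cannot overlap the exon it
replaces), and the query intron flanking it necessarily contains the
replaced reference exon. Read naively, every exon exchange would
therefore also register as intron retention plus exon skipping and could
never receive its own label. `isoneo` detects the exchange first and
excludes the paired exons from the other two rules; all non-exchange
cases are unaffected. A multi-event isoform is reduced to one primary
label by the fixed priority *intergenic > intron retention > exon
skipping > mutually exclusive exons > alt5 > alt3 > other*, with all
detected events still reported.

## From variant to peptide

* **ORF policy.** The longest ATG-initiated open reading frame across the
  three forward frames, minimum 30 residues, leftmost start on ties, no
  Kozak-context scoring. Simple, deterministic, and replaceable.
* **Novelty filter.** A protein position is tumor-novel iff it is covered
  by some k-mer absent from the reference proteome; maximal runs of such
  positions become novel regions. `k = 8` — the shortest class-I ligand —
  is deliberately conservative: any peptide window containing a self
  8-mer run of length k is treated as self.
* **Tiling.** Class I windows of 8–11 residues; class II 13–17 (the
  paper-scale eluted-ligand length range; the class II set is a package
  choice since no published length set exists for it). Windows may extend
  up to length−1 residues into flanking reference sequence so that
  junction-spanning peptides — the canonical LSTV product — are kept;
  every emitted window overlaps at least one novel position.
* **SNV arm.** Each missense variant yields the window
  `protein[p−12, p+12]` (25 residues, clipped at the termini), the
  conventional "around 25 amino acids" mutant context. Synonymous,
  stop-affecting and non-coding variants are skipped with logged reasons;
  a reference-base mismatch against the genome is a hard error.
* **Self-antigen screen.** A candidate is discarded as self-like when it
  occurs verbatim in the proteome or its longest proteome-matched
  substring reaches its length minus one.

## The presentation classifier

Each candidate peptide is front-padded with `X` to a fixed hotspot length
(default 9; the pipeline raises it to cover the longest configured class
II ligand) so C-terminal anchor positions stay aligned, then encoded per
position: one-hot or BLOSUM62 rows for testing, or a per-residue
embedding table loaded from TSV so externally precomputed protein
language-model embeddings can be plugged in — the package never runs a
language model in-process. The pad symbol encodes as the zero vector.

The network is the published two-branch design: four parallel 1-D
convolutions (kernel sizes 1, 3, 5, 7), each ReLU-activated and globally
max-pooled; in parallel a small dense layer over three scalar features —
`-log10` of the percentile binding rank (clipped at 0.001), the
hydrophobicity fraction (proportion of A, V, L, M, W, padding excluded),
and relative peptide length. Both branches concatenate into a dense stack
(2000 then 256 units by default) with dropout and a single sigmoid
output. Training minimizes binary cross-entropy (optionally
positive-weighted for imbalance) with Adam and decoupled weight decay.
The package defaults are the published settings — learning rate 1e-5,
weight decay 1e-6, dropout 0.1, batch size 50, 10-fold cross-validation —
with the epoch count governed by early stopping on a held-in 10%
validation slice, since no epoch count is published. The implementation
is plain R matrix algebra (explicit im2col convolution and
backpropagation), which keeps it dependency-free and bit-reproducible
under a fixed seed.

Negatives are generated from a source proteome: decoys are substrings
drawn uniformly over all eligible start positions, with the decoy length
multiset exactly `r` copies of the positives' length multiset and decoys
never equal to any positive. Cross-validation folds are stratified
jointly by label and allele. ROC-AUC uses the rank-statistic
(Mann-Whitney) form with midrank ties; PR-AUC is step-interpolated
average precision; both are validated in the test suite against
brute-force pairwise concordance and an independent implementation.

## The synthetic-locus generator

The generator is the package's study substrate, not a tuning knob. Each
requested event gets its own gene locus on a ~50 kb chromosome segment:
five exons of 300/360 nt separated by 300 nt introns, a full-length
coding transcript (ATG in exon 1, stop at the transcript end), and one
tumor isoform realizing exactly the planted event. All exon, intron and
insert lengths are multiples of 3 and inserted segments are stop-free in
frame, so the peptide-level consequence of every event is analytic —
which is what lets the tests assert exact novel-region coordinates and
window counts. Loci alternate strands so donor/acceptor semantics are
exercised on both. The matched-normal set carries the annotated isoforms
plus, optionally, a shared novel isoform (novel but not tumor-specific);
an FSM tumor copy is added alongside so the caller must reject both
confounders. Labeled presentation data plant an anchor motif
(defaults: Y at position 2, L at position 5, lengths 8–11) at 1:10
positive:decoy imbalance — a stand-in for the unpublished balance of
eluted-ligand training snapshots — with positive ranks in (0.01, 2] and
decoy ranks in (2, 100]. The disjoint rank default separates
feature-plumbing failures from model-capacity failures; an overlap
parameter hardens the task when the model itself is under study.

What the generator does **not** emulate: expression levels, sequencing
error, 5'/3' read degradation, real splice-site motifs, real MHC binding
motifs or genuine proteome composition. Passing tests therefore
demonstrate algorithmic correctness of the cascade — classification,
arithmetic, filtering, training machinery — not predictive performance on
biological data.

## Numerical choices and scale

Ranks are clipped below at 0.001 before the log transform (log base 10;
the base only rescales a learned layer). Max-pooling breaks ties toward
the first position; ORF ties toward the leftmost start; fold assignment,
dropout, initialization and all sampling flow from one integer seed per
operation, so fixtures, training and the whole pipeline are reproducible
byte-for-byte (reports differ only in their timestamp). The test suite
and the acceptance script train a scaled-down configuration (8 filters
per kernel, 32/16 dense units, learning rate 3e-3, batch 100) on 3,000
planted-motif peptides with 10-fold cross-validation — sizes chosen so
the full suite runs in minutes on one CPU while still separating planted
signal (pooled ROC-AUC ≥ 0.95) from permuted-label noise (ROC-AUC ≈
0.5). The architecture contract is identical at every scale.

## Limitations

The pipeline consumes collapsed transcript models and SNV calls; it does
not perform alignment, isoform collapse or variant calling. Fusion and
chimeric transcripts, indel- and fusion-derived peptides, NMD prediction,
proteasomal processing and TAP transport are out of scope. The rank-only
baseline scorer used when no training data are configured is a monotone
rescaling of the external binding rank, not a presentation model.
Immunogenicity — whether a presented peptide is actually recognized by T
cells — is beyond what any component here predicts.
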