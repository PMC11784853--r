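# isoneo

Tumor-specific transcript-variant detection and neoepitope candidate
discovery from full-length transcript models.

## The problem

Cancers with low mutation burden yield too few point-mutation neoantigens
for effective therapeutic vaccines. Full-length sequencing of actively
translated mRNA exposes a richer source: **large-scale transcript
variants (LSTVs)** — isoforms arising from intron retention, alternative
5′/3′ splice-site use, exon exchange, or intergenic transcription that
are present in tumor tissue but absent from the matched normal tissue and
the reference annotation. A single LSTV can insert tens to hundreds of
amino acids of proteome-novel sequence, seeding far more candidate MHC
ligands than a missense SNV, whose mutant peptide space is confined to a
~25-residue window around one substitution.

`isoneo` implements the computational side of this workflow end to end:

1. **LSTV calling** — tumor vs. matched-normal isoform comparison at the
   splice-chain level (the ordered intron set), with event classification
   into FSM / intergenic / alt5 / alt3 / intron retention / exon skipping
   / mutually exclusive exons. A novel exon carved from annotated
   intronic sequence is classed as intron retention.
2. **Peptidome extraction** — longest-ORF translation, proteome k-mer
   novelty filtering (default k = 8: any window containing no novel
   8-mer is self), candidate tiling at 8–11 (MHC I) and 13–17 (MHC II)
   residues with junction-spanning flank extension, missense SNV windows
   (25-mers), and a self-antigen similarity screen.
3. **Presentation scoring** — a two-branch classifier: four parallel 1-D
   convolutions (kernels 1/3/5/7) over the padded, per-residue-encoded
   peptide, each globally max-pooled, concatenated with a scalar branch
   over −log₁₀ binding rank and hydrophobicity (fraction of A/V/L/M/W),
   merged through a 2000→256 dense stack to a sigmoid output. Trained
   with Adam, decoupled weight decay and early stopping; evaluated by
   stratified 10-fold cross-validation (ROC-AUC / PR-AUC). Decoy
   negatives are length-matched proteome substrings.
4. **Construct design** — tandem-minigene assembly: ordered epitope
   concatenation and most-frequent-codon reverse translation.

A synthetic-fixture generator plants each event class into toy multi-exon
loci with analytic, in-frame peptide ground truth, so every stage is
testable without downloads.

## Worked example

```r
library(isoneo)

bundle <- make_locus_fixture(c(intron_retention = 2, intergenic = 1,
                               alt5 = 1, alt3 = 1), seed = 7)
res <- find_lstvs(bundle$tumor_models, bundle$normal_models, bundle$annotation)
res$table[, c("id", "strand", "primary_class", "support", "matched_reference")]
#>       id strand    primary_class support matched_reference
#> 1 PB.1.1      + intron_retention       4              G1.1
#> 2 PB.2.1      - intron_retention       3              G2.1
#> 3 PB.3.1      +       intergenic       6              <NA>
#> 4 PB.4.1      -             alt5       5              G4.1
#> 5 PB.5.1      +             alt3       9              G5.1
```

The bundle contains seven tumor isoforms; the full-splice-match copy and
the novel-but-shared isoform are correctly rejected, leaving five
tumor-specific variants (two intron retentions, one intergenic, one
alternative donor, one alternative acceptor — and no exon skipping or
mutually exclusive exons).

```r
rec <- res$records[[1]]
orf <- longest_orf(transcript_sequence(rec$transcript, bundle$genome))
idx <- build_kmer_index(bundle$proteome, k = 8)
regions <- novel_regions(orf$protein, idx, rec$transcript$id)
regions[, c("protein_id", "start", "end")]
#>   protein_id start end
#> 1     PB.1.1    93 137

tile_epitopes(regions[1, ], 8:11, "I") |> nrow()
#> [1] 142
```

The first variant's novel exon inserts 30 intron-derived residues;
together with the junction-spanning positions this yields a 44-residue
novel region (protein coordinates 93–137) and 142 class-I candidate
windows across lengths 8–11.

For scoring, `make_presentation_dataset()` builds a labeled
eluted-ligand-style table with a planted anchor motif, and `train_cv()`
runs the stratified cross-validation; `run_pipeline()` chains everything
(LSTV → ORF/novelty → tiling → self-screen → scoring → binder calling)
into a reproducible JSON report. A thin command-line front end with
`fixtures`, `lstv`, `peptides`, `snv`, `train`, `predict`, `pipeline` and
`minigene` subcommands is installed at `inst/cli/isoneo.R`.

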