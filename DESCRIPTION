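Package: isoneo
Title: Tumor-Specific Transcript Variant Detection and Neoepitope Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for discovering candidate tumor neoepitopes from
    full-length transcript models. Detects large-scale transcript variants
    (LSTVs) by comparing tumor isoform sets against matched-normal isoforms
    and a reference annotation, classifies splice events (intron retention,
    intergenic, alternative 5'/3' splice sites, exon skipping, mutually
    exclusive exons), translates variant transcripts, extracts
    proteome-novel peptide regions by k-mer filtering, tiles MHC class I and
    class II candidate windows, builds missense-variant peptide windows from
    SNV calls, and scores peptide-MHC presentation with a multi-kernel 1D
    convolutional network merged with a scalar-feature branch (binding rank
    and hydrophobicity), trained and evaluated by stratified k-fold
    cross-validation. Includes a synthetic-fixture generator for end-to-end
    testing and tandem-minigene construct assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
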