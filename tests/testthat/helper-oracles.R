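# Independent brute-force oracles used to validate the implementation.

# Novel-position mask by direct window membership testing (quadratic scan).
novelty_mask_oracle <- function(protein, proteome, k) {
  L <- nchar(protein)
  covered <- logical(L)
  if (k > L) return(covered)
  for (i in seq_len(L - k + 1L)) {
    w <- substr(protein, i, i + k - 1L)
    found <- any(vapply(proteome, function(p) grepl(w, p, fixed = TRUE),
                        logical(1L)))
    if (!found) covered[i:(i + k - 1L)] <- TRUE
  }
  covered
}

regions_to_mask <- function(regions, L) {
  covered <- logical(L)
  for (i in seq_len(nrow(regions)))
    covered[(regions$start[i] + 1L):regions$end[i]] <- TRUE
  covered
}

# Pairwise-concordance ROC-AUC: P(score_pos > score_neg) + 0.5 P(tie).
auc_concordance_oracle <- function(labels, scores) {
  p <- scores[labels == 1L]
  n <- scores[labels == 0L]
  mean(outer(p, n, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Exhaustive ORF scan: every ATG in every forward frame, extended to the
# next in-frame stop (or sequence end).
orf_oracle <- function(s, min_orf_aa = 30L) {
  n <- nchar(s)
  best <- NULL
  for (start in seq_len(max(0L, n - 2L))) {
    if (substr(s, start, start + 2L) != "ATG") next
    aa <- 0L
    pos <- start
    stopped <- FALSE
    while (pos + 2L <= n) {
      codon <- substr(s, pos, pos + 2L)
      if (codon %in% c("TAA", "TAG", "TGA")) { stopped <- TRUE; break }
      aa <- aa + 1L
      pos <- pos + 3L
    }
    if (aa < min_orf_aa) next
    if (is.null(best) || aa > best$aa || (aa == best$aa && start < best$start))
      best <- list(start = start, aa = aa, stopped = stopped)
  }
  best
}

# A random peptide over the 20 amino acids.
random_peptide <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE),
        collapse = "")
}

# Small presentation config used throughout the tests: same architecture
# contract (multi-kernel conv + scalar branch + dense stack), scaled down
# so the suite trains in seconds.
test_model_config <- function(seed = 1L, folds = 10L, epochs = 8L) {
  presentation_model_config(filters_per_kernel = 8L, dense_units = c(32L, 16L),
                            scalar_units = 8L, learning_rate = 3e-3,
                            batch_size = 100L, epochs = epochs, folds = folds,
                            seed = seed, patience = 2L)
}

model_id <- function(models) vapply(models, `[[`, character(1L), "id")

get_model <- function(models, id) models[[which(model_id(models) == id)]]

# Write a small hand-built GTF (1-based inclusive coordinates, as in the
# format) and return its path.
write_test_gtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

gtf_exon_line <- function(chrom, start1, end1, strand, gene, tx) {
  sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          chrom, start1, end1, strand, gene, tx)
}

# Tiny single-exon coding gene whose protein is M + L*58: every non-start,
# non-stop codon is CTG, so a C->A substitution at a codon's first base is
# a known missense (L -> M). Returns genome, annotation and coordinates.
tiny_cds_fixture <- function() {
  n_codons <- 60L
  mrna <- paste0("ATG", strrep("CTG", n_codons - 2L), "TAA")
  genome <- c(chrT = paste0(strrep("T", 10L), mrna, strrep("T", 10L)))
  exons <- matrix(c(10L, 10L + nchar(mrna)), ncol = 2L)
  tx <- transcript_model("T1.1", "chrT", "+", exons, support = 10L)
  attr(tx, "gene_id") <- "GT1"
  genes <- data.frame(gene_id = "GT1", chrom = "chrT", strand = "+",
                      start = exons[1L], end = exons[2L],
                      stringsAsFactors = FALSE)
  list(genome = genome, annotation = genome_annotation(genes, list(tx)),
       cds_genomic_start = 10L, n_codons = n_codons)
}
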