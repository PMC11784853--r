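test_that("longest ORF calling matches an exhaustive scan", {
  orf <- longest_orf("ATGGCCTAA", min_orf_aa = 1L)
  expect_equal(orf$protein, "MA")
  expect_equal(orf$cds, c(0, 9))
  expect_false(orf$partial)
  expect_null(longest_orf(strrep("N", 120)))
  # two ORFs of different lengths: the longer wins
  s <- paste0("CC", "ATG", strrep("GCA", 40), "TAA",
              "G", "ATG", strrep("GCA", 90), "TGA")
  orf <- longest_orf(s, min_orf_aa = 30L)
  expect_equal(nchar(orf$protein), 91L)  # M + 90 alanines
  # randomized agreement with the brute-force oracle
  set.seed(31)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
    got <- longest_orf(s, min_orf_aa = 10L)
    want <- orf_oracle(s, min_orf_aa = 10L)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$cds[1L] + 1L, want$start)
      expect_equal(nchar(got$protein), want$aa)
      expect_equal(got$partial, !want$stopped)
    }
  }
})

test_that("novelty regions equal the quadratic membership oracle", {
  # hand example: one substitution inside a known protein
  idx <- build_kmer_index(c(ref = "MKLVVVGAGG"), k = 4L)
  nr <- novel_regions("MKLVQVGAGG", idx)
  expect_equal(nrow(nr), 1L)
  expect_equal(c(nr$start, nr$end), c(1L, 8L))
  expect_equal(nr$sequence, "KLVQVGA")
  # verbatim self protein has no novel region; short query has no windows
  expect_equal(nrow(novel_regions("MKLVVVGAGG", idx)), 0L)
  expect_equal(nrow(novel_regions("MKL", idx)), 0L)
  # randomized agreement across k values
  set.seed(17)
  for (rep in 1:120) {
    k <- sample(c(4L, 8L, 9L), 1L)
    proteome <- setNames(vapply(rep(40L, 3L), random_peptide, character(1L)),
                         c("a", "b", "c"))
    # query: a proteome substring with a few point substitutions
    src <- sample(proteome, 1L)
    q <- substr(src, 6L, 35L)
    for (j in sample(30L, sample(0:4, 1L)))
      substr(q, j, j) <- sample(c("W", "Y", "H"), 1L)
    idx <- build_kmer_index(proteome, k)
    got <- regions_to_mask(novel_regions(q, idx), nchar(q))
    want <- novelty_mask_oracle(q, proteome, k)
    expect_identical(got, want)
  }
})

test_that("tiling counts follow the closed form", {
  for (L in c(5L, 9L, 14L, 20L, 27L)) {
    region <- list(sequence = random_peptide(L), start = 0L, end = L,
                   protein_id = "p", provenance = "LSTV")
    for (len in c(8L, 9L, 11L, 13L, 15L, 17L)) {
      tiles <- tile_epitopes(region, len, "I")
      expect_equal(nrow(tiles), max(0L, L - len + 1L),
                   label = sprintf("L=%d len=%d", L, len))
    }
    # multi-length grid sums the per-length counts
    tiles <- tile_epitopes(region, 8:11, "I")
    expect_equal(nrow(tiles), sum(pmax(0L, L - (8:11) + 1L)))
  }
})

test_that("flank extension adds the analytic number of junction windows", {
  L <- 9L; len <- 9L
  region <- list(sequence = random_peptide(L), start = 20L, end = 20L + L,
                 protein_id = "p", provenance = "LSTV")
  for (fl in c(0L, 3L, 8L, 12L)) {
    for (fr in c(0L, 8L)) {
      tiles <- tile_epitopes(region, len, "I",
                             flank_left = random_peptide(fl),
                             flank_right = random_peptide(fr))
      # windows overlapping >= 1 novel position, clipped to the context
      lo <- max(1L, fl - len + 2L)
      hi <- min(fl + L, fl + L + fr - len + 1L)
      expect_equal(nrow(tiles), max(0L, hi - lo + 1L),
                   label = sprintf("fl=%d fr=%d", fl, fr))
      expect_true(all(tiles$n_novel >= 1L))
      expect_true(all(nchar(tiles$peptide) == len))
    }
  }
})

test_that("missense windows are centered and clipped correctly", {
  fx <- tiny_cds_fixture()
  # codon 5 (0-based p = 4): variant near the N terminus is clipped
  v_near <- data.frame(chrom = "chrT", pos = fx$cds_genomic_start + 12L + 1L,
                       ref_base = "C", alt_base = "A",
                       filter_status = "PASS", stringsAsFactors = FALSE)
  w <- snv_peptides(v_near, fx$annotation, fx$genome, snv_flank = 12L)
  expect_equal(nchar(w$sequence), 17L)
  expect_equal(w$variant_index, 4L)
  expect_equal(substr(w$sequence, 5L, 5L), "M")  # CTG -> ATG
  # mid-protein variant gets the full 25-mer
  v_mid <- data.frame(chrom = "chrT", pos = fx$cds_genomic_start + 3L * 29L + 1L,
                      ref_base = "C", alt_base = "A",
                      filter_status = "PASS", stringsAsFactors = FALSE)
  w <- snv_peptides(v_mid, fx$annotation, fx$genome, snv_flank = 12L)
  expect_equal(nchar(w$sequence), 25L)
  expect_equal(w$variant_index, 12L)
})

test_that("synonymous and mismatching variants are handled", {
  fx <- tiny_cds_fixture()
  # CTG -> CTA is still leucine: no window
  v_syn <- data.frame(chrom = "chrT", pos = fx$cds_genomic_start + 12L + 3L,
                      ref_base = "G", alt_base = "A",
                      filter_status = "PASS", stringsAsFactors = FALSE)
  expect_message(w <- snv_peptides(v_syn, fx$annotation, fx$genome),
                 "synonymous")
  expect_equal(nrow(w), 0L)
  # declared reference base must match the genome
  v_bad <- data.frame(chrom = "chrT", pos = fx$cds_genomic_start + 13L,
                      ref_base = "T", alt_base = "A",
                      filter_status = "PASS", stringsAsFactors = FALSE)
  expect_error(snv_peptides(v_bad, fx$annotation, fx$genome), "does not match")
})

test_that("SNV windows from planted fixtures land on the variant", {
  b <- make_locus_fixture(c(alt5 = 1, intron_retention = 1), seed = 19)
  v <- make_snv_fixture(b, n = 2L, seed = 4)
  w <- snv_peptides(v, b$annotation, b$genome)
  expect_equal(nrow(w), 2L)
  expect_true(all(nchar(w$sequence) == 25L))
  expect_true(all(w$variant_index == 12L))
  # the mutant window differs from the reference protein at the variant
  for (i in seq_len(nrow(w))) {
    ref <- b$proteome[[w$protein_id[i]]]
    ref_window <- substr(ref, w$start[i] + 1L, w$end[i])
    expect_equal(sum(strsplit(ref_window, "")[[1L]] !=
                       strsplit(w$sequence[i], "")[[1L]]), 1L)
  }
})

test_that("self-similarity screening flags near-self peptides", {
  proteome <- c(p1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
  verbatim <- substr(proteome[[1L]], 5L, 13L)
  expect_equal(self_similarity_screen(verbatim, proteome)$flag, "self_like")
  one_off <- verbatim
  substr(one_off, 9L, 9L) <- "W"
  r <- self_similarity_screen(one_off, proteome)
  expect_equal(r$flag, "self_like")
  expect_equal(r$max_matched_run, 8L)
  # two spread-out differences pass
  two_off <- verbatim
  substr(two_off, 3L, 3L) <- "W"; substr(two_off, 7L, 7L) <- "W"
  expect_equal(self_similarity_screen(two_off, proteome)$flag, "pass")
  # empty proteome
  r0 <- self_similarity_screen("SIINFEKL", character(0L))
  expect_equal(r0$max_matched_run, 0L)
  expect_equal(r0$flag, "pass")
})
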