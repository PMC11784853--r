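test_that("GTF coordinates convert to 0-based half-open and back", {
  path <- write_test_gtf(c(
    gtf_exon_line("chr1", 101, 200, "+", "G1", "G1.1"),
    gtf_exon_line("chr1", 501, 600, "+", "G1", "G1.1")))
  models <- read_transcript_models(path)
  expect_length(models, 1L)
  expect_equal(unname(models[[1L]]$exons),
               matrix(c(100, 500, 200, 600), ncol = 2L))
  out <- tempfile(fileext = ".gtf")
  write_gtf(models, out)
  again <- read_transcript_models(out)
  expect_equal(again[[1L]]$exons, models[[1L]]$exons)
  expect_equal(again[[1L]]$strand, "+")
})

test_that("annotation reader groups transcripts under genes", {
  path <- write_test_gtf(c(
    gtf_exon_line("chr1", 101, 200, "+", "G1", "G1.1"),
    gtf_exon_line("chr1", 301, 400, "+", "G1", "G1.1"),
    gtf_exon_line("chr1", 101, 400, "+", "G1", "G1.2"),
    gtf_exon_line("chr2", 1001, 1300, "-", "G2", "G2.1")))
  ann <- read_annotation(path)
  expect_equal(nrow(ann$genes), 2L)
  expect_length(ann$transcripts, 3L)
  expect_setequal(names(ann$transcripts), c("G1.1", "G1.2", "G2.1"))
  # gene span is the hull of its transcripts
  g1 <- ann$genes[ann$genes$gene_id == "G1", ]
  expect_equal(c(g1$start, g1$end), c(100, 400))
})

test_that("reading is insensitive to GTF line order", {
  lines <- c(
    gtf_exon_line("chr1", 501, 600, "+", "G1", "G1.1"),
    gtf_exon_line("chr1", 101, 200, "+", "G1", "G1.1"),
    gtf_exon_line("chr1", 801, 900, "+", "G1", "G1.2"))
  m1 <- read_transcript_models(write_test_gtf(lines))
  m2 <- read_transcript_models(write_test_gtf(rev(lines)))
  expect_equal(m1, m2)
})

test_that("degenerate GTF inputs are rejected or warned about", {
  empty <- tempfile(fileext = ".gtf")
  writeLines(character(0L), empty)
  expect_warning(ann <- read_annotation(empty), "empty annotation")
  expect_equal(nrow(ann$genes), 0L)
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(gtf_exon_line("chr1", 101, 200, "+", "G1", "G1.1"),
               "chr1\tbroken line"), bad)
  expect_error(read_transcript_models(bad), "line 2")
  # same transcript_id on two chromosomes is a duplicate id
  dup <- write_test_gtf(c(
    gtf_exon_line("chr1", 101, 200, "+", "G1", "TX"),
    gtf_exon_line("chr2", 101, 200, "+", "G2", "TX")))
  expect_error(read_transcript_models(dup), "TX")
})

test_that("transcript model constructor enforces its invariants", {
  expect_error(transcript_model("t", "chr1", "+", matrix(numeric(0L), ncol = 2L)),
               "zero exons")
  expect_error(transcript_model("t", "chr1", "+", cbind(100, 100)), "empty")
  expect_error(transcript_model("t", "chr1", "+",
                                cbind(c(100, 150), c(200, 260))), "overlapping")
  # unsorted input is sorted
  m <- transcript_model("t", "chr1", "-", cbind(c(500, 100), c(600, 200)))
  expect_equal(unname(m$exons[, 1L]), c(100, 500))
})

test_that("FASTA round-trips and validates its alphabet", {
  set.seed(5)
  recs <- setNames(
    vapply(sample(20:80, 100, replace = TRUE), random_peptide, character(1L)),
    sprintf("p%03d", 1:100))
  path <- tempfile(fileext = ".fa")
  write_fasta(recs, path)
  expect_identical(read_fasta(path, "protein"), recs)
  # terminal stop is stripped with a message; internal junk is an error
  write_fasta(c(p1 = "MKV*"), path)
  expect_message(got <- read_fasta(path, "protein"), "stop")
  expect_identical(unname(got), "MKV")
  write_fasta(c(bad = "MK1V"), path)
  expect_error(read_fasta(path, "protein"), "offset 3")
})

test_that("minimal VCF reader keeps only biallelic SNVs", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA\tC\t.\tPASS\t.",
               "chr1\t200\t.\tAT\tA\t.\tPASS\t.",
               "chr1\t300\t.\tG\tC,T\t.\tPASS\t.",
               "chr1\t400\t.\tG\tT\t.\tq10\t.",
               "chr2\t500\t.\tC\tG\t.\tPASS\t."), path)
  expect_message(v <- read_vcf_minimal(path), "skipped")
  expect_equal(nrow(v), 3L)
  expect_equal(v$pos, c(100L, 400L, 500L))
  expect_equal(v$filter_status[2L], "q10")
  # headerless files are rejected
  writeLines("chr1\t100\t.\tA\tC\t.\tPASS\t.", path)
  expect_error(read_vcf_minimal(path))
})
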