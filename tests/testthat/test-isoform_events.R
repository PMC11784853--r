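two_exon_annotation <- function(exons = cbind(c(100, 500), c(200, 600)),
                                strand = "+") {
  tx <- transcript_model("R1.1", "chr1", strand, exons, support = 10L)
  attr(tx, "gene_id") <- "R1"
  genes <- data.frame(gene_id = "R1", chrom = "chr1", strand = strand,
                      start = min(exons[, 1L]), end = max(exons[, 2L]),
                      stringsAsFactors = FALSE)
  genome_annotation(genes, list(tx))
}

test_that("splice chains are the gaps between consecutive exons", {
  m <- transcript_model("t", "chr1", "+", cbind(c(100, 500), c(200, 600)))
  expect_equal(unname(splice_chain(m)$introns), matrix(c(200, 500), ncol = 2L))
  mono <- transcript_model("t", "chr1", "+", cbind(100, 200))
  expect_equal(nrow(splice_chain(mono)$introns), 0L)
  m4 <- transcript_model("t", "chr1", "-",
                         cbind(c(0, 100, 200, 300), c(50, 150, 250, 350)))
  ch <- splice_chain(m4)$introns
  expect_equal(nrow(ch), 3L)
  expect_true(all(diff(ch[, 1L]) > 0))
})

test_that("matching chains are full splice matches", {
  ann <- two_exon_annotation()
  q <- transcript_model("q", "chr1", "+", cbind(c(90, 500), c(200, 650)))
  cls <- classify_isoform(q, ann)  # terminal wobble, same junctions
  expect_equal(cls$primary_class, "FSM")
  expect_equal(cls$matched_reference_id, "R1.1")
  expect_equal(nrow(cls$events), 0L)
})

test_that("a novel exon inside an annotated intron is intron retention", {
  ann <- two_exon_annotation()
  q <- transcript_model("q", "chr1", "+",
                        cbind(c(100, 300, 500), c(200, 360, 600)))
  cls <- classify_isoform(q, ann)
  expect_equal(cls$primary_class, "intron_retention")
  ir <- cls$events[cls$events$class == "intron_retention", ]
  expect_equal(c(ir$start, ir$end), c(300, 360))
})

test_that("a retained annotated intron is intron retention", {
  ann <- two_exon_annotation()
  q <- transcript_model("q", "chr1", "+", cbind(100, 600))
  cls <- classify_isoform(q, ann)
  expect_equal(cls$primary_class, "intron_retention")
  ir <- cls$events[cls$events$class == "intron_retention", ]
  expect_equal(c(ir$start, ir$end), c(200, 500))
})

test_that("donor-side junction changes are alt5 on the plus strand", {
  ann <- two_exon_annotation()
  q <- transcript_model("q", "chr1", "+", cbind(c(100, 500), c(250, 600)))
  cls <- classify_isoform(q, ann)
  expect_equal(cls$primary_class, "alt5")
  # same geometry on the minus strand is an acceptor change
  ann_m <- two_exon_annotation(strand = "-")
  q_m <- transcript_model("q", "chr1", "-", cbind(c(100, 500), c(250, 600)))
  expect_equal(classify_isoform(q_m, ann_m)$primary_class, "alt3")
})

test_that("isoforms outside any gene span are intergenic", {
  ann <- two_exon_annotation()
  far <- transcript_model("q", "chr1", "+", cbind(5000, 5400))
  expect_equal(classify_isoform(far, ann)$primary_class, "intergenic")
  expect_warning(
    cls <- classify_isoform(
      transcript_model("q", "chrUn", "+", cbind(100, 400)), ann),
    "intergenic")
  expect_equal(cls$primary_class, "intergenic")
})

test_that("classification recovers every planted event class", {
  classes <- c("intron_retention", "intergenic", "alt5", "alt3",
               "exon_skipping", "mutually_exclusive_exons")
  for (seed in 1:3) {
    spec <- setNames(rep(1L, 6L), classes)
    b <- make_locus_fixture(spec, seed = seed, include_fsm = FALSE,
                            include_shared_novel = FALSE)
    for (id in names(b$truth)) {
      cls <- classify_isoform(get_model(b$tumor_models, id), b$annotation)
      expect_equal(cls$primary_class, unname(b$truth[[id]]),
                   label = sprintf("seed %d, %s", seed, id))
    }
  }
})

test_that("the five-LSTV fixture reproduces its class composition", {
  b <- make_locus_fixture(c(intron_retention = 2, intergenic = 1,
                            alt5 = 1, alt3 = 1), seed = 7)
  res <- find_lstvs(b$tumor_models, b$normal_models, b$annotation,
                    min_support = 2L)
  expect_length(res$records, 5L)
  expect_equal(res$class_counts[["intron_retention"]], 2L)
  expect_equal(res$class_counts[["intergenic"]], 1L)
  expect_equal(res$class_counts[["alt5"]], 1L)
  expect_equal(res$class_counts[["alt3"]], 1L)
  expect_equal(res$class_counts[["exon_skipping"]], 0L)
  expect_equal(res$class_counts[["mutually_exclusive_exons"]], 0L)
  expect_equal(sum(res$class_counts), length(res$records))
  # output is sorted by position
  expect_false(is.unsorted(res$table$start))
})

test_that("LSTV calling is order-invariant and excludes shared isoforms", {
  b <- make_locus_fixture(c(alt5 = 1, intron_retention = 1), seed = 13)
  res <- find_lstvs(b$tumor_models, b$normal_models, b$annotation)
  set.seed(99)
  res_shuf <- find_lstvs(sample(b$tumor_models), sample(b$normal_models),
                         b$annotation)
  expect_identical(res$table, res_shuf$table)
  expect_identical(res$class_counts, res_shuf$class_counts)
  # no FSM transcript is ever an LSTV
  expect_false("FSM" %in% res$table$primary_class)
  # tumor == normal means no tumor-specific variants
  res0 <- find_lstvs(b$normal_models, b$normal_models, b$annotation,
                     min_support = 0L)
  expect_length(res0$records, 0L)
})

test_that("LSTV count is non-increasing in the support threshold", {
  b <- make_locus_fixture(c(intron_retention = 2, alt3 = 1, intergenic = 1),
                          seed = 5)
  counts <- vapply(c(0L, 2L, 5L, 8L, 100L), function(ms)
    length(find_lstvs(b$tumor_models, b$normal_models, b$annotation,
                      min_support = ms)$records), integer(1L))
  expect_false(is.unsorted(rev(counts)))
  expect_equal(counts[[5L]], 0L)
})

test_that("mono-exonic fragments of annotated exons are not LSTVs", {
  ann <- two_exon_annotation()
  frag <- transcript_model("q", "chr1", "+", cbind(120, 180), support = 10L)
  intronic <- transcript_model("q2", "chr1", "+", cbind(300, 360), support = 10L)
  res <- find_lstvs(list(frag, intronic), list(), ann)
  expect_equal(res$table$id, "q2")
  expect_equal(res$table$primary_class, "intron_retention")
})
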