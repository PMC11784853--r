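STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")),
                              1L, paste0, collapse = ""), STOP_CODONS)

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n)
  intToUtf8(utf8ToInt("ACGT")[sample.int(4L, n, replace = TRUE)])

random_sense_codons <- function(n) paste(sample(SENSE_CODONS, n, replace = TRUE),
                                         collapse = "")

revcomp <- function(s) {
  codes <- rev(utf8ToInt(chartr("ACGTN", "TGCAN", s)))
  intToUtf8(codes)
}

# Overwrite genome bases on `interval` (0-based half-open) so that the
# transcript reads `fragment` (5'->3') across it on `strand`.
plant_fragment <- function(genome, chrom, interval, strand, fragment) {
  stopifnot(nchar(fragment) == interval[2L] - interval[1L])
  if (strand == "-") fragment <- revcomp(fragment)
  substr(genome[[chrom]], interval[1L] + 1L, interval[2L]) <- fragment
  genome
}

# Plant a full mRNA across a set of ascending exons (strand-aware).
plant_mrna <- function(genome, chrom, exons, strand, mrna) {
  stopifnot(nchar(mrna) == sum(exons[, 2L] - exons[, 1L]))
  seq_on_plus <- if (strand == "-") revcomp(mrna) else mrna
  off <- 0L
  for (i in seq_len(nrow(exons))) {
    w <- exons[i, 2L] - exons[i, 1L]
    substr(genome[[chrom]], exons[i, 1L] + 1L, exons[i, 2L]) <-
      substr(seq_on_plus, off + 1L, off + w)
    off <- off + w
  }
  genome
}

# Relative locus template: five 300/360-nt exons separated by 300-nt
# introns. All exon, intron and insert lengths are multiples of 3 so every
# planted event stays in frame and peptide-level ground truth is analytic.
LOCUS_EXONS <- cbind(start = c(1000, 1600, 2200, 2800, 3400),
                     end   = c(1300, 1900, 2500, 3100, 3760))
LOCUS_SPAN <- 50000
NOVEL_EXON <- c(1390, 1480)      # inside intron 1
MXE_EXON <- c(1990, 2080)        # inside intron 2, replaces exon 3
INTERGENIC_EXONS <- cbind(start = c(20000, 20600), end = c(20300, 20960))

#' Generate a toy genome with planted splice events
#'
#' Builds one multi-exon gene locus per requested event, each on a shared
#' toy chromosome, plus a tumor isoform realizing exactly that event. Every
#' locus carries a full-length coding transcript (ATG in exon 1, stop at the
#' transcript end, exon lengths multiples of 3), and every planted variant
#' inserts or rearranges in-frame coding sequence so that the variant
#' protein differs from the reference protein by an analytically known
#' peptide. Loci alternate between the two strands so strand-dependent
#' event semantics are exercised.
#'
#' Supported event names: `intron_retention` (alternating novel-exon-in-
#' intron and retained-intron styles), `intergenic`, `alt5`, `alt3`,
#' `exon_skipping`, `mutually_exclusive_exons`.
#'
#' @param event_spec named integer vector of event counts, e.g.
#'   `c(intron_retention = 2, intergenic = 1, alt5 = 1, alt3 = 1)`.
#' @param seed integer seed; the bundle is a deterministic function of
#'   `event_spec` and `seed`.
#' @param include_fsm add a tumor isoform identical to an annotated
#'   transcript (a full splice match, never an LSTV). Default: only when at
#'   least one event is requested.
#' @param include_shared_novel add a novel isoform present in both tumor
#'   and normal sets (novel but not tumor-specific). Same default.
#' @return a `FixtureBundle`: list with `genome` (named character),
#'   `annotation`, `tumor_models`, `normal_models`, `proteome` (translated
#'   annotated ORFs), `truth` (named vector: tumor-only isoform id ->
#'   planted event label), and `seed`.
#' @export
make_locus_fixture <- function(event_spec = integer(0L), seed,
                               include_fsm = NULL, include_shared_novel = NULL) {
  valid <- c("intron_retention", "intergenic", "alt5", "alt3",
             "exon_skipping", "mutually_exclusive_exons")
  event_spec <- event_spec[event_spec > 0L]
  if (length(event_spec) && !all(names(event_spec) %in% valid))
    stop("unknown event class(es): ",
         paste(setdiff(names(event_spec), valid), collapse = ", "))
  n_events <- sum(event_spec)
  if (is.null(include_fsm)) include_fsm <- n_events > 0L
  if (is.null(include_shared_novel)) include_shared_novel <- n_events > 0L

  events <- rep(names(event_spec), times = event_spec)
  n_extra <- as.integer(include_fsm || include_shared_novel)
  n_loci <- max(1L, n_events + n_extra)

  with_seed(seed, {
    chrom <- "chrS"
    genome <- setNames(list(random_dna(n_loci * LOCUS_SPAN + 5000L)), chrom)
    genes <- list(); annot_tx <- list()
    tumor <- list(); normal <- list()
    truth <- character(0L)
    ir_style <- 0L

    locus_strand <- function(i) if (i %% 2L == 1L) "+" else "-"

    # annotated gene + transcript for locus i; returns info list
    build_gene <- function(i) {
      off <- (i - 1L) * LOCUS_SPAN
      ex <- LOCUS_EXONS + off
      strand <- locus_strand(i)
      n_codon <- sum(ex[, 2L] - ex[, 1L]) / 3L
      mrna <- paste0("ATG", random_sense_codons(n_codon - 2L), "TAA")
      genome <<- plant_mrna(genome, chrom, ex, strand, mrna)
      gid <- sprintf("G%d", i); tid <- sprintf("G%d.1", i)
      tx <- transcript_model(tid, chrom, strand, ex, support = 10L)
      attr(tx, "gene_id") <- gid
      genes[[length(genes) + 1L]] <<- data.frame(
        gene_id = gid, chrom = chrom, strand = strand,
        start = ex[1L, 1L], end = ex[nrow(ex), 2L], stringsAsFactors = FALSE)
      annot_tx[[length(annot_tx) + 1L]] <<- tx
      list(off = off, exons = ex, strand = strand, mrna = mrna,
           gene_id = gid, tx_id = tid)
    }

    add_tumor <- function(exons, strand, label, i, support) {
      id <- sprintf("PB.%d.1", i)
      m <- transcript_model(id, chrom, strand, exons, support = support)
      tumor[[length(tumor) + 1L]] <<- m
      truth[id] <<- label
      m
    }

    for (idx in seq_along(events)) {
      ev <- events[idx]
      loc <- build_gene(idx)
      ex <- loc$exons; off <- loc$off; strand <- loc$strand
      support <- sample(2:9, 1L)
      if (ev == "intergenic") {
        iex <- INTERGENIC_EXONS + off
        n_codon <- sum(iex[, 2L] - iex[, 1L]) / 3L
        mrna <- paste0("ATG", random_sense_codons(n_codon - 2L), "TAA")
        genome <- plant_mrna(genome, chrom, iex, strand, mrna)
        add_tumor(iex, strand, "intergenic", idx, support)
      } else if (ev == "intron_retention") {
        ir_style <- ir_style + 1L
        if (ir_style %% 2L == 1L) {
          # novel exon carved from intron 1
          ne <- NOVEL_EXON + off
          genome <- plant_fragment(genome, chrom, ne, strand,
                                   random_sense_codons((ne[2L] - ne[1L]) / 3L))
          add_tumor(rbind(ex[1L, ], ne, ex[2:5, ]), strand,
                    "intron_retention", idx, support)
        } else {
          # retained intron 1: exons 1 and 2 merge
          intr <- c(ex[1L, 2L], ex[2L, 1L])
          genome <- plant_fragment(genome, chrom, intr, strand,
                                   random_sense_codons((intr[2L] - intr[1L]) / 3L))
          merged <- rbind(c(ex[1L, 1L], ex[2L, 2L]), ex[3:5, ])
          add_tumor(merged, strand, "intron_retention", idx, support)
        }
      } else if (ev %in% c("alt5", "alt3")) {
        # donor (5') side of intron 1 is its start on "+", its end on "-"
        change_start <- (ev == "alt5") == (strand == "+")
        ex2 <- ex
        if (change_start) {
          iv <- c(ex[1L, 2L], ex[1L, 2L] + 6L); ex2[1L, 2L] <- iv[2L]
        } else {
          iv <- c(ex[2L, 1L] - 6L, ex[2L, 1L]); ex2[2L, 1L] <- iv[1L]
        }
        genome <- plant_fragment(genome, chrom, iv, strand, random_sense_codons(2L))
        add_tumor(ex2, strand, ev, idx, support)
      } else if (ev == "exon_skipping") {
        add_tumor(ex[-3L, ], strand, "exon_skipping", idx, support)
      } else if (ev == "mutually_exclusive_exons") {
        me <- MXE_EXON + off
        genome <- plant_fragment(genome, chrom, me, strand,
                                 random_sense_codons((me[2L] - me[1L]) / 3L))
        add_tumor(rbind(ex[1:2, ], me, ex[4:5, ]), strand,
                  "mutually_exclusive_exons", idx, support)
      }
    }

    # background locus for the FSM copy and/or the shared novel isoform
    if (n_extra || n_loci > n_events) {
      i <- n_events + 1L
      loc <- build_gene(i)
      if (include_fsm) {
        m <- transcript_model(sprintf("PB.%d.1", i), chrom, loc$strand,
                              loc$exons, support = 3L)
        tumor[[length(tumor) + 1L]] <- m
      }
      if (include_shared_novel) {
        # a novel donor extension present in tumor AND normal: not an LSTV
        ex2 <- loc$exons
        iv <- c(ex2[1L, 2L], ex2[1L, 2L] + 9L); ex2[1L, 2L] <- iv[2L]
        genome <- plant_fragment(genome, chrom, iv, loc$strand,
                                 random_sense_codons(3L))
        tumor[[length(tumor) + 1L]] <-
          transcript_model(sprintf("PB.%d.2", i), chrom, loc$strand, ex2,
                           support = 4L)
        normal[[length(normal) + 1L]] <-
          transcript_model(sprintf("NB.%d.2", i), chrom, loc$strand, ex2,
                           support = 4L)
      }
    }

    genes_df <- if (length(genes)) do.call(rbind, genes) else
      data.frame(gene_id = character(0L), chrom = character(0L),
                 strand = character(0L), start = numeric(0L), end = numeric(0L),
                 stringsAsFactors = FALSE)
    annotation <- genome_annotation(genes_df, annot_tx, source_tag = "synthetic")

    # matched-normal set: the annotated isoforms plus any shared novel ones
    for (tx in annot_tx) {
      m <- transcript_model(sub("^G", "NB.", tx$id), tx$chrom, tx$strand,
                            tx$exons, support = 10L)
      normal[[length(normal) + 1L]] <- m
    }

    proteome <- vapply(annot_tx, function(tx) {
      orf <- longest_orf(transcript_sequence(tx, genome))
      orf$protein
    }, character(1L))
    names(proteome) <- vapply(annot_tx, `[[`, character(1L), "id")

    structure(list(genome = genome, annotation = annotation,
                   tumor_models = tumor, normal_models = normal,
                   proteome = proteome, truth = truth, seed = seed),
              class = "FixtureBundle")
  })
}

#' @export
print.FixtureBundle <- function(x, ...) {
  cat(sprintf(
    "FixtureBundle (seed %d): %d gene(s), %d tumor / %d normal isoform(s), %d planted event(s)\n",
    x$seed, nrow(x$annotation$genes), length(x$tumor_models),
    length(x$normal_models), length(x$truth)))
  invisible(x)
}

#' Serialize a fixture bundle to standard files
#'
#' Writes `genome.fa`, `annotation.gtf`, `tumor.gtf`, `normal.gtf`,
#' `proteome.fa` and `truth.json` so a bundle doubles as an end-to-end
#' input set.
#'
#' @param bundle a `FixtureBundle`.
#' @param dir output directory (created if needed).
#' @return named vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "annotation.gtf"),
             tumor = file.path(dir, "tumor.gtf"),
             normal = file.path(dir, "normal.gtf"),
             proteome = file.path(dir, "proteome.fa"),
             truth = file.path(dir, "truth.json"))
  write_fasta(bundle$genome, paths["genome"])
  write_gtf(bundle$annotation, paths["annotation"])
  write_gtf(bundle$tumor_models, paths["tumor"])
  write_gtf(bundle$normal_models, paths["normal"])
  write_fasta(bundle$proteome, paths["proteome"])
  jsonlite::write_json(as.list(bundle$truth), paths["truth"], auto_unbox = TRUE)
  invisible(paths)
}

#' Specify a planted peptide-presentation motif
#'
#' @param anchors named character vector: names are 1-based anchor
#'   positions, values the required residue (e.g. `c("2" = "Y", "5" = "L")`).
#'   Positions must fit within the shortest peptide length.
#' @param lengths allowed peptide lengths (default 8-11, MHC class I).
#' @param n_positive number of positive peptides (>= 10).
#' @param decoy_ratio r in the 1:r positive:decoy imbalance (default 10).
#' @param alleles allele names to assign.
#' @return a `MotifSpec` list.
#' @export
motif_spec <- function(anchors = c("2" = "Y", "5" = "L"), lengths = 8:11,
                       n_positive = 100L, decoy_ratio = 10L,
                       alleles = "H2-Kb") {
  pos <- as.integer(names(anchors))
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > min(lengths)))
    stop("anchor positions must lie within the shortest peptide length")
  if (any(duplicated(pos))) stop("duplicate anchor positions")
  if (!all(anchors %in% AA20)) stop("anchor residues must be amino acids")
  if (n_positive < 10L) stop("n_positive must be >= 10")
  if (decoy_ratio < 0L) stop("decoy_ratio must be >= 0")
  structure(list(anchors = anchors, lengths = as.integer(lengths),
                 n_positive = as.integer(n_positive),
                 decoy_ratio = as.integer(decoy_ratio), alleles = alleles),
            class = "MotifSpec")
}

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

#' Generate a labeled peptide-presentation dataset
#'
#' Emulates the statistical structure of eluted-ligand training data:
#' positives carry a planted anchor motif and low percentile binding ranks;
#' decoys are length-matched substrings of a generated source proteome with
#' high ranks; class imbalance is exactly 1:r. By default the positive and
#' decoy rank distributions are disjoint ((0.01, 2] vs (2, 100]), which
#' separates feature-plumbing tests from model-capacity tests; shrink the
#' gap with `decoy_rank_range` to harden the task.
#'
#' @param motif a [motif_spec()].
#' @param proteome_size total residues in the generated source proteome.
#' @param seed integer seed.
#' @param decoy_rank_range rank interval for decoys (default `c(2, 100)`).
#' @return list with `data` (data.frame: peptide, allele, rank_percent,
#'   label) and `proteome` (named character vector).
#' @export
make_presentation_dataset <- function(motif, proteome_size = 20000L, seed,
                                      decoy_rank_range = c(2, 100)) {
  stopifnot(inherits(motif, "MotifSpec"))
  with_seed(seed, {
    n_rec <- 10L
    rec_len <- rep(proteome_size %/% n_rec, n_rec)
    proteome <- setNames(vapply(rec_len, random_protein, character(1L)),
                         sprintf("src%02d", seq_len(n_rec)))
    apos <- as.integer(names(motif$anchors))
    lens <- sample(motif$lengths, motif$n_positive, replace = TRUE)
    positives <- vapply(lens, function(L) {
      aa <- sample(AA20, L, replace = TRUE)
      aa[apos] <- motif$anchors
      paste(aa, collapse = "")
    }, character(1L))
    pos_df <- data.frame(
      peptide = positives,
      allele = sample(motif$alleles, motif$n_positive, replace = TRUE),
      rank_percent = runif(motif$n_positive, 0.01, 2),
      label = 1L, stringsAsFactors = FALSE)
    if (motif$decoy_ratio > 0L) {
      decoys <- generate_decoys(positives, proteome, motif$decoy_ratio,
                                seed = sample.int(2^31 - 1L, 1L))
      dec_df <- data.frame(
        peptide = decoys,
        allele = sample(motif$alleles, length(decoys), replace = TRUE),
        rank_percent = runif(length(decoys), decoy_rank_range[1L],
                             decoy_rank_range[2L]),
        label = 0L, stringsAsFactors = FALSE)
    } else dec_df <- pos_df[0L, ]
    data <- rbind(pos_df, dec_df)
    data <- data[sample.int(nrow(data)), , drop = FALSE]
    rownames(data) <- NULL
    list(data = data, proteome = proteome)
  })
}

#' Plant a missense SNV fixture for the variant-calling comparison arm
#'
#' Picks coding positions in annotated transcripts of a fixture bundle and
#' substitutes one base per site so that the encoded amino acid changes
#' (never to a stop). Returns VCF-style 1-based records suitable for
#' [write_snv_vcf()] and [snv_peptides()].
#'
#' @param bundle a `FixtureBundle` with at least one annotated transcript.
#' @param n number of missense SNVs to plant.
#' @param seed integer seed.
#' @return data.frame with `chrom`, `pos`, `ref_base`, `alt_base`,
#'   `filter_status`.
#' @export
make_snv_fixture <- function(bundle, n = 1L, seed = 1L) {
  txs <- bundle$annotation$transcripts
  if (!length(txs)) stop("bundle has no annotated transcripts")
  with_seed(seed, {
    out <- list()
    for (i in seq_len(n)) {
      tx <- txs[[((i - 1L) %% length(txs)) + 1L]]
      seqs <- transcript_sequence(tx, bundle$genome)
      orf <- longest_orf(seqs)
      # mutate the first base of a mid-protein codon
      p <- sample(seq(10L, nchar(orf$protein) - 10L), 1L)
      tpos <- orf$cds[1L] + 3L * (p - 1L)  # 0-based transcript position
      codon <- substr(seqs, tpos + 1L, tpos + 3L)
      ref_aa <- translate_dna(codon)
      alt <- NULL
      for (b in setdiff(c("A", "C", "G", "T"), substr(codon, 1L, 1L))) {
        cd <- codon; substr(cd, 1L, 1L) <- b
        aa <- translate_dna(cd)
        if (aa != ref_aa && aa != "*") { alt <- b; break }
      }
      if (is.null(alt)) next
      gpos <- transcript_to_genomic(tx, tpos)  # 0-based genomic
      ref_genome <- substr(bundle$genome[[tx$chrom]], gpos + 1L, gpos + 1L)
      alt_genome <- if (tx$strand == "-") revcomp(alt) else alt
      out[[length(out) + 1L]] <- data.frame(
        chrom = tx$chrom, pos = gpos + 1L, ref_base = ref_genome,
        alt_base = alt_genome, filter_status = "PASS", stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Write SNV records as a minimal VCF 4.2 file
#'
#' @param variants data.frame with `chrom`, `pos`, `ref_base`, `alt_base`,
#'   `filter_status`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(variants, path) {
  header <- c("##fileformat=VCFv4.2",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.", variants$chrom,
                  as.integer(variants$pos), variants$ref_base,
                  variants$alt_base, variants$filter_status)
  writeLines(c(header, body), path)
  invisible(path)
}
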