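#' @importFrom stats runif rbinom setNames
#' @importFrom utils head tail
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a transcript model
#'
#' A `TranscriptModel` is the unit of isoform comparison: a stranded,
#' exon-structured transcript on one chromosome. Exons are stored as a
#' two-column matrix of 0-based half-open genomic intervals, always in
#' ascending genomic order regardless of strand; 5'/3' semantics are
#' resolved later, at event-classification time.
#'
#' @param id transcript identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column numeric matrix (start, end), 0-based half-open.
#' @param support optional full-length read support count (`NA` if unknown).
#' @return an object of class `TranscriptModel`.
#' @export
transcript_model <- function(id, chrom, strand, exons, support = NA_integer_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("transcript '", id, "' has zero exons")
  if (any(exons[, 1L] >= exons[, 2L]))
    stop("transcript '", id, "' has an empty or inverted exon interval")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("transcript '", id, "' has overlapping exons")
  structure(
    list(id = id, chrom = as.character(chrom), strand = strand,
         exons = exons, support = support),
    class = "TranscriptModel"
  )
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s %s:%s [%d exon(s)] %d-%d support=%s\n",
              x$id, x$chrom, x$strand, nrow(x$exons),
              min(x$exons[, 1L]), max(x$exons[, 2L]),
              as.character(x$support)))
  invisible(x)
}

model_span <- function(model) c(model$exons[1L, 1L], model$exons[nrow(model$exons), 2L])

#' Construct a genome annotation
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open gene spans).
#' @param transcripts named list of [transcript_model()] objects; each must
#'   carry a `gene_id` attribute naming its parent gene.
#' @param source_tag free-text provenance tag.
#' @return an object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(genes, transcripts, source_tag = "") {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)))
  if (length(transcripts)) {
    ids <- vapply(transcripts, `[[`, character(1L), "id")
    if (anyDuplicated(ids))
      stop("duplicate transcript id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(transcripts) <- ids
    parents <- vapply(transcripts, function(tx) attr(tx, "gene_id") %||% NA_character_,
                      character(1L))
    if (anyNA(parents) || !all(parents %in% genes$gene_id))
      stop("every transcript must belong to exactly one known gene")
  } else {
    transcripts <- setNames(list(), character(0L))
  }
  structure(list(genes = genes, transcripts = transcripts, source_tag = source_tag),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d gene(s), %d transcript(s)%s\n",
              nrow(x$genes), length(x$transcripts),
              if (nzchar(x$source_tag)) paste0(" [", x$source_tag, "]") else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Light structural pre-scan so malformed GTF lines are reported with their
# line number (the underlying importer does not track them).
check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  bad <- which(keep)[vapply(strsplit(lines[keep], "\t", fixed = TRUE),
                            length, integer(1L)) < 9L]
  if (length(bad))
    stop("malformed GTF line ", bad[1L], " in '", path,
         "': fewer than 9 tab-separated fields")
  any(keep)
}

import_gtf_exons <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!check_gtf_lines(path)) return(NULL)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (!length(gr)) return(NULL)
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id) || anyNA(mc$transcript_id))
    stop("GTF exon records must carry transcript_id attributes: ", path)
  gr
}

# Group imported exon ranges into TranscriptModel objects.
# GTF is 1-based inclusive; internal coordinates are 0-based half-open.
granges_to_models <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  df <- data.frame(
    transcript_id = as.character(mc$transcript_id),
    gene_id = if (!is.null(mc$gene_id)) as.character(mc$gene_id) else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    support = if (!is.null(mc$support)) suppressWarnings(as.integer(mc$support))
              else NA_integer_,
    stringsAsFactors = FALSE
  )
  models <- lapply(split(df, df$transcript_id), function(d) {
    if (length(unique(d$chrom)) > 1L || length(unique(d$strand)) > 1L)
      stop("duplicate transcript_id '", d$transcript_id[1L],
           "': exons on multiple chromosomes or strands")
    if (anyDuplicated(d[, c("start", "end")]))
      stop("duplicate transcript_id '", d$transcript_id[1L],
           "': repeated identical exon lines")
    m <- transcript_model(d$transcript_id[1L], d$chrom[1L], d$strand[1L],
                          cbind(d$start, d$end), support = d$support[1L])
    attr(m, "gene_id") <- d$gene_id[1L]
    m
  })
  models[order(names(models))]
}

#' Read a GTF annotation
#'
#' Parses gene/transcript/exon structure from a GTF file into a
#' [genome_annotation()]. GTF 1-based inclusive coordinates are converted to
#' the internal 0-based half-open convention at this boundary; exons are
#' sorted per transcript. Gene spans are the hull of each gene's transcripts.
#'
#' @param path path to a GTF file.
#' @return a `GenomeAnnotation`.
#' @export
read_annotation <- function(path) {
  gr <- import_gtf_exons(path)
  if (is.null(gr)) {
    warning("no exon records in '", path, "': returning empty annotation")
    genes <- data.frame(gene_id = character(0L), chrom = character(0L),
                        strand = character(0L), start = numeric(0L),
                        end = numeric(0L), stringsAsFactors = FALSE)
    return(genome_annotation(genes, list(), source_tag = path))
  }
  models <- granges_to_models(gr)
  parent <- vapply(models, function(m) attr(m, "gene_id"), character(1L))
  if (anyNA(parent)) stop("GTF exon records must carry gene_id attributes: ", path)
  genes <- do.call(rbind, lapply(split(seq_along(models), parent), function(i) {
    spans <- t(vapply(models[i], model_span, numeric(2L)))
    data.frame(gene_id = parent[i[1L]], chrom = models[[i[1L]]]$chrom,
               strand = models[[i[1L]]]$strand,
               start = min(spans[, 1L]), end = max(spans[, 2L]),
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  genome_annotation(genes[order(genes$gene_id), , drop = FALSE], models,
                    source_tag = path)
}

#' Read transcript models from a GTF file
#'
#' Like [read_annotation()] but returns the flat list of transcript models
#' (gene grouping optional in the source file).
#'
#' @inheritParams read_annotation
#' @return list of `TranscriptModel` objects, sorted by id.
#' @export
read_transcript_models <- function(path) {
  gr <- import_gtf_exons(path)
  if (is.null(gr)) {
    warning("no exon records in '", path, "': returning empty model list")
    return(list())
  }
  granges_to_models(gr)
}

models_to_granges <- function(models) {
  rows <- do.call(rbind, lapply(models, function(m) {
    data.frame(chrom = m$chrom, start = m$exons[, 1L] + 1L, end = m$exons[, 2L],
               strand = m$strand, transcript_id = m$id,
               gene_id = attr(m, "gene_id") %||% m$id,
               support = m$support, stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(rows$chrom,
                               IRanges::IRanges(rows$start, rows$end),
                               strand = rows$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = "exon", gene_id = rows$gene_id, transcript_id = rows$transcript_id,
    support = rows$support)
  gr
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_transcript_models()]: internal 0-based half-open exon
#' intervals are emitted as 1-based inclusive GTF exon records.
#'
#' @param models list of `TranscriptModel` objects or a `GenomeAnnotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  if (inherits(models, "GenomeAnnotation")) models <- models$transcripts
  if (!length(models)) {
    writeLines(character(0L), path)
    return(invisible(path))
  }
  rtracklayer::export(models_to_granges(models), path, format = "gtf")
  invisible(path)
}

validate_alphabet <- function(seqs, alphabet, what) {
  ok <- paste0("[", paste(alphabet, collapse = ""), "]*")
  for (nm in names(seqs)) {
    m <- regmatches(seqs[[nm]], regexpr(ok, seqs[[nm]]))
    if (nchar(m) != nchar(seqs[[nm]]))
      stop("record '", nm, "': non-", what, " character at offset ",
           nchar(m) + 1L)
  }
  invisible(TRUE)
}

#' Read a FASTA file
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @param alphabet `"dna"` (A/C/G/T/N) or `"protein"` (20 amino acids plus
#'   X). Protein records are upper-cased and a single terminal `*` stop is
#'   stripped; internal stops are rejected.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  seqs <- setNames(toupper(as.character(ss)), names(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (alphabet == "protein") {
    stripped <- sub("\\*$", "", seqs)
    if (any(stripped != seqs))
      message(sum(stripped != seqs), " terminal stop codon(s) stripped")
    seqs <- stripped
    validate_alphabet(seqs, c(AA20, "X"), "protein")
  } else {
    validate_alphabet(seqs, c("A", "C", "G", "T", "N"), "DNA")
  }
  seqs
}

#' Write a FASTA file
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @param line_width residues per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  if (is.list(records)) records <- unlist(records)
  ss <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(ss, path, width = line_width)
  invisible(path)
}

#' Read single-nucleotide variants from a VCF file
#'
#' Minimal VCF 4.x ingestion for the SNV comparison arm: only biallelic
#' single-nucleotide substitutions are retained; indels and multi-allelic
#' records are skipped (counts reported via `message()`). Positions stay
#' 1-based as in the VCF; FILTER is carried through.
#'
#' @param path path to a VCF file.
#' @return data.frame with columns `chrom`, `pos`, `ref_base`, `alt_base`,
#'   `filter_status`.
#' @export
read_vcf_minimal <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || !nrow(fix)) {
    return(data.frame(chrom = character(0L), pos = integer(0L),
                      ref_base = character(0L), alt_base = character(0L),
                      filter_status = character(0L), stringsAsFactors = FALSE))
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  snv <- !multi & nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  n_indel <- sum(!multi & !snv)
  if (sum(multi)) message(sum(multi), " multi-allelic record(s) skipped")
  if (n_indel) message(n_indel, " non-SNV record(s) skipped")
  data.frame(
    chrom = unname(fix[snv, "CHROM"]),
    pos = as.integer(fix[snv, "POS"]),
    ref_base = unname(ref[snv]),
    alt_base = unname(alt[snv]),
    filter_status = unname(ifelse(is.na(fix[snv, "FILTER"]), ".",
                                  fix[snv, "FILTER"])),
    stringsAsFactors = FALSE
  )
}
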