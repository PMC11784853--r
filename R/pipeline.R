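#' Assemble a pipeline configuration
#'
#' All paths are checked at construction. The configuration is serialized
#' verbatim into every report, so a report always records the exact inputs
#' and thresholds that produced it.
#'
#' @param genome,annotation,proteome,tumor,normal required input paths
#'   (genome FASTA, reference GTF, reference proteome FASTA, tumor and
#'   matched-normal transcript-model GTFs).
#' @param vcf optional SNV calls (VCF) for the point-mutation comparison
#'   arm.
#' @param rank_table optional TSV `peptide, allele, rank_percent` from an
#'   external MHC binding-rank tool.
#' @param training_table optional labeled TSV `peptide, allele,
#'   rank_percent, label`; when given, the presentation model is trained on
#'   it and used for scoring, otherwise a rank-only baseline score
#'   `(100 - rank)/100` is used.
#' @param outdir output directory (default: no files written).
#' @param k proteome k-mer length for the novelty filter (default 8).
#' @param min_orf_aa minimum ORF length in residues.
#' @param mhc1_lengths,mhc2_lengths tiling lengths for the two MHC classes.
#' @param snv_flank residues flanking a missense substitution.
#' @param min_support minimum full-length read support for LSTV calling.
#' @param score_threshold,rank_threshold binder-calling thresholds.
#' @param alleles_mhc1,alleles_mhc2 allele names assigned to candidates.
#' @param model a [presentation_model_config()]; defaults applied when
#'   `NULL`.
#' @param features a [feature_config()]; when `NULL`, a one-hot config
#'   with hotspot length `max(mhc1_lengths, mhc2_lengths)` is used.
#' @param seed integer master seed.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(genome, annotation, proteome, tumor, normal,
                            vcf = NULL, rank_table = NULL,
                            training_table = NULL, outdir = NULL,
                            k = 8L, min_orf_aa = 30L,
                            mhc1_lengths = 8:11, mhc2_lengths = 13:17,
                            snv_flank = 12L, min_support = 2L,
                            score_threshold = 0.5, rank_threshold = 2,
                            alleles_mhc1 = c("H2-Kb", "H2-Db"),
                            alleles_mhc2 = "IA-b",
                            model = NULL, features = NULL, seed = 1L) {
  paths <- c(genome = genome, annotation = annotation, proteome = proteome,
             tumor = tumor, normal = normal, vcf = vcf,
             rank_table = rank_table, training_table = training_table)
  missing <- paths[!vapply(paths, file.exists, logical(1L))]
  if (length(missing))
    stop("input path(s) not found: ",
         paste(sprintf("%s (%s)", missing, names(missing)), collapse = ", "))
  if (is.null(features))
    features <- feature_config(hotspot_length = max(mhc1_lengths, mhc2_lengths))
  if (is.null(model)) model <- presentation_model_config(seed = seed)
  structure(list(genome = genome, annotation = annotation,
                 proteome = proteome, tumor = tumor, normal = normal,
                 vcf = vcf, rank_table = rank_table,
                 training_table = training_table, outdir = outdir,
                 k = as.integer(k), min_orf_aa = as.integer(min_orf_aa),
                 mhc1_lengths = as.integer(mhc1_lengths),
                 mhc2_lengths = as.integer(mhc2_lengths),
                 snv_flank = as.integer(snv_flank),
                 min_support = as.integer(min_support),
                 score_threshold = score_threshold,
                 rank_threshold = rank_threshold,
                 alleles_mhc1 = alleles_mhc1, alleles_mhc2 = alleles_mhc2,
                 model = model, features = features, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the file's directory.
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("genome", "annotation", "proteome", "tumor", "normal", "vcf",
                "rank_table", "training_table", "outdir")) {
    if (!is.null(y[[key]]) && !grepl("^/", y[[key]]))
      y[[key]] <- file.path(base, y[[key]])
  }
  do.call(pipeline_config, y)
}

# Flank context around a novel region: up to `width` reference residues on
# each side, so junction-spanning windows can be tiled.
region_flanks <- function(protein, start0, end0, width) {
  lo <- max(0L, start0 - width)
  list(left = substr(protein, lo + 1L, start0),
       right = substr(protein, end0 + 1L, min(nchar(protein), end0 + width)))
}

tile_both_classes <- function(region, flanks, cfg) {
  rbind(
    tile_epitopes(region, cfg$mhc1_lengths, "I",
                  flank_left = flanks$left, flank_right = flanks$right),
    tile_epitopes(region, cfg$mhc2_lengths, "II",
                  flank_left = flanks$left, flank_right = flanks$right))
}

expand_alleles <- function(cands, cfg) {
  if (!nrow(cands)) { cands$allele <- character(0L); return(cands) }
  parts <- lapply(seq_len(nrow(cands)), function(i) {
    alleles <- if (cands$mhc_class[i] == "I") cfg$alleles_mhc1 else cfg$alleles_mhc2
    d <- cands[rep(i, length(alleles)), , drop = FALSE]
    d$allele <- alleles
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Rank-only baseline presentation score
#'
#' `(100 - rank) / 100`, with missing ranks imputed: a monotone rescaling
#' of the percentile binding rank onto `[0, 1)` used when no trained model
#' is available.
#'
#' @param rank_percent percentile ranks, possibly `NA`.
#' @param impute_rank imputation for missing ranks.
#' @return scores in `[0, 1)`.
#' @export
score_by_rank <- function(rank_percent, impute_rank = 50) {
  rank_percent[is.na(rank_percent)] <- impute_rank
  (100 - rank_percent) / 100
}

#' Run the neoepitope discovery pipeline
#'
#' Stages, in order: LSTV calling (tumor vs normal vs annotation), ORF
#' calling and proteome-novelty extraction, candidate tiling (both MHC
#' classes), the SNV comparison arm (when a VCF is given), self-antigen
#' screening, presentation scoring, binder calling, and report assembly.
#' Per-stage candidate counts are recorded per provenance arm so the
#' filtering cascade is auditable. Rerunning with the same configuration
#' and seed reproduces the report byte-identically apart from the
#' timestamp.
#'
#' @param config a [pipeline_config()].
#' @return a `PipelineReport` list; also written to `config$outdir` via
#'   [write_report()] when an output directory is configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  genome <- read_fasta(config$genome, "dna")
  annotation <- read_annotation(config$annotation)
  proteome <- read_fasta(config$proteome, "protein")
  tumor <- read_transcript_models(config$tumor)
  normal <- read_transcript_models(config$normal)

  lstv <- find_lstvs(tumor, normal, annotation, min_support = config$min_support)
  index <- build_kmer_index(proteome, k = config$k)
  max_len <- max(config$mhc1_lengths, config$mhc2_lengths)

  dropped <- list()
  cand_parts <- list()
  for (rec in lstv$records) {
    seqs <- transcript_sequence(rec$transcript, genome)
    orf <- longest_orf(seqs, min_orf_aa = config$min_orf_aa)
    if (is.null(orf)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        stage = "orf", id = rec$transcript$id, reason = "no qualifying ORF")
      next
    }
    regions <- novel_regions(orf$protein, index, protein_id = rec$transcript$id)
    if (!nrow(regions)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        stage = "novelty", id = rec$transcript$id, reason = "no novel k-mers")
      next
    }
    for (i in seq_len(nrow(regions))) {
      fl <- region_flanks(orf$protein, regions$start[i], regions$end[i],
                          max_len - 1L)
      cand_parts[[length(cand_parts) + 1L]] <-
        tile_both_classes(regions[i, ], fl, config)
    }
  }

  if (!is.null(config$vcf)) {
    variants <- read_vcf_minimal(config$vcf)
    snv_regions <- snv_peptides(variants, annotation, genome,
                                snv_flank = config$snv_flank,
                                min_orf_aa = config$min_orf_aa)
    for (i in seq_len(nrow(snv_regions))) {
      cand_parts[[length(cand_parts) + 1L]] <-
        tile_both_classes(snv_regions[i, ], list(left = "", right = ""), config)
    }
  }

  cands <- if (length(cand_parts)) do.call(rbind, cand_parts) else
    tile_epitopes(list(sequence = "", start = 0L, end = 0L,
                       protein_id = "", provenance = "LSTV"), 9L, "I")
  rownames(cands) <- NULL
  n_tiled <- table(factor(cands$provenance, levels = c("LSTV", "SNV")))

  # self-antigen screen on unique peptides
  if (nrow(cands)) {
    uniq <- unique(cands$peptide)
    flags <- vapply(uniq, function(p) self_similarity_screen(p, proteome)$flag,
                    character(1L))
    cands <- cands[flags[cands$peptide] == "pass", , drop = FALSE]
  }
  n_screened <- table(factor(cands$provenance, levels = c("LSTV", "SNV")))

  cands <- expand_alleles(cands, config)

  # attach external binding ranks when provided
  if (!is.null(config$rank_table)) {
    rt <- utils::read.table(config$rank_table, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    key <- paste(cands$peptide, cands$allele)
    m <- match(key, paste(rt$peptide, rt$allele))
    cands$rank_percent <- rt$rank_percent[m]
  } else {
    cands$rank_percent <- rep(NA_real_, nrow(cands))
  }

  scoring_mode <- if (!is.null(config$training_table)) "model" else "rank_baseline"
  if (scoring_mode == "model" && nrow(cands)) {
    train <- utils::read.table(config$training_table, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    model <- fit_presentation_model(train, config$model, config$features)
    cands <- predict_presentation(model, cands)
  } else {
    cands$score <- score_by_rank(cands$rank_percent)
  }

  called <- call_binders(cands, config$score_threshold, config$rank_threshold)
  # stage counts stay at window level (pre allele expansion) so the
  # filtering cascade is monotone: tiled >= self_screened >= binders
  kept <- called$candidates
  win_key <- function(d) unique(paste(d$protein_id, d$peptide_start,
                                      d$mhc_class, d$peptide, d$provenance))
  n_binders <- vapply(c("LSTV", "SNV"), function(pr)
    length(win_key(kept[kept$provenance == pr, , drop = FALSE])), integer(1L))

  stage_counts <- data.frame(
    stage = rep(c("tiled", "self_screened", "binders"), each = 2L),
    provenance = rep(c("LSTV", "SNV"), 3L),
    count = as.integer(c(n_tiled, n_screened, n_binders)),
    stringsAsFactors = FALSE)

  report <- structure(list(
    tool = "isoneo",
    version = as.character(utils::packageVersion("isoneo")),
    seed = config$seed,
    config = config[!vapply(config, is.null, logical(1L)) &
                      !names(config) %in% c("model", "features")],
    model_config = unclass(config$model),
    feature_config = unclass(config$features)[
      setdiff(names(config$features), "embedding_table")],
    scoring_mode = scoring_mode,
    lstv_table = lstv$table,
    class_counts = as.list(lstv$class_counts),
    stage_counts = stage_counts,
    binder_counts = list(I = unname(called$counts["I"]),
                         II = unname(called$counts["II"])),
    dropped = if (length(dropped)) do.call(rbind, dropped) else NULL,
    candidates = cands,
    binders = called$candidates,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "PipelineReport")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat(sprintf("PipelineReport: %d LSTV(s), %d candidate row(s), %d binder row(s)\n",
              nrow(x$lstv_table), nrow(x$candidates), nrow(x$binders)))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (the full report), `lstvs.tsv` and
#' `candidates.tsv`.
#'
#' @param report a `PipelineReport`.
#' @param outdir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(report = file.path(outdir, "report.json"),
             lstvs = file.path(outdir, "lstvs.tsv"),
             candidates = file.path(outdir, "candidates.tsv"))
  jsonlite::write_json(unclass(report), paths["report"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  utils::write.table(report$lstv_table, paths["lstvs"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$candidates, paths["candidates"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# Most-frequent mammalian codon per amino acid; used for reverse
# translation of minigene constructs.
PREFERRED_CODON <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
  H = "CAC", I = "ATC", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
  P = "CCC", Q = "CAG", R = "AGA", S = "AGC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAC")

#' Assemble a tandem-minigene construct
#'
#' Concatenates epitopes (optionally separated by a linker) in the given
#' order into one open reading frame and reverse-translates it using the
#' most frequent codon per residue. The construct layout (ordered epitope
#' concatenation) is the computable content of a tandem-minigene mRNA
#' design; UTRs, codon-optimization objectives and nucleoside chemistry
#' are out of scope.
#'
#' @param epitopes character vector of epitope peptides (>= 1), in the
#'   order they should appear.
#' @param linker residue string between consecutive epitopes (may be
#'   empty).
#' @param codon_table named character vector residue -> codon.
#' @return list with `protein`, `nucleotide`, and `n_segments`; the
#'   nucleotide sequence translates back to the protein exactly.
#' @export
assemble_minigene <- function(epitopes, linker = "",
                              codon_table = PREFERRED_CODON) {
  if (!length(epitopes)) stop("at least one epitope is required")
  protein <- paste(epitopes, collapse = linker)
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  bad <- setdiff(aa, names(codon_table))
  if (length(bad))
    stop("no codon for residue(s): ", paste(bad, collapse = ", "))
  nucleotide <- paste(codon_table[aa], collapse = "")
  check <- translate_dna(nucleotide)
  if (check != protein)
    stop("reverse translation failed to round-trip")  # defensive; codon table bug
  list(protein = protein, nucleotide = nucleotide,
       n_segments = length(epitopes))
}
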