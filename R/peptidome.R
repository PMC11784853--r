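#' Extract the spliced transcript sequence from a genome
#'
#' Concatenates exon sequences in ascending genomic order and
#' reverse-complements for minus-strand transcripts, yielding the 5'->3'
#' transcript sequence.
#'
#' @param model a `TranscriptModel`.
#' @param genome named character vector of chromosome sequences.
#' @return transcript sequence (character scalar).
#' @export
transcript_sequence <- function(model, genome) {
  if (!model$chrom %in% names(genome))
    stop("chromosome '", model$chrom, "' not in genome")
  chr <- genome[[model$chrom]]
  parts <- apply(model$exons, 1L, function(iv)
    substr(chr, iv[1L] + 1L, iv[2L]))
  s <- paste(parts, collapse = "")
  if (model$strand == "-") s <- revcomp(s)
  s
}

#' Map a transcript coordinate to a genomic coordinate
#'
#' @param model a `TranscriptModel`.
#' @param tpos 0-based position in the spliced transcript (5'->3').
#' @return 0-based genomic position.
#' @export
transcript_to_genomic <- function(model, tpos) {
  widths <- model$exons[, 2L] - model$exons[, 1L]
  total <- sum(widths)
  if (tpos < 0L || tpos >= total) stop("transcript position out of range")
  # position along the plus-strand concatenation
  ppos <- if (model$strand == "-") total - 1L - tpos else tpos
  cum <- cumsum(widths)
  i <- which(ppos < cum)[1L]
  offset_in_exon <- ppos - c(0L, cum)[i]
  model$exons[i, 1L] + offset_in_exon
}

#' Map a genomic coordinate to a transcript coordinate
#'
#' @param model a `TranscriptModel`.
#' @param gpos 0-based genomic position; must fall in an exon.
#' @return 0-based transcript position, or `NA` if `gpos` is not exonic.
#' @export
genomic_to_transcript <- function(model, gpos) {
  widths <- model$exons[, 2L] - model$exons[, 1L]
  i <- which(model$exons[, 1L] <= gpos & gpos < model$exons[, 2L])
  if (!length(i)) return(NA_integer_)
  ppos <- sum(widths[seq_len(i - 1L)]) + (gpos - model$exons[i, 1L])
  if (model$strand == "-") sum(widths) - 1L - ppos else ppos
}

# Standard-code translation by table lookup (vectorized over codons);
# codons containing N translate to X. Kept free of S4 dispatch because ORF
# scanning dominates fixture generation and pipeline runtime.
.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

translate_dna <- function(s) {
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return("")
  starts <- seq.int(1L, n - 2L, 3L)
  aa <- .codon_table()[substring(s, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Find the longest ATG-initiated open reading frame
#'
#' Scans the three forward frames for ATG-initiated ORFs that terminate at
#' a stop codon (or at the transcript end, in which case the ORF is flagged
#' partial) and returns the longest one with at least `min_orf_aa` residues.
#' Ties are broken by the leftmost nucleotide start. No Kozak-context
#' scoring is applied.
#'
#' @param sequence nucleotide sequence over A/C/G/T/N.
#' @param min_orf_aa minimum protein length in residues (default 30).
#' @return `NULL` when no ORF qualifies; otherwise a list with `protein`
#'   (residues, stop excluded), `cds` (0-based half-open nucleotide
#'   coordinates, stop codon included when present) and `partial` (logical:
#'   no stop codon before the transcript end).
#' @export
longest_orf <- function(sequence, min_orf_aa = 30L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  best <- NULL
  for (frame in 0:2) {
    sub <- substr(sequence, frame + 1L, n)
    usable <- nchar(sub) - nchar(sub) %% 3L
    if (usable < 3L) next
    prot <- translate_dna(substr(sub, 1L, usable))
    # ATG-initiated runs up to (and excluding) the next stop
    m <- gregexpr("M[^*]*", prot)[[1L]]
    if (m[1L] == -1L) next
    for (j in seq_along(m)) {
      aa_start <- m[j]
      aa_len <- attr(m, "match.length")[j]
      if (aa_len < min_orf_aa) next
      stop_follows <- substr(prot, aa_start + aa_len, aa_start + aa_len) == "*"
      nt_start <- frame + (aa_start - 1L) * 3L
      nt_end <- nt_start + aa_len * 3L + if (stop_follows) 3L else 0L
      cand <- list(protein = substr(prot, aa_start, aa_start + aa_len - 1L),
                   cds = c(nt_start, nt_end), partial = !stop_follows)
      if (is.null(best) || aa_len > nchar(best$protein) ||
          (aa_len == nchar(best$protein) && nt_start < best$cds[1L]))
        best <- cand
    }
  }
  best
}

#' Build a k-mer membership index over a reference proteome
#'
#' @param proteome named character vector of protein sequences.
#' @param k k-mer length in residues (default 8, the shortest class-I
#'   ligand; any peptide window matching a self 8-mer is treated as
#'   non-novel).
#' @return list with `k` and the sorted unique k-mer `set`, of class
#'   `KmerIndex`.
#' @export
build_kmer_index <- function(proteome, k = 8L) {
  kmers <- unlist(lapply(proteome, function(p) {
    L <- nchar(p)
    if (L < k) return(character(0L))
    substring(p, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  }), use.names = FALSE)
  structure(list(k = as.integer(k), set = sort(unique(kmers))),
            class = "KmerIndex")
}

#' Extract proteome-novel regions of a protein
#'
#' A protein position is novel-covered iff it lies in some length-k window
#' absent from the reference proteome k-mer set; maximal runs of
#' novel-covered positions become regions. A protein present verbatim in
#' the proteome yields no regions; a protein shorter than k yields none
#' (no windows to test).
#'
#' @param protein protein sequence.
#' @param index a [build_kmer_index()] result.
#' @param protein_id identifier recorded on the regions.
#' @return data.frame with `protein_id`, `start`, `end` (0-based half-open
#'   protein coordinates), `sequence`, `provenance` (`"LSTV"`).
#' @export
novel_regions <- function(protein, index, protein_id = "query") {
  k <- index$k
  L <- nchar(protein)
  empty <- data.frame(protein_id = character(0L), start = integer(0L),
                      end = integer(0L), sequence = character(0L),
                      provenance = character(0L), stringsAsFactors = FALSE)
  if (k > L) return(empty)
  starts <- seq_len(L - k + 1L)
  windows <- substring(protein, starts, starts + k - 1L)
  absent <- !(windows %in% index$set)
  if (!any(absent)) return(empty)
  covered <- logical(L)
  for (i in starts[absent]) covered[i:(i + k - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(protein_id = protein_id,
             start = begins[keep] - 1L, end = ends[keep],
             sequence = substring(protein, begins[keep], ends[keep]),
             provenance = "LSTV", stringsAsFactors = FALSE)
}

#' Tile candidate epitope windows over a novel region
#'
#' For each requested length, emits every window that overlaps at least one
#' novel position, allowing windows to extend into flanking reference
#' context by up to length-1 residues on each side so junction-spanning
#' epitopes are kept. Without flanking context the count per length is
#' `max(0, L - length + 1)`.
#'
#' @param region one row of [novel_regions()] output (or a list with
#'   `sequence`, `start`, `end`, `protein_id`, `provenance`; an optional
#'   `variant_index` marks an SNV substitution position within the region).
#' @param lengths peptide lengths to tile (e.g. 8:11 for class I, 13:17
#'   for class II).
#' @param mhc_class `"I"` or `"II"`.
#' @param flank_left,flank_right reference residues adjacent to the region
#'   (may be empty strings).
#' @return data.frame of candidates: `peptide`, `mhc_class`, `allele`
#'   (`NA`, assigned later), `protein_id`, `region_start`, `region_end`,
#'   `peptide_start` (0-based, protein coordinates), `provenance`,
#'   `n_novel` (novel positions covered).
#' @export
tile_epitopes <- function(region, lengths, mhc_class = c("I", "II"),
                          flank_left = "", flank_right = "") {
  mhc_class <- match.arg(mhc_class)
  seq_region <- region$sequence
  L <- nchar(seq_region)
  fl <- nchar(flank_left)
  context <- paste0(flank_left, seq_region, flank_right)
  novel_lo <- fl + 1L
  novel_hi <- fl + L
  out <- list()
  for (len in sort(unique(as.integer(lengths)))) {
    n_win <- nchar(context) - len + 1L
    if (n_win < 1L) next
    starts <- seq_len(n_win)
    keep <- (starts + len - 1L) >= novel_lo & starts <= novel_hi
    starts <- starts[keep]
    if (!length(starts)) next
    n_novel <- pmin(starts + len - 1L, novel_hi) - pmax(starts, novel_lo) + 1L
    if (!is.null(region$variant_index) && !is.na(region$variant_index)) {
      vpos <- novel_lo + region$variant_index
      keep2 <- starts <= vpos & vpos <= starts + len - 1L
      starts <- starts[keep2]; n_novel <- n_novel[keep2]
      if (!length(starts)) next
    }
    out[[length(out) + 1L]] <- data.frame(
      peptide = substring(context, starts, starts + len - 1L),
      mhc_class = mhc_class, allele = NA_character_,
      protein_id = region$protein_id,
      region_start = region$start, region_end = region$end,
      peptide_start = region$start - fl + starts - 1L,
      provenance = region$provenance, n_novel = n_novel,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(peptide = character(0L), mhc_class = character(0L),
                      allele = character(0L), protein_id = character(0L),
                      region_start = integer(0L), region_end = integer(0L),
                      peptide_start = integer(0L), provenance = character(0L),
                      n_novel = integer(0L), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Build missense-variant peptide windows
#'
#' For each SNV falling inside the coding region of an annotated transcript
#' and changing the encoded amino acid, emits the mutant window
#' `protein[p - flank, p + flank]` (0-based residue `p`, clipped at the
#' protein termini), i.e. 25 residues at the default flank of 12.
#' Synonymous, stop-gain/loss and non-coding variants are skipped with a
#' reason reported via `message()`.
#'
#' @param variants data.frame from [read_vcf_minimal()].
#' @param annotation a `GenomeAnnotation` with CDS-bearing transcripts.
#' @param genome named character vector of chromosome sequences.
#' @param snv_flank residues on each side of the substitution (default 12).
#' @param min_orf_aa passed to [longest_orf()].
#' @return data.frame of regions with `protein_id`, `start`, `end`,
#'   `sequence`, `provenance` (`"SNV"`) and `variant_index` (0-based
#'   position of the substituted residue within the window).
#' @export
snv_peptides <- function(variants, annotation, genome, snv_flank = 12L,
                         min_orf_aa = 30L) {
  out <- list()
  skipped <- c(non_cds = 0L, synonymous = 0L, stop = 0L)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    gpos <- v$pos - 1L  # to 0-based
    hit <- FALSE
    for (tx in annotation$transcripts) {
      if (tx$chrom != v$chrom) next
      tpos <- genomic_to_transcript(tx, gpos)
      if (is.na(tpos)) next
      seqs <- transcript_sequence(tx, genome)
      orf <- longest_orf(seqs, min_orf_aa = min_orf_aa)
      if (is.null(orf)) next
      cds_rel <- tpos - orf$cds[1L]
      if (cds_rel < 0L || cds_rel >= 3L * nchar(orf$protein)) next
      ref_genomic <- substr(genome[[tx$chrom]], v$pos, v$pos)
      if (ref_genomic != v$ref_base)
        stop("variant ", v$chrom, ":", v$pos, " reference base '", v$ref_base,
             "' does not match genome '", ref_genomic, "'")
      p <- cds_rel %/% 3L
      codon_start <- orf$cds[1L] + 3L * p
      codon <- substr(seqs, codon_start + 1L, codon_start + 3L)
      base_tx <- if (tx$strand == "-") revcomp(v$alt_base) else v$alt_base
      mut_codon <- codon
      substr(mut_codon, cds_rel %% 3L + 1L, cds_rel %% 3L + 1L) <- base_tx
      ref_aa <- translate_dna(codon)
      mut_aa <- translate_dna(mut_codon)
      hit <- TRUE
      if (mut_aa == ref_aa) { skipped["synonymous"] <- skipped["synonymous"] + 1L; next }
      if (mut_aa == "*" || ref_aa == "*") { skipped["stop"] <- skipped["stop"] + 1L; next }
      prot <- orf$protein
      substr(prot, p + 1L, p + 1L) <- mut_aa
      lo <- max(0L, p - snv_flank)
      hi <- min(nchar(prot), p + snv_flank + 1L)
      out[[length(out) + 1L]] <- data.frame(
        protein_id = tx$id, start = lo, end = hi,
        sequence = substr(prot, lo + 1L, hi),
        provenance = "SNV", variant_index = p - lo,
        stringsAsFactors = FALSE)
      break
    }
    if (!hit) skipped["non_cds"] <- skipped["non_cds"] + 1L
  }
  if (any(skipped > 0L))
    message("snv_peptides skipped: ",
            paste(names(skipped), skipped, sep = "=", collapse = ", "))
  if (!length(out)) {
    return(data.frame(protein_id = character(0L), start = integer(0L),
                      end = integer(0L), sequence = character(0L),
                      provenance = character(0L), variant_index = integer(0L),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Screen a candidate peptide against the self proteome
#'
#' Computes the longest substring of the peptide occurring anywhere in the
#' reference proteome. The peptide is flagged `self_like` when it occurs
#' verbatim or when the longest matched run reaches its length minus one
#' (a single mismatch from self).
#'
#' @param peptide candidate peptide.
#' @param proteome named character vector of protein sequences.
#' @return list with `max_matched_run` (residues) and `flag` (`"pass"` or
#'   `"self_like"`).
#' @export
self_similarity_screen <- function(peptide, proteome) {
  L <- nchar(peptide)
  if (L < 1L) stop("empty peptide")
  haystack <- paste(proteome, collapse = "\x01")
  run <- 0L
  for (m in seq(L, 1L)) {
    starts <- seq_len(L - m + 1L)
    subs <- unique(substring(peptide, starts, starts + m - 1L))
    if (any(vapply(subs, function(s) grepl(s, haystack, fixed = TRUE),
                   logical(1L)))) { run <- m; break }
  }
  flag <- if (run == L || (L > 1L && run >= L - 1L)) "self_like" else "pass"
  list(max_matched_run = run, flag = flag)
}
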