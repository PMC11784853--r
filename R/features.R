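#' Feature-engineering configuration for presentation prediction
#'
#' Collects the knobs of the peptide featurization used by the
#' presentation classifier: the fixed window length peptides are padded to,
#' the pad symbol, the hydrophobic residue set used for the hydrophobicity
#' fraction, the clipping floor of the percentile-rank transform, and the
#' per-residue encoder.
#'
#' @param hotspot_length fixed number of positions after padding
#'   (default 9, the dominant class-I ligand length; raise it to cover
#'   longer class-II ligands).
#' @param pad_symbol padding residue symbol, encoded as the zero vector.
#' @param hydrophobic_set residues counted as hydrophobic; the default is
#'   the five-residue set A, V, L, M, W.
#' @param rank_floor lower clip for the percentile rank before the -log10
#'   transform.
#' @param encoder `"onehot"`, `"blosum62"`, or `"table"` (per-residue
#'   embedding vectors loaded from a TSV via [read_embedding_table()], so
#'   externally precomputed protein-language-model embeddings can be
#'   plugged in).
#' @param embedding_table matrix (residues x dims) required when
#'   `encoder = "table"`.
#' @return a `FeatureConfig` list.
#' @export
feature_config <- function(hotspot_length = 9L, pad_symbol = "X",
                           hydrophobic_set = c("A", "V", "L", "M", "W"),
                           rank_floor = 0.001,
                           encoder = c("onehot", "blosum62", "table"),
                           embedding_table = NULL) {
  encoder <- match.arg(encoder)
  stopifnot(hotspot_length >= 1L, nchar(pad_symbol) == 1L, rank_floor > 0)
  if (encoder == "table" && is.null(embedding_table))
    stop("encoder 'table' requires an embedding_table")
  structure(list(hotspot_length = as.integer(hotspot_length),
                 pad_symbol = pad_symbol,
                 hydrophobic_set = hydrophobic_set,
                 rank_floor = rank_floor, encoder = encoder,
                 embedding_table = embedding_table),
            class = "FeatureConfig")
}

#' Front-pad a peptide to a fixed length
#'
#' Pad symbols are prepended, so the original peptide is a suffix of the
#' result and C-terminal residues keep their alignment (the convention of
#' aligning shorter peptides to fixed-length binding hotspots).
#'
#' @param peptide peptide sequence.
#' @param target_length length after padding; must be >= the peptide
#'   length (core extraction for longer ligands is the caller's concern).
#' @param pad_symbol padding character.
#' @return padded peptide of exactly `target_length` characters.
#' @export
pad_peptide <- function(peptide, target_length, pad_symbol = "X") {
  n <- nchar(peptide)
  if (n > target_length)
    stop("peptide of length ", n, " exceeds target length ", target_length)
  paste0(strrep(pad_symbol, target_length - n), peptide)
}

#' Hydrophobicity fraction of a peptide
#'
#' The proportion of residues in the hydrophobic set (default A, V, L, M,
#' W). Pad symbols are excluded from both numerator and denominator, so
#' padding never changes the value.
#'
#' @param peptide peptide sequence (possibly padded).
#' @param hydrophobic_set residues counted as hydrophobic.
#' @param pad_symbol padding character to ignore.
#' @return fraction in `[0, 1]`.
#' @export
hydrophobicity <- function(peptide, hydrophobic_set = c("A", "V", "L", "M", "W"),
                           pad_symbol = "X") {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  aa <- aa[aa != pad_symbol]
  if (!length(aa)) stop("empty peptide")
  mean(aa %in% hydrophobic_set)
}

#' Negative-log transform of a percentile binding rank
#'
#' `-log10(max(rank, floor))`: strictly decreasing in the rank, so stronger
#' binders (lower percentile rank) map to larger feature values. Rank 1
#' maps to 0; rank 100 to -2.
#'
#' @param rank_percent percentile rank(s) in `(0, 100]`.
#' @param rank_floor clipping floor.
#' @return numeric feature value(s).
#' @export
rank_transform <- function(rank_percent, rank_floor = 0.001) {
  if (any(is.na(rank_percent)) || any(rank_percent <= 0) ||
      any(rank_percent > 100))
    stop("rank_percent must lie in (0, 100]")
  -log10(pmax(rank_percent, rank_floor))
}

encoder_matrix <- function(cfg) {
  switch(cfg$encoder,
    onehot = {
      m <- diag(length(AA20))
      dimnames(m) <- list(AA20, AA20)
      m
    },
    blosum62 = {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      e$BLOSUM62[AA20, AA20]
    },
    table = cfg$embedding_table
  )
}

#' Encode a padded peptide as a positions-by-dimensions matrix
#'
#' The pad symbol maps to the zero vector; any residue absent from the
#' encoder's alphabet is an error.
#'
#' @param padded_peptide peptide already padded to the hotspot length.
#' @param cfg a [feature_config()].
#' @return numeric matrix, `nchar(padded_peptide)` rows by embedding-dim
#'   columns.
#' @export
encode_peptide <- function(padded_peptide, cfg) {
  enc <- encoder_matrix(cfg)
  aa <- strsplit(padded_peptide, "", fixed = TRUE)[[1L]]
  out <- matrix(0, nrow = length(aa), ncol = ncol(enc))
  known <- aa %in% rownames(enc)
  bad <- !known & aa != cfg$pad_symbol
  if (any(bad)) stop("unknown residue(s): ", paste(unique(aa[bad]), collapse = ", "))
  out[known, ] <- enc[aa[known], , drop = FALSE]
  out
}

# Encode a batch of raw (unpadded) peptides into an n x P x D array.
encode_batch <- function(peptides, cfg) {
  enc <- encoder_matrix(cfg)
  P <- cfg$hotspot_length
  D <- ncol(enc)
  X <- array(0, dim = c(length(peptides), P, D))
  for (i in seq_along(peptides)) {
    X[i, , ] <- encode_peptide(pad_peptide(peptides[i], P, cfg$pad_symbol), cfg)
  }
  X
}

#' Write a per-residue embedding table as TSV
#'
#' Format: a header line `residue<TAB>d1..dK`, then one row per residue.
#'
#' @param table numeric matrix with residue rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(table, path) {
  df <- data.frame(residue = rownames(table), table, check.names = FALSE)
  colnames(df) <- c("residue", paste0("d", seq_len(ncol(table))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-residue embedding table from TSV
#'
#' @param path path written by [write_embedding_table()] (or produced
#'   externally in the same layout).
#' @return numeric matrix with residue rownames.
#' @export
read_embedding_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
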