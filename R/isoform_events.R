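#' Splice-event classes
#'
#' The taxonomy used for isoform comparison. `FSM` (full splice match) means
#' the query's intron chain exactly matches an annotated transcript; the
#' remaining classes describe how a novel isoform differs. Note the intron
#' retention convention used throughout: a novel exon lying entirely inside
#' an annotated intron is classed as intron retention (the exon is made of
#' intronic sequence), alongside the classic retained-intron case.
#'
#' @export
EVENT_CLASSES <- c("FSM", "intergenic", "alt5", "alt3", "intron_retention",
                   "exon_skipping", "mutually_exclusive_exons", "other_novel")

# Priority used to collapse a multi-event isoform to one primary label.
PRIMARY_PRIORITY <- c("intergenic", "intron_retention", "exon_skipping",
                      "mutually_exclusive_exons", "alt5", "alt3", "other_novel")

#' Derive the splice chain of a transcript
#'
#' The splice chain is the ordered set of introns (gaps between consecutive
#' exons) and is the identity key for isoform comparison. Mono-exonic
#' transcripts have an empty chain.
#'
#' @param model a `TranscriptModel`.
#' @return list with `chrom`, `strand` and `introns` (two-column matrix of
#'   0-based half-open intervals), of class `SpliceChain`.
#' @export
splice_chain <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  introns <- if (n > 1L) cbind(start = ex[-n, 2L], end = ex[-1L, 1L])
             else matrix(numeric(0L), ncol = 2L,
                         dimnames = list(NULL, c("start", "end")))
  structure(list(chrom = model$chrom, strand = model$strand, introns = introns),
            class = "SpliceChain")
}

interval_key <- function(m) {
  if (!nrow(m)) return("")
  paste(paste0(m[, 1L], "-", m[, 2L]), collapse = ",")
}

# Identity key used for tumor-specificity: intron chain for spliced
# transcripts; exact exon set for mono-exonic ones (no junctions to match).
chain_key <- function(model) {
  ch <- splice_chain(model)
  if (nrow(ch$introns)) {
    paste(model$chrom, model$strand, "J", interval_key(ch$introns), sep = "|")
  } else {
    paste(model$chrom, model$strand, "M", interval_key(model$exons), sep = "|")
  }
}

overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
contains <- function(s1, e1, s2, e2) s1 <= s2 & e2 <= e1

# rows of `m` (2-col matrix) as "start-end" strings
row_keys <- function(m) if (nrow(m)) paste0(m[, 1L], "-", m[, 2L]) else character(0L)

#' Classify a query isoform against a reference annotation
#'
#' Implements the decision procedure used for isoform-variant
#' categorization:
#' 1. a query whose span overlaps no annotated gene span (strand-agnostic)
#'    is `intergenic`;
#' 2. a query whose splice chain equals an annotated transcript's chain is
#'    `FSM`;
#' 3. otherwise the best-matching annotated transcript is selected (maximal
#'    count of shared introns; ties broken by closest exon count, then
#'    lexicographically smallest id) and events are detected against it:
#'    intron retention (query exon fully contains a reference intron, or a
#'    query exon lies entirely within a reference intron), exon skipping
#'    (query intron fully contains a reference internal exon), mutually
#'    exclusive exons (a query-only and a reference-only exon, mutually
#'    non-overlapping, between the same pair of shared introns), and
#'    alternative 5'/3' splice sites (query intron sharing exactly one
#'    boundary with a reference intron; strand-aware, the donor side is 5').
#'
#' A reference exon that is replaced by a mutually exclusive query exon is
#' not additionally reported as skipped. A multi-event isoform is collapsed
#' to one primary class by the fixed priority intergenic > intron retention
#' > exon skipping > mutually exclusive exons > alt5 > alt3 > other_novel;
#' all detected events are still reported.
#'
#' @param query a `TranscriptModel`.
#' @param annotation a `GenomeAnnotation`.
#' @return list with `primary_class`, `events` (data.frame of class,
#'   start, end), and `matched_reference_id` (`NA` for intergenic).
#' @export
classify_isoform <- function(query, annotation) {
  span <- model_span(query)
  genes <- annotation$genes
  hit <- genes$chrom == query$chrom &
    overlaps(genes$start, genes$end, span[1L], span[2L])
  empty_events <- data.frame(class = character(0L), start = numeric(0L),
                             end = numeric(0L), stringsAsFactors = FALSE)
  if (nrow(genes) && !query$chrom %in% genes$chrom)
    warning("chromosome '", query$chrom,
            "' absent from annotation: treating '", query$id, "' as intergenic")
  if (!any(hit)) {
    return(list(primary_class = "intergenic", events = empty_events,
                matched_reference_id = NA_character_))
  }

  qchain <- splice_chain(query)
  qkeys <- row_keys(qchain$introns)
  cand_ids <- names(annotation$transcripts)[
    vapply(annotation$transcripts, function(tx) {
      sp <- model_span(tx)
      tx$chrom == query$chrom && overlaps(sp[1L], sp[2L], span[1L], span[2L])
    }, logical(1L))]

  for (id in cand_ids) {
    tx <- annotation$transcripts[[id]]
    if (tx$strand != query$strand) next
    if (identical(interval_key(splice_chain(tx)$introns), interval_key(qchain$introns))) {
      # mono-exonic chains are both empty; require genuine overlap (ensured
      # by candidate selection) so FSM is meaningful for them too
      return(list(primary_class = "FSM", events = empty_events,
                  matched_reference_id = id))
    }
  }

  # best-matching reference transcript
  score <- vapply(cand_ids, function(id) {
    rk <- row_keys(splice_chain(annotation$transcripts[[id]])$introns)
    sum(qkeys %in% rk)
  }, numeric(1L))
  exdiff <- vapply(cand_ids, function(id)
    abs(nrow(annotation$transcripts[[id]]$exons) - nrow(query$exons)), numeric(1L))
  ord <- order(-score, exdiff, cand_ids)
  ref <- annotation$transcripts[[cand_ids[ord[1L]]]]
  ref_id <- ref$id

  qex <- query$exons; rex <- ref$exons
  qint <- qchain$introns; rint <- splice_chain(ref)$introns
  rkeys <- row_keys(rint)
  shared_int <- rint[rkeys %in% qkeys, , drop = FALSE]

  ev <- list()
  add <- function(class, start, end)
    ev[[length(ev) + 1L]] <<- data.frame(class = class, start = start, end = end,
                                         stringsAsFactors = FALSE)

  # --- mutually exclusive exons (detected first so the replaced reference
  # exon is not also counted as skipped) ---
  q_only <- qex[!row_keys(qex) %in% row_keys(rex), , drop = FALSE]
  r_only <- rex[!row_keys(rex) %in% row_keys(qex), , drop = FALSE]
  mxe_ref_rows <- character(0L)
  mxe_query_rows <- character(0L)
  if (nrow(shared_int) && nrow(q_only) == 1L && nrow(r_only) == 1L &&
      !overlaps(q_only[1L, 1L], q_only[1L, 2L], r_only[1L, 1L], r_only[1L, 2L])) {
    lo <- min(q_only[1L, 1L], r_only[1L, 1L])
    hi <- max(q_only[1L, 2L], r_only[1L, 2L])
    left <- shared_int[shared_int[, 2L] <= lo, , drop = FALSE]
    right <- shared_int[shared_int[, 1L] >= hi, , drop = FALSE]
    if (nrow(left) && nrow(right)) {
      add("mutually_exclusive_exons", q_only[1L, 1L], q_only[1L, 2L])
      mxe_ref_rows <- row_keys(r_only)
      mxe_query_rows <- row_keys(q_only)
    }
  }

  # --- intron retention (both conventions); an exon that replaces a
  # mutually exclusive reference exon is not additionally an intronic exon ---
  for (i in seq_len(nrow(qex))) {
    within_ref_intron <- any(contains(rint[, 1L], rint[, 2L], qex[i, 1L], qex[i, 2L])) &&
      !row_keys(qex)[i] %in% mxe_query_rows
    if (nrow(rint) && within_ref_intron)
      add("intron_retention", qex[i, 1L], qex[i, 2L])
    retained <- rint[contains(qex[i, 1L], qex[i, 2L], rint[, 1L], rint[, 2L]), ,
                     drop = FALSE]
    for (j in seq_len(nrow(retained)))
      add("intron_retention", retained[j, 1L], retained[j, 2L])
  }

  # --- exon skipping: reference internal exon inside a query intron ---
  if (nrow(rex) > 2L && nrow(qint)) {
    internal <- rex[-c(1L, nrow(rex)), , drop = FALSE]
    for (i in seq_len(nrow(internal))) {
      if (row_keys(internal)[i] %in% mxe_ref_rows) next
      if (any(contains(qint[, 1L], qint[, 2L], internal[i, 1L], internal[i, 2L])))
        add("exon_skipping", internal[i, 1L], internal[i, 2L])
    }
  }

  # --- alternative 5'/3' splice sites ---
  novel_qint <- qint[!qkeys %in% rkeys, , drop = FALSE]
  for (i in seq_len(nrow(novel_qint))) {
    qs <- novel_qint[i, 1L]; qe <- novel_qint[i, 2L]
    for (j in seq_len(nrow(rint))) {
      share_start <- rint[j, 1L] == qs
      share_end <- rint[j, 2L] == qe
      if (xor(share_start, share_end)) {
        # the changed boundary determines the event; donor = 5' side
        changed_start <- !share_start
        cls <- if (query$strand == "+") {
          if (changed_start) "alt5" else "alt3"
        } else {
          if (changed_start) "alt3" else "alt5"
        }
        add(cls, qs, qe)
      }
    }
  }

  events <- if (length(ev)) do.call(rbind, ev) else empty_events
  events <- unique(events)
  present <- intersect(PRIMARY_PRIORITY, events$class)
  primary <- if (length(present)) present[1L] else "other_novel"
  list(primary_class = primary, events = events, matched_reference_id = ref_id)
}

# Is a mono-exonic model entirely inside an intron of some annotated
# transcript? Mono-exonic isoforms only qualify as tumor-specific variants
# when intergenic or fully intronic, so fragments of annotated exons (a
# common long-read degradation artifact) are not called.
mono_fully_intronic <- function(model, annotation) {
  ex <- model$exons
  for (tx in annotation$transcripts) {
    if (tx$chrom != model$chrom) next
    rint <- splice_chain(tx)$introns
    if (nrow(rint) &&
        any(contains(rint[, 1L], rint[, 2L], ex[1L, 1L], ex[1L, 2L])))
      return(TRUE)
  }
  FALSE
}

#' Call tumor-specific transcript variants (LSTVs)
#'
#' A tumor transcript is called an LSTV when (i) its read support passes
#' `min_support` (transcripts with unknown support are kept), (ii) its
#' classification against the annotation is not FSM, and (iii) its splice
#' chain (exact junction set; for mono-exonic transcripts the exact exon
#' interval set) occurs in neither the matched-normal isoform set nor the
#' annotation. Terminal exon start/end wobble therefore does not defeat
#' tumor-specificity for spliced isoforms. Mono-exonic transcripts qualify
#' only when intergenic or fully intronic.
#'
#' @param tumor,normal lists of `TranscriptModel` objects.
#' @param annotation a `GenomeAnnotation`.
#' @param min_support minimum full-length read support (default 2, dropping
#'   singleton isoforms).
#' @return list with `records` (list of `LstvRecord`: transcript, primary
#'   class, events, matched reference, support), `class_counts` (named
#'   integer vector over all event classes), and `table` (one row per LSTV).
#' @export
find_lstvs <- function(tumor, normal, annotation, min_support = 2L) {
  if (!length(tumor)) {
    warning("empty tumor transcript set")
    tumor <- list()
  }
  known <- unique(c(vapply(normal, chain_key, character(1L)),
                    vapply(annotation$transcripts, chain_key, character(1L))))
  records <- list()
  for (m in tumor) {
    if (!is.na(m$support) && m$support < min_support) next
    if (chain_key(m) %in% known) next
    cls <- classify_isoform(m, annotation)
    if (cls$primary_class == "FSM") next
    if (nrow(m$exons) == 1L && cls$primary_class != "intergenic" &&
        !mono_fully_intronic(m, annotation)) next
    records[[length(records) + 1L]] <- structure(
      list(transcript = m, primary_class = cls$primary_class,
           events = cls$events,
           matched_reference_id = cls$matched_reference_id,
           support = m$support),
      class = "LstvRecord")
  }
  if (length(records)) {
    ord <- order(vapply(records, function(r) r$transcript$chrom, character(1L)),
                 vapply(records, function(r) model_span(r$transcript)[1L], numeric(1L)),
                 vapply(records, function(r) r$transcript$id, character(1L)))
    records <- records[ord]
  }
  counts <- setNames(integer(length(EVENT_CLASSES)), EVENT_CLASSES)
  for (r in records) counts[r$primary_class] <- counts[r$primary_class] + 1L
  counts <- counts[setdiff(EVENT_CLASSES, "FSM")]
  list(records = records, class_counts = counts, table = lstv_table(records))
}

#' Tabulate LSTV records
#'
#' @param records list of `LstvRecord` objects (from [find_lstvs()]).
#' @return data.frame with one row per LSTV.
#' @export
lstv_table <- function(records) {
  if (!length(records)) {
    return(data.frame(id = character(0L), chrom = character(0L),
                      strand = character(0L), start = numeric(0L),
                      end = numeric(0L), primary_class = character(0L),
                      events = character(0L), matched_reference = character(0L),
                      support = integer(0L), stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, lapply(records, function(r) {
    sp <- model_span(r$transcript)
    data.frame(
      id = r$transcript$id, chrom = r$transcript$chrom,
      strand = r$transcript$strand, start = sp[1L], end = sp[2L],
      primary_class = r$primary_class,
      events = paste(sprintf("%s:%d-%d", r$events$class,
                             as.integer(r$events$start),
                             as.integer(r$events$end)), collapse = ";"),
      matched_reference = r$matched_reference_id %||% NA_character_,
      support = r$support, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab
}

#' Export LSTV event intervals as BED
#'
#' @param records list of `LstvRecord` objects.
#' @param path output path (BED 6: chrom, start, end, name, score, strand).
#' @return `path`, invisibly.
#' @export
write_lstv_bed <- function(records, path) {
  rows <- character(0L)
  for (r in records) {
    ev <- r$events
    if (!nrow(ev)) {
      sp <- model_span(r$transcript)
      ev <- data.frame(class = r$primary_class, start = sp[1L], end = sp[2L])
    }
    rows <- c(rows, sprintf("%s\t%d\t%d\t%s|%s\t%d\t%s",
                            r$transcript$chrom, as.integer(ev$start),
                            as.integer(ev$end), r$transcript$id, ev$class,
                            ifelse(is.na(r$support), 0L, as.integer(r$support)),
                            r$transcript$strand))
  }
  writeLines(rows, path)
  invisible(path)
}
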