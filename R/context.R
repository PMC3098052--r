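# Genomic-context partition of ORFs against the annotation, and the
# 3' start-rescue rule for false 5' overlaps.
#
# Context rules:
#   annotated          a gene feature on the same strand shares the ORF's
#                      stop-codon position (same 3' boundary and frame);
#                      annotations frequently differ in their chosen start
#                      codon, so exact-interval matching would misclassify
#                      them as overlapping.
#   entity_overlapping any feature of any kind overlaps >= 1 bp of the
#                      ORF's genomic span (stop codon included),
#                      strand-blind, and the ORF is not annotated.
#   intergenic         otherwise: the ORF shares no genomic space with
#                      any annotated entity.

# Stop-inclusive genomic span of each ORF, 0-based half-open. For plus
# ORFs the stop codon sits at [end, end+3); for minus ORFs at
# [start-3, start).
orf_full_span <- function(orfs) {
  lo <- ifelse(orfs$strand == "+", orfs$start, orfs$start - 3L)
  hi <- ifelse(orfs$strand == "+", orfs$end + 3L, orfs$end)
  data.frame(lo = as.integer(lo), hi = as.integer(hi))
}

# 3' boundary of the stop codon in forward coordinates: the coordinate a
# same-strand annotation (written stop-inclusive, the GFF/GenBank CDS
# convention) must share for the ORF to count as annotated. A second
# boundary without the stop codon is accepted for stop-exclusive
# annotations.
orf_stop_boundaries <- function(orfs) {
  with_stop <- ifelse(orfs$strand == "+", orfs$end + 3L, orfs$start - 3L)
  without <- ifelse(orfs$strand == "+", orfs$end, orfs$start)
  cbind(with_stop = as.integer(with_stop), without = as.integer(without))
}

#' Assign genomic context labels to ORFs
#'
#' Partitions ORFs into `annotated`, `entity_overlapping` and
#' `intergenic` against the feature annotation of their replicon. Every
#' ORF receives exactly one label.
#'
#' @param orfs ORF data frame from [find_maximal_orfs()] (any mix of
#'   replicons).
#' @param features Feature data frame (see [read_features()]).
#' @return `orfs` with the `context` column filled in.
#' @export
assign_context <- function(orfs, features) {
  if (nrow(orfs) == 0L) return(orfs)
  orfs$context <- "intergenic"
  span <- orf_full_span(orfs)
  bnd <- orf_stop_boundaries(orfs)
  for (rep_id in unique(orfs$replicon_id)) {
    oi <- which(orfs$replicon_id == rep_id)
    fi <- which(features$replicon_id == rep_id)
    if (!length(fi)) next
    f <- features[fi, , drop = FALSE]
    # >= 1 bp overlap, any feature kind, strand-blind
    oq <- IRanges::IRanges(start = span$lo[oi] + 1L, end = span$hi[oi])
    fq <- IRanges::IRanges(start = f$start + 1L, end = f$end)
    ov <- IRanges::countOverlaps(oq, fq, minoverlap = 1L) > 0L
    orfs$context[oi[ov]] <- "entity_overlapping"
    # annotated: same strand gene feature sharing the stop boundary
    g <- f[f$kind == "gene", , drop = FALSE]
    if (nrow(g)) {
      for (k in seq_along(oi)) {
        j <- oi[k]
        if (orfs$strand[j] == "+") {
          hit <- any(g$strand == "+" &
                       (g$end == bnd[j, "with_stop"] |
                        g$end == bnd[j, "without"]))
        } else {
          hit <- any(g$strand == "-" &
                       (g$start == bnd[j, "with_stop"] |
                        g$start == bnd[j, "without"]))
        }
        if (hit) orfs$context[j] <- "annotated"
      }
    }
  }
  orfs
}

#' Rescue a falsely overlapping ORF by moving its start 3'-wards
#'
#' An ORF classified `entity_overlapping` only because its default
#' (maximal, 5'-most) start codon creates the overlap is re-anchored at
#' the 5'-most in-frame start codon that removes all feature overlap
#' while keeping the coding length at or above `min_len`. ORFs whose
#' overlap cannot be removed this way (e.g. overlap at the 3' end) are
#' returned unchanged. The operation is idempotent.
#'
#' @param orfs ORF data frame with contexts assigned.
#' @param features Feature data frame.
#' @param min_len Minimum coding length in bp.
#' @param start_codons Accepted start codons.
#' @return `orfs` with rescued rows re-coordinated, re-translated and
#'   re-classified, plus a logical `rescued` column.
#' @export
rescue_start <- function(orfs, features, min_len = 99L,
                         start_codons = ORF_START_CODONS) {
  if (!"rescued" %in% names(orfs))
    orfs$rescued <- logical(nrow(orfs))
  cand <- which(orfs$context == "entity_overlapping")
  if (!length(cand)) return(orfs)
  for (j in cand) {
    f <- features[features$replicon_id == orfs$replicon_id[j], ,
                  drop = FALSE]
    if (!nrow(f)) next
    fq <- IRanges::IRanges(start = f$start + 1L, end = f$end)
    L <- orfs$length_nt[j]
    nt <- orfs$nt_seq[j]
    # candidate trims: in-frame start codons downstream of the original
    if (L - min_len < 3L) next
    trims <- seq.int(3L, L - min_len, by = 3L)
    codons <- substring(nt, trims + 1L, trims + 3L)
    trims <- trims[codons %in% start_codons]
    ok_trim <- NA_integer_
    for (tr in trims) {
      if (orfs$strand[j] == "+") {
        lo <- orfs$start[j] + tr; hi <- orfs$end[j] + 3L
      } else {
        lo <- orfs$start[j] - 3L; hi <- orfs$end[j] - tr
      }
      nov <- IRanges::countOverlaps(
        IRanges::IRanges(start = lo + 1L, end = hi), fq,
        minoverlap = 1L)
      if (nov == 0L) { ok_trim <- tr; break }   # 5'-most qualifying start
    }
    if (is.na(ok_trim)) next
    if (orfs$strand[j] == "+") orfs$start[j] <- orfs$start[j] + ok_trim
    else orfs$end[j] <- orfs$end[j] - ok_trim
    orfs$nt_seq[j] <- substring(nt, ok_trim + 1L, L)
    orfs$aa_seq[j] <- translate_cds(orfs$nt_seq[j],
                                    start_codons = start_codons)
    orfs$length_nt[j] <- L - ok_trim
    orfs$length_aa[j] <- (L - ok_trim) %/% 3L
    orfs$orf_id[j] <- orf_identifier(orfs$replicon_id[j], orfs$strand[j],
                                     orfs$start[j], orfs$end[j])
    orfs$rescued[j] <- TRUE
  }
  # re-classify rescued ORFs
  if (any(orfs$rescued)) {
    idx <- which(orfs$rescued)
    reclass <- assign_context(orfs[idx, , drop = FALSE], features)
    orfs$context[idx] <- reclass$context
  }
  orfs
}

#' Export ORF contexts to TSV
#'
#' One row per ORF with 1-based inclusive coordinates, the context label
#' and the rescue flag.
#'
#' @param orfs ORF data frame with contexts (and optionally `rescued`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_context_tsv <- function(orfs, path) {
  g <- to_gff_coords(orfs$start, orfs$end)
  tab <- data.frame(orf_id = orfs$orf_id, replicon_id = orfs$replicon_id,
                    start = g$start, end = g$end, strand = orfs$strand,
                    context = orfs$context,
                    rescued = orfs$rescued %||% FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
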