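# Alignment-hit container and ingestion of external all-vs-all reports.
#
# A hit set is a plain data frame; the derived columns I (average percent
# identity with respect to query and subject lengths), cov_q/cov_s
# (percent span coverage) and avg_cov are always computed here so that
# every producer (built-in aligner or external report) satisfies the same
# contract.

#' Construct an alignment-hit table
#'
#' Derives the average percent identity `I`, the per-sequence coverages
#' and their mean from raw alignment quantities, and validates the
#' invariants of the hit contract.
#'
#' @param query_id,subject_id Character vectors of ORF identifiers.
#' @param e_value Numeric vector of alignment e-values.
#' @param n_identities Integer vector: identical residues in the alignment.
#' @param q_span,s_span Aligned residue counts on query and subject
#'   (span = end - start + 1, gaps excluded).
#' @param q_len,s_len Full query/subject lengths in amino acids.
#' @return A data frame of class `alignment_hits` with the input columns
#'   plus `I`, `cov_q`, `cov_s`, `avg_cov` (all percentages in (0, 100]).
#' @export
alignment_hits <- function(query_id, subject_id, e_value, n_identities,
                           q_span, s_span, q_len, s_len) {
  n <- length(query_id)
  stopifnot(length(subject_id) == n, length(e_value) == n,
            length(n_identities) == n, length(q_span) == n,
            length(s_span) == n, length(q_len) == n, length(s_len) == n)
  hits <- data.frame(
    query_id = as.character(query_id),
    subject_id = as.character(subject_id),
    e_value = as.numeric(e_value),
    n_identities = as.integer(n_identities),
    q_span = as.integer(q_span), s_span = as.integer(s_span),
    q_len = as.integer(q_len), s_len = as.integer(s_len),
    stringsAsFactors = FALSE)
  hits$I <- (100 * hits$n_identities / hits$q_len +
             100 * hits$n_identities / hits$s_len) / 2
  hits$cov_q <- 100 * hits$q_span / hits$q_len
  hits$cov_s <- 100 * hits$s_span / hits$s_len
  hits$avg_cov <- (hits$cov_q + hits$cov_s) / 2
  if (n > 0L) {
    if (any(hits$q_len <= 0L | hits$s_len <= 0L))
      stop("alignment hits: non-positive sequence length")
    if (any(hits$I <= 0 | hits$I > 100))
      stop("alignment hits: average percent identity outside (0, 100]")
    if (any(hits$q_span <= 0L | hits$s_span <= 0L))
      stop("alignment hits: non-positive aligned span")
  }
  class(hits) <- c("alignment_hits", "data.frame")
  hits
}

empty_hits <- function() {
  alignment_hits(character(0), character(0), numeric(0), integer(0),
                 integer(0), integer(0), integer(0), integer(0))
}

#' Read a 12-column tabular alignment report
#'
#' Ingests the common tab-separated all-vs-all protein search dialect
#' (query, subject, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore), e.g. the output of an external
#' BLASTP-style tool run with tabular output. Identity counts are
#' recovered as `round(pident * length / 100)`; spans as
#' `end - start + 1`. Query and subject lengths are not part of the
#' dialect and must be supplied as named integer maps.
#'
#' @param path Path to the report.
#' @param q_lens,s_lens Named integer vectors mapping query/subject ids to
#'   their amino-acid lengths.
#' @return An `alignment_hits` data frame (see [alignment_hits()]).
#' @export
read_alignment_report <- function(path, q_lens, s_lens) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L) return(empty_hits())
  if (ncol(raw) < 12L)
    stop("alignment report must have 12 tab-separated columns, found ",
         ncol(raw))
  names(raw)[1:12] <- c("query", "subject", "pident", "length", "mismatch",
                        "gapopen", "qstart", "qend", "sstart", "send",
                        "evalue", "bitscore")
  num_cols <- c("pident", "length", "qstart", "qend", "sstart", "send",
                "evalue")
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    if (anyNA(v))
      stop("non-numeric value in alignment report column '", cl, "' (row ",
           which(is.na(v))[1], ")")
    raw[[cl]] <- v
  }
  unknown_q <- setdiff(unique(raw$query), names(q_lens))
  if (length(unknown_q))
    stop("alignment report: unknown query id(s): ",
         paste(utils::head(unknown_q, 5), collapse = ", "))
  unknown_s <- setdiff(unique(raw$subject), names(s_lens))
  if (length(unknown_s))
    stop("alignment report: unknown subject id(s): ",
         paste(utils::head(unknown_s, 5), collapse = ", "))
  alignment_hits(
    query_id = raw$query,
    subject_id = raw$subject,
    e_value = raw$evalue,
    n_identities = as.integer(round(raw$pident * raw$length / 100)),
    q_span = as.integer(raw$qend - raw$qstart + 1),
    s_span = as.integer(raw$send - raw$sstart + 1),
    q_len = as.integer(q_lens[raw$query]),
    s_len = as.integer(s_lens[raw$subject]))
}

#' Write hits in the 12-column tabular dialect
#'
#' Round-trip companion of [read_alignment_report()]; mismatch and gapopen
#' counts are not tracked internally and are written as 0, start/end pairs
#' as 1..span.
#'
#' @param hits An `alignment_hits` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_report <- function(hits, path) {
  pident <- ifelse(hits$q_span > 0, 100 * hits$n_identities /
                     pmax(hits$q_span, hits$s_span), 0)
  tab <- data.frame(hits$query_id, hits$subject_id,
                    sprintf("%.3f", pident),
                    pmax(hits$q_span, hits$s_span), 0L, 0L,
                    1L, hits$q_span, 1L, hits$s_span,
                    format(hits$e_value, digits = 3),
                    0, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
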