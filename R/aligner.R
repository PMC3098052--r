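# All-vs-all protein alignment: a built-in exact local aligner for
# desk-scale runs and tests, plus the shared hit filter. Real-scale runs
# ingest an external search tool's tabular report instead
# (read_alignment_report) and trust its e-values.

ALIGN_GAP_OPEN <- 11
ALIGN_GAP_EXTEND <- 1
# Gapped Karlin-Altschul constants for BLOSUM62 with gap 11/1; fixed so
# that the built-in backend is reproducible.
ALIGN_LAMBDA <- 0.267
ALIGN_K <- 0.041

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

check_protein <- function(x, alphabet) {
  bad <- setdiff(unique(strsplit(x, "", fixed = TRUE)[[1]]), alphabet)
  if (length(bad))
    stop("non-amino-acid symbol(s) in protein sequence: ",
         paste(bad, collapse = ", "))
}

#' Best local alignment of two protein sequences
#'
#' Smith-Waterman local alignment under affine gap penalties (BLOSUM62,
#' gap open 11, extend 1). The e-value follows the Karlin-Altschul form
#' `K * m * n * exp(-lambda * S)` with `m` the query length and `n` the
#' total database size in residues.
#'
#' @param query_aa,subject_aa Protein strings.
#' @param query_id,subject_id Identifiers recorded in the hit.
#' @param db_size_aa Database size in amino acids for the e-value.
#' @param gap_open,gap_extend Affine gap penalties (a gap of length k
#'   costs `gap_open + k * gap_extend`).
#' @param lambda,K Karlin-Altschul constants.
#' @return A one-row `alignment_hits` data frame, or `NULL` when no
#'   positive-scoring local alignment exists.
#' @export
local_align <- function(query_aa, subject_aa,
                        query_id = "query", subject_id = "subject",
                        db_size_aa = nchar(subject_aa),
                        gap_open = ALIGN_GAP_OPEN,
                        gap_extend = ALIGN_GAP_EXTEND,
                        lambda = ALIGN_LAMBDA, K = ALIGN_K) {
  stopifnot(nzchar(query_aa), nzchar(subject_aa))
  mat <- blosum62()
  check_protein(query_aa, rownames(mat))
  check_protein(subject_aa, rownames(mat))
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(subject_aa),
    subject = Biostrings::AAString(query_aa),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  s <- Biostrings::score(aln)
  if (s <= 0) return(NULL)
  hit_from_alignment(aln, s, query_id, subject_id,
                     nchar(query_aa), nchar(subject_aa),
                     db_size_aa, lambda, K)
}

hit_from_alignment <- function(aln, s, query_id, subject_id,
                               q_len, s_len, db_size_aa, lambda, K) {
  # pattern holds the subject, subject slot holds the query (see callers)
  q_span <- BiocGenerics::end(Biostrings::subject(aln)) -
    BiocGenerics::start(Biostrings::subject(aln)) + 1L
  s_span <- BiocGenerics::end(Biostrings::pattern(aln)) -
    BiocGenerics::start(Biostrings::pattern(aln)) + 1L
  alignment_hits(
    query_id = query_id, subject_id = subject_id,
    e_value = K * q_len * db_size_aa * exp(-lambda * s),
    n_identities = Biostrings::nmatch(aln),
    q_span = q_span, s_span = s_span,
    q_len = q_len, s_len = s_len)
}

#' Align every query against every subject
#'
#' Runs the built-in local aligner for each query ORF against the whole
#' subject set (one vectorised call per query) and returns the
#' positive-scoring hits. `db_size_aa` defaults to the total residue
#' count of the subject set, mirroring how a database search tool sizes
#' its e-values.
#'
#' @param queries,subjects ORF data frames (need `orf_id`, `aa_seq`).
#' @param db_size_aa Database size in residues.
#' @param gap_open,gap_extend,lambda,K See [local_align()].
#' @return An `alignment_hits` data frame (self-hits included; use
#'   [filter_hits()] downstream).
#' @export
align_all <- function(queries, subjects,
                      db_size_aa = sum(nchar(subjects$aa_seq)),
                      gap_open = ALIGN_GAP_OPEN,
                      gap_extend = ALIGN_GAP_EXTEND,
                      lambda = ALIGN_LAMBDA, K = ALIGN_K) {
  if (nrow(queries) == 0L || nrow(subjects) == 0L) return(empty_hits())
  mat <- blosum62()
  subj_set <- Biostrings::AAStringSet(subjects$aa_seq)
  out <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = subj_set, subject = queries$aa_seq[i],
      type = "local", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend)
    s <- Biostrings::score(aln)
    # positive score with at least one identical residue (a hit without
    # identities carries no I and cannot survive the screens anyway)
    pos <- which(s > 0 & Biostrings::nmatch(aln) > 0L)
    if (!length(pos)) next
    a <- aln[pos]
    q_len <- nchar(queries$aa_seq[i])
    q_span <- BiocGenerics::end(Biostrings::subject(a)) -
      BiocGenerics::start(Biostrings::subject(a)) + 1L
    s_span <- BiocGenerics::end(Biostrings::pattern(a)) -
      BiocGenerics::start(Biostrings::pattern(a)) + 1L
    out[[i]] <- alignment_hits(
      query_id = rep(queries$orf_id[i], length(pos)),
      subject_id = subjects$orf_id[pos],
      e_value = K * q_len * db_size_aa * exp(-lambda * s[pos]),
      n_identities = Biostrings::nmatch(a),
      q_span = q_span, s_span = s_span,
      q_len = rep(q_len, length(pos)),
      s_len = nchar(subjects$aa_seq[pos]))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_hits())
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  class(res) <- c("alignment_hits", "data.frame")
  res
}

#' Screen alignment hits
#'
#' Applies the screening used throughout the pipeline: e-value at most
#' `max_evalue` (inclusive), coverage of *both* query and subject at
#' least `min_cov` percent, self-hits removed, and at most
#' `max_hits_per_query` hits kept per query, ranked by ascending e-value
#' (ties broken by descending average percent identity, then by subject
#' id). The ordering rule is total, so the output is deterministic.
#'
#' @param hits An `alignment_hits` data frame.
#' @param max_evalue Inclusive e-value cutoff.
#' @param min_cov Minimum percent coverage required on query and subject.
#' @param max_hits_per_query Cap on retained hits per query.
#' @return The surviving hits, ordered by query then rank.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, min_cov = 80,
                        max_hits_per_query = 1000L) {
  keep <- hits$e_value <= max_evalue &
    hits$cov_q >= min_cov & hits$cov_s >= min_cov &
    hits$query_id != hits$subject_id
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) {
    rownames(hits) <- NULL
    return(hits)
  }
  ord <- order(hits$query_id, hits$e_value, -hits$I, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(hits)), hits$query_id,
                     FUN = seq_along)
  hits <- hits[rank <= max_hits_per_query, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
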