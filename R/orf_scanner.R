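# Maximal-ORF enumeration and translation.
#
# An ORF is anchored at an in-frame stop codon; among all start codons
# upstream of that stop with no intervening in-frame stop, the furthest
# upstream (5'-most) one is chosen, making the ORF maximal. The stored
# coding interval excludes the stop codon, so the default 99 bp minimum
# corresponds exactly to proteins of >= 33 aa.

ORF_START_CODONS <- c("ATG", "GTG", "TTG")
ORF_STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a coding sequence
#'
#' Standard genetic code (the bacterial code is identical for all sense
#' codons); the initiator codon is rendered as M when it is one of the
#' accepted starts (ATG/GTG/TTG). Codons containing N (or other
#' ambiguity) translate to X. The input must be a complete coding
#' sequence without its stop codon; an internal stop is an error.
#'
#' @param nt_seq DNA string with length divisible by 3.
#' @param start_codons Codons rendered as M in initiator position.
#' @return The protein sequence as a character scalar.
#' @export
translate_cds <- function(nt_seq, start_codons = ORF_START_CODONS) {
  stopifnot(is.character(nt_seq), length(nt_seq) == 1L)
  nt_seq <- toupper(nt_seq)
  if (nchar(nt_seq) %% 3L != 0L)
    stop("coding sequence length not divisible by 3")
  if (nchar(nt_seq) == 0L) return("")
  codons <- split_codons(nt_seq)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"   # codons containing N or other ambiguity
  if (any(aa == "*"))
    stop("internal stop codon at codon ", which(aa == "*")[1])
  if (codons[1] %in% start_codons) aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Enumerate all maximal ORFs of a replicon
#'
#' Scans both strands in all three frames and reports, for every
#' (strand, frame, stop codon), the single maximal ORF of coding length
#' at least `min_len`. Coordinates are 0-based half-open on the forward
#' strand and exclude the stop codon. On circular replicons the scan
#' wraps the origin; an origin-spanning ORF is reported once, with
#' `end = start + length` possibly exceeding the replicon length
#' (positions are taken modulo the length).
#'
#' ORFs truncated by a linear replicon end (no stop codon inside the
#' sequence) are not reported: without a stop they are not maximal ORFs.
#'
#' @param replicon A [replicon()] object.
#' @param min_len Minimum coding length in bp (positive multiple of 3).
#' @param start_codons,stop_codons Codon sets used by the scan.
#' @return A data frame with one row per ORF: `orf_id`, `replicon_id`,
#'   `start`, `end`, `strand`, `nt_seq`, `aa_seq`, `length_nt`,
#'   `length_aa`, `context` (NA until assigned).
#' @export
find_maximal_orfs <- function(replicon, min_len = 99L,
                              start_codons = ORF_START_CODONS,
                              stop_codons = ORF_STOP_CODONS) {
  stopifnot(inherits(replicon, "replicon"))
  min_len <- as.integer(min_len)
  if (is.na(min_len) || min_len <= 0L || min_len %% 3L != 0L)
    stop("min_len must be a positive multiple of 3")
  n <- nchar(replicon$sequence)
  circular <- replicon$topology == "circular"
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") replicon$sequence else revcomp(replicon$sequence)
    orfs <- scan_strand_orfs(s, n, circular, min_len,
                             start_codons, stop_codons)
    if (nrow(orfs) == 0L) next
    # strand-local [a, b) -> forward-strand coordinates
    if (strand == "+") {
      fstart <- orfs$a
      fend <- orfs$a + orfs$len
    } else {
      bm <- orfs$b %% n
      fstart <- ifelse(bm == 0L, 0L, n - bm)
      fend <- fstart + orfs$len
    }
    rows[[strand]] <- data.frame(
      orf_id = orf_identifier(replicon$replicon_id, strand, fstart, fend),
      replicon_id = replicon$replicon_id,
      start = as.integer(fstart), end = as.integer(fend),
      strand = strand,
      nt_seq = orfs$nt, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty_orfs())
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$aa_seq <- vapply(out$nt_seq, translate_cds, character(1),
                       start_codons = start_codons, USE.NAMES = FALSE)
  out$length_nt <- nchar(out$nt_seq)
  out$length_aa <- nchar(out$aa_seq)
  out$context <- NA_character_
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_orfs <- function() {
  data.frame(orf_id = character(0), replicon_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             nt_seq = character(0), aa_seq = character(0),
             length_nt = integer(0), length_aa = integer(0),
             context = character(0), stringsAsFactors = FALSE)
}

# Core scan of one strand. `s` is the strand sequence (already
# reverse-complemented for the minus strand), `n` the replicon length.
# Returns strand-local 0-based half-open coding intervals [a, b) (b may
# exceed n for origin-spanning ORFs on circular replicons) plus the coding
# sequence.
scan_strand_orfs <- function(s, n, circular, min_len,
                             start_codons, stop_codons) {
  # circular: scan two copies plus two bases so that codons wrapping the
  # origin (positions n-2, n-1) are enumerable in the second copy
  scan <- if (circular) paste0(s, s, substring(s, 1L, 2L)) else s
  N <- nchar(scan)
  res <- list()
  for (f in 0:2) {
    if (N - f < 3L) next
    cs <- seq.int(f + 1L, N - 2L, by = 3L)  # 1-based codon start positions
    cod <- substring(scan, cs, cs + 2L)
    stop_i <- which(cod %in% stop_codons)
    start_i <- which(cod %in% start_codons)
    if (!length(stop_i) || !length(start_i)) next
    # first stop strictly after each start (codon-index space); since it is
    # the *first* stop downstream, there is no intervening stop.
    pos <- findInterval(start_i, stop_i) + 1L
    has <- pos <= length(stop_i)
    st <- start_i[has]
    sp <- stop_i[pos[has]]
    if (!length(st)) next
    # maximality: the 5'-most start per stop
    first_start <- tapply(st, sp, min)
    sp_u <- as.integer(names(first_start))
    st_u <- as.integer(first_start)
    len <- (sp_u - st_u) * 3L
    keep <- len >= min_len
    if (circular) {
      # each circular stop position appears exactly once with its codon
      # start in (n, 2n]; cap coding length at n - 3 (stop needs room)
      keep <- keep & (cs[sp_u] - 1L) >= n & (cs[sp_u] - 1L) < 2L * n &
        len <= n - 3L
    }
    if (!any(keep)) next
    a <- cs[st_u[keep]] - 1L          # 0-based coding start in scan coords
    b <- cs[sp_u[keep]] - 1L          # 0-based exclusive coding end
    nt <- substring(scan, a + 1L, b)
    if (circular) {
      shift <- ifelse(a >= n, n, 0L)
      a <- a - shift; b <- b - shift
    }
    res[[length(res) + 1L]] <- data.frame(
      a = a, b = b, len = b - a, nt = nt, stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(a = integer(0), b = integer(0), len = integer(0),
                      nt = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  # a circular replicon whose length is a multiple of 3 yields each stop
  # twice across the doubled scan only in the same frame; the position
  # filter above keeps one copy, but ORFs can still coincide when n %% 3
  # != 0 frames alias -- deduplicate defensively on the interval.
  out[!duplicated(out[, c("a", "b")]), , drop = FALSE]
}

#' Export ORF sequences to FASTA
#'
#' Writes the nucleotide or amino-acid sequences of an ORF table with the
#' deterministic `replicon|strand|start-end` identifiers as headers.
#'
#' @param orfs ORF data frame from [find_maximal_orfs()].
#' @param path Output path.
#' @param what `"aa"` or `"nt"`.
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(orfs, path, what = c("aa", "nt")) {
  what <- match.arg(what)
  seqs <- if (what == "aa") orfs$aa_seq else orfs$nt_seq
  set <- if (what == "aa") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  names(set) <- orfs$orf_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
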