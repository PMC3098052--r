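# Supporting analyses: GC content, GC3, the MUM-index genome distance and
# the flank ultra-conservation check.

#' GC content of a DNA string
#'
#' Fraction of G+C among unambiguous bases; N is excluded from both
#' numerator and denominator.
#'
#' @param seq DNA string.
#' @return Fraction in [0, 1].
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  gc <- nchar(gsub("[^GC]", "", seq))
  acgt <- nchar(gsub("[^ACGT]", "", seq))
  if (acgt == 0L) return(NA_real_)
  gc / acgt
}

#' GC3: GC fraction at the third codon position
#'
#' Fraction of codons whose third base is G or C. A trailing stop codon,
#' if supplied, is excluded.
#'
#' @param cds DNA string of complete codons.
#' @param stop_codons Codon set recognised (and dropped) as a trailing
#'   stop.
#' @return Fraction in [0, 1].
#' @export
gc3 <- function(cds, stop_codons = ORF_STOP_CODONS) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("coding sequence length not divisible by 3")
  codons <- split_codons(cds)
  if (length(codons) > 1L && codons[length(codons)] %in% stop_codons)
    codons <- codons[-length(codons)]
  third <- substring(codons, 3L, 3L)
  mean(third %in% c("G", "C"))
}

#' MUM-index distance between two sequences
#'
#' Genome distance in [0, 1] based on maximal exact matches that are
#' unique in both sequences (MUMs) of length at least `min_mum_len`,
#' with both strands of `seq_b` considered. The matches are tiled
#' greedily (longest first, no overlap in either sequence) and the
#' distance is `1 - Lmum / mean(len_a, len_b)` where `Lmum` is the total
#' tiled match length, clamped to [0, 1]. Identical sequences score 0;
#' unrelated sequences score near 1.
#'
#' @param seq_a,seq_b DNA strings.
#' @param min_mum_len Minimum MUM length in bp.
#' @return Distance in [0, 1].
#' @export
mumi <- function(seq_a, seq_b, min_mum_len = 19L) {
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  na <- nchar(seq_a); nb <- nchar(seq_b)
  mums <- find_mums(seq_a, seq_b, min_mum_len)
  if (nrow(mums) == 0L) return(1)
  # greedy non-overlapping tiling, longest first (ties by position)
  mums <- mums[order(-mums$len, mums$start_a, mums$start_b), ,
               drop = FALSE]
  used_a <- logical(na); used_b <- logical(nb)
  lmum <- 0L
  for (i in seq_len(nrow(mums))) {
    ia <- (mums$start_a[i] + 1L):(mums$start_a[i] + mums$len[i])
    ib <- (mums$start_b[i] + 1L):(mums$start_b[i] + mums$len[i])
    if (any(used_a[ia]) || any(used_b[ib])) next
    used_a[ia] <- TRUE; used_b[ib] <- TRUE
    lmum <- lmum + mums$len[i]
  }
  d <- 1 - lmum / mean(c(na, nb))
  min(max(d, 0), 1)
}

# Maximal exact matches unique in both sequences, both strands of b.
# Anchor-based: unique shared k-mers (k = min length) are chained along
# diagonals and extended to maximality, then the full match string is
# verified to occur exactly once in a and once across both strands of b.
# Coordinates are 0-based on the forward strands of a and b.
find_mums <- function(a, b, k) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k)
    return(data.frame(start_a = integer(0), start_b = integer(0),
                      len = integer(0)))
  b_rev <- revcomp(b)
  kmers <- function(x) {
    n <- nchar(x)
    substring(x, 1:(n - k + 1L), k:n)
  }
  ka <- kmers(a); kb_f <- kmers(b); kb_r <- kmers(b_rev)
  cnt_a <- table(ka)
  cnt_b <- table(c(kb_f, kb_r))
  uniq <- names(cnt_a)[cnt_a == 1L]
  uniq <- uniq[cnt_b[uniq] == 1L & !is.na(cnt_b[uniq])]
  uniq <- uniq[!grepl("N", uniq, fixed = TRUE)]
  count_occ <- function(pat, x) {
    length(gregexpr(pat, x, fixed = TRUE)[[1]][
      gregexpr(pat, x, fixed = TRUE)[[1]] > 0])
  }
  res <- list()
  for (strand in c("+", "-")) {
    bs <- if (strand == "+") b else b_rev
    kb <- if (strand == "+") kb_f else kb_r
    pa <- match(uniq, ka); pb <- match(uniq, kb)
    ok <- !is.na(pa) & !is.na(pb)
    if (!any(ok)) next
    pa <- pa[ok] - 1L; pb <- pb[ok] - 1L   # 0-based anchor starts
    d <- pa - pb
    o <- order(d, pa)
    pa <- pa[o]; pb <- pb[o]; dd <- d[o]
    run_start <- c(TRUE, diff(pa) != 1L | diff(dd) != 0L)
    run_id <- cumsum(run_start)
    for (r in unique(run_id)) {
      sel <- run_id == r
      a0 <- min(pa[sel]); b0 <- min(pb[sel])
      len <- max(pa[sel]) - a0 + k
      # extend to maximality
      while (a0 > 0L && b0 > 0L &&
             substring(a, a0, a0) == substring(bs, b0, b0)) {
        a0 <- a0 - 1L; b0 <- b0 - 1L; len <- len + 1L
      }
      while (a0 + len < na && b0 + len < nchar(bs) &&
             substring(a, a0 + len + 1L, a0 + len + 1L) ==
             substring(bs, b0 + len + 1L, b0 + len + 1L)) {
        len <- len + 1L
      }
      if (len < k) next
      m <- substring(a, a0 + 1L, a0 + len)
      if (count_occ(m, a) != 1L) next
      if (count_occ(m, b) + count_occ(m, b_rev) != 1L) next
      # map b coordinates back to the forward strand
      sb <- if (strand == "+") b0 else nb - b0 - len
      res[[length(res) + 1L]] <- c(a0, sb, len)
    }
  }
  if (!length(res))
    return(data.frame(start_a = integer(0), start_b = integer(0),
                      len = integer(0)))
  m <- do.call(rbind, res)
  out <- data.frame(start_a = m[, 1], start_b = m[, 2], len = m[, 3])
  out[!duplicated(out), , drop = FALSE]
}

#' Average MUMi distance within a missing-gene group
#'
#' One representative replicon is chosen per taxonomic family present in
#' the group (deterministically, the lexicographically smallest replicon
#' id) and the MUM-index distance is averaged over all unordered family
#' pairs.
#'
#' @param member_replicons Character vector: replicon of each group
#'   member.
#' @param replicons Named list of [replicon()] objects.
#' @param taxonomy Taxonomy data frame.
#' @param min_mum_len Minimum MUM length in bp.
#' @return Mean pairwise distance; requires at least two families.
#' @export
group_mumi <- function(member_replicons, replicons, taxonomy,
                       min_mum_len = 19L) {
  fams <- family_of(member_replicons, taxonomy)
  reps <- vapply(split(member_replicons, fams),
                 function(x) sort(unique(x))[1], character(1))
  if (length(reps) < 2L)
    stop("group MUMi requires members from at least two families")
  pairs <- utils::combn(unname(reps), 2L)
  mean(apply(pairs, 2L, function(p)
    mumi(replicons[[p[1]]]$sequence, replicons[[p[2]]]$sequence,
         min_mum_len)))
}

# Flanking sequence of one ORF in gene orientation; truncated at replicon
# ends. `side` is relative to the coding direction; the stop codon is
# part of the gene, so the downstream flank starts after it.
orf_flank <- function(orf, replicons, flank, side = c("up", "down")) {
  side <- match.arg(side)
  seq <- replicons[[orf$replicon_id]]$sequence
  n <- nchar(seq)
  if (orf$strand == "+") {
    if (side == "up") {
      lo <- max(0L, orf$start - flank); hi <- orf$start
      substring(seq, lo + 1L, hi)
    } else {
      lo <- orf$end + 3L; hi <- min(n, orf$end + 3L + flank)
      if (lo >= hi) "" else substring(seq, lo + 1L, hi)
    }
  } else {
    if (side == "up") {
      lo <- orf$end; hi <- min(n, orf$end + flank)
      if (lo >= hi) "" else revcomp(substring(seq, lo + 1L, hi))
    } else {
      lo <- max(0L, orf$start - 3L - flank); hi <- orf$start - 3L
      if (lo >= hi) "" else revcomp(substring(seq, lo + 1L, hi))
    }
  }
}

#' Ultra-conservation check for a missing-gene group
#'
#' TRUE iff the upstream 30 bp flanks of all members are identical to
#' each other AND the downstream flanks are identical to each other,
#' flanks taken in gene orientation (reverse-strand members are
#' reverse-complemented). Exact flank identity is equivalent to perfect
#' conservation of the flanking columns in a multiple alignment.
#'
#' @param members ORF data frame rows of the group members.
#' @param replicons Named list of [replicon()] objects.
#' @param flank Flank width in bp.
#' @return Logical scalar.
#' @export
ultra_conserved <- function(members, replicons, flank = 30L) {
  stopifnot(nrow(members) >= 1L)
  up <- character(nrow(members)); down <- character(nrow(members))
  for (i in seq_len(nrow(members))) {
    up[i] <- orf_flank(members[i, ], replicons, flank, "up")
    down[i] <- orf_flank(members[i, ], replicons, flank, "down")
  }
  length(unique(up)) == 1L && length(unique(down)) == 1L
}
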