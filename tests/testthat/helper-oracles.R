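# Independent oracles used across the suite. Each is written from the
# definition of the quantity it checks, not from the package code paths.

oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

# --- six-frame brute-force ORF enumeration ---------------------------------
# Walks codon-by-codon from every start-codon position to the first
# in-frame stop, then keeps per stop the longest (5'-most) ORF. Returns
# strand-local tuples; comparison with the scanner is done on strand-
# tagged sequence multisets plus coordinate re-extraction.
oracle_orfs <- function(seq, min_len = 99L, circular = FALSE,
                        starts = c("ATG", "GTG", "TTG"),
                        stops = c("TAA", "TAG", "TGA")) {
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    ss <- if (circular) paste0(s, s) else s
    N <- nchar(ss)
    codon_at <- substring(ss, seq_len(N), seq_len(N) + 2L)
    is_start <- codon_at %in% starts
    is_stop <- codon_at %in% stops
    found <- list()
    for (p in seq_len(n)) {
      if (!is_start[p]) next
      q <- p
      hit <- NA_integer_
      while (q + 2L <= N) {
        if (is_stop[q]) { hit <- q; break }
        q <- q + 3L
      }
      if (is.na(hit)) next                       # truncated: not maximal
      len <- hit - p
      if (len < min_len) next
      if (circular && len > n - 3L) next
      stop_key <- if (circular) (hit - 1L) %% n else hit - 1L
      found[[length(found) + 1L]] <-
        list(start = p - 1L, stop_key = stop_key, len = len,
             nt = substring(ss, p, hit - 1L))
    }
    if (length(found)) {
      keys <- vapply(found, `[[`, numeric(1), "stop_key")
      for (k in unique(keys)) {
        grp <- found[keys == k]
        lens <- vapply(grp, `[[`, numeric(1), "len")
        best <- grp[[which.max(lens)]]
        out[[length(out) + 1L]] <-
          data.frame(strand = strand, stop_key = k, len = best$len,
                     nt = best$nt, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(strand = character(0), stop_key = numeric(0),
                      len = numeric(0), nt = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$strand, res$stop_key), , drop = FALSE]
}

# sorted strand-tagged sequence multiset for set comparison
orf_signature <- function(strands, nts) {
  sort(paste(strands, nts, sep = ":"))
}

# re-extract the nucleotide sequence of an ORF row straight from the
# forward genome sequence (independent arithmetic, modular for wrapped
# circular ORFs)
oracle_extract <- function(seq, start0, end0, strand) {
  n <- nchar(seq)
  pos <- (seq.int(start0, end0 - 1L) %% n) + 1L
  fwd <- paste(substring(seq, pos, pos), collapse = "")
  if (strand == "+") fwd else oracle_revcomp(fwd)
}

# --- independent codon table ----------------------------------------------
ORACLE_CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(nt) {
  cods <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  paste(ORACLE_CODON_TABLE[cods], collapse = "")
}

# --- textbook affine-gap local alignment DP --------------------------------
# Three-state Smith-Waterman; a gap of length k costs open + k * ext
# (matching the package's scoring convention). Quadratic, loops only.
oracle_sw_score <- function(a, b, mat, open = 11, ext = 1) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(va); nb <- length(vb)
  NEG <- -1e9
  M <- matrix(0, na + 1L, nb + 1L)
  X <- matrix(NEG, na + 1L, nb + 1L)  # gap in b (a residue vs gap)
  Y <- matrix(NEG, na + 1L, nb + 1L)  # gap in a
  best <- 0
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      sub <- mat[va[i], vb[j]]
      M[i + 1L, j + 1L] <- max(0,
                               M[i, j] + sub,
                               X[i, j] + sub,
                               Y[i, j] + sub)
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                               X[i, j + 1L] - ext)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                               Y[i + 1L, j] - ext)
      best <- max(best, M[i + 1L, j + 1L])
    }
  }
  best
}

# --- breadth-first-search connected components -----------------------------
oracle_components <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (NROW(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- stats::setNames(logical(length(nodes)), nodes)
  comps <- list()
  for (v in nodes) {
    if (seen[v]) next
    queue <- v; seen[v] <- TRUE; comp <- character(0)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      comp <- c(comp, u)
      for (w in adj[[u]]) if (!seen[w]) { seen[w] <- TRUE
        queue <- c(queue, w) }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, `[[`, character(1), 1L))]
}

# --- brute-force MUM search -------------------------------------------------
# Match-matrix diagonal runs give every maximal exact match; uniqueness is
# verified by substring counting. Returns forward-strand coordinates.
oracle_mums <- function(a, b, k = 19L) {
  count_occ <- function(pat, x) {
    hits <- gregexpr(pat, x, fixed = TRUE)[[1]]
    sum(hits > 0)
  }
  na <- nchar(a); nb <- nchar(b)
  b_rev <- oracle_revcomp(b)
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  res <- list()
  for (strand in c("+", "-")) {
    bs <- if (strand == "+") b else b_rev
    vb <- strsplit(bs, "", fixed = TRUE)[[1]]
    eq <- outer(va, vb, "==")
    for (d in -(nb - 1L):(na - 1L)) {
      ii <- seq.int(max(1L, 1L + d), min(na, nb + d))
      if (!length(ii)) next
      jj <- ii - d
      runs <- rle(eq[cbind(ii, jj)])
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (r in which(runs$values & runs$lengths >= k)) {
        a0 <- ii[starts[r]] - 1L
        b0 <- jj[starts[r]] - 1L
        len <- runs$lengths[r]
        m <- substring(a, a0 + 1L, a0 + len)
        if (count_occ(m, a) != 1L) next
        if (count_occ(m, b) + count_occ(m, b_rev) != 1L) next
        sb <- if (strand == "+") b0 else nb - b0 - len
        res[[length(res) + 1L]] <- c(a0, sb, len)
      }
    }
  }
  if (!length(res))
    return(data.frame(start_a = integer(0), start_b = integer(0),
                      len = integer(0)))
  m <- unique(do.call(rbind, res))
  data.frame(start_a = m[, 1], start_b = m[, 2], len = m[, 3])
}

# --- small constructors for hit fixtures -----------------------------------
# Build a one-row hit table with a prescribed average percent identity I
# and average coverage (identical q/s lengths keep the arithmetic exact).
make_hit <- function(query, subject, I, avg_cov = 100, e_value = 1e-10,
                     len = 100L) {
  n_id <- as.integer(round(I * len / 100))
  span <- as.integer(round(avg_cov * len / 100))
  alignment_hits(query, subject, e_value, n_id, span, span, len, len)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"), n,
               replace = TRUE), collapse = "")
}
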