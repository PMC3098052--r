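# Maximal-ORF enumeration against a six-frame brute-force oracle, and
# translation against an independently written codon table.

test_that("translation follows the standard code with M initiators", {
  expect_equal(translate_cds("ATGAAA"), "MK")
  expect_equal(translate_cds("GTGAAA"), "MK")  # initiator GTG -> M
  expect_equal(translate_cds("TTGAAA"), "MK")  # initiator TTG -> M
  expect_equal(translate_cds("CTGAAA"), "LK")  # CTG is not a start here
  expect_equal(translate_cds("ATGANA"), "MX")  # N codon -> X
  expect_error(translate_cds("ATGTAAAAA"), "stop")
  expect_error(translate_cds("ATGA"), "divisible")

  set.seed(21)
  for (i in 1:5) {
    nt <- paste(sample(setdiff(names(ORACLE_CODON_TABLE),
                               c("TAA", "TAG", "TGA")), 300,
                       replace = TRUE), collapse = "")
    got <- translate_cds(nt)
    want <- oracle_translate(nt)
    # initiator convention only affects the first residue
    substring(want, 1, 1) <-
      if (substring(nt, 1, 3) %in% c("ATG", "GTG", "TTG")) "M"
      else substring(want, 1, 1)
    expect_equal(got, want)
  }
})

test_that("stated scanner examples hold", {
  # no start codon anywhere -> no ORFs
  r <- replicon("r", strrep("CCA", 40))
  expect_equal(nrow(find_maximal_orfs(r)), 0L)

  # minimal 99 bp ORF: ATG + 32 lysine codons + TAA
  r2 <- replicon("r2", paste0("ATG", strrep("AAA", 32), "TAA"))
  o <- find_maximal_orfs(r2)
  expect_equal(nrow(o), 1L)
  expect_equal(o$start, 0L)
  expect_equal(o$end, 99L)
  expect_equal(o$strand, "+")
  expect_equal(o$aa_seq, paste0("M", strrep("K", 32)))

  # two in-frame starts before one stop: anchored at the 5'-most
  r3 <- replicon("r3", paste0("ATGAAAATG", strrep("GCA", 31), "TAA"))
  o3 <- find_maximal_orfs(r3)
  expect_equal(nrow(o3), 1L)
  expect_equal(o3$start, 0L)

  # 96 bp of coding is below the 99 bp minimum
  r4 <- replicon("r4", paste0("ATG", strrep("AAA", 31), "TAA"))
  expect_equal(nrow(find_maximal_orfs(r4)), 0L)

  expect_error(find_maximal_orfs(r2, min_len = 100), "multiple of 3")
  expect_error(find_maximal_orfs(r2, min_len = -3), "multiple of 3")
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(31)
  for (i in 1:12) {
    circular <- i > 6
    seq <- random_dna(2000, gc = sample(c(0.35, 0.5, 0.65), 1))
    r <- replicon(sprintf("t%02d", i), seq,
                  topology = if (circular) "circular" else "linear")
    got <- find_maximal_orfs(r)
    want <- oracle_orfs(seq, circular = circular)
    expect_equal(orf_signature(got$strand, got$nt_seq),
                 orf_signature(want$strand, want$nt))
    # coordinates are self-consistent: independent re-extraction from the
    # forward sequence reproduces nt_seq, start/stop codon structure
    for (j in seq_len(nrow(got))) {
      nt <- oracle_extract(seq, got$start[j], got$end[j], got$strand[j])
      expect_equal(nt, got$nt_seq[j])
      expect_true(substring(nt, 1, 3) %in% c("ATG", "GTG", "TTG"))
      stop_nt <- if (got$strand[j] == "+")
        oracle_extract(seq, got$end[j], got$end[j] + 3L, "+")
      else oracle_extract(seq, got$start[j] - 3L, got$start[j], "-")
      expect_true(stop_nt %in% c("TAA", "TAG", "TGA"))
    }
  }
})

test_that("strand symmetry: reverse ORFs equal forward ORFs of revcomp", {
  set.seed(37)
  for (i in 1:5) {
    seq <- random_dna(1500)
    a <- find_maximal_orfs(replicon("a", seq))
    b <- find_maximal_orfs(replicon("b", oracle_revcomp(seq)))
    n <- nchar(seq)
    a_minus <- a[a$strand == "-", ]
    b_plus <- b[b$strand == "+", ]
    # reflection: [s, e) on the minus strand of S is [n-e, n-s) forward
    # on revcomp(S)
    expect_setequal(
      paste(n - a_minus$end, n - a_minus$start, a_minus$nt_seq),
      paste(b_plus$start, b_plus$end, b_plus$nt_seq))
  }
})

test_that("no two ORFs share strand, frame and stop position", {
  set.seed(41)
  for (topo in c("linear", "circular")) {
    seq <- random_dna(3000)
    o <- find_maximal_orfs(replicon("r", seq, topology = topo))
    stop_pos <- ifelse(o$strand == "+", o$end %% nchar(seq),
                       o$start %% nchar(seq))
    expect_false(any(duplicated(paste(o$strand, stop_pos))))
  }
})

test_that("circular replicons report origin-spanning ORFs exactly once", {
  set.seed(43)
  # build: [tail of ORF | spacer with no starts | head of ORF]
  coding <- paste0("ATG", strrep("GAA", 40), "TAA")   # 126 bp
  spacer <- strrep("CCT", 60)
  head_len <- 50L
  seq <- paste0(substring(coding, head_len + 1, nchar(coding)), spacer,
                substring(coding, 1, head_len))
  n <- nchar(seq)
  lin <- find_maximal_orfs(replicon("lin", seq, topology = "linear"))
  circ <- find_maximal_orfs(replicon("circ", seq, topology = "circular"))
  expect_false(substring(coding, 1, 123) %in% lin$nt_seq)
  wrapped <- circ[circ$nt_seq == substring(coding, 1, 123), ]
  expect_equal(nrow(wrapped), 1L)
  expect_equal(wrapped$start, n - head_len)
  expect_equal(wrapped$end, n - head_len + 123L)
  expect_true(wrapped$end > n)
})
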