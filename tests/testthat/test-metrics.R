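# GC content, GC3, MUM-index distance and ultra-conservation.

test_that("GC content counts G+C over unambiguous bases", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ATGC"), 0.5)
  # N excluded from numerator and denominator
  expect_equal(gc_content("ATGCNN"), 0.5)
  set.seed(121)
  s <- random_dna(1000, gc = 0.64)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  expect_equal(gc_content(s), sum(v %in% c("G", "C")) / length(v))
})

test_that("GC3 is the GC fraction of third codon positions", {
  expect_equal(gc3("ATGGCG"), 1.0)
  expect_equal(gc3("ATAGCA"), 0.0)
  expect_error(gc3("ATGG"), "divisible")
  # a trailing stop codon is excluded
  expect_equal(gc3("ATGGCGTAA"), 1.0)
  set.seed(123)
  for (i in 1:5) {
    cds <- paste(sample(names(ORACLE_CODON_TABLE), 100, replace = TRUE),
                 collapse = "")
    thirds <- substring(cds, seq(3, 300, 3), seq(3, 300, 3))
    if (substring(cds, 298, 300) %in% c("TAA", "TAG", "TGA"))
      thirds <- thirds[-100]
    expect_equal(gc3(cds), mean(thirds %in% c("G", "C")))
    # property: gc3 equals gc_content of the concatenated third bases
    stopfree <- paste0(paste(sample(setdiff(names(ORACLE_CODON_TABLE),
                                            c("TAA", "TAG", "TGA")), 50,
                                    replace = TRUE), collapse = ""))
    expect_equal(gc3(stopfree),
                 gc_content(paste(substring(stopfree, seq(3, 150, 3),
                                            seq(3, 150, 3)),
                                  collapse = "")))
  }
})

test_that("MUMi closed forms: identity, symmetry, unrelatedness", {
  set.seed(131)
  a <- random_dna(800)
  expect_equal(mumi(a, a), 0)
  b <- random_dna(800)
  expect_equal(mumi(a, b), mumi(b, a), tolerance = 1e-12)
  expect_gt(mumi(a, b), 0.9)   # unrelated random sequences
  # a shared segment reduces the distance proportionally
  shared <- random_dna(200)
  a2 <- paste0(random_dna(300), shared, random_dna(300))
  b2 <- paste0(random_dna(100), shared, random_dna(500))
  expect_lt(mumi(a2, b2), mumi(a, b))
  # matches on the reverse strand are found
  b3 <- paste0(random_dna(100), oracle_revcomp(shared), random_dna(100))
  expect_lt(mumi(a2, b3), 0.9)
})

test_that("MUM discovery agrees with the brute-force oracle", {
  set.seed(137)
  for (i in 1:6) {
    shared1 <- random_dna(60)
    shared2 <- random_dna(35)
    a <- paste0(random_dna(120), shared1, random_dna(80), shared2,
                random_dna(100))
    b <- paste0(random_dna(60), shared2, random_dna(150),
                if (i %% 2 == 0) shared1 else oracle_revcomp(shared1),
                random_dna(40))
    got <- orfmiss:::find_mums(a, b, 19L)
    want <- oracle_mums(a, b, 19L)
    o <- function(d) {
      d <- d[order(d$start_a, d$start_b, d$len), ]
      rownames(d) <- NULL
      d
    }
    expect_equal(o(got), o(want), info = sprintf("case %d", i))
  }
})

test_that("group MUMi averages representative family pairs", {
  set.seed(139)
  base <- random_dna(600)
  mutate_at <- function(s, rate) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    k <- which(runif(length(v)) < rate)
    v[k] <- sample(c("A", "C", "G", "T"), length(k), replace = TRUE)
    paste(v, collapse = "")
  }
  reps <- list(rA = replicon("rA", base),
               rB = replicon("rB", mutate_at(base, 0.03)),
               rC = replicon("rC", mutate_at(base, 0.35)))
  tax <- data.frame(replicon_id = c("rA", "rB", "rC"), order = "O1",
                    family = c("F1", "F2", "F3"),
                    genus = c("G1", "G2", "G3"), stringsAsFactors = FALSE)
  # two families: the single pairwise distance
  expect_equal(group_mumi(c("rA", "rB"), reps, tax),
               mumi(base, reps$rB$sequence))
  # three families: mean of the three pairs
  d3 <- group_mumi(c("rA", "rB", "rC"), reps, tax)
  expect_equal(d3, mean(c(mumi(reps$rA$sequence, reps$rB$sequence),
                          mumi(reps$rA$sequence, reps$rC$sequence),
                          mumi(reps$rB$sequence, reps$rC$sequence))))
  # controlled divergence is recovered in the ordering
  expect_lt(mumi(reps$rA$sequence, reps$rB$sequence),
            mumi(reps$rA$sequence, reps$rC$sequence))
})

test_that("ultra-conservation is exact flank identity in orientation", {
  set.seed(149)
  up <- random_dna(30); down <- random_dna(30)
  coding <- paste0("ATG", strrep("GCT", 33))
  insert <- paste0(up, coding, "TAA", down)
  mk_rep <- function(id, insert_fwd, minus = FALSE) {
    s <- paste0(random_dna(150),
                if (minus) oracle_revcomp(insert_fwd) else insert_fwd,
                random_dna(150))
    replicon(id, s)
  }
  reps <- list(p1 = mk_rep("p1", insert),
               p2 = mk_rep("p2", insert),
               m1 = mk_rep("m1", insert, minus = TRUE))
  L <- nchar(coding)
  members <- data.frame(
    orf_id = c("a", "b", "c"),
    replicon_id = c("p1", "p2", "m1"),
    start = c(180L, 180L, 150L + 33L),
    end = c(180L + L, 180L + L, 150L + 33L + L),
    strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  expect_true(ultra_conserved(members, reps))
  # order of members is irrelevant
  expect_true(ultra_conserved(members[c(3, 1, 2), ], reps))
  # one mismatching flank base breaks it
  s <- reps$p2$sequence
  pos <- 160L
  substring(s, pos, pos) <- if (substring(s, pos, pos) == "A") "C" else "A"
  reps2 <- reps; reps2$p2 <- replicon("p2", s)
  expect_false(ultra_conserved(members, reps2))
})
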