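# Stage-1 labelling: hit partition under the family rule and the 20-point
# coverage-differential rule.

# shared toy universe: replicons r1 (family F1), r2 (F2), r3 (F2)
s1_taxonomy <- data.frame(
  replicon_id = c("r1", "r2", "r3"),
  order = "O1", family = c("F1", "F2", "F2"),
  genus = c("G1", "G2", "G3"), stringsAsFactors = FALSE)

s1_orf_info <- data.frame(
  orf_id = c("q", "int_f1", "int_f2", "int_f2b", "gene_f1", "gene_f2",
             "ent_f2"),
  replicon_id = c("r1", "r1", "r2", "r3", "r1", "r2", "r2"),
  context = c("intergenic", "intergenic", "intergenic", "intergenic",
              "annotated", "annotated", "entity_overlapping"),
  stringsAsFactors = FALSE)

s1_query <- data.frame(orf_id = "q", replicon_id = "r1",
                       stringsAsFactors = FALSE)

test_that("hit partition applies the family rule to intergenic only", {
  # all intergenic hits are to the query's own family: no support
  h_own <- make_hit("q", "int_f1", I = 90)
  p <- partition_hits("q", h_own, s1_orf_info, s1_taxonomy)
  expect_equal(nrow(p$intergenic), 0L)
  expect_equal(nrow(p$same_family), 1L)

  # an annotated-gene hit in the same genome still counts as a gene hit
  h_gene <- make_hit("q", "gene_f1", I = 90)
  p2 <- partition_hits("q", h_gene, s1_orf_info, s1_taxonomy)
  expect_equal(nrow(p2$gene), 1L)

  # mixed hit list: partition sizes sum to the input size
  hits <- rbind(make_hit("q", "int_f1", I = 90),
                make_hit("q", "int_f2", I = 85),
                make_hit("q", "gene_f2", I = 70),
                make_hit("q", "ent_f2", I = 60))
  p3 <- partition_hits("q", hits, s1_orf_info, s1_taxonomy)
  expect_equal(nrow(p3$intergenic) + nrow(p3$same_family) +
                 nrow(p3$gene) + nrow(p3$entity), nrow(hits))
  expect_equal(p3$intergenic$subject_id, "int_f2")

  # a subject with no taxonomy record is a hard error
  bad_info <- rbind(s1_orf_info,
                    data.frame(orf_id = "mystery", replicon_id = "rX",
                               context = "intergenic"))
  expect_error(
    partition_hits("q", make_hit("q", "mystery", I = 90), bad_info,
                   s1_taxonomy), "rX")
})

test_that("labels follow the stated precedence and differential rule", {
  label_of <- function(hits, diff = 20) {
    p <- partition_hits("q", hits, s1_orf_info, s1_taxonomy)
    stage1_label("q", p, diff)$label
  }
  # only cross-family intergenic hits -> potentially missing
  expect_equal(label_of(make_hit("q", "int_f2", I = 90)),
               "potentially_missing")
  # top intergenic avg_cov 95 vs gene hit 80: gap 15 < 20 -> absent
  expect_equal(label_of(rbind(
    make_hit("q", "int_f2", I = 90, avg_cov = 95),
    make_hit("q", "gene_f2", I = 70, avg_cov = 80))),
    "absent_annotation")
  # gap exactly 20 qualifies (<= top - 20)
  expect_equal(label_of(rbind(
    make_hit("q", "int_f2", I = 90, avg_cov = 100),
    make_hit("q", "gene_f2", I = 70, avg_cov = 80))),
    "potentially_missing")
  # entity hit alone -> genomic artifact
  expect_equal(label_of(make_hit("q", "ent_f2", I = 70)),
               "genomic_artifact")
  # no hits at all -> unclassified
  expect_equal(label_of(empty_hits()), "unclassified")
  # only same-family intergenic hits -> unclassified
  expect_equal(label_of(make_hit("q", "int_f1", I = 95)), "unclassified")
})

test_that("differential rule matches arithmetic on a coverage grid", {
  for (top_cov in seq(84, 100, by = 4)) {
    for (gene_cov in seq(60, 100, by = 5)) {
      if (gene_cov > top_cov) next
      hits <- rbind(
        make_hit("q", "int_f2", I = 90, avg_cov = top_cov,
                 e_value = 1e-30),
        make_hit("q", "gene_f2", I = 70, avg_cov = gene_cov))
      p <- partition_hits("q", hits, s1_orf_info, s1_taxonomy)
      got <- stage1_label("q", p, 20)$label
      want <- if (gene_cov <= top_cov - 20) "potentially_missing"
              else "absent_annotation"
      expect_equal(got, want,
                   info = sprintf("top=%d gene=%d", top_cov, gene_cov))
    }
  }
})

test_that("the differential compares against the lowest-e-value hit", {
  # a *stronger-covering* but higher-e-value intergenic hit must not be
  # the comparison point: top-scoring = lowest e-value
  hits <- rbind(
    make_hit("q", "int_f2", I = 90, avg_cov = 85, e_value = 1e-40),
    make_hit("q", "int_f2b", I = 80, avg_cov = 100, e_value = 1e-10),
    make_hit("q", "gene_f2", I = 70, avg_cov = 70))
  p <- partition_hits("q", hits, s1_orf_info, s1_taxonomy)
  # top is the 1e-40 hit with avg_cov 85; 70 > 85 - 20 -> not missing
  expect_equal(stage1_label("q", p, 20)$label, "absent_annotation")
})

test_that("stage-1 labels are exclusive, exhaustive and stable", {
  set.seed(81)
  subjects <- s1_orf_info$orf_id[-1]
  queries <- s1_query
  for (rep in 1:25) {
    n <- sample(0:5, 1)
    hits <- if (n == 0) empty_hits() else
      do.call(rbind, lapply(seq_len(n), function(i)
        make_hit("q", sample(subjects, 1), I = sample(50:100, 1),
                 avg_cov = sample(80:100, 1),
                 e_value = 10^-sample(6:40, 1))))
    out <- stage1_classify(queries, hits, s1_orf_info, s1_taxonomy)
    lab <- out$classifications$label
    expect_length(lab, 1L)
    expect_true(lab %in% c("potentially_missing", "absent_annotation",
                           "genomic_artifact", "unclassified"))
    # removing same-family intergenic hits never changes the label
    p <- partition_hits("q", hits, s1_orf_info, s1_taxonomy)
    pruned <- rbind(p$intergenic, p$gene, p$entity)
    out2 <- stage1_classify(queries, pruned, s1_orf_info, s1_taxonomy)
    expect_equal(out2$classifications$label, lab)
    # adding a gene hit can demote missing but never promote absent
    if (lab == "absent_annotation") {
      extra <- rbind(hits, make_hit("q", "gene_f2", I = 99,
                                    avg_cov = 100, e_value = 1e-50))
      out3 <- stage1_classify(queries, extra, s1_orf_info, s1_taxonomy)
      expect_true(out3$classifications$label != "potentially_missing")
    }
  }
})
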