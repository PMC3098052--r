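# Stage 1: label each intergenic query ORF from its filtered hits plus
# the replicon taxonomy.
#
# Labels, evaluated in order:
#   (a) potentially_missing  cross-family intergenic support exists AND
#       every hit to an annotated gene or entity-overlapping ORF has an
#       average percent coverage at least `diff_threshold` percentage
#       points below the top-scoring intergenic hit's;
#   (b) absent_annotation    else, if any hit to an annotated gene
#       (no phylogenetic requirement);
#   (c) genomic_artifact     else, if any hit to an entity-overlapping
#       ORF (no phylogenetic requirement);
#   (d) unclassified         otherwise (no hits, or only same-family
#       intergenic hits).

#' Partition a query's hits by subject context and taxonomy
#'
#' Hits to intergenic subjects only support a missing classification when
#' query and subject come from two different taxonomic families;
#' same-family intergenic hits are segregated and never support it. Hits
#' to annotated or entity-overlapping subjects carry no family
#' requirement.
#'
#' @param query_id Identifier of the query ORF.
#' @param hits Filtered `alignment_hits` rows for this query.
#' @param orf_info Data frame mapping `orf_id` to `replicon_id` and
#'   `context` for every subject.
#' @param taxonomy Taxonomy data frame (see [read_taxonomy()]).
#' @return A list of hit subsets: `intergenic` (cross-family),
#'   `same_family`, `gene`, `entity`.
#' @export
partition_hits <- function(query_id, hits, orf_info, taxonomy) {
  hits <- hits[hits$query_id == query_id, , drop = FALSE]
  idx <- match(hits$subject_id, orf_info$orf_id)
  if (anyNA(idx))
    stop("subject ORF(s) without context: ",
         paste(utils::head(hits$subject_id[is.na(idx)], 5), collapse = ", "))
  s_ctx <- orf_info$context[idx]
  s_fam <- family_of(orf_info$replicon_id[idx], taxonomy)
  q_idx <- match(query_id, orf_info$orf_id)
  if (is.na(q_idx)) stop("unknown query ORF: ", query_id)
  q_fam <- family_of(orf_info$replicon_id[q_idx], taxonomy)
  inter <- s_ctx == "intergenic"
  list(
    intergenic = hits[inter & s_fam != q_fam, , drop = FALSE],
    same_family = hits[inter & s_fam == q_fam, , drop = FALSE],
    gene = hits[s_ctx == "annotated", , drop = FALSE],
    entity = hits[s_ctx == "entity_overlapping", , drop = FALSE])
}

# Index of the top-scoring hit: lowest e-value, ties by highest I, then
# lexicographic subject id.
top_hit_index <- function(hits) {
  order(hits$e_value, -hits$I, hits$subject_id)[1]
}

#' Stage-1 label for one partitioned query
#'
#' @param query_id Identifier of the query ORF.
#' @param parts Hit partition from [partition_hits()].
#' @param diff_threshold Coverage differential in absolute percentage
#'   points required between the top intergenic hit and every
#'   gene/entity hit for the missing route.
#' @return A list with `label`, `supporting` and `conflicting` hit
#'   subsets, and `top_supporting_subject`.
#' @export
stage1_label <- function(query_id, parts, diff_threshold = 20) {
  no_hits <- function(h) is.null(h) || nrow(h) == 0L
  conflict <- rbind(parts$gene, parts$entity)
  if (!no_hits(parts$intergenic)) {
    top <- parts$intergenic[top_hit_index(parts$intergenic), , drop = FALSE]
    ok <- no_hits(conflict) ||
      all(conflict$avg_cov <= top$avg_cov - diff_threshold)
    if (ok)
      return(list(label = "potentially_missing",
                  supporting = parts$intergenic,
                  conflicting = conflict,
                  top_supporting_subject = top$subject_id))
  }
  if (!no_hits(parts$gene))
    return(list(label = "absent_annotation",
                supporting = parts$gene,
                conflicting = parts$entity,
                top_supporting_subject =
                  parts$gene$subject_id[top_hit_index(parts$gene)]))
  if (!no_hits(parts$entity))
    return(list(label = "genomic_artifact",
                supporting = parts$entity,
                conflicting = empty_hits(),
                top_supporting_subject =
                  parts$entity$subject_id[top_hit_index(parts$entity)]))
  list(label = "unclassified", supporting = empty_hits(),
       conflicting = empty_hits(), top_supporting_subject = NA_character_)
}

#' Stage-1 classification of all intergenic queries
#'
#' @param queries ORF data frame of the intergenic queries.
#' @param hits Filtered `alignment_hits` for those queries.
#' @param orf_info Data frame with `orf_id`, `replicon_id`, `context`
#'   for every ORF that can appear as a subject.
#' @param taxonomy Taxonomy data frame.
#' @param diff_threshold See [stage1_label()].
#' @return A list: `classifications` data frame (`orf_id`, `label`,
#'   `n_supporting`, `n_conflicting`, `top_supporting_subject`) and
#'   `details`, a per-query list of supporting/conflicting hit sets used
#'   later for clustering and the alpha score.
#' @export
stage1_classify <- function(queries, hits, orf_info, taxonomy,
                            diff_threshold = 20) {
  n <- nrow(queries)
  labels <- character(n)
  n_sup <- integer(n)
  n_con <- integer(n)
  top_subj <- character(n)
  details <- vector("list", n)
  names(details) <- queries$orf_id
  for (i in seq_len(n)) {
    qid <- queries$orf_id[i]
    parts <- partition_hits(qid, hits, orf_info, taxonomy)
    res <- stage1_label(qid, parts, diff_threshold)
    labels[i] <- res$label
    n_sup[i] <- nrow(res$supporting)
    n_con[i] <- nrow(res$conflicting)
    top_subj[i] <- res$top_supporting_subject
    details[[i]] <- list(parts = parts, supporting = res$supporting,
                         conflicting = res$conflicting)
  }
  list(
    classifications = data.frame(
      orf_id = queries$orf_id, label = labels,
      n_supporting = n_sup, n_conflicting = n_con,
      top_supporting_subject = top_subj, stringsAsFactors = FALSE),
    details = details)
}
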