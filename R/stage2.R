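# Stage 2: single-linkage clustering of potentially-missing ORFs over
# their qualifying alignments, and promotion of family-diverse clusters
# to missing-gene groups.

#' Single-linkage clusters of candidate ORFs
#'
#' Connected components of the graph whose vertices are the candidate
#' ORFs and whose edges are the qualifying alignments (cross-family
#' intergenic hits with both endpoints potentially missing). Transitive
#' by construction: if x aligns to y and y to z, all three cluster
#' together. Singleton candidates form singleton clusters.
#'
#' @param candidates Character vector of candidate ORF ids.
#' @param edges Two-column data frame (or matrix) of ORF id pairs.
#' @return A named list of character vectors (sorted member ids); list
#'   names are deterministic group ids assigned in order of each
#'   cluster's smallest member id.
#' @export
build_clusters <- function(candidates, edges) {
  candidates <- unique(as.character(candidates))
  if (is.null(edges) || NROW(edges) == 0L) {
    comp <- as.list(candidates)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    ends <- unique(c(as.character(edges[[1]]), as.character(edges[[2]])))
    stray <- setdiff(ends, candidates)
    if (length(stray))
      stop("edge endpoint(s) not in candidate set: ",
           paste(utils::head(stray, 5), collapse = ", "))
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = as.character(edges[[1]]),
                     to = as.character(edges[[2]]),
                     stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = candidates, stringsAsFactors = FALSE))
    memb <- igraph::components(g)$membership
    comp <- split(names(memb), memb)
  }
  comp <- lapply(comp, function(x) sort(unname(x)))
  comp <- comp[order(vapply(comp, `[[`, character(1), 1L))]
  names(comp) <- sprintf("MG%04d", seq_along(comp))
  comp
}

#' Promote family-diverse clusters to missing-gene groups
#'
#' Clusters holding at least two ORFs from at least two different
#' taxonomic families become missing-gene groups; their members take the
#' final label `missing_gene`. Members of failing clusters are demoted to
#' `unclassified`, with the near-miss reason reported for triage.
#'
#' @param clusters Cluster list from [build_clusters()].
#' @param orf_info Data frame mapping `orf_id` to `replicon_id`.
#' @param taxonomy Taxonomy data frame.
#' @return A list: `groups` (named list of member id vectors, renumbered
#'   `MG0001`... over the promoted clusters only), `demoted` (data frame
#'   `orf_id`, `cluster_size`, `n_families`, `reason`).
#' @export
finalize_missing <- function(clusters, orf_info, taxonomy) {
  fam_of_orf <- function(ids) {
    idx <- match(ids, orf_info$orf_id)
    if (anyNA(idx)) stop("unknown ORF id(s) in cluster")
    family_of(orf_info$replicon_id[idx], taxonomy)
  }
  keep <- logical(length(clusters))
  dem <- list()
  fams <- vector("list", length(clusters))
  for (k in seq_along(clusters)) {
    members <- clusters[[k]]
    fams[[k]] <- fam_of_orf(members)
    nf <- length(unique(fams[[k]]))
    if (length(members) >= 2L && nf >= 2L) {
      keep[k] <- TRUE
    } else {
      reason <- if (length(members) < 2L) "single_member"
                else "single_family"
      dem[[length(dem) + 1L]] <- data.frame(
        orf_id = members, cluster_size = length(members),
        n_families = nf, reason = reason, stringsAsFactors = FALSE)
    }
  }
  groups <- clusters[keep]
  if (length(groups))
    names(groups) <- sprintf("MG%04d", seq_along(groups))
  demoted <- if (length(dem))
    do.call(rbind, c(dem, list(make.row.names = FALSE)))
  else data.frame(orf_id = character(0), cluster_size = integer(0),
                  n_families = integer(0), reason = character(0),
                  stringsAsFactors = FALSE)
  list(groups = groups, demoted = demoted)
}

# Qualifying edges for stage-2 clustering: the supporting (cross-family
# intergenic) hits of potentially-missing queries whose subject is itself
# potentially missing.
stage2_edges <- function(stage1, candidates) {
  out <- list()
  for (qid in candidates) {
    sup <- stage1$details[[qid]]$supporting
    if (is.null(sup) || nrow(sup) == 0L) next
    keep <- sup$subject_id %in% candidates
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        from = qid, to = sup$subject_id[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
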