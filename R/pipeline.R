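# End-to-end orchestration: scan, context partition, alignment, two-stage
# classification, alpha scoring, group metrics and report files.

#' Run the missing-gene discovery pipeline
#'
#' Executes the full analysis over a set of replicons: maximal-ORF
#' enumeration, start rescue and genomic-context partition, all-vs-all
#' protein alignment of the intergenic queries against every ORF
#' (built-in aligner, or an external tabular report), hit screening,
#' Stage-1 labelling, Stage-2 single-linkage clustering with the
#' two-family rule, alpha scores and per-group metrics (average MUMi and
#' flank ultra-conservation).
#'
#' @param replicons Named list of [replicon()] objects.
#' @param features Feature data frame (see [read_features()]).
#' @param taxonomy Taxonomy data frame; every replicon must be covered
#'   (the family filter is mandatory).
#' @param alignment_report Optional path to a 12-column tabular report
#'   from an external all-vs-all protein search; when `NULL` the
#'   built-in aligner is used.
#' @param min_len Minimum ORF coding length (bp).
#' @param max_evalue,min_cov,max_hits_per_query Hit screening thresholds
#'   (see [filter_hits()]).
#' @param diff_threshold Stage-1 coverage differential (percentage
#'   points).
#' @param flank Flank width (bp) for the ultra-conservation check.
#' @param min_mum_len Minimum MUM length (bp) for group MUMi.
#' @param compute_mumi,compute_ultra Toggle the group-level sequence
#'   analyses.
#' @param out_dir Optional directory for the report bundle (TSVs, FASTA,
#'   summary).
#' @param representative_seed Optional seed for randomised selection of
#'   group representatives; by default the smallest member ORF id is
#'   chosen deterministically.
#' @return A list: `orfs` (with contexts), `hits` (screened),
#'   `stage1`, `classifications` (final per-query labels with alpha and
#'   cluster id), `groups` (per-group table), `group_members`,
#'   `summary`, `params`.
#' @export
run_pipeline <- function(replicons, features, taxonomy,
                         alignment_report = NULL,
                         min_len = 99L, max_evalue = 1e-5, min_cov = 80,
                         max_hits_per_query = 1000L, diff_threshold = 20,
                         flank = 30L, min_mum_len = 19L,
                         compute_mumi = TRUE, compute_ultra = TRUE,
                         out_dir = NULL, representative_seed = NULL) {
  stopifnot(length(replicons) >= 1L)
  validate_taxonomy(taxonomy)
  invisible(family_of(vapply(replicons, `[[`, character(1),
                             "replicon_id"), taxonomy))
  validate_features(features, replicons)

  # 1. maximal ORFs on both strands of every replicon
  orfs <- do.call(rbind, c(lapply(replicons, find_maximal_orfs,
                                  min_len = min_len),
                           list(make.row.names = FALSE)))
  if (is.null(orfs) || nrow(orfs) == 0L)
    stop("no ORFs >= ", min_len, " bp found in any replicon")

  # 2. context partition with start rescue
  orfs <- assign_context(orfs, features)
  orfs <- rescue_start(orfs, features, min_len = min_len)

  queries <- orfs[orfs$context == "intergenic", , drop = FALSE]
  subjects <- orfs

  # 3. all-vs-all alignment of queries against the full ORF database
  hits <- if (is.null(alignment_report)) {
    align_all(queries, subjects)
  } else {
    read_alignment_report(
      alignment_report,
      q_lens = stats::setNames(queries$length_aa, queries$orf_id),
      s_lens = stats::setNames(subjects$length_aa, subjects$orf_id))
  }
  hits <- filter_hits(hits, max_evalue = max_evalue, min_cov = min_cov,
                      max_hits_per_query = max_hits_per_query)

  # 4. Stage 1
  orf_info <- orfs[, c("orf_id", "replicon_id", "context")]
  s1 <- stage1_classify(queries, hits, orf_info, taxonomy,
                        diff_threshold = diff_threshold)

  # 5. Stage 2
  candidates <- s1$classifications$orf_id[
    s1$classifications$label == "potentially_missing"]
  edges <- stage2_edges(s1, candidates)
  clusters <- build_clusters(candidates, edges)
  fin <- finalize_missing(clusters, orf_info, taxonomy)

  # 6. final labels + alpha
  cls <- s1$classifications
  cls$alpha <- rep(NA_real_, nrow(cls))
  cls$cluster_id <- rep(NA_character_, nrow(cls))
  for (gid in names(fin$groups))
    cls$cluster_id[match(fin$groups[[gid]], cls$orf_id)] <- gid
  cls$label[cls$label == "potentially_missing" &
              !is.na(cls$cluster_id)] <- "missing_gene"
  cls$label[cls$label == "potentially_missing"] <- "unclassified"
  for (i in seq_len(nrow(cls))) {
    d <- s1$details[[cls$orf_id[i]]]
    if (cls$label[i] == "missing_gene") {
      cls$alpha[i] <- alpha_score("missing_gene", d$supporting,
                                  d$conflicting)
    } else if (cls$label[i] == "absent_annotation") {
      cls$alpha[i] <- alpha_score("absent_annotation", d$parts$gene,
                                  d$parts$entity)
    }
  }

  # 7. per-group table
  groups <- summarize_groups(fin$groups, cls, orfs, replicons, taxonomy,
                             s1, flank = flank,
                             min_mum_len = min_mum_len,
                             compute_mumi = compute_mumi,
                             compute_ultra = compute_ultra)

  summary <- list(
    n_replicons = length(replicons),
    n_orfs = nrow(orfs),
    n_annotated = sum(orfs$context == "annotated"),
    n_entity_overlapping = sum(orfs$context == "entity_overlapping"),
    n_intergenic = nrow(queries),
    n_missing_gene = sum(cls$label == "missing_gene"),
    n_absent_annotation = sum(cls$label == "absent_annotation"),
    n_genomic_artifact = sum(cls$label == "genomic_artifact"),
    n_unclassified = sum(cls$label == "unclassified"),
    n_groups = length(fin$groups))

  result <- list(orfs = orfs, hits = hits,
                 stage1 = s1$classifications, classifications = cls,
                 groups = groups, group_members = fin$groups,
                 demoted = fin$demoted, summary = summary,
                 params = list(min_len = min_len,
                               max_evalue = max_evalue,
                               min_cov = min_cov,
                               max_hits_per_query = max_hits_per_query,
                               diff_threshold = diff_threshold,
                               flank = flank,
                               min_mum_len = min_mum_len))
  if (!is.null(out_dir))
    write_report_bundle(result, replicons, taxonomy, out_dir,
                        representative_seed = representative_seed)
  result
}

summarize_groups <- function(groups, cls, orfs, replicons, taxonomy, s1,
                             flank = 30L, min_mum_len = 19L,
                             compute_mumi = TRUE, compute_ultra = TRUE) {
  if (!length(groups))
    return(data.frame(group_id = character(0), n_members = integer(0),
                      n_families = integer(0), families = character(0),
                      avg_alpha = numeric(0), avg_length_aa = numeric(0),
                      avg_identity = numeric(0),
                      n_replicons = integer(0),
                      n_chromosomes = integer(0), n_plasmids = integer(0),
                      avg_mumi = numeric(0), ultra_conserved = logical(0),
                      stringsAsFactors = FALSE))
  rows <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    gid <- names(groups)[k]
    members <- groups[[k]]
    oidx <- match(members, orfs$orf_id)
    reps <- orfs$replicon_id[oidx]
    fams <- sort(unique(family_of(reps, taxonomy)))
    mols <- vapply(replicons[reps], `[[`, character(1), "molecule")
    alphas <- cls$alpha[match(members, cls$orf_id)]
    best_i <- vapply(members, function(m) {
      sup <- s1$details[[m]]$supporting
      if (is.null(sup) || nrow(sup) == 0L) NA_real_ else max(sup$I)
    }, numeric(1))
    rows[[k]] <- data.frame(
      group_id = gid,
      n_members = length(members),
      n_families = length(fams),
      families = paste(fams, collapse = ","),
      avg_alpha = group_alpha(alphas),
      avg_length_aa = mean(orfs$length_aa[oidx]),
      avg_identity = mean(best_i, na.rm = TRUE),
      n_replicons = length(unique(reps)),
      n_chromosomes = length(unique(reps[mols == "chromosome"])),
      n_plasmids = length(unique(reps[mols == "plasmid"])),
      avg_mumi = if (compute_mumi)
        group_mumi(reps, replicons, taxonomy, min_mum_len) else NA_real_,
      ultra_conserved = if (compute_ultra)
        ultra_conserved(orfs[oidx, , drop = FALSE], replicons, flank)
      else NA,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

write_report_bundle <- function(result, replicons, taxonomy, out_dir,
                                representative_seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  orfs <- result$orfs
  cls <- result$classifications

  write_context_tsv(orfs, file.path(out_dir, "orf_contexts.tsv"))
  utils::write.table(cls, file.path(out_dir, "classifications.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # per-gene table for missing genes (1-based inclusive coordinates)
  mg <- cls[cls$label == "missing_gene", , drop = FALSE]
  oidx <- match(mg$orf_id, orfs$orf_id)
  tidx <- match(orfs$replicon_id[oidx], taxonomy$replicon_id)
  g <- to_gff_coords(orfs$start[oidx], orfs$end[oidx])
  gene_tab <- data.frame(
    replicon_id = orfs$replicon_id[oidx], gene_id = mg$orf_id,
    start = g$start, stop = g$end, length_aa = orfs$length_aa[oidx],
    alpha = mg$alpha, cluster_id = mg$cluster_id,
    order = taxonomy$order[tidx], family = taxonomy$family[tidx],
    genus = taxonomy$genus[tidx], stringsAsFactors = FALSE)
  utils::write.table(gene_tab, file.path(out_dir, "missing_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$groups,
                     file.path(out_dir, "missing_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # FASTA: amino-acid sequences of all missing genes; one representative
  # nucleotide sequence per group
  if (nrow(mg)) {
    write_orf_fasta(orfs[oidx, , drop = FALSE],
                    file.path(out_dir, "missing_genes_aa.fasta"), "aa")
    rep_ids <- vapply(result$group_members, function(m) {
      if (is.null(representative_seed)) sort(m)[1]
      else with_seed(representative_seed, sample(m, 1L))
    }, character(1))
    ridx <- match(rep_ids, orfs$orf_id)
    write_orf_fasta(orfs[ridx, , drop = FALSE],
                    file.path(out_dir, "group_representatives_nt.fasta"),
                    "nt")
  }

  s <- result$summary
  utils::write.table(
    data.frame(metric = names(s), value = unlist(s)),
    file.path(out_dir, "summary.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  p <- result$params
  utils::write.table(
    data.frame(parameter = names(p), value = unlist(p)),
    file.path(out_dir, "parameters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(out_dir)
}
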