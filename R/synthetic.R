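# Seeded synthetic pan-genome generator with exact ground truth.
#
# The generator builds toy multi-replicon datasets that exercise every
# pipeline label: annotated genes (and RNA features), intergenic ORFs
# planted across taxonomic families ("missing genes"), intergenic copies
# of annotated genes from other families ("absent annotations"), shadow
# ORFs embedded on the reverse strand of carrier genes, intergenic copies
# of those shadows ("genomic artifacts"), and same-family-only conserved
# ORFs that the phylogenetic filter must reject.
#
# Spurious conserved ORFs are suppressed constructively rather than by
# rejection screening: short stop-codon cassettes are interleaved into
# spacer DNA and into every planted coding sequence so that each
# unintended reading frame (both strands) hits a stop codon within
# < 75 bp. Any stray ORF (>= 99 bp) crossing an element boundary can then
# share at most 74 bp with a conserved insert, which is below the 80%
# dual-coverage screen, so strays never align into the conserved classes.

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

STOP_TRIPLETS <- c("TAA", "TAG", "TGA")
REV_STOP_TRIPLETS <- c("TTA", "CTA", "TCA")  # revcomp reads as a stop

# Stop cassettes: short segments that place a stop codon in specific
# reading frames while staying sense in the host frame. Only the stop
# *skeleton* is fixed; stop choices and filler bases are randomised per
# instance so that no two cassette copies are alignably identical
# (constant cassettes would hand every stray ORF a block of shared
# sequence and could push chance alignments past the screens).

# 12 bp, sense in the host frame, reverse strand stopped in all three
# phases (reverse reading: stop at offsets 0, 4, 8).
rand_cas_rev <- function() {
  repeat {
    rev_read <- paste0(
      sample(STOP_TRIPLETS, 1), sample(c("A", "C", "G", "T"), 1),
      sample(STOP_TRIPLETS, 1), sample(c("A", "C", "G", "T"), 1),
      sample(STOP_TRIPLETS, 1), sample(c("A", "C", "G", "T"), 1))
    fwd <- revcomp(rev_read)
    if (!any(split_codons(fwd) %in% STOP_TRIPLETS)) return(fwd)
  }
}

# 12 bp, sense in the host frame, forward phases 1 and 2 stopped
# (stops at offsets 1 and 5).
rand_cas_fwd <- function() {
  repeat {
    fwd <- paste0(
      sample(c("A", "C", "G", "T"), 1), sample(STOP_TRIPLETS, 1),
      sample(c("A", "C", "G", "T"), 1), sample(STOP_TRIPLETS, 1),
      paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
            collapse = ""))
    if (!any(split_codons(fwd) %in% STOP_TRIPLETS)) return(fwd)
  }
}

# cassette pair for coding sequences: kills all five non-host readings
rand_cas_pair <- function() paste0(rand_cas_rev(), rand_cas_fwd())

# 24 bp spacer cassette: all six readings stopped (forward stops at
# offsets 0, 4, 8; reverse-stop triplets at 12, 16, 20), fillers random.
rand_cas_all <- function() {
  paste0(
    sample(STOP_TRIPLETS, 1), sample(c("A", "C", "G", "T"), 1),
    sample(STOP_TRIPLETS, 1), sample(c("A", "C", "G", "T"), 1),
    sample(STOP_TRIPLETS, 1), sample(c("A", "C", "G", "T"), 1),
    sample(REV_STOP_TRIPLETS, 1), sample(c("A", "C", "G", "T"), 1),
    sample(REV_STOP_TRIPLETS, 1), sample(c("A", "C", "G", "T"), 1),
    sample(REV_STOP_TRIPLETS, 1), sample(c("A", "C", "G", "T"), 1))
}

rand_bases <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rand_sense_codons <- function(n) {
  paste(sample(SENSE_CODONS, n, replace = TRUE), collapse = "")
}

# Spacer DNA: opens with an all-frame stop cassette (so any reading
# frame leaving the neighbouring element is terminated within 24 bp),
# then random chunks (30-45 bp) separated by further cassettes, trimmed
# to the requested length. No reading of the result stays stop-free for
# >= 75 bp.
make_spacer <- function(len, gc = 0.5) {
  if (len <= 0L) return("")
  out <- rand_cas_all()
  total <- nchar(out)
  while (total < len) {
    chunk <- rand_bases(sample(30:45, 1L), gc)
    cas <- rand_cas_all()
    out <- c(out, chunk, cas)
    total <- total + nchar(chunk) + nchar(cas)
  }
  substring(paste(out, collapse = ""), 1L, len)
}

# Coding sequence (start codon .. last sense codon, no stop): blocks of
# at most `block` random sense codons separated by randomised cassette
# pairs, so unintended readings stay stop-free < 75 bp.
make_coding <- function(n_random_codons, block = 12L) {
  n_chunks <- ceiling(n_random_codons / block)
  sizes <- rep(n_random_codons %/% n_chunks, n_chunks)
  extra <- n_random_codons - sum(sizes)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  parts <- vapply(sizes, rand_sense_codons, character(1))
  out <- parts[1]
  for (i in seq_len(n_chunks - 1L))
    out <- paste0(out, rand_cas_pair(), parts[i + 1L])
  paste0("ATG", out)
}

# Point mutations at `rate` per base, skipping protected positions and
# any substitution that would create an in-frame stop codon.
mutate_coding <- function(coding, rate, protect_first = TRUE) {
  if (rate <= 0) return(coding)
  bases <- strsplit(coding, "", fixed = TRUE)[[1]]
  n <- length(bases)
  hit <- which(stats::runif(n) < rate)
  if (protect_first) hit <- hit[hit > 3L]
  for (p in hit) {
    new <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
    ci <- (p - 1L) %/% 3L
    codon <- bases[(ci * 3L + 1L):(ci * 3L + 3L)]
    codon[(p - 1L) %% 3L + 1L] <- new
    if (paste(codon, collapse = "") %in% c("TAA", "TAG", "TGA")) next
    bases[p] <- new
  }
  paste(bases, collapse = "")
}

mutate_flank <- function(flank, rate, protect_tail_stop = FALSE) {
  if (rate <= 0) return(flank)
  bases <- strsplit(flank, "", fixed = TRUE)[[1]]
  n <- length(bases)
  upper <- if (protect_tail_stop) n - 3L else n
  if (upper < 1L) return(flank)
  hit <- which(stats::runif(n) < rate)
  hit <- hit[hit <= upper]
  for (p in hit)
    bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
  paste(bases, collapse = "")
}

# A planted intergenic element: 30 bp upstream flank ending in an
# in-frame TAA guard (which pins the scanned ORF's maximal start to the
# planted ATG), the coding sequence, its stop, and a 30 bp downstream
# flank. Returns the forward string plus the coding offsets within it.
plant_insert <- function(coding, up_flank = NULL, down_flank = NULL,
                         gc = 0.5) {
  if (is.null(up_flank)) up_flank <- paste0(rand_bases(27L, gc), "TAA")
  if (is.null(down_flank)) down_flank <- rand_bases(30L, gc)
  stopifnot(nchar(up_flank) == 30L,
            substring(up_flank, 28L, 30L) == "TAA")
  list(seq = paste0(up_flank, coding, "TAA", down_flank),
       coding_offset = 30L, coding_len = nchar(coding),
       up_flank = up_flank, down_flank = down_flank)
}

# A gene element: in-frame TAA guard + coding + stop. The guard stops the
# scanner from extending the annotated ORF 5'-wards into the spacer, so
# the scanned ORF coincides exactly with the annotation.
gene_element <- function(coding) {
  list(seq = paste0("TAA", coding, "TAA"),
       coding_offset = 3L, coding_len = nchar(coding))
}

# Shadow construction: a carrier gene whose reverse strand contains a
# complete ORF. F = revcomp(shadow coding + stop) is embedded at a codon
# boundary; the TTA codon 3' of F reads TAA on the reverse strand,
# pinning the shadow ORF's maximal start to its own ATG. The shadow
# coding is resampled until (a) F's codons are all sense in the carrier
# frame and (b) the shadow coding contains no unintended complete ORF of
# >= 99 bp in any other reading.
make_shadow_carrier <- function(min_len = 99L, max_tries = 2000L) {
  for (try in seq_len(max_tries)) {
    s_coding <- paste0("ATG", rand_sense_codons(sample(32:38, 1L)))
    s_full <- paste0(s_coding, "TAA")
    f <- revcomp(s_full)
    f_codons <- split_codons(f)
    if (any(f_codons %in% c("TAA", "TAG", "TGA"))) next
    if (has_unintended_orf(s_full, min_len)) next
    carrier_coding <- paste0(
      "ATG", rand_sense_codons(6L), rand_cas_pair(),
      f, "TTA", rand_cas_pair(), rand_sense_codons(6L))
    f_offset <- 3L + 18L + 24L  # ATG + 6 codons + cassette pair
    return(list(carrier_coding = carrier_coding,
                shadow_coding = s_coding,
                f_offset = f_offset, f_len = nchar(f)))
  }
  stop("failed to construct a shadow carrier after ", max_tries, " tries")
}

# TRUE when `seq` contains a complete ORF >= min_len outside the intended
# forward frame-0 reading.
has_unintended_orf <- function(seq, min_len = 99L) {
  tmp <- replicon("chk", seq)
  orfs <- find_maximal_orfs(tmp, min_len = min_len)
  intended <- orfs$strand == "+" & orfs$start %% 3L == 0L
  any(!intended)
}

#' Generate a synthetic pan-genome with known ground truth
#'
#' Builds `n_families * replicons_per_family` replicons carrying
#' annotated genes and RNA features, planted cross-family conserved
#' intergenic ORFs (intended missing genes), intergenic copies of
#' annotated genes from other families (intended absent annotations),
#' reverse-strand shadow ORFs inside carrier genes plus one intergenic
#' copy of each (intended genomic artifacts), and same-family-only
#' conserved ORFs (intended to stay unclassified under the family
#' filter). Every planted element is recorded in the truth table with
#' its exact coordinates and intended final label.
#'
#' Copies of a planted missing family share fixed 30 bp flanks, so with
#' `mutation_rate = 0` the groups are also ultra-conserved.
#'
#' @param n_families Number of taxonomic families.
#' @param replicons_per_family Replicons per family.
#' @param replicon_len Target replicon length in bp.
#' @param n_annotated_genes Annotated genes per replicon.
#' @param n_planted_missing_families Number of cross-family conserved
#'   ORF families planted (two copies each, in two different families).
#' @param n_planted_absent Number of absent-annotation plants.
#' @param n_shadow_orfs Number of shadow ORFs (each with one intergenic
#'   copy planted elsewhere).
#' @param n_samefam_families Number of conserved ORF families whose
#'   copies all sit within one taxonomic family.
#' @param mutation_rate Per-base substitution rate applied to each
#'   planted missing/same-family copy (never creating an in-frame stop
#'   or destroying the start).
#' @param n_rna RNA features per replicon.
#' @param gc_bias GC fraction of spacer DNA.
#' @param seed RNG seed; the full dataset is a deterministic function of
#'   the configuration and this seed.
#' @return A list with `replicons` (named list of [replicon()]),
#'   `features` (data frame), `taxonomy` (data frame), `truth`
#'   (data frame: `element_id`, `replicon_id`, `start`, `end`, `strand`,
#'   `intended_label`, `family_set`) and `config`.
#' @export
generate_pangenome <- function(n_families = 4L,
                               replicons_per_family = 2L,
                               replicon_len = 15000L,
                               n_annotated_genes = 8L,
                               n_planted_missing_families = 10L,
                               n_planted_absent = 5L,
                               n_shadow_orfs = 10L,
                               n_samefam_families = 2L,
                               mutation_rate = 0,
                               n_rna = 2L,
                               gc_bias = 0.5,
                               seed = 1L) {
  stopifnot(n_families >= 1L, replicons_per_family >= 1L)
  if (n_planted_missing_families > 0L && n_families < 2L)
    stop("planting missing families requires at least two families")
  if (n_samefam_families > 0L && replicons_per_family < 2L)
    stop("same-family plants require at least two replicons per family")
  if (n_planted_absent > 0L &&
      (n_families < 2L || n_annotated_genes < 1L))
    stop("absent-annotation plants require >= 2 families and >= 1 gene")
  config <- list(n_families = n_families,
                 replicons_per_family = replicons_per_family,
                 replicon_len = replicon_len,
                 n_annotated_genes = n_annotated_genes,
                 n_planted_missing_families = n_planted_missing_families,
                 n_planted_absent = n_planted_absent,
                 n_shadow_orfs = n_shadow_orfs,
                 n_samefam_families = n_samefam_families,
                 mutation_rate = mutation_rate, n_rna = n_rna,
                 gc_bias = gc_bias, seed = seed)
  with_seed(seed, generate_pangenome_impl(config))
}

generate_pangenome_impl <- function(cfg) {
  fam_ids <- sprintf("FAM%02d", seq_len(cfg$n_families))
  rep_tab <- expand.grid(fam = seq_len(cfg$n_families),
                         idx = seq_len(cfg$replicons_per_family))
  rep_tab <- rep_tab[order(rep_tab$fam, rep_tab$idx), ]
  rep_ids <- sprintf("R%02d.%02d", rep_tab$fam, rep_tab$idx)
  rep_fam <- fam_ids[rep_tab$fam]
  n_reps <- length(rep_ids)
  taxonomy <- data.frame(
    replicon_id = rep_ids,
    order = sprintf("ORD%02d", (rep_tab$fam + 1L) %/% 2L),
    family = rep_fam,
    genus = sprintf("GEN%02d", rep_tab$fam),
    stringsAsFactors = FALSE)

  # plain annotated genes per replicon (sequences needed for absent plants)
  genes <- vector("list", n_reps)
  for (r in seq_len(n_reps))
    genes[[r]] <- vapply(seq_len(cfg$n_annotated_genes), function(i)
      make_coding(sample(45:75, 1L)), character(1))

  # element queues per replicon; each element: list(kind, seq, strand,
  # coding_offset, coding_len, element_id, label, family_set)
  queue <- lapply(seq_len(n_reps), function(r) list())
  push <- function(r, el) queue[[r]][[length(queue[[r]]) + 1L]] <<- el
  # sample from a set regardless of its size (avoids sample()'s scalar
  # expansion when the set has one element)
  pick <- function(x, k = 1L) x[sample.int(length(x), k)]

  for (r in seq_len(n_reps)) {
    for (i in seq_along(genes[[r]])) {
      ge <- gene_element(genes[[r]][i])
      push(r, list(kind = "gene", seq = ge$seq,
                   strand = sample(c("+", "-"), 1L),
                   coding_offset = ge$coding_offset,
                   coding_len = ge$coding_len,
                   element_id = sprintf("gene_%s_%02d", rep_ids[r], i),
                   label = "annotated_gene", family_set = ""))
    }
    for (i in seq_len(cfg$n_rna))
      push(r, list(kind = "rna", seq = make_spacer(90L, cfg$gc_bias),
                   strand = "+", coding_offset = 0L, coding_len = 90L,
                   element_id = sprintf("rna_%s_%02d", rep_ids[r], i),
                   label = "rna", family_set = ""))
  }

  plant_pair <- function(tag, hosts, label) {
    # one conserved ORF family planted (with shared flanks) in `hosts`;
    # 24-36 random codons yield coding lengths of 99-159 bp
    coding <- make_coding(sample(24:36, 1L))
    up <- paste0(rand_bases(27L, cfg$gc_bias), "TAA")
    down <- rand_bases(30L, cfg$gc_bias)
    fams <- sort(unique(rep_fam[hosts]))
    for (h in seq_along(hosts)) {
      cod <- mutate_coding(coding, cfg$mutation_rate)
      ins <- plant_insert(cod,
                          mutate_flank(up, cfg$mutation_rate, TRUE),
                          mutate_flank(down, cfg$mutation_rate))
      push(hosts[h], list(kind = "plant", seq = ins$seq,
                          strand = sample(c("+", "-"), 1L),
                          coding_offset = ins$coding_offset,
                          coding_len = ins$coding_len,
                          element_id = sprintf("%s_copy%d", tag, h),
                          label = label,
                          family_set = paste(fams, collapse = ",")))
    }
  }

  for (m in seq_len(cfg$n_planted_missing_families)) {
    fam_pair <- sample(cfg$n_families, 2L)
    hosts <- vapply(fam_pair, function(f)
      pick(which(rep_tab$fam == f)), integer(1))
    plant_pair(sprintf("missing%02d", m), hosts, "missing_gene")
  }
  for (k in seq_len(cfg$n_samefam_families)) {
    f <- sample(cfg$n_families, 1L)
    hosts <- pick(which(rep_tab$fam == f), 2L)
    plant_pair(sprintf("samefam%02d", k), hosts, "unclassified")
  }
  for (a in seq_len(cfg$n_planted_absent)) {
    src_rep <- sample(n_reps, 1L)
    gi <- sample(cfg$n_annotated_genes, 1L)
    host <- pick(which(rep_fam != rep_fam[src_rep]))
    ins <- plant_insert(genes[[src_rep]][gi], gc = cfg$gc_bias)
    push(host, list(kind = "plant", seq = ins$seq,
                    strand = sample(c("+", "-"), 1L),
                    coding_offset = ins$coding_offset,
                    coding_len = ins$coding_len,
                    element_id = sprintf("absent%02d", a),
                    label = "absent_annotation", family_set = ""))
  }
  for (s in seq_len(cfg$n_shadow_orfs)) {
    sh <- make_shadow_carrier()
    carrier_host <- sample(n_reps, 1L)
    ge <- gene_element(sh$carrier_coding)
    push(carrier_host, list(kind = "carrier", seq = ge$seq, strand = "+",
                            coding_offset = ge$coding_offset,
                            coding_len = ge$coding_len,
                            element_id = sprintf("carrier%02d", s),
                            label = "annotated_gene", family_set = "",
                            f_offset = sh$f_offset, f_len = sh$f_len,
                            shadow_id = sprintf("shadow%02d", s)))
    probe_host <- pick(setdiff(seq_len(n_reps), carrier_host))
    ins <- plant_insert(sh$shadow_coding, gc = cfg$gc_bias)
    push(probe_host, list(kind = "plant", seq = ins$seq,
                          strand = sample(c("+", "-"), 1L),
                          coding_offset = ins$coding_offset,
                          coding_len = ins$coding_len,
                          element_id = sprintf("artifact%02d", s),
                          label = "genomic_artifact", family_set = ""))
  }

  # assemble each replicon: spacer / element / spacer / ...
  replicons <- list()
  features <- list()
  truth <- list()
  add_truth <- function(eid, rep_id, start, end, strand, label, fams) {
    truth[[length(truth) + 1L]] <<- data.frame(
      element_id = eid, replicon_id = rep_id, start = start, end = end,
      strand = strand, intended_label = label, family_set = fams,
      stringsAsFactors = FALSE)
  }
  for (r in seq_len(n_reps)) {
    els <- queue[[r]]
    els <- els[sample(length(els))]
    parts <- character(0)
    cursor <- 0L
    spacer <- make_spacer(sample(120:200, 1L), cfg$gc_bias)
    parts <- c(parts, spacer); cursor <- cursor + nchar(spacer)
    for (el in els) {
      fwd <- if (el$strand == "-") revcomp(el$seq) else el$seq
      elen <- nchar(fwd)
      # coding interval in forward coordinates (0-based half-open,
      # excluding the stop codon)
      if (el$strand == "+") {
        cstart <- cursor + el$coding_offset
        cend <- cstart + el$coding_len
      } else {
        cstart <- cursor + elen - el$coding_offset - el$coding_len
        cend <- cstart + el$coding_len
      }
      if (el$kind %in% c("gene", "carrier")) {
        # annotation is stop-inclusive
        fs <- if (el$strand == "+") cstart else cstart - 3L
        fe <- if (el$strand == "+") cend + 3L else cend
        features[[length(features) + 1L]] <- data.frame(
          replicon_id = rep_ids[r], kind = "gene", start = fs, end = fe,
          strand = el$strand, stringsAsFactors = FALSE)
        add_truth(el$element_id, rep_ids[r], cstart, cend, el$strand,
                  el$label, el$family_set)
        if (el$kind == "carrier") {
          # shadow ORF coordinates: F sits at f_offset within the
          # carrier coding; its reverse reading is stop + coding,
          # so the shadow coding spans F minus its first 3 bases
          sh_start <- cstart + el$f_offset + 3L
          sh_end <- cstart + el$f_offset + el$f_len
          add_truth(el$shadow_id, rep_ids[r], sh_start, sh_end, "-",
                    "shadow_orf", "")
        }
      } else if (el$kind == "rna") {
        features[[length(features) + 1L]] <- data.frame(
          replicon_id = rep_ids[r], kind = "rna", start = cursor,
          end = cursor + elen, strand = "+", stringsAsFactors = FALSE)
      } else {
        add_truth(el$element_id, rep_ids[r], cstart, cend, el$strand,
                  el$label, el$family_set)
      }
      spacer <- make_spacer(sample(120:200, 1L), cfg$gc_bias)
      parts <- c(parts, fwd, spacer)
      cursor <- cursor + elen + nchar(spacer)
    }
    if (cursor > cfg$replicon_len)
      stop("replicon_len = ", cfg$replicon_len, " too small for the ",
           "requested elements on ", rep_ids[r], " (need >= ", cursor,
           " bp)")
    if (cursor < cfg$replicon_len)
      parts <- c(parts, make_spacer(cfg$replicon_len - cursor,
                                    cfg$gc_bias))
    replicons[[rep_ids[r]]] <- replicon(
      rep_ids[r], paste(parts, collapse = ""), topology = "linear",
      genome_id = sprintf("G%02d", rep_tab$fam[r]))
  }
  features <- do.call(rbind, c(features, list(make.row.names = FALSE)))
  truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  list(replicons = replicons, features = features, taxonomy = taxonomy,
       truth = truth, config = cfg)
}

#' Write a synthetic pan-genome to standard files
#'
#' FASTA (all replicons), GFF3 annotation, taxonomy TSV and the truth
#' TSV (1-based inclusive coordinates, matching the other exports).
#'
#' @param dataset Result of [generate_pangenome()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_pangenome <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(
    vapply(dataset$replicons, `[[`, character(1), "sequence"))
  names(seqs) <- names(dataset$replicons)
  Biostrings::writeXStringSet(seqs, file.path(dir, "replicons.fasta"))
  write_features_gff3(dataset$features, file.path(dir, "features.gff3"))
  write_taxonomy(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  tr <- dataset$truth
  g <- to_gff_coords(tr$start, tr$end)
  tr$start <- g$start; tr$end <- g$end
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Score pipeline output against planted truth
#'
#' Matches final query classifications to the truth table by replicon,
#' strand and exact coding coordinates, and reports recall and precision
#' per intended label. Precision counts every query the pipeline assigned
#' to a label (planted or not); recall counts recovered plants.
#'
#' @param result A [run_pipeline()] result.
#' @param truth Truth data frame from [generate_pangenome()] (0-based
#'   half-open coordinates, as returned in memory).
#' @return A data frame: `label`, `n_truth`, `n_predicted`, `recall`,
#'   `precision`.
#' @export
score_against_truth <- function(result, truth) {
  labels <- c("missing_gene", "absent_annotation", "genomic_artifact",
              "unclassified")
  orfs <- result$orfs
  cls <- result$classifications
  key_of <- function(rep, strand, start, end)
    sprintf("%s|%s|%d-%d", rep, strand, start, end)
  pred_key <- key_of(orfs$replicon_id[match(cls$orf_id, orfs$orf_id)],
                     orfs$strand[match(cls$orf_id, orfs$orf_id)],
                     orfs$start[match(cls$orf_id, orfs$orf_id)],
                     orfs$end[match(cls$orf_id, orfs$orf_id)])
  truth_q <- truth[truth$intended_label %in% labels, , drop = FALSE]
  truth_key <- key_of(truth_q$replicon_id, truth_q$strand,
                      truth_q$start, truth_q$end)
  out <- data.frame(label = labels, n_truth = NA_integer_,
                    n_predicted = NA_integer_, recall = NA_real_,
                    precision = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(labels)) {
    lb <- labels[i]
    t_keys <- truth_key[truth_q$intended_label == lb]
    p_keys <- pred_key[cls$label == lb]
    good <- sum(t_keys %in% p_keys)
    out$n_truth[i] <- length(t_keys)
    out$n_predicted[i] <- length(p_keys)
    out$recall[i] <- if (length(t_keys)) good / length(t_keys) else NA_real_
    out$precision[i] <- if (length(p_keys)) good / length(p_keys)
                        else NA_real_
  }
  out
}
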