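# Annotation, taxonomy and alignment-report input/output.
#
# Internal coordinates are 0-based half-open on the forward strand for all
# features and ORFs; every emitted file uses the standard 1-based inclusive
# convention (GFF3, TSV exports).

GFF_KIND_MAP <- c(
  CDS = "gene", gene = "gene",
  tRNA = "rna", rRNA = "rna", ncRNA = "rna", tmRNA = "rna",
  misc_RNA = "rna", rRNA_gene = "rna", tRNA_gene = "rna",
  pseudogene = "pseudogene")

#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' The inverse of [to_gff_coords()]. Both directions are exact bijections
#' on integer intervals.
#'
#' @param start,end Integer vectors, 1-based inclusive.
#' @return A list with components `start` and `end` (0-based half-open).
#' @export
from_gff_coords <- function(start, end) {
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Convert 0-based half-open coordinates to 1-based inclusive
#'
#' @param start,end Integer vectors, 0-based half-open.
#' @return A list with components `start` and `end` (1-based inclusive).
#' @export
to_gff_coords <- function(start, end) {
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

#' Read feature annotations
#'
#' Reads genomic features from GFF3 (via rtracklayer) or from a GenBank
#' flat file's feature table. Feature types are mapped onto the pipeline's
#' four kinds: `CDS`/`gene` to `gene`; `tRNA`/`rRNA`/`ncRNA` (and similar)
#' to `rna`; `pseudogene` (or a `/pseudo` qualifier) to `pseudogene`;
#' everything else to `other`.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"genbank"`.
#' @param replicons Optional named list of [replicon()] objects; when
#'   given, features referencing unknown replicons or exceeding the
#'   replicon length raise an error.
#' @return A data frame with columns `replicon_id`, `kind`, `start`,
#'   `end` (0-based half-open), `strand`.
#' @export
read_features <- function(path, format = c("gff3", "genbank"),
                          replicons = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gff3") {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e)
                     stop("malformed GFF3 in ", path, ": ",
                          conditionMessage(e)))
    if (length(gr) == 0L)
      return(data.frame(replicon_id = character(0), kind = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE))
    type <- as.character(gr$type)
    kind <- unname(GFF_KIND_MAP[type])
    kind[is.na(kind)] <- "other"
    strand <- as.character(BiocGenerics::strand(gr))
    strand[strand == "*"] <- "+"
    feats <- data.frame(
      replicon_id = as.character(GenomicRanges::seqnames(gr)),
      kind = kind,
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr),
      strand = strand,
      stringsAsFactors = FALSE)
  } else {
    recs <- parse_genbank(path)
    feats <- do.call(rbind, c(lapply(recs, `[[`, "features"),
                              list(make.row.names = FALSE)))
    if (is.null(feats) || nrow(feats) == 0L)
      return(data.frame(replicon_id = character(0), kind = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE))
  }
  validate_features(feats, replicons)
  feats
}

validate_features <- function(features, replicons = NULL) {
  if (nrow(features) == 0L) return(invisible(features))
  bad <- features$start < 0L | features$start >= features$end
  if (any(bad))
    stop("invalid feature interval(s) after coordinate conversion (",
         sum(bad), " with start >= end or start < 0)")
  if (!is.null(replicons)) {
    known <- vapply(replicons, `[[`, character(1), "replicon_id")
    unk <- setdiff(unique(features$replicon_id), known)
    if (length(unk))
      stop("feature(s) reference unknown replicon id(s): ",
           paste(unk, collapse = ", "))
    lens <- stats::setNames(
      vapply(replicons, function(r) nchar(r$sequence), integer(1)), known)
    over <- features$end > lens[features$replicon_id]
    if (any(over))
      stop("feature(s) extend beyond replicon end on: ",
           paste(unique(features$replicon_id[over]), collapse = ", "))
  }
  invisible(features)
}

#' Write features to GFF3
#'
#' Inverse of [read_features()] for the GFF3 format; internal 0-based
#' half-open intervals are emitted as 1-based inclusive.
#'
#' @param features Feature data frame (see [read_features()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path) {
  type_map <- c(gene = "gene", rna = "ncRNA", pseudogene = "pseudogene",
                other = "misc_feature")
  if (nrow(features)) {
    gr <- GenomicRanges::GRanges(
      seqnames = features$replicon_id,
      ranges = IRanges::IRanges(start = features$start + 1L,
                                end = features$end),
      strand = features$strand)
    gr$type <- unname(type_map[features$kind])
    gr$ID <- sprintf("feat%05d", seq_len(nrow(features)))
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    writeLines("##gff-version 3", path)
  }
  invisible(path)
}

#' Read the replicon taxonomy table
#'
#' Tab-separated file with header columns `replicon_id`, `order`,
#' `family`, `genus`. The family is the unit of the phylogenetic filter
#' and must be non-empty for every replicon.
#'
#' @param path Path to the TSV file.
#' @return A data frame with the four columns above.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tx <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("replicon_id", "order", "family", "genus")
  miss <- setdiff(need, names(tx))
  if (length(miss))
    stop("taxonomy table missing column(s): ", paste(miss, collapse = ", "))
  tx <- tx[, need]
  validate_taxonomy(tx)
  tx
}

validate_taxonomy <- function(taxonomy) {
  if (any(!nzchar(taxonomy$family) | is.na(taxonomy$family)))
    stop("taxonomy: empty family for replicon(s): ",
         paste(taxonomy$replicon_id[!nzchar(taxonomy$family)],
               collapse = ", "))
  if (anyDuplicated(taxonomy$replicon_id))
    stop("taxonomy: duplicated replicon id(s)")
  invisible(taxonomy)
}

#' Write the taxonomy table
#' @param taxonomy Taxonomy data frame (see [read_taxonomy()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# family lookup (replicon_id -> family) with a hard error for gaps: the
# phylogenetic filter is mandatory.
family_of <- function(replicon_ids, taxonomy) {
  fam <- stats::setNames(taxonomy$family, taxonomy$replicon_id)
  out <- fam[replicon_ids]
  if (anyNA(out))
    stop("no taxonomy record for replicon(s): ",
         paste(unique(replicon_ids[is.na(out)]), collapse = ", "))
  unname(out)
}
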