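# Sequence input: FASTA via Biostrings, GenBank flat files via a minimal
# built-in reader. The in-memory replicon representation is a plain list so
# that toy genomes can be constructed directly in tests and simulations.

#' Construct a replicon object
#'
#' A replicon is the basic genomic unit of the pipeline: one chromosome or
#' plasmid nucleotide sequence together with its identity and topology.
#'
#' @param replicon_id Unique identifier of the replicon within a run.
#' @param sequence DNA string over A/C/G/T/N. Lower-case input is
#'   upper-cased; characters outside the alphabet are converted to `N`.
#' @param topology `"linear"` or `"circular"`. Controls whether the ORF
#'   scanner wraps the origin.
#' @param genome_id Identifier of the genome this replicon belongs to
#'   (defaults to the replicon id).
#' @param molecule `"chromosome"` or `"plasmid"`; used only in group-level
#'   reporting.
#' @return An object of class `replicon`.
#' @export
replicon <- function(replicon_id, sequence,
                     topology = c("linear", "circular"),
                     genome_id = replicon_id,
                     molecule = c("chromosome", "plasmid")) {
  topology <- match.arg(topology)
  molecule <- match.arg(molecule)
  stopifnot(is.character(replicon_id), length(replicon_id) == 1L,
            nzchar(replicon_id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  sequence <- gsub("[^ACGTN]", "N", sequence)
  if (nchar(sequence) < 1L)
    stop("replicon '", replicon_id, "': sequence must have length >= 1")
  structure(
    list(replicon_id = replicon_id, sequence = sequence,
         topology = topology, genome_id = genome_id, molecule = molecule),
    class = "replicon")
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon %s: %d bp, %s, genome %s, %s>\n",
              x$replicon_id, nchar(x$sequence), x$topology, x$genome_id,
              x$molecule))
  invisible(x)
}

#' Read replicon sequences
#'
#' Reads one replicon per record from a FASTA or GenBank flat file.
#' FASTA descriptions may carry the tokens `circular` and `plasmid` to set
#' topology and molecule type; GenBank records take both from the LOCUS
#' line and the source/definition fields.
#'
#' @param path Path to the input file.
#' @param format `"fasta"` or `"genbank"`.
#' @return A named list of [replicon()] objects (possibly empty).
#' @export
read_replicons <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readDNAStringSet(path),
                    error = function(e)
                      stop("malformed FASTA in ", path, ": ",
                           conditionMessage(e)))
    if (length(set) == 0L) return(list())
    heads <- names(set)
    ids <- vapply(strsplit(heads, "\\s+"), `[[`, character(1), 1L)
    if (anyDuplicated(ids))
      stop("duplicate replicon id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    reps <- lapply(seq_along(set), function(i) {
      desc <- heads[i]
      replicon(
        replicon_id = ids[i],
        sequence = as.character(set[[i]]),
        topology = if (grepl("\\bcircular\\b", desc, ignore.case = TRUE))
          "circular" else "linear",
        molecule = if (grepl("\\bplasmid\\b", desc, ignore.case = TRUE))
          "plasmid" else "chromosome")
    })
    names(reps) <- ids
    reps
  } else {
    recs <- parse_genbank(path)
    if (length(recs) == 0L) return(list())
    ids <- vapply(recs, `[[`, character(1), "replicon_id")
    if (anyDuplicated(ids))
      stop("duplicate replicon id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    reps <- lapply(recs, function(r)
      replicon(r$replicon_id, r$sequence, r$topology, molecule = r$molecule))
    names(reps) <- ids
    reps
  }
}

# Minimal GenBank flat-file parser: LOCUS name/topology, FEATURES intervals
# and ORIGIN sequence. Qualifiers are ignored except /pseudo. join()
# locations are collapsed to their enclosing span (prokaryotic CDS are
# almost never compound; a warning is emitted when it happens).
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec_bounds <- c(0L, which(trimws(lines) == "//"))
  out <- list()
  for (k in seq_len(length(rec_bounds) - 1L)) {
    block <- lines[(rec_bounds[k] + 1L):(rec_bounds[k + 1L] - 1L)]
    block <- block[nzchar(trimws(block)) | seq_along(block) > 0]
    locus <- grep("^LOCUS", block, value = TRUE)
    if (length(locus) != 1L)
      stop("malformed GenBank record (missing LOCUS) in ", path,
           " [record ", k, "]")
    toks <- strsplit(trimws(locus), "\\s+")[[1]]
    id <- toks[2]
    topo <- if (any(tolower(toks) == "circular")) "circular" else "linear"
    def <- grep("^DEFINITION", block, value = TRUE)
    molecule <- if (length(def) &&
                    grepl("plasmid", def[1], ignore.case = TRUE))
      "plasmid" else "chromosome"

    ori <- grep("^ORIGIN", block)
    if (length(ori) != 1L)
      stop("malformed GenBank record '", id, "' (missing ORIGIN)")
    seq_lines <- block[(ori + 1L):length(block)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

    feats <- data.frame(replicon_id = character(0), kind = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
    fstart <- grep("^FEATURES", block)
    if (length(fstart) == 1L) {
      fend <- ori - 1L
      flines <- block[(fstart + 1L):fend]
      # Feature keys sit at column 6; continuation/qualifier lines at 22.
      key_idx <- grep("^ {5}\\S", flines)
      for (j in seq_along(key_idx)) {
        ln <- flines[key_idx[j]]
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        key <- parts[1]
        if (key == "source") next
        loc <- paste(parts[-1], collapse = "")
        upto <- if (j < length(key_idx)) key_idx[j + 1L] - 1L
                else length(flines)
        qual <- flines[key_idx[j]:upto]
        pseudo <- any(grepl("/pseudo\\b", qual))
        # continuation of a multi-line location (rare) -- append lines that
        # are location-like (no '/'):
        extra <- qual[-1]
        extra <- extra[!grepl("/", extra)]
        if (length(extra)) loc <- paste0(loc, gsub("\\s+", "", extra))
        strand <- if (grepl("complement", loc)) "-" else "+"
        if (grepl("join|order", loc))
          warning("GenBank compound location collapsed to its span: ", loc)
        nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
        if (length(nums) < 2L) next
        a <- min(nums); b <- max(nums)
        kind <- genbank_kind(key, pseudo)
        feats <- rbind(feats, data.frame(
          replicon_id = id, kind = kind, start = a - 1L, end = b,
          strand = strand, stringsAsFactors = FALSE))
      }
    }
    out[[length(out) + 1L]] <- list(
      replicon_id = id, sequence = seq, topology = topo,
      molecule = molecule, features = feats)
  }
  out
}

genbank_kind <- function(key, pseudo = FALSE) {
  if (pseudo) return("pseudogene")
  switch(key,
         CDS = "gene", gene = "gene",
         tRNA = "rna", rRNA = "rna", ncRNA = "rna", tmRNA = "rna",
         misc_RNA = "rna",
         pseudogene = "pseudogene",
         "other")
}
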