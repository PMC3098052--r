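# Internal helpers shared across modules.

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the alphabet A/C/G/T/N (case is
#' preserved for upper-case input; ambiguity codes other than N are mapped
#' through unchanged complement pairs where defined).
#'
#' @param x A single DNA string.
#' @return The reverse complement as a character scalar.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# Split a sequence into consecutive codons starting at 1-based offset
# `frame + 1`. Trailing bases that do not fill a codon are dropped.
split_codons <- function(seq, frame = 0L) {
  n <- nchar(seq)
  first <- frame + 1L
  if (n - frame < 3L) return(character(0))
  starts <- seq.int(first, n - 2L, by = 3L)
  substring(seq, starts, starts + 2L)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# 1-based inclusive rendering of an internal 0-based half-open interval.
to_1based <- function(start0, end0) list(start = start0 + 1L, end = end0)

# Deterministic ORF identifier: replicon|strand|start-end in the emitted
# 1-based inclusive convention.
orf_identifier <- function(replicon_id, strand, start0, end0) {
  sprintf("%s|%s|%d-%d", replicon_id, strand, start0 + 1L, end0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
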