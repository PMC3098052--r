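# The alpha uniqueness score: how unambiguously a query's alignments
# support its classification.
#
# alpha = I1 - I2, where I1 is the highest average percent identity I
# over the alignments supporting the classification and I2 the highest I
# over the alignments indicating a different one. With no conflicting
# alignments alpha equals I1. For missing genes the conflict set is every
# hit to an annotated gene or entity-overlapping ORF; for absent
# annotations only hits to entity-overlapping ORFs conflict -- gene-hit I
# values never enter I2 for absent annotations, even when larger.

#' Alpha uniqueness score of a classification
#'
#' @param label `"missing_gene"` or `"absent_annotation"` (the two labels
#'   that carry an alpha score).
#' @param supporting Non-empty `alignment_hits` subset supporting the
#'   classification.
#' @param conflicting `alignment_hits` subset indicating a different
#'   classification (may be empty or NULL).
#' @return The alpha score (percentage points, at most 100; unclamped
#'   below, so it can in principle be negative).
#' @export
alpha_score <- function(label = c("missing_gene", "absent_annotation"),
                        supporting, conflicting = NULL) {
  label <- match.arg(label)
  if (is.null(supporting) || nrow(supporting) == 0L)
    stop("alpha is undefined without supporting alignments (label '",
         label, "' requires at least one)")
  i1 <- max(supporting$I)
  if (is.null(conflicting) || nrow(conflicting) == 0L) return(i1)
  i1 - max(conflicting$I)
}

#' Average alpha score of a missing-gene group
#'
#' @param alphas Numeric vector of the members' alpha scores.
#' @return Their arithmetic mean.
#' @export
group_alpha <- function(alphas) {
  stopifnot(length(alphas) >= 1L, !anyNA(alphas))
  mean(alphas)
}
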