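#' Reference-quality index for read-mapping reference choice
#'
#' Combines annotation completeness, the proportion of properly paired
#' read pairs, and the mean Phred-scaled mapping quality into a single
#' score in `[0, 1]`:
#' `completeness * p_proper * (1 - 10^(-mean_mapq / 10))`,
#' the last factor being the probability that a read with the given MAPQ
#' is correctly placed.
#'
#' @param completeness Annotation completeness fraction in `[0, 1]`.
#' @param p_proper Proportion of properly mapped read pairs in `[0, 1]`.
#' @param mean_mapq Mean mapping quality (Phred scale, >= 0).
#' @param literal If `TRUE`, evaluate the uncorrected expression
#'   `completeness * p_proper * (1 - 10^mean_mapq)` instead (for audit
#'   against sources that print the index without the Phred rescaling;
#'   note it is negative for any positive MAPQ). Default `FALSE`.
#' @return The index (vectorized over inputs).
#' @export
reference_quality_index <- function(completeness, p_proper, mean_mapq,
                                    literal = FALSE) {
  if (any(completeness < 0 | completeness > 1))
    stop("completeness must be in [0, 1]")
  if (any(p_proper < 0 | p_proper > 1))
    stop("p_proper must be in [0, 1]")
  if (any(mean_mapq < 0)) stop("mean_mapq must be >= 0")
  if (literal)
    return(completeness * p_proper * (1 - 10^mean_mapq))
  completeness * p_proper * (1 - 10^(-mean_mapq / 10))
}

#' Choose the best reference genome from mapping summaries
#'
#' Ranks candidate references by [reference_quality_index()] and returns
#' the argmax; ties are broken by higher completeness, then by lexical
#' reference id, so the choice is deterministic and order-invariant.
#'
#' @param summaries Data frame with columns `reference, completeness,
#'   p_proper, mean_mapq` (unique reference ids).
#' @return List with `reference` (chosen id) and `ranking` (the input with
#'   an `index` column, sorted best-first).
#' @export
choose_reference <- function(summaries) {
  need <- c("reference", "completeness", "p_proper", "mean_mapq")
  if (!is.data.frame(summaries) || !nrow(summaries))
    stop("summaries must be a non-empty data frame")
  miss <- setdiff(need, names(summaries))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(summaries$reference))
    stop("reference ids must be unique")
  idx <- reference_quality_index(summaries$completeness,
                                 summaries$p_proper,
                                 summaries$mean_mapq)
  ord <- order(-idx, -summaries$completeness, summaries$reference)
  ranking <- summaries[ord, , drop = FALSE]
  ranking$index <- idx[ord]
  rownames(ranking) <- NULL
  list(reference = ranking$reference[1L], ranking = ranking)
}
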