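ALIGN_SCORING <- list(match = 1, mismatch = -1, gap_open = -2,
                      gap_extend = -1)

#' Maximal-scoring local alignment of two DNA sequences
#'
#' Smith–Waterman local alignment with match +1, mismatch −1 and affine
#' gaps (−2 to open, −1 per additional gapped base), computed with
#' [Biostrings::pairwiseAlignment()]. When nothing aligns (best score
#' would be negative), an empty alignment of score 0 is returned.
#'
#' @param query,target DNA as character or `DNAString`; both non-empty.
#' @return list with `score`, `identity` (matched fraction of aligned
#'   columns, 0 for an empty alignment), `query_range` and
#'   `target_range` ([IRanges::IRanges], zero-width for an empty
#'   alignment) and `aligned_width` (aligned columns).
#' @export
alignLocal <- function(query, target) {
  q <- if (is.character(query)) normalizeDNA(query, "query") else
    as.character(query)
  t <- if (is.character(target)) normalizeDNA(target, "target") else
    as.character(target)
  if (nchar(q) == 0L || nchar(t) == 0L)
    stop("alignLocal: empty input sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = ALIGN_SCORING$match, mismatch = ALIGN_SCORING$mismatch,
    baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(q, t, type = "local",
          substitutionMatrix = mat,
          gapOpening = 1, gapExtension = 1)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(list(score = 0,
                identity = 0,
                query_range = IRanges::IRanges(1L, 0L),
                target_range = IRanges::IRanges(1L, 0L),
                aligned_width = 0L))
  }
  pr <- pa@pattern@range
  sr <- pa@subject@range
  aw <- nchar(as.character(Biostrings::alignedPattern(pa)))
  list(score = sc,
       identity = Biostrings::pid(pa) / 100,
       query_range = IRanges::IRanges(BiocGenerics::start(pr),
                                      BiocGenerics::end(pr)),
       target_range = IRanges::IRanges(BiocGenerics::start(sr),
                                       BiocGenerics::end(sr)),
       aligned_width = aw)
}
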