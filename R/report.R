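.groupingVector <- function(catalog, what) {
  switch(what,
    chromosome = as.character(GenomicRanges::seqnames(catalog)),
    class = as.character(catalog$class),
    length_bin = as.character(catalog$length_bin),
    hexamer_flag = ifelse(catalog$hexamer_flag, "3+ hexamers",
                          "<3 hexamers"),
    context = as.character(catalog$context),
    annotation_status = as.character(catalog$annotation_status),
    stop("unknown grouping: ", what))
}

#' Census / contingency tables over a classified catalog
#'
#' Cross-tabulates a catalog by any two of chromosome, class, length
#' bin, hexamer flag, insertion context or annotation status, and adds
#' `Total` margins. Margins are conserved: every per-row and per-column
#' total equals the sum of its cells, and the grand total equals the
#' catalog size.
#'
#' @param catalog classified `GRanges` catalog.
#' @param rows,cols grouping keys; each one of `"chromosome"`,
#'   `"class"`, `"length_bin"`, `"hexamer_flag"`, `"context"`,
#'   `"annotation_status"`.
#' @param rowLevels,colLevels optional explicit level orderings (e.g.
#'   chromosome order with `"Unknown"` last).
#' @return integer matrix with `Total` margin row and column.
#' @export
summarizeCounts <- function(catalog, rows = "chromosome", cols = "class",
                            rowLevels = NULL, colLevels = NULL) {
  if (length(catalog) == 0L) {
    m <- matrix(0L, 1L, 1L, dimnames = list("Total", "Total"))
    return(m)
  }
  rv <- .groupingVector(catalog, rows)
  cv <- .groupingVector(catalog, cols)
  if (is.null(rowLevels)) rowLevels <- sort(unique(rv))
  if (is.null(colLevels)) colLevels <- sort(unique(cv))
  tab <- table(factor(rv, levels = rowLevels),
               factor(cv, levels = colLevels))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m <- rbind(m, Total = colSums(m))
  cbind(m, Total = rowSums(m))
}

#' Per-class percentage of a census column
#'
#' Rounded percentages of one column of a census table relative to the
#' per-class totals (e.g. the percentage of each class inserted in or
#' within 200 bp of a gene).
#'
#' @param tab matrix from [summarizeCounts()] with a `Total` column.
#' @param column column name to express as a percentage of the row
#'   totals.
#' @param digits rounding digits (default 0, as printed).
#' @return named numeric vector of percentages (margin row excluded).
#' @export
percentOfTotal <- function(tab, column, digits = 0) {
  rows <- setdiff(rownames(tab), "Total")
  round(100 * tab[rows, column] / tab[rows, "Total"], digits)
}

#' Chi-square test of element counts against chromosome length
#'
#' Tests whether per-chromosome element counts follow chromosome
#' length, with expected counts proportional to length
#' (`expected_i = total * length_i / sum(lengths)`). Delegates to
#' [stats::chisq.test()]; `df = #chromosomes - 1`. Unplaced/scaffold
#' counts must be excluded by the caller.
#'
#' @param observed named integer vector of per-chromosome counts.
#' @param chromLengths named numeric vector of chromosome lengths
#'   (same names).
#' @return list with `chi2`, `df`, `p_value`, `expected`.
#' @export
chiSquareDistribution <- function(observed, chromLengths) {
  if (!setequal(names(observed), names(chromLengths)))
    stop("observed and chromLengths must cover the same chromosomes")
  chromLengths <- chromLengths[names(observed)]
  if (any(chromLengths <= 0)) stop("zero-length chromosome")
  ht <- suppressWarnings(
    chisq.test(observed, p = chromLengths / sum(chromLengths)))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' Compare a catalog against a prior annotation
#'
#' Labels every element `full` when some prior feature reciprocally
#' overlaps it by at least `reciprocal` (both directions), `partial`
#' when any overlap exists below that, and `new` otherwise.
#'
#' @param catalog `GRanges` element catalog.
#' @param prior `GRanges` of previously annotated features on the same
#'   assembly.
#' @param reciprocal reciprocal-overlap fraction for `full`
#'   (default 0.9).
#' @return character vector of statuses, one per catalog element.
#' @export
compareToAnnotation <- function(catalog, prior, reciprocal = 0.9) {
  n <- length(catalog)
  status <- rep("new", n)
  if (n == 0L || length(prior) == 0L) return(status)
  ov <- GenomicRanges::findOverlaps(catalog, prior, ignore.strand = TRUE)
  if (length(ov) == 0L) return(status)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  inter <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(catalog)[qh], IRanges::ranges(prior)[sh]))
  fullhit <- inter >= reciprocal * IRanges::width(catalog)[qh] &
             inter >= reciprocal * IRanges::width(prior)[sh]
  status[unique(qh)] <- "partial"
  status[unique(qh[fullhit])] <- "full"
  status
}
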