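#' Classification thresholds
#'
#' Tunable thresholds of the structural decision cascade. The published
#' class definitions are qualitative ("~200 bp of the subterminal
#' region", "about 30 bp at either end", "a large amount of
#' similarity"); these defaults separate the class archetypes with wide
#' margins and are all overridable.
#'
#' @param acFullCov minimum aligned fraction of the whole reference for
#'   an Ac-like call.
#' @param acIdentity minimum alignment identity for an Ac-like call.
#' @param strCov minimum aligned fraction of each 200-bp subterminal
#'   region for a Ds2 call.
#' @param exonCov minimum aligned fraction of the transposase exon-2/3
#'   segment for a Ds-l3 call.
#' @param exonBlock minimum aligned block length (bp) supporting a
#'   Ds-l3 call.
#' @param ds1MaxLen length ceiling for Ds1 (known Ds1 are < 500 bp).
#' @param ds1Identity,ds1Block identity and block-length floor of the
#'   Ds1 family-consensus match.
#' @param termMax maximum terminal homology run (bp) for Ds-l4 (and the
#'   consensus-free Ds1 fallback).
#' @param minCovScore minimum local-alignment score for a segment
#'   alignment to count towards coverage at all (suppresses the short
#'   spurious alignments any pair of random sequences has).
#' @param termWindow,termIdentity window size and per-window identity
#'   of the ungapped terminal extension.
#' @return named list of thresholds.
#' @export
classifyThresholds <- function(acFullCov = 0.9, acIdentity = 0.9,
                               strCov = 0.5, exonCov = 0.1,
                               exonBlock = 200L, ds1MaxLen = 500L,
                               ds1Identity = 0.7, ds1Block = 100L,
                               termMax = 40L, minCovScore = 25,
                               termWindow = 10L, termIdentity = 0.8) {
  list(acFullCov = acFullCov, acIdentity = acIdentity, strCov = strCov,
       exonCov = exonCov, exonBlock = exonBlock, ds1MaxLen = ds1MaxLen,
       ds1Identity = ds1Identity, ds1Block = ds1Block, termMax = termMax,
       minCovScore = minCovScore, termWindow = termWindow,
       termIdentity = termIdentity)
}

## ungapped terminal identity run between two character sequences,
## compared window-wise from position 1; stops at the first window
## below the identity floor and adds the leading match run inside it
.terminalRun <- function(a, b, window = 10L, identity = 0.8) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "")[[1]]
  bv <- strsplit(substr(b, 1L, n), "")[[1]]
  eq <- av == bv & av != "N"
  run <- 0L
  i <- 1L
  while (i <= n) {
    j <- min(i + window - 1L, n)
    w <- eq[i:j]
    if (mean(w) >= identity) {
      run <- j
      i <- j + 1L
    } else {
      lead <- which(!w)[1] - 1L
      run <- run + lead
      break
    }
  }
  as.integer(run)
}

## coverage of a reference segment by the best local alignment of the
## element against it; 0 unless the alignment clears the score floor
.segCoverage <- function(elemSeq, segSeq, minScore) {
  al <- alignLocal(elemSeq, segSeq)
  if (al$score < minScore)
    return(list(cov = 0, block = 0L, identity = 0))
  list(cov = IRanges::width(al$target_range) / nchar(segSeq),
       block = IRanges::width(al$target_range),
       identity = al$identity)
}

#' Homology profile of an element against the reference Ac
#'
#' Measures which parts of the reference Activator element survive in a
#' called element: the contiguous terminal identity runs at the 5' and
#' 3' ends (ungapped window-wise extension at >= 80% identity, stopping
#' at the first failing window), the aligned fraction of each ~200-bp
#' subterminal region, of the transposase exon-2/3 segment, and of the
#' whole reference, all via [alignLocal()].
#'
#' @param call single-element `GRanges` row (an element call).
#' @param genome `DNAStringSet` the call refers to.
#' @param acRef an [AcReference-class].
#' @param thresholds list from [classifyThresholds()].
#' @return list with `term5_len`, `term3_len`, `str5_cov`, `str3_cov`,
#'   `exon23_cov`, `exon23_block`, `full_cov`, `best_identity`.
#' @export
homologyProfile <- function(call, genome, acRef,
                            thresholds = classifyThresholds()) {
  th <- thresholds
  sid <- as.character(GenomicRanges::seqnames(call))[1]
  s <- BiocGenerics::start(call)[1]; e <- BiocGenerics::end(call)[1]
  if (e - s + 1L < 22L) stop("element shorter than two TIRs (22 bp)")
  elem <- gseq(genome, sid, s, e)
  ref <- as.character(refSeq(acRef))
  term5 <- .terminalRun(elem, ref, th$termWindow, th$termIdentity)
  term3 <- .terminalRun(revComp(elem), revComp(ref),
                        th$termWindow, th$termIdentity)
  str5 <- .segCoverage(elem, refSegmentSeq(acRef, "str5"), th$minCovScore)
  str3 <- .segCoverage(elem, refSegmentSeq(acRef, "str3"), th$minCovScore)
  ex <- .segCoverage(elem, refSegmentSeq(acRef, "exon23"), th$minCovScore)
  full <- .segCoverage(elem, ref, th$minCovScore)
  list(term5_len = term5, term3_len = term3,
       str5_cov = str5$cov, str3_cov = str3$cov,
       exon23_cov = ex$cov, exon23_block = ex$block,
       full_cov = full$cov, best_identity = full$identity)
}

#' Count subterminal hexamers
#'
#' Counts occurrences of the transposase-binding hexamer (AAACGG) in
#' the two subterminal windows of an element, reading inward from each
#' end on the element's own strand: the 5' window is the first
#' `window` bp as-is, the 3' window is the reverse complement of the
#' last `window` bp. For elements shorter than `2 * window` the two
#' windows are the element halves.
#'
#' @param call single-element `GRanges` row.
#' @param genome `DNAStringSet`.
#' @param hexamer 6-mer motif (default [hexamerMotif()]).
#' @param window subterminal window size in bp (default 200).
#' @return integer vector `c(hexamers5, hexamers3)`.
#' @export
countHexamers <- function(call, genome, hexamer = hexamerMotif(),
                          window = 200L) {
  sid <- as.character(GenomicRanges::seqnames(call))[1]
  s <- BiocGenerics::start(call)[1]; e <- BiocGenerics::end(call)[1]
  len <- e - s + 1L
  w <- if (len < 2L * window) len %/% 2L else window
  elem <- gseq(genome, sid, s, e)
  w5 <- substr(elem, 1L, w)
  w3 <- revComp(substr(elem, len - w + 1L, len))
  cnt <- function(x) {
    if (nchar(x) < nchar(hexamer)) return(0L)
    Biostrings::countPattern(hexamer, Biostrings::DNAString(x))
  }
  c(hexamers5 = cnt(w5), hexamers3 = cnt(w3))
}

#' Assign a structural class label
#'
#' First-match-wins decision cascade over the homology profile:
#' \enumerate{
#'   \item \strong{Ac-like}: nearly full-length reference homology
#'     (`full_cov >= 0.9` at identity `>= 0.9`) — the reference save
#'     for small indels;
#'   \item \strong{Ds2}: both ~200-bp subterminal regions retained
#'     (`str5_cov` and `str3_cov >= 0.5`);
#'   \item \strong{Ds-l3}: a transposase exon-2/3 fragment retained
#'     (`exon23_cov >= 0.1` over an aligned block of >= 200 bp);
#'   \item \strong{Ds1}: shorter than 500 bp and matching the supplied
#'     Ds1 family consensus (identity >= 0.7 over >= 100 bp); without a
#'     consensus, the fallback is length < 500 bp with terminal runs
#'     <= 40 bp (warned once);
#'   \item \strong{Ds-l4}: homology confined to the termini
#'     (`term5_len` and `term3_len <= 40`);
#'   \item \strong{unclassified} otherwise.
#' }
#'
#' @param profile list from [homologyProfile()].
#' @param call single-element `GRanges` row (for its length).
#' @param genome `DNAStringSet` (needed for the Ds1 consensus match).
#' @param ds1Consensus optional Ds1 family consensus (character or
#'   `DNAString`).
#' @param thresholds list from [classifyThresholds()].
#' @return character class label.
#' @export
assignClass <- function(profile, call, genome, ds1Consensus = NULL,
                        thresholds = classifyThresholds()) {
  th <- thresholds
  p <- profile
  len <- IRanges::width(call)[1]
  if (p$full_cov >= th$acFullCov && p$best_identity >= th$acIdentity)
    return("Ac-like")
  if (p$str5_cov >= th$strCov && p$str3_cov >= th$strCov)
    return("Ds2")
  if (p$exon23_cov >= th$exonCov && p$exon23_block >= th$exonBlock)
    return("Ds-l3")
  if (len < th$ds1MaxLen) {
    if (!is.null(ds1Consensus)) {
      sid <- as.character(GenomicRanges::seqnames(call))[1]
      elem <- gseq(genome, sid, BiocGenerics::start(call)[1],
                   BiocGenerics::end(call)[1])
      al <- alignLocal(elem, as.character(ds1Consensus))
      if (al$identity >= th$ds1Identity &&
          al$aligned_width >= th$ds1Block)
        return("Ds1")
    } else if (p$term5_len <= th$termMax && p$term3_len <= th$termMax) {
      return("Ds1")
    }
  }
  if (p$term5_len <= th$termMax && p$term3_len <= th$termMax)
    return("Ds-l4")
  "unclassified"
}

LENGTH_BINS <- c("<500", "500-1000", "1000-5000", ">5000")

lengthBin <- function(len) {
  LENGTH_BINS[findInterval(len, c(-Inf, 500, 1000, 5000))]
}

#' Classify a whole element catalog
#'
#' Runs [homologyProfile()], [countHexamers()] and [assignClass()] over
#' every call and appends the results as metadata columns:
#' profile fields, `hexamers5`/`hexamers3`, `hexamer_flag` (3 or more
#' hexamers pooled over both subterminal windows — the mobility-
#' associated criterion; per-end counts are kept alongside),
#' `length_bin` and `class`.
#'
#' @param catalog `GRanges` element catalog from [pairCandidates()].
#' @param genome `DNAStringSet`.
#' @param acRef [AcReference-class].
#' @param ds1Consensus optional Ds1 family consensus sequence; when
#'   absent the Ds1 rule degrades to its length + terminal-run fallback
#'   with a warning.
#' @param thresholds list from [classifyThresholds()].
#' @param hexamerWindow subterminal window for hexamer counting.
#' @return the catalog `GRanges` with classification mcols added.
#' @export
classifyCatalog <- function(catalog, genome, acRef, ds1Consensus = NULL,
                            thresholds = classifyThresholds(),
                            hexamerWindow = 200L) {
  n <- length(catalog)
  if (is.null(ds1Consensus))
    warning("no Ds1 family consensus supplied; ",
            "Ds1 assigned by length + terminal-run fallback")
  cols <- list(term5_len = integer(n), term3_len = integer(n),
               str5_cov = numeric(n), str3_cov = numeric(n),
               exon23_cov = numeric(n), full_cov = numeric(n),
               best_identity = numeric(n), hexamers5 = integer(n),
               hexamers3 = integer(n), hexamer_flag = logical(n),
               length_bin = character(n), class = character(n))
  for (i in seq_len(n)) {
    call <- catalog[i]
    p <- homologyProfile(call, genome, acRef, thresholds)
    hx <- countHexamers(call, genome, hexamer = acRef@hexamer,
                        window = hexamerWindow)
    cols$term5_len[i] <- p$term5_len; cols$term3_len[i] <- p$term3_len
    cols$str5_cov[i] <- p$str5_cov; cols$str3_cov[i] <- p$str3_cov
    cols$exon23_cov[i] <- p$exon23_cov; cols$full_cov[i] <- p$full_cov
    cols$best_identity[i] <- p$best_identity
    cols$hexamers5[i] <- hx[1]; cols$hexamers3[i] <- hx[2]
    cols$hexamer_flag[i] <- sum(hx) >= 3L
    cols$length_bin[i] <- lengthBin(IRanges::width(call))
    cols$class[i] <- assignClass(p, call, genome, ds1Consensus,
                                 thresholds)
  }
  for (nm in names(cols)) S4Vectors::mcols(catalog)[[nm]] <- cols[[nm]]
  catalog
}
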