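#' Scan a genome for TIR motif hits
#'
#' Finds every 11-bp window whose degenerate-aware Hamming distance to
#' one of the Ac/Ds TIR motifs is at most `maxMismatch`. The degenerate
#' terminal position (`[C/T]AGGGATGAAA` / `TTTCATCCCT[A/G]`) matches its
#' allowed set at zero cost. Because the two TIR motifs are exact
#' reverse complements, every genomic match is reported for both element
#' orientations: a forward-strand `YAGGGATGAAA` match is emitted as a
#' `five_prime` hit of a plus-strand element and as a `three_prime` hit
#' of a minus-strand element (and symmetrically for `TTTCATCCCTR`).
#' Windows overlapping `N` are discarded.
#'
#' @param genome [Biostrings::DNAStringSet] (or a FASTA path).
#' @param maxMismatch integer mismatch budget in `{0,1,2}`.
#' @param motifs length-2 named character vector of 11-mers (IUPAC
#'   degeneracies allowed); default [tirMotifs()].
#' @return `GRanges` of 11-bp hits, sorted, with mcols `end_type`
#'   (`five_prime`/`three_prime` in element orientation), `mismatches`
#'   and `matched_seq`; the range strand is the element strand.
#' @export
scanTIR <- function(genome, maxMismatch = 2L, motifs = tirMotifs()) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- readGenome(genome)
  if (!maxMismatch %in% 0:2) stop("maxMismatch must be 0, 1 or 2")
  if (any(nchar(motifs) != 11L)) stop("TIR motifs must be 11 bp")
  out <- list()
  for (sid in names(genome)) {
    subj <- genome[[sid]]
    for (which5 in c(TRUE, FALSE)) {
      motif <- unname(if (which5) motifs["five_prime"] else
                        motifs["three_prime"])
      m <- Biostrings::matchPattern(Biostrings::DNAString(motif), subj,
             max.mismatch = maxMismatch,
             fixed = c(pattern = FALSE, subject = TRUE))
      if (length(m) == 0L) next
      words <- as.character(m)
      keep <- !grepl("N", words, fixed = TRUE)
      if (!any(keep)) next
      st <- BiocGenerics::start(m)[keep]
      words <- words[keep]
      mm <- vapply(words, degenerateMismatch, integer(1), motif = motif,
                   USE.NAMES = FALSE)
      keep2 <- mm <= maxMismatch
      if (!any(keep2)) next
      st <- st[keep2]; words <- words[keep2]; mm <- mm[keep2]
      n <- length(st)
      ## each genomic match is a terminus of one element per strand
      gr <- GenomicRanges::GRanges(rep(sid, 2L * n),
              IRanges::IRanges(rep(st, 2L), width = 11L),
              strand = rep(c("+", "-"), each = n))
      gr$end_type <- if (which5)
        rep(c("five_prime", "three_prime"), each = n) else
        rep(c("three_prime", "five_prime"), each = n)
      gr$mismatches <- rep(mm, 2L)
      gr$matched_seq <- rep(words, 2L)
      out[[length(out) + 1L]] <- gr
    }
  }
  if (length(out) == 0L) {
    res <- GenomicRanges::GRanges()
    res$end_type <- character(); res$mismatches <- integer()
    res$matched_seq <- character()
    return(res)
  }
  res <- suppressWarnings(do.call(c, unname(out)))
  GenomicRanges::sort(res, ignore.strand = TRUE)
}

#' Target-site-duplication evidence at candidate element boundaries
#'
#' Extracts the 8-mers immediately outside `[start, end]` and returns
#' them with their Hamming distance. The TSD is host sequence, so any
#' 8-bp word qualifies; only agreement of the two copies is scored.
#'
#' @param genome `DNAStringSet`.
#' @param seqid sequence identifier.
#' @param start,end 1-based inclusive element boundaries (TIR-inclusive).
#' @param maxMismatch admission bound on the Hamming distance.
#' @return list with `left_word`, `right_word`, `mismatches`, or `NULL`
#'   when a flank runs off the sequence or the distance exceeds
#'   `maxMismatch` (absence is a value, not an error).
#' @export
detectTSD <- function(genome, seqid, start, end, maxMismatch = 2L) {
  L <- Biostrings::width(genome)[match(seqid, names(genome))]
  if (is.na(L)) stop("unknown sequence: ", seqid)
  if (start - 8L < 1L || end + 8L > L) return(NULL)
  left <- gseq(genome, seqid, start - 8L, start - 1L)
  right <- gseq(genome, seqid, end + 1L, end + 8L)
  mm <- hammingDist(left, right)
  if (mm > maxMismatch) return(NULL)
  list(left_word = left, right_word = right, mismatches = mm)
}

## enumerate candidate (five, three) pairings as a data.frame
.candidatePairs <- function(hits, genome, minLen, maxLen,
                            tsdMaxMismatch, maxScore, requireTsd) {
  ## TIR grammar is strand-symmetric: pair left YAGGGATGAAA-class ends
  ## with right TTTCATCCCTR-class ends once, on the plus sense
  h5 <- hits[hits$end_type == "five_prime" &
             BiocGenerics::strand(hits) == "+"]
  h3 <- hits[hits$end_type == "three_prime" &
             BiocGenerics::strand(hits) == "+"]
  rows <- list()
  for (sid in unique(as.character(GenomicRanges::seqnames(h5)))) {
    a <- h5[GenomicRanges::seqnames(h5) == sid]
    b <- h3[GenomicRanges::seqnames(h3) == sid]
    if (length(a) == 0L || length(b) == 0L) next
    bstart <- BiocGenerics::start(b)
    ord <- order(bstart)
    b <- b[ord]; bstart <- bstart[ord]
    for (i in seq_along(a)) {
      s <- BiocGenerics::start(a)[i]
      lo <- findInterval(s + minLen - 11L - 0.5, bstart) + 1L
      if (lo > length(b)) next
      for (j in lo:length(b)) {
        e <- bstart[j] + 10L
        len <- e - s + 1L
        if (len < minLen || bstart[j] <= s + 10L) next
        if (len > maxLen) break
        tirScore <- a$mismatches[i] + b$mismatches[j]
        if (tirScore > maxScore) next
        if (!requireTsd) {
          ## no-TSD mode: TSD evidence neither gates nor scores
          tsdw <- NA_character_; tsdmm <- NA_integer_; score <- tirScore
        } else {
          tsd <- detectTSD(genome, sid, s, e, maxMismatch = tsdMaxMismatch)
          if (is.null(tsd) || tirScore + tsd$mismatches > maxScore) next
          tsdw <- tsd$left_word; tsdmm <- tsd$mismatches
          score <- tirScore + tsdmm
        }
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = sid, start = s, end = e, length = len,
          tir5_mismatches = a$mismatches[i],
          tir3_mismatches = b$mismatches[j],
          tsd = tsdw, tsd_mismatches = tsdmm, score = score,
          id5 = paste0(sid, ":", s), id3 = paste0(sid, ":", bstart[j]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

.callsToGRanges <- function(df) {
  if (is.null(df) || nrow(df) == 0L) {
    gr <- GenomicRanges::GRanges()
    for (col in c("element_id", "tsd"))
      S4Vectors::mcols(gr)[[col]] <- character()
    for (col in c("tir5_mismatches", "tir3_mismatches", "tsd_mismatches",
                  "score"))
      S4Vectors::mcols(gr)[[col]] <- integer()
    return(gr)
  }
  gr <- GenomicRanges::GRanges(df$seqid,
          IRanges::IRanges(df$start, df$end), strand = "*")
  gr$element_id <- paste0("element_", seq_len(nrow(df)))
  gr$tir5_mismatches <- df$tir5_mismatches
  gr$tir3_mismatches <- df$tir3_mismatches
  gr$tsd <- df$tsd
  gr$tsd_mismatches <- df$tsd_mismatches
  gr$score <- df$score
  gr
}

#' Pair TIR hits into element calls
#'
#' Evaluates, for every left (5'-motif) hit, all right (3'-motif) hits
#' within the allowed length window, admits a pairing when the flanking
#' 8-mers agree within the TSD budget (or `requireTsd = FALSE`) and the
#' combined mismatch score (`tir5 + tir3 + tsd`) does not exceed
#' `maxScore`, then resolves competition for a shared TIR hit
#' innermost-first (shortest span), then by lowest score, then leftmost.
#' A TIR hit supports at most one call, but nested elements use four
#' distinct hits and are therefore both reported. Element orientation is
#' not determined by the TIR grammar alone (both strand assignments are
#' always simultaneously consistent), so calls carry strand `*`.
#'
#' @param hits `GRanges` from [scanTIR()] on the same genome.
#' @param genome `DNAStringSet` the hits were found in.
#' @param minLen,maxLen admissible element span in bp (TIR-inclusive).
#'   The default ceiling of 30 kb accommodates elements inflated by
#'   retrotransposon cargo (observed up to 24 kb).
#' @param tsdMaxMismatch Hamming budget between the two TSD copies.
#' @param maxScore combined budget on `tir5 + tir3 + tsd` mismatches.
#' @param requireTsd when `FALSE`, calls without TSD evidence are
#'   admitted (`tsd` = `NA`); used by [rescueNoTSD()].
#' @return sorted `GRanges` of element calls with mcols `element_id`,
#'   `tir5_mismatches`, `tir3_mismatches`, `tsd`, `tsd_mismatches`,
#'   `score`.
#' @export
pairCandidates <- function(hits, genome, minLen = 50L, maxLen = 30000L,
                           tsdMaxMismatch = 2L, maxScore = 2L,
                           requireTsd = TRUE) {
  df <- .candidatePairs(hits, genome, minLen, maxLen, tsdMaxMismatch,
                        maxScore, requireTsd)
  if (is.null(df)) return(.callsToGRanges(NULL))
  df <- df[!duplicated(df[, c("seqid", "start", "end")]), , drop = FALSE]
  df <- df[order(df$length, df$score, df$start), , drop = FALSE]
  used <- character()
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (df$id5[i] %in% used || df$id3[i] %in% used) next
    keep[i] <- TRUE
    used <- c(used, df$id5[i], df$id3[i])
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$seqid, df$start, df$end), , drop = FALSE]
  gr <- .callsToGRanges(df)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' One-call discovery scan
#'
#' Convenience wrapper: [scanTIR()] followed by [pairCandidates()].
#'
#' @inheritParams pairCandidates
#' @param genome `DNAStringSet` or FASTA path.
#' @param tirMaxMismatch per-TIR mismatch budget passed to [scanTIR()].
#' @param ... passed to [pairCandidates()].
#' @return `GRanges` element catalog.
#' @export
scanElements <- function(genome, tirMaxMismatch = 2L, ...) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- readGenome(genome)
  hits <- scanTIR(genome, maxMismatch = tirMaxMismatch)
  pairCandidates(hits, genome, ...)
}

#' Rescue elements lacking a target-site duplication
#'
#' Re-runs pairing with the TSD requirement removed and returns only
#' calls that do not overlap the primary catalog. Because TSD agreement
#' is the main specificity filter, the rescue pass demands perfect TIRs
#' by default. Each rescued call is annotated with the identity of its
#' flanking 8-mers (`flank_identity` out of 8).
#'
#' @param genome `DNAStringSet`.
#' @param primary `GRanges` primary catalog (TSD-validated calls).
#' @param tirMaxMismatch per-TIR budget for the rescue scan (default 0).
#' @param minLen,maxLen,maxScore as in [pairCandidates()].
#' @return `GRanges` of rescued calls with `flank_identity` mcol.
#' @export
rescueNoTSD <- function(genome, primary, tirMaxMismatch = 0L,
                        minLen = 50L, maxLen = 30000L, maxScore = 2L) {
  hits <- scanTIR(genome, maxMismatch = tirMaxMismatch)
  calls <- pairCandidates(hits, genome, minLen = minLen, maxLen = maxLen,
                          tsdMaxMismatch = 8L, maxScore = maxScore,
                          requireTsd = FALSE)
  if (length(calls) && length(primary)) {
    ov <- GenomicRanges::findOverlaps(calls, primary, ignore.strand = TRUE)
    if (length(ov)) calls <- calls[-unique(S4Vectors::queryHits(ov))]
  }
  if (length(calls)) {
    fid <- vapply(seq_along(calls), function(i) {
      sid <- as.character(GenomicRanges::seqnames(calls)[i])
      s <- BiocGenerics::start(calls)[i]; e <- BiocGenerics::end(calls)[i]
      L <- Biostrings::width(genome)[match(sid, names(genome))]
      if (s - 8L < 1L || e + 8L > L) return(NA_integer_)
      8L - hammingDist(gseq(genome, sid, s - 8L, s - 1L),
                       gseq(genome, sid, e + 1L, e + 8L))
    }, integer(1))
    calls$flank_identity <- fid
  } else calls$flank_identity <- integer()
  calls
}
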