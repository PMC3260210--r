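#' Flank copy-number estimate from k-mer frequencies
#'
#' Median genome-wide occurrence count of the k-mers of the two 200-bp
#' flanks of an element, as an alignment-free stand-in for a
#' repeat-masking protocol. Occurrences are counted on both strands, so
#' the estimate is invariant under reverse-complementing the genome.
#' A flank is skipped when it runs off the sequence or contains more
#' than 10% `N`; when both are unavailable the result is `NA`.
#'
#' @param call single-element `GRanges` row.
#' @param genome `DNAStringSet`.
#' @param k k-mer size (default 20).
#' @param flank flank width in bp (default 200).
#' @return numeric copy-number estimate (1.0 means unique) or `NA`.
#' @export
flankCopyNumber <- function(call, genome, k = 20L, flank = 200L) {
  sid <- as.character(GenomicRanges::seqnames(call))[1]
  s <- BiocGenerics::start(call)[1]; e <- BiocGenerics::end(call)[1]
  L <- Biostrings::width(genome)[match(sid, names(genome))]
  flanks <- character()
  if (s - flank >= 1L) flanks <- c(flanks, gseq(genome, sid, s - flank, s - 1L))
  if (e + flank <= L) flanks <- c(flanks, gseq(genome, sid, e + 1L, e + flank))
  flanks <- flanks[vapply(flanks, function(f)
    mean(strsplit(f, "")[[1]] == "N") <= 0.1, logical(1))]
  if (length(flanks) == 0L) return(NA_real_)
  kmers <- unlist(lapply(flanks, function(f) {
    n <- nchar(f)
    if (n < k) return(character())
    substring(f, 1:(n - k + 1L), k:n)
  }))
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (length(kmers) == 0L) return(NA_real_)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  fwd <- rowSums(as.matrix(Biostrings::vcountPDict(pd, genome)))
  pdr <- Biostrings::PDict(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  rev <- rowSums(as.matrix(Biostrings::vcountPDict(pdr, genome)))
  median(fwd + rev)
}

#' Insertion context of an element
#'
#' Categorizes an insertion site with precedence genic > repetitive >
#' intergenic: `genic` when a gene model lies in or within `genicDist`
#' bp of the element (strand ignored), `repetitive` when the flank
#' copy-number estimate reaches `repeatThreshold`, `intergenic`
#' otherwise.
#'
#' @param call single-element `GRanges` row.
#' @param geneModels `GRanges` of gene models, or `NULL` (then `genic`
#'   is never assigned).
#' @param flankCopy numeric from [flankCopyNumber()] (`NA` allowed).
#' @param repeatThreshold copy-number threshold for `repetitive`
#'   (default 2.0).
#' @param genicDist distance defining "in or near a gene" (default
#'   200 bp).
#' @return list with `category` and `nearest_gene_distance` (`NA` when
#'   no gene models are given).
#' @export
insertionContext <- function(call, geneModels = NULL, flankCopy = NA_real_,
                             repeatThreshold = 2.0, genicDist = 200L) {
  dist <- NA_integer_
  if (!is.null(geneModels) && length(geneModels) > 0L) {
    dn <- GenomicRanges::distanceToNearest(call, geneModels,
                                           ignore.strand = TRUE)
    if (length(dn) > 0L) dist <- S4Vectors::mcols(dn)$distance[1]
  }
  category <- if (!is.na(dist) && dist <= genicDist) "genic"
    else if (!is.na(flankCopy) && flankCopy >= repeatThreshold) "repetitive"
    else "intergenic"
  list(category = category, nearest_gene_distance = dist)
}

#' Annotate a catalog with insertion context
#'
#' Adds `flank_copy`, `context` and `nearest_gene_distance` metadata
#' columns to every element.
#'
#' @param catalog `GRanges` catalog.
#' @param genome `DNAStringSet`.
#' @param geneModels optional `GRanges` of gene models.
#' @param repeatThreshold,k,flank see [flankCopyNumber()] /
#'   [insertionContext()].
#' @return annotated catalog `GRanges`.
#' @export
annotateCatalog <- function(catalog, genome, geneModels = NULL,
                            repeatThreshold = 2.0, k = 20L,
                            flank = 200L) {
  n <- length(catalog)
  fc <- numeric(n); ctx <- character(n); nd <- integer(n)
  for (i in seq_len(n)) {
    fc[i] <- flankCopyNumber(catalog[i], genome, k = k, flank = flank)
    ic <- insertionContext(catalog[i], geneModels, fc[i],
                           repeatThreshold = repeatThreshold)
    ctx[i] <- ic$category
    nd[i] <- ic$nearest_gene_distance
  }
  catalog$flank_copy <- fc
  catalog$context <- ctx
  catalog$nearest_gene_distance <- nd
  catalog
}

## candidate cargo matches of the element interior against a library
.libraryMatches <- function(interior, library, kindFromName, minIdentity,
                            minLength) {
  out <- list()
  for (nm in names(library)) {
    al <- alignLocal(interior, as.character(library[[nm]]))
    if (al$identity >= minIdentity && al$aligned_width >= minLength) {
      out[[length(out) + 1L]] <- data.frame(
        kind = kindFromName(nm), start = BiocGenerics::start(al$query_range),
        end = BiocGenerics::end(al$query_range), donor = nm,
        score = al$score, intron_ok = NA, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

.repeatKind <- function(nm) {
  tag <- sub("^.*#", "", nm)
  if (grepl("dna|DNA", tag)) "dna_transposon" else "ltr_retro"
}

#' Scan an element interior for cargo
#'
#' Identifies internal sequence of an element: local-alignment matches
#' (identity >= `minIdentity` over >= `minLength` bp) against a repeat
#' library (kind `ltr_retro` / `dna_transposon` from a
#' RepeatMasker-style `name#type` suffix) and against a donor exon
#' database (kind `gene_fragment`; record names `donor.exonN`); nested
#' elements from a recursive TIR scan of the interior; residual
#' interior as `intergenic_filler`. Two exon matches of one donor
#' separated by an interior segment with `GT...AG` termini are merged
#' into a single `gene_fragment` with `intron_ok = TRUE`. Overlapping
#' matches are resolved best-score-first, then longest. Features never
#' extend into the TIRs; coordinates are 1-based within the element.
#'
#' @param call single-element `GRanges` row (>= 22 bp).
#' @param genome `DNAStringSet`.
#' @param repeatLibrary optional named `DNAStringSet` of repeat
#'   consensi.
#' @param geneDb optional named `DNAStringSet` of donor exons
#'   (`donor.exon1`, `donor.exon2`, ...).
#' @param minIdentity,minLength cargo-match thresholds (0.8 / 100 bp).
#' @return data.frame with columns `kind`, `start`, `end`, `donor`,
#'   `intron_ok`, `score`.
#' @export
internalFeatureScan <- function(call, genome, repeatLibrary = NULL,
                                geneDb = NULL, minIdentity = 0.8,
                                minLength = 100L) {
  sid <- as.character(GenomicRanges::seqnames(call))[1]
  s <- BiocGenerics::start(call)[1]; e <- BiocGenerics::end(call)[1]
  len <- e - s + 1L
  if (len < 22L) stop("element shorter than two TIRs")
  intStart <- 12L; intEnd <- len - 11L
  if (intEnd < intStart)
    return(data.frame(kind = character(), start = integer(),
                      end = integer(), donor = character(),
                      intron_ok = logical(), score = numeric()))
  elem <- gseq(genome, sid, s, e)
  interior <- substr(elem, intStart, intEnd)
  cand <- list()
  if (!is.null(repeatLibrary) && length(repeatLibrary)) {
    rm <- .libraryMatches(interior, repeatLibrary, .repeatKind,
                          minIdentity, minLength)
    if (!is.null(rm)) cand[[length(cand) + 1L]] <- rm
  }
  exonHits <- NULL
  if (!is.null(geneDb) && length(geneDb)) {
    exonHits <- .libraryMatches(interior, geneDb,
                                function(nm) "gene_fragment",
                                minIdentity, minLength)
  }
  if (!is.null(exonHits)) {
    exonHits$gene <- sub("\\.exon[0-9]+$", "", exonHits$donor)
    merged <- list()
    for (g in unique(exonHits$gene)) {
      hh <- exonHits[exonHits$gene == g, , drop = FALSE]
      hh <- hh[order(hh$start), , drop = FALSE]
      if (nrow(hh) >= 2L) {
        iv <- substr(interior, hh$end[1] + 1L, hh$start[2] - 1L)
        ok <- nchar(iv) >= 4L && startsWith(iv, "GT") && endsWith(iv, "AG")
        merged[[length(merged) + 1L]] <- data.frame(
          kind = "gene_fragment", start = hh$start[1],
          end = hh$end[nrow(hh)], donor = g, score = sum(hh$score),
          intron_ok = ok, stringsAsFactors = FALSE)
      } else {
        hh$donor <- g; hh$intron_ok <- FALSE
        merged[[length(merged) + 1L]] <-
          hh[, c("kind", "start", "end", "donor", "score", "intron_ok")]
      }
    }
    cand[[length(cand) + 1L]] <- do.call(rbind, merged)
  }
  ## nested elements: recursive discovery scan of the interior
  mini <- Biostrings::DNAStringSet(interior)
  names(mini) <- "interior"
  nested <- scanElements(mini, tirMaxMismatch = 0L, minLen = 50L,
                         maxLen = max(50L, nchar(interior)))
  if (length(nested)) {
    cand[[length(cand) + 1L]] <- data.frame(
      kind = "nested_element", start = BiocGenerics::start(nested),
      end = BiocGenerics::end(nested), donor = NA_character_,
      score = 1e6 - nested$score, intron_ok = NA,
      stringsAsFactors = FALSE)
  }
  feats <- if (length(cand)) do.call(rbind, cand) else NULL
  accepted <- NULL
  if (!is.null(feats) && nrow(feats)) {
    feats <- feats[order(-feats$score, -(feats$end - feats$start)), ,
                   drop = FALSE]
    taken <- IRanges::IRanges()
    for (i in seq_len(nrow(feats))) {
      r <- IRanges::IRanges(feats$start[i], feats$end[i])
      if (length(taken) == 0L ||
          !any(IRanges::overlapsAny(r, taken))) {
        accepted <- rbind(accepted, feats[i, , drop = FALSE])
        taken <- c(taken, r)
      }
    }
  }
  ## residual interior = filler
  covered <- if (is.null(accepted)) IRanges::IRanges() else
    IRanges::reduce(IRanges::IRanges(accepted$start, accepted$end))
  gaps <- BiocGenerics::setdiff(IRanges::IRanges(1L, nchar(interior)),
                                covered)
  filler <- if (length(gaps))
    data.frame(kind = "intergenic_filler",
               start = BiocGenerics::start(gaps),
               end = BiocGenerics::end(gaps), donor = NA_character_,
               score = 0, intron_ok = NA, stringsAsFactors = FALSE)
    else NULL
  cols <- c("kind", "start", "end", "donor", "score", "intron_ok")
  res <- rbind(if (is.null(accepted)) NULL else
                 accepted[, cols, drop = FALSE], filler)
  res <- res[order(res$start), , drop = FALSE]
  ## shift from interior coordinates to element coordinates
  res$start <- res$start + intStart - 1L
  res$end <- res$end + intStart - 1L
  rownames(res) <- NULL
  res
}

#' Decompose a compound element into its segments
#'
#' A compound element carries extra internal copies of its own 8-bp TSD
#' word between its outermost termini: the core element's right TSD
#' copy survives internally, and further cargo blocks each begin with
#' another TSD copy. Segment boundaries are therefore placed at every
#' internal exact occurrence of the element's TSD word; the first
#' segment is the `core_element`, the last is a `truncated_duplicate`
#' when it ends in a TIR and locally aligns to the core (identity >=
#' 0.8 over >= 50 bp), and everything between is `cargo`. Segments tile
#' the element exactly. An element without internal TSD copies is a
#' single core segment.
#'
#' @param call single-element `GRanges` row with a `tsd` metadata
#'   column.
#' @param genome `DNAStringSet`.
#' @return list with `segments` (data.frame `role`, `start`, `end`,
#'   `width`, 1-based element coordinates) and `extra_tsd_positions`
#'   (starts of the internal TSD copies).
#' @export
decomposeCompound <- function(call, genome) {
  sid <- as.character(GenomicRanges::seqnames(call))[1]
  s <- BiocGenerics::start(call)[1]; e <- BiocGenerics::end(call)[1]
  len <- e - s + 1L
  elem <- gseq(genome, sid, s, e)
  tsd <- call$tsd[1]
  single <- list(
    segments = data.frame(role = "core_element", start = 1L, end = len,
                          width = len, stringsAsFactors = FALSE),
    extra_tsd_positions = integer())
  if (is.null(tsd) || is.na(tsd)) return(single)
  m <- Biostrings::matchPattern(tsd, Biostrings::DNAString(elem))
  pos <- BiocGenerics::start(m)
  pos <- pos[pos > 11L & pos + 7L < len - 10L]  # strictly internal
  if (length(pos) == 0L) return(single)
  bounds <- c(1L, pos, len + 1L)
  segs <- data.frame(start = bounds[-length(bounds)],
                     end = bounds[-1] - 1L)
  segs$width <- segs$end - segs$start + 1L
  n <- nrow(segs)
  roles <- c("core_element", rep("cargo", n - 1L))
  if (n >= 2L) {
    lastSeq <- substr(elem, segs$start[n], segs$end[n])
    coreSeq <- substr(elem, segs$start[1], segs$end[1])
    endsInTIR <- degenerateMismatch(
      substr(lastSeq, nchar(lastSeq) - 10L, nchar(lastSeq)),
      tirMotifs()["three_prime"]) <= 2L
    al <- alignLocal(lastSeq, coreSeq)
    if (endsInTIR && al$identity >= 0.8 && al$aligned_width >= 50L)
      roles[n] <- "truncated_duplicate"
  }
  segs$role <- roles
  list(segments = segs[, c("role", "start", "end", "width")],
       extra_tsd_positions = pos)
}

#' Predicted excision ("empty site") sequence
#'
#' Reconstructs the expected PCR template after excision of an element:
#' left host flank, a single retained copy of the TSD, right host
#' flank (`2 * flank + 8` bp). For an element without TSD evidence the
#' flanks are joined directly and the result is flagged.
#'
#' @param call single-element `GRanges` row with `tsd` mcol.
#' @param genome `DNAStringSet`.
#' @param flank flank width (default 500 bp).
#' @return list with `sequence` and `tsd` (`NA` when the element had no
#'   TSD).
#' @export
emptySiteSequence <- function(call, genome, flank = 500L) {
  sid <- as.character(GenomicRanges::seqnames(call))[1]
  s <- BiocGenerics::start(call)[1]; e <- BiocGenerics::end(call)[1]
  L <- Biostrings::width(genome)[match(sid, names(genome))]
  tsd <- call$tsd[1]
  hasTsd <- !is.null(tsd) && !is.na(tsd)
  if (hasTsd) {
    ls <- max(1L, s - 8L - flank); le <- s - 9L
    rs <- e + 9L; re <- min(L, e + 8L + flank)
    if (le < ls || rs > re) stop("flanks unavailable for empty site")
    seqn <- paste0(gseq(genome, sid, ls, le),
                   gseq(genome, sid, s - 8L, s - 1L),
                   gseq(genome, sid, rs, re))
  } else {
    ls <- max(1L, s - flank); re <- min(L, e + flank)
    if (s - 1L < ls || e + 1L > re) stop("flanks unavailable for empty site")
    seqn <- paste0(gseq(genome, sid, ls, s - 1L),
                   gseq(genome, sid, e + 1L, re))
    tsd <- NA_character_
  }
  list(sequence = seqn, tsd = tsd)
}

#' Match transposon-display junction reads against a catalog
#'
#' A junction read is host flank followed by the element 5' terminus
#' (starting at the TIR). The element boundary inside the read is
#' located at the first TIR-motif occurrence (<= 1 mismatch); the
#' host word adjacent to it (`minFlankMatch` bp) is then mapped to the
#' genome on both strands allowing 10% mismatches. A read is `shared`
#' when the host word maps immediately adjacent (within `slack` bp,
#' absorbing TSD ambiguity) to a cataloged element terminus,
#' `polymorphic` when it maps elsewhere, and `unmapped` otherwise.
#'
#' @param reads character vector or `DNAStringSet` of junction reads.
#' @param catalog `GRanges` element catalog of the target genome.
#' @param genome `DNAStringSet` of the target genome.
#' @param minFlankMatch host word length (default 30 bp); reads shorter
#'   than `minFlankMatch + 11` are an error.
#' @param slack adjacency slack in bp (default 8).
#' @return character vector in `{shared, polymorphic, unmapped}`.
#' @export
matchJunction <- function(reads, catalog, genome, minFlankMatch = 30L,
                          slack = 8L) {
  if (is(reads, "DNAStringSet")) reads <- as.character(reads)
  reads <- normalizeDNA(reads, "read")
  if (any(nchar(reads) < minFlankMatch + 11L))
    stop("read shorter than minFlankMatch + 11")
  motif <- Biostrings::DNAString(unname(tirMotifs()["five_prime"]))
  termStarts <- BiocGenerics::start(catalog)
  termEnds <- BiocGenerics::end(catalog)
  termSeq <- as.character(GenomicRanges::seqnames(catalog))
  vapply(reads, function(rd) {
    m <- Biostrings::matchPattern(motif, Biostrings::DNAString(rd),
           max.mismatch = 1,
           fixed = c(pattern = FALSE, subject = TRUE))
    if (length(m) == 0L) return("unmapped")
    cut <- BiocGenerics::start(m)[1]
    if (cut - 1L < minFlankMatch) return("unmapped")
    word <- substr(rd, cut - minFlankMatch, cut - 1L)
    maxmm <- floor(0.1 * minFlankMatch)
    mapped <- FALSE
    for (sid in names(genome)) {
      fm <- Biostrings::matchPattern(word, genome[[sid]],
              max.mismatch = maxmm)
      if (length(fm)) {
        mapped <- TRUE
        jp <- BiocGenerics::end(fm) + 1L   # expected element start
        for (p in jp) {
          hit <- termSeq == sid &
            (abs(termStarts - p) <= slack | abs(termEnds + 1L - p) <= slack)
          if (any(hit)) return("shared")
        }
      }
      rm <- Biostrings::matchPattern(revComp(word), genome[[sid]],
              max.mismatch = maxmm)
      if (length(rm)) {
        mapped <- TRUE
        jp <- BiocGenerics::start(rm) - 1L  # expected element end
        for (p in jp) {
          hit <- termSeq == sid &
            (abs(termEnds - p) <= slack | abs(termStarts - 1L - p) <= slack)
          if (any(hit)) return("shared")
        }
      }
    }
    if (mapped) "polymorphic" else "unmapped"
  }, character(1), USE.NAMES = FALSE)
}
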