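#' Generate a synthetic annotated reference Ac element
#'
#' Builds a 4,565-bp reference autonomous element with the canonical
#' terminal structure: the printed 11-bp TIRs (`CAGGGATGAAA` /
#' `TTTCATCCCTG`), 200-bp subterminal regions carrying four
#' transposase-binding hexamers each (forward AAACGG copies in the 5'
#' STR, reverse-complement copies in the 3' STR), and a designated
#' transposase exon-2/3 segment. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param dir optional directory; when given, `ac.fasta` and `ac.yaml`
#'   are written there.
#' @return an [AcReference-class].
#' @export
makeAcReference <- function(seed = 1L, dir = NULL) {
  set.seed(seed)
  total <- 4565L
  tir5 <- "CAGGGATGAAA"
  tir3 <- revComp(tir5)
  str5 <- randomDNA(200)
  for (off in c(15L, 60L, 105L, 150L))
    substr(str5, off, off + 5L) <- hexamerMotif()
  str3 <- randomDNA(200)
  for (off in c(20L, 70L, 120L, 170L))
    substr(str3, off, off + 5L) <- revComp(hexamerMotif())
  gap1 <- randomDNA(788)
  exon23 <- randomDNA(1801)
  gap2 <- randomDNA(1554)
  seqn <- paste0(tir5, str5, gap1, exon23, gap2, str3, tir3)
  stopifnot(nchar(seqn) == total)
  ref <- AcReference(seqn,
    tir5 = IRanges::IRanges(1L, 11L),
    tir3 = IRanges::IRanges(total - 10L, total),
    str5 = IRanges::IRanges(12L, 211L),
    str3 = IRanges::IRanges(4355L, 4554L),
    exon23 = IRanges::IRanges(1000L, 2800L))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeAcReference(ref, file.path(dir, "ac.fasta"),
                     file.path(dir, "ac.yaml"))
  }
  ref
}

## simulation-level auxiliary sequences shared by element builds
.makeAux <- function(acRef) {
  ds1 <- randomDNA(458)
  substr(ds1, 30L, 35L) <- hexamerMotif()
  fam <- Biostrings::DNAStringSet(vapply(1:3, function(i) randomDNA(1600),
                                         character(1)))
  names(fam) <- paste0("filler_family_", 1:3)
  retro <- randomDNA(500)
  list(ds1Consensus = ds1, fillerFamilies = fam, retro = retro)
}

.drawLen <- function(mean, sd, lo, hi) {
  as.integer(max(lo, min(hi, round(rnorm(1, mean, sd)))))
}

## erode a TIR by k substitutions at non-degenerate positions
.erodeTIR <- function(tir, k) {
  if (k <= 0L) return(tir)
  ch <- strsplit(tir, "")[[1]]
  for (i in sample(3:9, k)) ch[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                                    ch[i]), 1)
  paste(ch, collapse = "")
}

## cargo blocks inserted into element interiors
.buildCargo <- function(kind, aux, geneDb = NULL) {
  switch(kind,
    ltr_retro = mutateDNA(aux$retro, 0.02),
    gene_fragment = {
      if (is.null(geneDb) || length(geneDb) < 2L)
        stop("gene_fragment cargo needs a donor exon database")
      donor <- sub("\\.exon[0-9]+$", "", names(geneDb)[1])
      ex <- geneDb[grepl(paste0("^", donor, "\\.exon"), names(geneDb))]
      paste0(as.character(ex[[1]]),
             "GT", randomDNA(146), "AG",
             as.character(ex[[2]]))
    },
    nested_element = {
      inner <- paste0("TAGGGATGAAA", randomDNA(180), "TTTCATCCCTA")
      w <- randomDNA(8)
      paste0(w, inner, w)
    },
    stop("unknown cargo kind: ", kind))
}

#' Build one synthetic element of a given structural class
#'
#' Emits a DNA sequence matching the class architecture:
#' \itemize{
#'   \item `Ds1`: ~400 bp, TIRs around a lightly mutated copy of the
#'     shared Ds1 family filler (one hexamer);
#'   \item `Ds2`: the reference's first and last 200 bp (TIRs + STRs)
#'     around variable filler, ~1.4 kb mean;
#'   \item `Ds-l3`: ~4 kb, 30-bp reference termini, hexamer-bearing
#'     subterminal filler, and a transposase exon-2/3 fragment;
#'   \item `Ds-l4`: ~1 kb, 30-bp reference termini, filler drawn from
#'     one of the simulation's filler families, three hexamers per end;
#'   \item `Ac-like`: the full reference with small indels and sparse
#'     substitutions.
#' }
#' Optional cargo (an LTR-retrotransposon copy, a donor gene fragment
#' with a GT..AG intron, or a nested TSD-flanked element) is spliced
#' into the interior. Uses the session RNG; seed before calling for
#' reproducibility.
#'
#' @param class one of `"Ds1"`, `"Ds2"`, `"Ds-l3"`, `"Ds-l4"`,
#'   `"Ac-like"`.
#' @param acRef [AcReference-class].
#' @param aux auxiliary sequences (internal list; generated ad hoc when
#'   `NULL`).
#' @param cargo `NA` or one of `"ltr_retro"`, `"gene_fragment"`,
#'   `"nested_element"`.
#' @param geneDb donor exon `DNAStringSet` (needed for gene-fragment
#'   cargo).
#' @return list with `seq`, `class`, `cargo`.
#' @export
buildElement <- function(class, acRef, aux = NULL, cargo = NA,
                         geneDb = NULL) {
  if (is.null(aux)) aux <- .makeAux(acRef)
  ref <- as.character(refSeq(acRef))
  L <- nchar(ref)
  hex <- hexamerMotif()
  seqn <- switch(class,
    "Ds1" = {
      len <- .drawLen(400, 30, 300, 480)
      body <- substr(mutateDNA(aux$ds1Consensus, 0.02), 1L, len - 22L)
      paste0("TAGGGATGAAA", body, "TTTCATCCCTA")
    },
    "Ds2" = {
      len <- .drawLen(1400, 300, 800, 3000)
      paste0(substr(ref, 1L, 200L), randomDNA(len - 400L),
             substr(ref, L - 199L, L))
    },
    "Ds-l3" = {
      len <- .drawLen(4000, 500, 2500, 6000)
      frag <- .drawLen(900, 150, 600, 1200)
      sub5 <- randomDNA(170)
      for (off in c(20L, 60L, 100L)) substr(sub5, off, off + 5L) <- hex
      sub3 <- randomDNA(170)
      for (off in c(20L, 60L, 100L))
        substr(sub3, off, off + 5L) <- revComp(hex)
      o <- sample.int(1801L - frag, 1L)
      exonFrag <- substr(refSegmentSeq(acRef, "exon23"), o, o + frag - 1L)
      mid <- len - 30L - 170L - frag - 170L - 30L
      m1 <- mid %/% 2L; m2 <- mid - m1
      paste0(substr(ref, 1L, 30L), sub5, randomDNA(m1), exonFrag,
             randomDNA(m2), sub3, substr(ref, L - 29L, L))
    },
    "Ds-l4" = {
      len <- .drawLen(1000, 150, 600, 1600)
      fam <- sample(length(aux$fillerFamilies), 1L)
      body <- substr(mutateDNA(as.character(aux$fillerFamilies[[fam]]),
                               0.05), 1L, len - 60L)
      for (off in c(20L, 50L, 80L)) substr(body, off, off + 5L) <- hex
      bl <- nchar(body)
      for (off in c(bl - 85L, bl - 55L, bl - 25L))
        substr(body, off, off + 5L) <- revComp(hex)
      paste0(substr(ref, 1L, 30L), body, substr(ref, L - 29L, L))
    },
    "Ac-like" = {
      s <- ref
      ## sparse substitutions in the interior, then two small deletions
      ## and one insertion, away from termini and segment boundaries
      core <- substr(s, 301L, L - 300L)
      core <- mutateDNA(core, 0.005)
      s <- paste0(substr(s, 1L, 300L), core, substr(s, L - 299L, L))
      d1 <- sample(500:1500, 1L); w1 <- sample(4:8, 1L)
      s <- paste0(substr(s, 1L, d1 - 1L), substr(s, d1 + w1, nchar(s)))
      d2 <- sample(3000:4000, 1L); w2 <- sample(4:8, 1L)
      s <- paste0(substr(s, 1L, d2 - 1L), substr(s, d2 + w2, nchar(s)))
      i1 <- sample(2000:2500, 1L)
      paste0(substr(s, 1L, i1), randomDNA(sample(4:8, 1L)),
             substr(s, i1 + 1L, nchar(s)))
    },
    stop("unknown element class: ", class))
  if (!is.na(cargo)) {
    block <- .buildCargo(cargo, aux, geneDb)
    len <- nchar(seqn)
    at <- sample(seq(250L, len - 250L), 1L)
    seqn <- paste0(substr(seqn, 1L, at), block,
                   substr(seqn, at + 1L, len))
  }
  list(seq = seqn, class = class, cargo = cargo)
}

#' Build a synthetic compound element
#'
#' Concatenates a core element, cargo blocks each led by an extra copy
#' of the element's TSD word, and a truncated duplicate of the core
#' (suffix retaining the 3' TIR, also led by a TSD copy), mirroring the
#' architecture of compound elements that trap extraneous sequence
#' between their outermost termini. The TSD word is drawn so that it
#' occurs nowhere else in the element, making the decomposition
#' boundaries unambiguous.
#'
#' @param acRef [AcReference-class].
#' @param segLens integer segment lengths (core, cargo..., duplicate);
#'   default the 987/663/4887/807 architecture.
#' @param aux auxiliary sequences (optional).
#' @return list with `seq`, `tsd` (the 8-bp word to use at
#'   implantation), `segLens`.
#' @export
buildCompoundElement <- function(acRef, segLens = c(987L, 663L, 4887L,
                                                    807L), aux = NULL) {
  if (length(segLens) < 2L) stop("a compound needs >= 2 segments")
  if (is.null(aux)) aux <- .makeAux(acRef)
  ref <- as.character(refSeq(acRef))
  L <- nchar(ref)
  coreLen <- segLens[1]
  dupLen <- segLens[length(segLens)]
  if (dupLen - 8L > coreLen)
    stop("truncated duplicate cannot be longer than the core")
  core <- paste0(substr(ref, 1L, 30L), randomDNA(coreLen - 60L),
                 substr(ref, L - 29L, L))
  nCargo <- length(segLens) - 2L
  repeat {
    tsd <- randomDNA(8)
    cargo <- character(0)
    if (nCargo > 0L)
      cargo <- vapply(segLens[2:(1L + nCargo)], function(w)
        paste0(tsd, randomDNA(w - 8L)), character(1))
    dup <- paste0(tsd, substr(core, coreLen - (dupLen - 8L) + 1L, coreLen))
    seqn <- paste0(core, paste(cargo, collapse = ""), dup)
    ## the word must occur exactly at the intended boundaries
    hits <- Biostrings::countPattern(tsd, Biostrings::DNAString(seqn))
    if (hits == length(segLens) - 1L) break
  }
  list(seq = seqn, tsd = tsd, segLens = segLens)
}

#' Generate a synthetic genome background
#'
#' I.i.d. random chromosomes at the given GC content, with synthetic
#' two-exon gene models (plain background intervals recorded as gene
#' models and donor exons) and repeat families implanted as diverged
#' copy arrays (1% per-copy divergence) for the repetitive/unique
#' flank distinction.
#'
#' @param length total background length in bp.
#' @param gc GC content (default 0.47).
#' @param nChrom number of chromosomes (equal sizes).
#' @param geneCount number of gene models.
#' @param repeatCopies copies per repeat family (two families: one
#'   LTR-retro-like, one DNA-transposon-like).
#' @param seed integer seed.
#' @return list with `genome` (`DNAStringSet`), `genes` (`GRanges`),
#'   `geneDb` (`DNAStringSet` of donor exons), `repeats` (consensus
#'   `DNAStringSet`), `repeatRegions` (`GRanges`), `aux` (internal).
#' @export
makeBackground <- function(length = 2e6, gc = 0.47, nChrom = 1L,
                           geneCount = 30L, repeatCopies = 20L,
                           seed = 1L) {
  set.seed(seed)
  per <- as.integer(floor(length / nChrom))
  chrom <- vapply(seq_len(nChrom), function(i) randomDNA(per, gc),
                  character(1))
  names(chrom) <- paste0("chr", seq_len(nChrom))
  geneLen <- 1500L
  repLen <- 500L
  repCons <- Biostrings::DNAStringSet(c(randomDNA(repLen),
                                        randomDNA(repLen)))
  names(repCons) <- c("retro1#LTR/Copia", "tnp1#DNA/hAT")
  ## lay out non-overlapping feature slots on a grid, then shuffle
  slotW <- 5000L
  nSlots <- (per - 2L * slotW) %/% slotW
  genes <- NULL; repRegions <- NULL; geneDb <- list()
  for (ci in seq_len(nChrom)) {
    starts <- slotW + slotW * (seq_len(nSlots) - 1L) + 1L
    need <- geneCount + 2L * repeatCopies
    if (need > nSlots) stop("background too small for requested features")
    pick <- sample(starts, need)
    gs <- pick[seq_len(geneCount)]
    rs <- pick[geneCount + seq_len(2L * repeatCopies)]
    for (gi in seq_along(gs)) {
      g <- gs[gi]
      genes <- rbind(genes, data.frame(chr = names(chrom)[ci],
                                       start = g, end = g + geneLen - 1L))
      gene <- substr(chrom[ci], g, g + geneLen - 1L)
      id <- paste0("gene", ci, "_", gi)
      geneDb[[paste0(id, ".exon1")]] <- substr(gene, 1L, 400L)
      geneDb[[paste0(id, ".exon2")]] <- substr(gene, 701L, 1100L)
    }
    for (ri in seq_along(rs)) {
      fam <- if (ri <= repeatCopies) 1L else 2L
      copy <- mutateDNA(as.character(repCons[[fam]]), 0.01)
      substr(chrom[ci], rs[ri], rs[ri] + repLen - 1L) <- copy
      repRegions <- rbind(repRegions,
        data.frame(chr = names(chrom)[ci], start = rs[ri],
                   end = rs[ri] + repLen - 1L,
                   family = names(repCons)[fam]))
    }
  }
  genome <- Biostrings::DNAStringSet(chrom)
  genesGR <- GenomicRanges::GRanges(genes$chr,
    IRanges::IRanges(genes$start, genes$end))
  genesGR$ID <- names(geneDb)[seq(1L, length(geneDb), by = 2L)]
  genesGR$ID <- sub("\\.exon1$", "", genesGR$ID)
  repGR <- GenomicRanges::GRanges(repRegions$chr,
    IRanges::IRanges(repRegions$start, repRegions$end))
  repGR$family <- repRegions$family
  geneDbSS <- Biostrings::DNAStringSet(unlist(geneDb))
  list(genome = genome, genes = genesGR, geneDb = geneDbSS,
       repeats = repCons, repeatRegions = repGR,
       aux = NULL)
}

#' Default implant specification
#'
#' Sixty implants over the five structural classes with mixed insertion
#' contexts, clean TIRs and intact TSDs; the benchmark condition for
#' recall/precision scoring.
#'
#' @return data.frame with columns `class`, `count`, `context`,
#'   `cargo`, `tir_mismatches`, `tsd_destroy`.
#' @export
defaultImplantSpecs <- function() {
  data.frame(
    class = c("Ds1", "Ds1", "Ds1", "Ds2", "Ds2", "Ds-l3", "Ds-l3",
              "Ds-l4", "Ds-l4", "Ds-l4", "Ac-like"),
    count = c(10L, 5L, 5L, 5L, 3L, 5L, 3L, 10L, 6L, 5L, 3L),
    context = c("unique", "genic", "repeat_array", "unique", "genic",
                "unique", "repeat_array", "unique", "genic",
                "repeat_array", "unique"),
    cargo = NA_character_,
    tir_mismatches = 0L,
    tsd_destroy = FALSE,
    stringsAsFactors = FALSE)
}

#' Implant synthetic elements into a background genome
#'
#' Inserts elements with true target-site-duplication semantics: at
#' each insertion site the 8-bp host word is duplicated so that the
#' element ends up flanked by a direct repeat the insertion itself
#' created. Insertion contexts are honored (`genic`: inside a gene
#' model; `repeat_array`: inside a repeat copy; `unique`: away from
#' both), coordinates of all background features and of any prior
#' implants are shifted accordingly, and the ground truth records
#' post-insertion coordinates. Deterministic per seed.
#'
#' @param specs data.frame as [defaultImplantSpecs()]; `cargo` may also
#'   be `"compound"` for the compound architecture.
#' @param background list from [makeBackground()] or a prior
#'   [DsSim-class] (layered implantation, e.g. shared + genome-specific
#'   elements).
#' @param seed integer seed for element construction and site choice.
#' @param shared logical flag stored in the truth records created by
#'   this call (prior records keep theirs).
#' @param acRef optional [AcReference-class]; default
#'   `makeAcReference(seed)`.
#' @return a [DsSim-class].
#' @export
implantGenome <- function(specs, background = makeBackground(seed = seed),
                          seed = 1L, shared = TRUE, acRef = NULL) {
  set.seed(seed + 1L)
  if (is.null(acRef)) acRef <- makeAcReference(seed)
  set.seed(seed + 2L)
  prior <- NULL
  if (is(background, "DsSim")) {
    prior <- background
    bg <- list(genome = prior@genome, genes = prior@genes,
               geneDb = attr(prior, "geneDb"), repeats = prior@repeats,
               repeatRegions = prior@repeatRegions,
               aux = attr(prior, "aux"))
    if (is.null(bg$geneDb)) bg$geneDb <- Biostrings::DNAStringSet()
  } else bg <- background
  aux <- bg$aux
  if (is.null(aux)) aux <- .makeAux(acRef)
  specs$cargo <- as.character(specs$cargo)
  ## build all elements first
  rows <- list()
  for (si in seq_len(nrow(specs))) {
    for (k in seq_len(specs$count[si])) {
      if (!is.na(specs$cargo[si]) && specs$cargo[si] == "compound") {
        ce <- buildCompoundElement(acRef, aux = aux)
        el <- list(seq = ce$seq, class = "Ds-l4", cargo = "compound")
        forcedTsd <- ce$tsd
      } else {
        el <- buildElement(specs$class[si], acRef, aux = aux,
                           cargo = specs$cargo[si], geneDb = bg$geneDb)
        forcedTsd <- NA_character_
      }
      seqn <- el$seq
      if (specs$tir_mismatches[si] > 0L) {
        n <- nchar(seqn)
        t5 <- .erodeTIR(substr(seqn, 1L, 11L), specs$tir_mismatches[si])
        t3 <- .erodeTIR(substr(seqn, n - 10L, n), specs$tir_mismatches[si])
        seqn <- paste0(t5, substr(seqn, 12L, n - 11L), t3)
      }
      rows[[length(rows) + 1L]] <- list(
        seq = seqn, class = el$class, cargo = el$cargo,
        context = specs$context[si],
        tir_mismatches = specs$tir_mismatches[si],
        tsd_destroy = specs$tsd_destroy[si], forcedTsd = forcedTsd)
    }
  }
  totalLen <- sum(vapply(rows, function(r) nchar(r$seq), numeric(1)))
  if (totalLen >= sum(Biostrings::width(bg$genome)) / 2)
    stop("total implant length must be below half the background length")
  ## choose insertion sites per context, all on the genome as it stands
  truthAll <- if (!is.null(prior)) prior@truth else NULL
  forbidden <- GenomicRanges::GRanges()
  if (!is.null(truthAll) && length(truthAll))
    forbidden <- GenomicRanges::resize(truthAll,
      IRanges::width(truthAll) + 600L, fix = "center")
  usedGenes <- integer(); usedReps <- integer()
  sites <- data.frame()
  for (ri in seq_along(rows)) {
    r <- rows[[ri]]
    ok <- FALSE
    for (attempt in 1:200) {
      if (r$context == "genic") {
        gi <- setdiff(seq_along(bg$genes), usedGenes)
        if (length(gi) == 0L) stop("not enough gene models for genic implants")
        gi <- if (length(gi) == 1L) gi else sample(gi, 1L)
        sid <- as.character(GenomicRanges::seqnames(bg$genes)[gi])
        p <- BiocGenerics::start(bg$genes)[gi] + 1150L
      } else if (r$context == "repeat_array") {
        qi <- setdiff(seq_along(bg$repeatRegions), usedReps)
        if (length(qi) == 0L) stop("not enough repeat copies for implants")
        qi <- if (length(qi) == 1L) qi else sample(qi, 1L)
        sid <- as.character(GenomicRanges::seqnames(bg$repeatRegions)[qi])
        p <- BiocGenerics::start(bg$repeatRegions)[qi] + 246L
      } else {
        sid <- sample(names(bg$genome), 1L)
        L <- Biostrings::width(bg$genome)[match(sid, names(bg$genome))]
        p <- sample(seq(1000L, L - 1000L), 1L)
      }
      cand <- GenomicRanges::GRanges(sid, IRanges::IRanges(p - 300L,
                                                           p + 300L))
      clash <- length(forbidden) &&
        any(IRanges::overlapsAny(cand, forbidden,
                                       ignore.strand = TRUE))
      if (r$context == "unique") {
        nearFeat <- any(IRanges::overlapsAny(
          GenomicRanges::resize(cand, 2500L, fix = "center"),
          c(GenomicRanges::granges(bg$genes),
            GenomicRanges::granges(bg$repeatRegions)),
          ignore.strand = TRUE))
        clash <- clash || nearFeat
      }
      if (!clash) {
        if (r$context == "genic") usedGenes <- c(usedGenes, gi)
        if (r$context == "repeat_array") usedReps <- c(usedReps, qi)
        forbidden <- c(forbidden, cand)
        sites <- rbind(sites, data.frame(row = ri, sid = sid, p = p))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place implant (context ", r$context, ")")
  }
  ## perform insertions chromosome-wise and compute final coordinates
  genome <- bg$genome
  truthNew <- NULL
  shiftTables <- list()
  for (sid in unique(sites$sid)) {
    ss <- sites[sites$sid == sid, , drop = FALSE]
    ss <- ss[order(ss$p), , drop = FALSE]
    elems <- vapply(ss$row, function(i) rows[[i]]$seq, character(1))
    words <- vapply(seq_len(nrow(ss)), function(i)
      gseq(genome, sid, ss$p[i], ss$p[i] + 7L), character(1))
    ## honor a forced TSD word (compound architecture) by rewriting the
    ## host word at the site before insertion
    for (i in seq_len(nrow(ss))) {
      ft <- rows[[ss$row[i]]]$forcedTsd
      if (!is.na(ft)) words[i] <- ft
    }
    rightWords <- vapply(seq_len(nrow(ss)), function(i) {
      if (rows[[ss$row[i]]]$tsd_destroy) randomDNA(8) else words[i]
    }, character(1))
    inserts <- Biostrings::DNAStringSet(paste0(elems, rightWords))
    ## rewrite forced host words in place first (no length change)
    forced <- which(!is.na(vapply(ss$row, function(i)
      rows[[i]]$forcedTsd, character(1))))
    if (length(forced)) {
      genome[[sid]] <- Biostrings::replaceAt(genome[[sid]],
        IRanges::IRanges(ss$p[forced], ss$p[forced] + 7L),
        Biostrings::DNAStringSet(words[forced]))
    }
    genome[[sid]] <- Biostrings::replaceAt(genome[[sid]],
      IRanges::IRanges(start = ss$p + 8L, width = 0L), inserts)
    insLens <- nchar(elems) + 8L
    cumBefore <- c(0, cumsum(insLens))[seq_len(nrow(ss))]
    starts <- ss$p + 8L + cumBefore
    ends <- starts + nchar(elems) - 1L
    tr <- GenomicRanges::GRanges(sid, IRanges::IRanges(starts, ends))
    tr$class <- vapply(ss$row, function(i) rows[[i]]$class, character(1))
    tr$tsd <- words
    tr$cargo <- vapply(ss$row, function(i)
      as.character(rows[[i]]$cargo), character(1))
    tr$context <- vapply(ss$row, function(i) rows[[i]]$context,
                         character(1))
    tr$tir_mismatches <- vapply(ss$row, function(i)
      rows[[i]]$tir_mismatches, integer(1))
    tr$tsd_destroyed <- vapply(ss$row, function(i)
      rows[[i]]$tsd_destroy, logical(1))
    tr$shared <- shared
    truthNew <- if (is.null(truthNew)) tr else c(truthNew, tr)
    shiftTables[[sid]] <- list(p = ss$p, cum = cumsum(insLens))
  }
  shiftPos <- function(sid, x) {
    st <- shiftTables[[sid]]
    if (is.null(st)) return(x)
    idx <- findInterval(x - 8L, st$p)
    x + ifelse(idx > 0L, st$cum[pmax(idx, 1L)], 0L)
  }
  shiftGR <- function(gr) {
    if (is.null(gr) || length(gr) == 0L) return(gr)
    ns <- mapply(shiftPos, as.character(GenomicRanges::seqnames(gr)),
                 BiocGenerics::start(gr))
    ne <- mapply(shiftPos, as.character(GenomicRanges::seqnames(gr)),
                 BiocGenerics::end(gr))
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::IRanges(ns, ne),
                                  strand = BiocGenerics::strand(gr))
    S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
    out
  }
  genes <- shiftGR(bg$genes)
  repRegions <- shiftGR(bg$repeatRegions)
  truthPrior <- shiftGR(truthAll)
  truth <- if (is.null(truthPrior) || length(truthPrior) == 0L) truthNew
           else c(truthPrior, truthNew)
  truth <- GenomicRanges::sort(truth, ignore.strand = TRUE)
  sim <- new("DsSim", genome = genome, genes = genes,
             repeats = bg$repeats, repeatRegions = repRegions,
             truth = truth,
             ds1Consensus = Biostrings::DNAStringSet(aux$ds1Consensus),
             fillerFamilies = aux$fillerFamilies, seed = as.integer(seed))
  attr(sim, "geneDb") <- bg$geneDb
  attr(sim, "aux") <- aux
  sim
}

#' Write a simulation bundle to disk
#'
#' Writes `genome.fasta`, `genes.gff3`, `repeats.fasta`, `truth.tsv`
#' (and the Ds1 consensus) into a directory.
#'
#' @param sim a [DsSim-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeGenome(sim@genome, file.path(dir, "genome.fasta"))
  g <- sim@genes
  if (length(g)) g$type <- "gene"
  rtracklayer::export(g, file.path(dir, "genes.gff3"), format = "gff3")
  writeGenome(sim@repeats, file.path(dir, "repeats.fasta"))
  writeCatalog(sim@truth, file.path(dir, "truth.tsv"), format = "tsv")
  if (length(sim@ds1Consensus)) {
    ds1 <- sim@ds1Consensus
    names(ds1) <- "Ds1_consensus"
    writeGenome(ds1, file.path(dir, "ds1_consensus.fasta"))
  }
  invisible(dir)
}

#' Generate transposon-display junction reads
#'
#' Emulates the display protocol: each read is host flank (the sheared
#' fragment trimmed to the read) followed by the element's 5' terminus,
#' so the element boundary and its adjacent host word are both present.
#'
#' @param sim a [DsSim-class] (reads are drawn from its truth records).
#' @param n number of reads; when `n` exceeds the implant count,
#'   sampling is with replacement (with a message).
#' @param readLen total read length (default 120).
#' @param termLen element terminus length included (default 30).
#' @param seed integer seed.
#' @param which optional logical/integer index into the truth records
#'   (e.g. only genome-specific implants).
#' @return named `DNAStringSet` of reads.
#' @export
generateJunctionReads <- function(sim, n, readLen = 120L, termLen = 30L,
                                  seed = 1L, which = NULL) {
  set.seed(seed)
  truth <- sim@truth
  if (!is.null(which)) truth <- truth[which]
  if (length(truth) == 0L) stop("no truth records to sample reads from")
  replace <- n > length(truth)
  if (replace) message("sampling junction reads with replacement")
  idx <- sample(seq_along(truth), n, replace = replace)
  hostLen <- readLen - termLen
  reads <- vapply(idx, function(i) {
    sid <- as.character(GenomicRanges::seqnames(truth)[i])
    s <- BiocGenerics::start(truth)[i]
    e <- BiocGenerics::end(truth)[i]
    paste0(gseq(sim@genome, sid, s - hostLen, s - 1L),
           gseq(sim@genome, sid, s, min(e, s + termLen - 1L)))
  }, character(1))
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- paste0("read_", seq_len(n), "_implant_", idx)
  out
}
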