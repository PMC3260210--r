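#' AcReference: an annotated reference Activator element
#'
#' Holds the sequence of a reference autonomous Ac element together with
#' the segment annotation classification depends on: the two 11-bp
#' terminal inverted repeats (TIRs), the ~200-bp subterminal regions
#' (STRs) that carry the transposase-binding AAACGG hexamers, and the
#' segment spanning transposase exons 2–3 (the part retained by Ds-l3
#' elements).
#'
#' @slot refseq [Biostrings::DNAString] of the full element.
#' @slot tir5,tir3 [IRanges::IRanges] of the terminal 11-bp repeats.
#' @slot str5,str3 [IRanges::IRanges] of the subterminal regions
#'   (each at most 200 bp, anchored at its TIR-proximal boundary).
#' @slot exon23 [IRanges::IRanges] of the transposase exon-2/3 segment,
#'   strictly internal to the TIRs.
#' @slot hexamer single 6-mer motif string (normally `AAACGG`).
#'
#' @seealso [makeAcReference()] to generate a synthetic reference,
#'   [readAcReference()] / [writeAcReference()] for FASTA+YAML I/O.
#' @export
setClass("AcReference",
  representation(refseq = "DNAString",
                 tir5 = "IRanges", tir3 = "IRanges",
                 str5 = "IRanges", str3 = "IRanges",
                 exon23 = "IRanges", hexamer = "character"))

setValidity("AcReference", function(object) {
  msg <- character()
  L <- length(object@refseq)
  for (nm in c("tir5", "tir3", "str5", "str3", "exon23")) {
    r <- slot(object, nm)
    if (length(r) != 1L) msg <- c(msg, paste(nm, "must be a single range"))
    else if (IRanges::start(r) < 1L || IRanges::end(r) > L)
      msg <- c(msg, paste(nm, "outside the reference sequence"))
  }
  if (length(msg) == 0L) {
    if (IRanges::width(object@tir5) != 11L ||
        IRanges::width(object@tir3) != 11L)
      msg <- c(msg, "TIRs must be 11 bp")
    t5 <- as.character(Biostrings::subseq(object@refseq,
            IRanges::start(object@tir5), IRanges::end(object@tir5)))
    t3 <- as.character(Biostrings::subseq(object@refseq,
            IRanges::start(object@tir3), IRanges::end(object@tir3)))
    ## the two ends must be reverse complements up to the one
    ## degenerate terminal position
    if (degenerateMismatch(t5, tirMotifs()["five_prime"]) > 0L ||
        degenerateMismatch(t3, tirMotifs()["three_prime"]) > 0L)
      msg <- c(msg, "TIR slices do not match the canonical motifs")
    if (IRanges::width(object@str5) > 200L ||
        IRanges::width(object@str3) > 200L)
      msg <- c(msg, "subterminal regions must be <= 200 bp")
    if (IRanges::start(object@exon23) <= IRanges::end(object@tir5) ||
        IRanges::end(object@exon23) >= IRanges::start(object@tir3))
      msg <- c(msg, "exon23 must lie strictly inside the TIRs")
  }
  if (nchar(object@hexamer) != 6L)
    msg <- c(msg, "hexamer must be a 6-mer")
  if (length(msg)) msg else TRUE
})

#' Construct an AcReference
#'
#' @param refseq DNA of the reference element (character or
#'   [Biostrings::DNAString]).
#' @param tir5,tir3,str5,str3,exon23 [IRanges::IRanges] segment
#'   annotations (1-based inclusive on `refseq`).
#' @param hexamer subterminal hexamer motif; default [hexamerMotif()].
#' @return an [AcReference-class] object.
#' @export
AcReference <- function(refseq, tir5, tir3, str5, str3, exon23,
                        hexamer = hexamerMotif()) {
  if (is.character(refseq))
    refseq <- Biostrings::DNAString(normalizeDNA(refseq))
  new("AcReference", refseq = refseq, tir5 = tir5, tir3 = tir3,
      str5 = str5, str3 = str3, exon23 = exon23, hexamer = hexamer)
}

#' @describeIn AcReference-class full reference sequence as `DNAString`.
#' @param x,object an `AcReference`.
#' @export
refSeq <- function(x) x@refseq

#' @describeIn AcReference-class named list of the five annotated
#'   segment ranges.
#' @export
refSegments <- function(x)
  list(tir5 = x@tir5, tir3 = x@tir3, str5 = x@str5, str3 = x@str3,
       exon23 = x@exon23)

#' @describeIn AcReference-class extract one annotated segment's
#'   sequence as character.
#' @param segment one of `"tir5"`, `"tir3"`, `"str5"`, `"str3"`,
#'   `"exon23"`.
#' @export
refSegmentSeq <- function(x, segment) {
  r <- refSegments(x)[[match.arg(segment,
        c("tir5", "tir3", "str5", "str3", "exon23"))]]
  as.character(Biostrings::subseq(x@refseq, IRanges::start(r),
                                  IRanges::end(r)))
}

setMethod("show", "AcReference", function(object) {
  cat("AcReference of length", length(object@refseq), "bp\n")
  cat("  TIRs:", refSegmentSeq(object, "tir5"), "/",
      refSegmentSeq(object, "tir3"), "\n")
  cat("  STR5:", as.character(object@str5), " STR3:",
      as.character(object@str3), "\n")
  cat("  exon2-3 segment:", as.character(object@exon23),
      " hexamer:", object@hexamer, "\n")
})

#' DsSim: a seeded synthetic genome with implanted elements
#'
#' Bundle returned by [implantGenome()]: the genome carrying implanted
#' Ac/Ds-family elements, optional gene models and repeat regions of the
#' background, auxiliary family sequences, and the ground-truth catalog
#' of every implant for recall/precision scoring.
#'
#' @slot genome [Biostrings::DNAStringSet], one record per chromosome.
#' @slot genes [GenomicRanges::GRanges] of synthetic gene models.
#' @slot repeats [Biostrings::DNAStringSet] repeat family consensi.
#' @slot repeatRegions [GenomicRanges::GRanges] of implanted repeat
#'   copies in the final coordinates.
#' @slot truth [GenomicRanges::GRanges] of implanted elements: mcols
#'   `class`, `tsd`, `cargo`, `context`, `shared`, `tir_mismatches`,
#'   `tsd_destroyed`.
#' @slot ds1Consensus the shared Ds1 family filler consensus
#'   (`DNAStringSet`, may be empty).
#' @slot fillerFamilies `DNAStringSet` of Ds-l4 filler family consensi.
#' @slot seed integer seed the simulation was generated from.
#' @export
setClass("DsSim",
  representation(genome = "DNAStringSet", genes = "GRanges",
                 repeats = "DNAStringSet", repeatRegions = "GRanges",
                 truth = "GRanges", ds1Consensus = "DNAStringSet",
                 fillerFamilies = "DNAStringSet", seed = "integer"))

#' @describeIn DsSim-class genome `DNAStringSet`.
#' @param x,object a `DsSim`.
#' @export
simGenome <- function(x) x@genome

#' @describeIn DsSim-class ground-truth element catalog (`GRanges`).
#' @export
simTruth <- function(x) x@truth

#' @describeIn DsSim-class synthetic gene models (`GRanges`).
#' @export
simGenes <- function(x) x@genes

#' @describeIn DsSim-class repeat family consensi (`DNAStringSet`).
#' @export
simRepeats <- function(x) x@repeats

setMethod("show", "DsSim", function(object) {
  cat("DsSim:", length(object@genome), "sequence(s),",
      sum(Biostrings::width(object@genome)), "bp total; seed",
      object@seed, "\n")
  tab <- table(object@truth$class)
  cat("  implants:", length(object@truth), "(",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  cat("  genes:", length(object@genes),
      " repeat copies:", length(object@repeatRegions), "\n")
})
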