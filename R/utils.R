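#' @import methods
#' @importFrom stats median rnorm runif setNames chisq.test
#' @importFrom utils read.delim write.table head tail
NULL

DNA_OK <- c("A", "C", "G", "T", "N")

## Normalize arbitrary textual DNA to uppercase {A,C,G,T,N}; U -> T.
## Errors on anything else (IUPAC ambiguity codes other than N are not
## part of the toolkit's alphabet).
normalizeDNA <- function(x, what = "sequence") {
  nm <- names(x)
  x <- chartr("U", "T", toupper(as.character(x)))
  names(x) <- nm
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop("non-ACGTN characters in ", what, ": ",
         paste(unique(unlist(strsplit(gsub("[ACGTN]", "", x[bad]), ""))),
               collapse = ","))
  x
}

#' Reverse complement of a DNA string
#'
#' Thin character-level wrapper around [Biostrings::reverseComplement()]
#' that accepts and returns plain character vectors. `N` maps to `N`;
#' the empty string maps to itself. The two Ac/Ds TIR motifs are mutual
#' reverse complements under this map.
#'
#' @param x character vector of DNA strings over `{A,C,G,T,N}`
#'   (lowercase and `U` accepted and normalized).
#' @return character vector of the same length.
#' @examples
#' revComp("TTTCATCCCTA")  # "TAGGGATGAAA"
#' @export
revComp <- function(x) {
  x <- normalizeDNA(x)
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz))
    out[nz] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x[nz])))
  out
}

#' TIR motifs of the Ac/Ds family
#'
#' The 11-bp terminal inverted repeats defining the two ends of every
#' Ac/Ds element: 5' \code{[C/T]AGGGATGAAA} and 3'
#' \code{TTTCATCCCT[A/G]}. The single degenerate position is written in
#' IUPAC code (`Y` = C/T, `R` = A/G) and never counts as a mismatch
#' during scanning; the degeneracy is symmetric so the two motifs remain
#' exact reverse complements.
#'
#' @return named character vector with entries `five_prime` and
#'   `three_prime`.
#' @export
tirMotifs <- function() {
  c(five_prime = "YAGGGATGAAA", three_prime = "TTTCATCCCTR")
}

#' Subterminal hexamer motif
#'
#' The AAACGG hexamer bound cooperatively by the Ac transposase; three
#' or more copies in the subterminal regions are associated with
#' mobility.
#' @return character scalar `"AAACGG"`.
#' @export
hexamerMotif <- function() "AAACGG"

## Hamming distance between two equal-length character-scalar DNA words.
hammingDist <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hammingDist: unequal lengths")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## Degenerate-aware Hamming distance of word against motif (IUPAC codes
## in the motif match their set at cost 0; N in the word matches
## nothing, i.e. always a mismatch).
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))

degenerateMismatch <- function(word, motif) {
  w <- strsplit(word, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  if (length(w) != length(m)) stop("length mismatch")
  sum(vapply(seq_along(m),
             function(i) !(w[i] %in% IUPAC_SETS[[m[i]]]), logical(1)))
}

## Draw a random i.i.d. DNA string at given GC content using the
## session RNG (callers seed).
randomDNA <- function(n, gc = 0.47) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## Point-mutate a DNA string at the given per-base rate (substitutions
## only, always to a different base).
mutateDNA <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[i])
    ch[i] <- sample(alt, 1)
  }
  paste(ch, collapse = "")
}

## substring of a genome record (DNAStringSet) as plain character
gseq <- function(genome, seqid, start, end) {
  as.character(Biostrings::subseq(genome[[seqid]], start = start, end = end))
}
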