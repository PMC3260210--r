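#' Read a genome (or any DNA collection) from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()]: sequences are uppercased,
#' `U` is converted to `T`, identifiers are truncated at the first
#' whitespace, and any character outside `{A,C,G,T,N}` is rejected.
#'
#' @param path FASTA file.
#' @return [Biostrings::DNAStringSet] with unique names.
#' @export
readGenome <- function(path) {
  ## read as raw strings first: the DNA reader silently drops invalid
  ## letters, and normalization (case, U->T, residue validation) is
  ## this function's contract
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  dup <- names(ss)[duplicated(names(ss))]
  if (length(dup))
    stop("duplicate FASTA identifier(s): ",
         paste(unique(dup), collapse = ", "))
  out <- Biostrings::DNAStringSet(normalizeDNA(as.character(ss),
                                               what = path))
  names(out) <- names(ss)
  out
}

#' Write sequences to FASTA
#'
#' @param x named [Biostrings::DNAStringSet] (or named character vector).
#' @param path output file.
#' @param width line-wrap width (canonical 60).
#' @return `path`, invisibly.
#' @export
writeGenome <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(normalizeDNA(x))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

CATALOG_COLUMNS <- c("element_id", "class", "tir5_mismatches",
                     "tir3_mismatches", "tsd", "tsd_mismatches", "score")

#' Write an element catalog
#'
#' Serializes a catalog `GRanges` (as produced by [pairCandidates()] or
#' [classifyCatalog()]) to GFF3, BED or TSV. GFF3 is 1-based inclusive
#' with feature type `terminal_inverted_repeat_element` and the class,
#' TSD and hexamer counts as attributes; BED is 0-based half-open; TSV
#' keeps every metadata column and round-trips through
#' [readCatalog()].
#'
#' @param catalog `GRanges` with element metadata columns.
#' @param path output file.
#' @param format one of `"gff3"`, `"bed"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeCatalog <- function(catalog, path, format = c("tsv", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- as.data.frame(catalog)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "gff3") {
    gr <- catalog
    if (length(gr) == 0L) {
      writeLines("##gff-version 3", path)
      return(invisible(path))
    }
    if (length(gr)) {
      gr$type <- "terminal_inverted_repeat_element"
      if (is.null(gr$element_id))
        gr$element_id <- paste0("element_", seq_along(gr))
      gr$ID <- gr$element_id
      gr$source <- "AcDsTools"
    }
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    gr <- catalog
    if (length(gr)) {
      gr$name <- if (!is.null(gr$element_id)) gr$element_id else
        paste0("element_", seq_along(gr))
      gr$score <- if (!is.null(catalog$score)) catalog$score else 0L
    }
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Read a TSV element catalog back into GRanges
#'
#' Inverse of `writeCatalog(..., format = "tsv")`.
#'
#' @param path TSV file written by [writeCatalog()].
#' @return `GRanges` with the original metadata columns.
#' @export
readCatalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(df$seqnames,
          IRanges::IRanges(df$start, df$end),
          strand = df$strand)
  meta <- df[, setdiff(colnames(df), c("seqnames", "start", "end",
                                       "width", "strand")), drop = FALSE]
  S4Vectors::mcols(gr) <- meta
  gr
}

#' Write / read an AcReference as FASTA + YAML
#'
#' The sequence goes to FASTA; segment coordinates (1-based inclusive)
#' and the hexamer motif go to a YAML side-car.
#'
#' @param ref an [AcReference-class].
#' @param fasta,yaml file paths.
#' @return `readAcReference` returns an `AcReference`;
#'   `writeAcReference` returns the fasta path invisibly.
#' @export
writeAcReference <- function(ref, fasta, yaml) {
  ss <- Biostrings::DNAStringSet(as.character(ref@refseq))
  names(ss) <- "Ac_reference"
  Biostrings::writeXStringSet(ss, fasta)
  seg <- lapply(refSegments(ref), function(r)
    list(start = IRanges::start(r), end = IRanges::end(r)))
  yaml::write_yaml(c(seg, list(hexamer = ref@hexamer)), yaml)
  invisible(fasta)
}

#' @rdname writeAcReference
#' @export
readAcReference <- function(fasta, yaml) {
  ss <- readGenome(fasta)
  cfg <- yaml::read_yaml(yaml)
  rng <- function(nm) IRanges::IRanges(cfg[[nm]]$start, cfg[[nm]]$end)
  AcReference(as.character(ss[[1]]), tir5 = rng("tir5"), tir3 = rng("tir3"),
              str5 = rng("str5"), str3 = rng("str3"),
              exon23 = rng("exon23"),
              hexamer = if (is.null(cfg$hexamer)) hexamerMotif()
                        else cfg$hexamer)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 and keeps `gene` features (or all features when no
#' `gene` type is present).
#'
#' @param path GFF3 file.
#' @return `GRanges` of gene models.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% colnames(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
  gr
}
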