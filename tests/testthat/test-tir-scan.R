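tirGenome <- function(seqchar) {
  Biostrings::DNAStringSet(c(chr = seqchar))
}

test_that("exact and degenerate TIR implants are found without mismatch", {
  set.seed(21)
  bgchar <- randDNA(1000)
  s <- paste0(substr(bgchar, 1, 100), "TAGGGATGAAA",
              substr(bgchar, 112, 1000))
  hits <- scanTIR(tirGenome(s), maxMismatch = 0L)
  h5 <- hits[hits$end_type == "five_prime" &
             BiocGenerics::strand(hits) == "+"]
  expect_true(101 %in% BiocGenerics::start(h5))
  expect_equal(h5$mismatches[BiocGenerics::start(h5) == 101], 0L)
  ## the C variant of the degenerate first position is also exact
  s2 <- paste0(substr(bgchar, 1, 100), "CAGGGATGAAA",
               substr(bgchar, 112, 1000))
  hits2 <- scanTIR(tirGenome(s2), maxMismatch = 0L)
  h52 <- hits2[hits2$end_type == "five_prime" &
               BiocGenerics::strand(hits2) == "+"]
  expect_true(101 %in% BiocGenerics::start(h52))
  expect_equal(h52$mismatches[BiocGenerics::start(h52) == 101], 0L)
  ## every genomic match is reported in both element orientations
  expect_true(any(hits$end_type == "three_prime" &
                  BiocGenerics::strand(hits) == "-" &
                  BiocGenerics::start(hits) == 101))
})

test_that("scanTIR equals a brute-force degenerate Hamming scan", {
  set.seed(22)
  for (rep in 1:10) {
    s <- randDNA(2000)
    ## implant a couple of slightly eroded motifs
    substr(s, 500, 510) <- "TAGGGATCAAA"
    substr(s, 1200, 1210) <- "TTTCATCCCTG"
    for (mm in 0:2) {
      got <- scanTIR(tirGenome(s), maxMismatch = mm)
      gdf <- data.frame(start = BiocGenerics::start(got),
                        strand = as.character(BiocGenerics::strand(got)),
                        end_type = got$end_type,
                        mismatches = got$mismatches)
      gdf <- gdf[order(gdf$start, gdf$strand, gdf$end_type), ]
      rownames(gdf) <- NULL
      exp <- bruteTirScan(s, mm)
      rownames(exp) <- NULL
      expect_equal(gdf, exp, info = paste("rep", rep, "mm", mm))
    }
  }
})

test_that("windows overlapping N are discarded", {
  s <- paste0(strrep("C", 50), "TAGGGATGANA", strrep("C", 50))
  hits <- scanTIR(tirGenome(s), maxMismatch = 2L)
  expect_length(hits, 0L)
})

test_that("scan inputs are validated", {
  g <- tirGenome("ACGTACGTACGTACGT")
  expect_error(scanTIR(g, maxMismatch = 3L), "maxMismatch")
  expect_error(scanTIR(g, motifs = c(five_prime = "ACGT",
                                     three_prime = "ACGT")), "11 bp")
})

test_that("TSD detection scores the flanking 8-mers by Hamming distance", {
  s <- paste0(strrep("G", 42), "ACGTACGT", "TAGGGATGAAA", strrep("C", 78),
              "TTTCATCCCTA", "ACGTACGT", strrep("G", 42))
  g <- tirGenome(s)
  tsd <- detectTSD(g, "chr", 51L, 150L, maxMismatch = 2L)
  expect_equal(tsd$mismatches, 0L)
  expect_identical(tsd$left_word, "ACGTACGT")
  ## one mismatch within budget
  s1 <- sub("ACGTACGTTAGGG", "ACGAACGTTAGGG", s)
  expect_equal(detectTSD(tirGenome(s1), "chr", 51L, 150L, 2L)$mismatches,
               1L)
  ## three mismatches exceed the admission bound: absent, not an error
  s3 <- sub("ACGTACGTTAGGG", "TCGAAGGTTAGGG", s)
  expect_null(detectTSD(tirGenome(s3), "chr", 51L, 150L, 2L))
  ## flank off the sequence end: absent
  expect_null(detectTSD(g, "chr", 4L, 150L, 2L))
})

test_that("a clean implant yields exactly one exact call", {
  set.seed(23)
  w <- randDNA(8)
  elem <- paste0("TAGGGATGAAA", randDNA(300), "TTTCATCCCTA")
  s <- paste0(randDNA(200), w, elem, w, randDNA(200))
  calls <- scanElements(tirGenome(s))
  expect_length(calls, 1L)
  expect_equal(BiocGenerics::start(calls), 209L)
  expect_equal(BiocGenerics::end(calls), 208L + nchar(elem))
  expect_identical(calls$tsd, w)
  expect_equal(calls$score, 0L)
})

test_that("nested elements are both called, not suppressed", {
  set.seed(24)
  w_out <- randDNA(8); w_in <- randDNA(8)
  inner <- paste0("TAGGGATGAAA", randDNA(160), "TTTCATCCCTA")
  outer <- paste0("TAGGGATGAAA", randDNA(200), w_in, inner, w_in,
                  randDNA(200), "TTTCATCCCTA")
  s <- paste0(randDNA(300), w_out, outer, w_out, randDNA(300))
  calls <- scanElements(tirGenome(s))
  expect_length(calls, 2L)
  widths <- sort(IRanges::width(calls))
  expect_equal(widths, c(nchar(inner), nchar(outer)))
  ## the inner call is strictly inside the outer
  expect_true(BiocGenerics::start(calls)[1] < BiocGenerics::start(calls)[2])
  expect_true(BiocGenerics::end(calls)[2] < BiocGenerics::end(calls)[1])
})

test_that("element calls re-verify against the genome", {
  sim <- smallSim()
  g <- simGenome(sim)
  calls <- scanElements(g)
  expect_gt(length(calls), 0L)
  for (i in seq_along(calls)) {
    sid <- as.character(GenomicRanges::seqnames(calls)[i])
    s <- BiocGenerics::start(calls)[i]; e <- BiocGenerics::end(calls)[i]
    t5 <- as.character(Biostrings::subseq(g[[sid]], s, s + 10L))
    t3 <- as.character(Biostrings::subseq(g[[sid]], e - 10L, e))
    expect_lte(AcDsTools:::degenerateMismatch(t5, "YAGGGATGAAA"), 2L)
    expect_lte(AcDsTools:::degenerateMismatch(t3, "TTTCATCCCTR"), 2L)
    left <- as.character(Biostrings::subseq(g[[sid]], s - 8L, s - 1L))
    right <- as.character(Biostrings::subseq(g[[sid]], e + 1L, e + 8L))
    expect_equal(sum(strsplit(left, "")[[1]] != strsplit(right, "")[[1]]),
                 calls$tsd_mismatches[i])
  }
})

test_that("scanning is deterministic and invariant under genome RC", {
  sim <- smallSim()
  g <- simGenome(sim)
  c1 <- scanElements(g)
  c2 <- scanElements(g)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  grc <- Biostrings::reverseComplement(g)
  names(grc) <- names(g)
  c3 <- scanElements(grc)
  L <- Biostrings::width(g)[1]
  mappedStart <- sort(L - BiocGenerics::end(c3) + 1L)
  expect_identical(mappedStart, sort(BiocGenerics::start(c1)))
})

test_that("TSD-less elements are invisible to the primary scan and
           recovered, flank-annotated, by the rescue pass", {
  set.seed(25)
  w <- randDNA(8)
  elem <- paste0("TAGGGATGAAA", randDNA(250), "TTTCATCCCTA")
  ## right TSD copy randomized: identity far below the budget
  s <- paste0(randDNA(400), w, elem, "GGGGCCCC", randDNA(400))
  g <- tirGenome(s)
  primary <- scanElements(g)
  expect_length(primary, 0L)
  rescued <- rescueNoTSD(g, primary)
  expect_length(rescued, 1L)
  expect_equal(BiocGenerics::start(rescued), 409L)
  expect_true(rescued$flank_identity <= 5L)
  expect_true(is.na(rescued$tsd))
})

test_that("rescued calls never overlap the primary catalog", {
  for (seed in 1:5) {
    set.seed(seed * 100)
    parts <- character()
    for (k in 1:4) {
      w <- randDNA(8)
      elem <- paste0("TAGGGATGAAA", randDNA(150 + 20 * k), "TTTCATCCCTA")
      right <- if (k %% 2 == 0) w else randDNA(8)
      parts <- c(parts, randDNA(300), w, elem, right)
    }
    g <- tirGenome(paste0(paste(parts, collapse = ""), randDNA(300)))
    primary <- scanElements(g)
    rescued <- rescueNoTSD(g, primary)
    expect_length(GenomicRanges::findOverlaps(rescued, primary), 0L)
    expect_length(primary, 2L)
    expect_length(rescued, 2L)
  }
})
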