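## wrap an element sequence into a one-record genome with padding and
## return the (genome, call) pair
wrapElement <- function(seqchar, pad = 60L) {
  g <- Biostrings::DNAStringSet(c(chr = paste0(randDNA(pad), seqchar,
                                               randDNA(pad))))
  call <- GenomicRanges::GRanges("chr",
    IRanges::IRanges(pad + 1L, pad + nchar(seqchar)))
  call$tsd <- NA_character_
  list(genome = g, call = call)
}

test_that("homology profiles separate the class architectures", {
  ref <- smallRef()
  refchar <- as.character(refSeq(ref))
  set.seed(41)
  ## an exact reference copy
  w <- wrapElement(refchar)
  p <- homologyProfile(w$call, w$genome, ref)
  expect_gte(p$full_cov, 0.99)
  expect_gte(p$str5_cov, 0.9); expect_gte(p$str3_cov, 0.9)
  expect_gte(p$exon23_cov, 0.99)
  expect_gte(p$best_identity, 0.99)
  ## subterminal regions around random filler (the Ds2 architecture)
  ds2 <- paste0(substr(refchar, 1, 200), randDNA(900),
                substr(refchar, nchar(refchar) - 199, nchar(refchar)))
  w2 <- wrapElement(ds2)
  p2 <- homologyProfile(w2$call, w2$genome, ref)
  expect_gte(p2$str5_cov, 0.9)
  expect_gte(p2$str3_cov, 0.9)
  expect_lte(p2$exon23_cov, 0.1)
  ## TIRs around pure filler (the Ds-l4 architecture)
  dsl4 <- paste0("TAGGGATGAAA", randDNA(1000), "TTTCATCCCTA")
  w3 <- wrapElement(dsl4)
  p3 <- homologyProfile(w3$call, w3$genome, ref)
  expect_true(p3$term5_len >= 11 && p3$term5_len <= 30)
  expect_true(p3$term3_len >= 11 && p3$term3_len <= 30)
  expect_lte(p3$str5_cov, 0.15)
  expect_lte(p3$full_cov, 0.15)
  expect_error(homologyProfile(
    GenomicRanges::GRanges("chr", IRanges::IRanges(61, 70)),
    w3$genome, ref), "22 bp")
})

test_that("hexamer counts match a brute-force substring count", {
  ref <- smallRef()
  set.seed(42)
  ## constructed element: exactly three hexamers in the 5' window
  lead <- randDNA(200)
  for (off in c(20L, 80L, 140L)) substr(lead, off, off + 5L) <- "AAACGG"
  elem <- paste0("TAGGGATGAAA", substr(lead, 12, 200), randDNA(400),
                 "TTTCATCCCTA")
  w <- wrapElement(elem)
  hx <- countHexamers(w$call, w$genome, window = 200L)
  lead5 <- substr(elem, 1, 200)
  expected5 <- length(gregexpr("AAACGG", lead5, fixed = TRUE)[[1]])
  if (gregexpr("AAACGG", lead5, fixed = TRUE)[[1]][1] == -1)
    expected5 <- 0L
  expect_equal(unname(hx[1]), expected5)
  expect_gte(hx[1], 3L)
  ## brute-force equality on random elements, both windows
  for (i in 1:30) {
    el <- paste0("TAGGGATGAAA", randDNA(sample(150:900, 1)),
                 "TTTCATCCCTA")
    ww <- wrapElement(el)
    got <- countHexamers(ww$call, ww$genome, window = 200L)
    n <- nchar(el)
    win <- if (n < 400) n %/% 2 else 200L
    w5 <- substr(el, 1, win)
    w3 <- revComp(substr(el, n - win + 1, n))
    cnt <- function(x) {
      g <- gregexpr("AAACGG", x, fixed = TRUE)[[1]]
      if (g[1] == -1) 0L else length(g)
    }
    expect_equal(unname(got), c(cnt(w5), cnt(w3)))
  }
})

test_that("clean exemplars of all five architectures are labelled
           correctly with and without a Ds1 consensus", {
  ref <- smallRef()
  set.seed(43)
  aux <- AcDsTools:::.makeAux(ref)
  classes <- c("Ds1", "Ds2", "Ds-l3", "Ds-l4", "Ac-like")
  for (cl in classes) {
    for (k in 1:3) {
      el <- buildElement(cl, ref, aux = aux)
      w <- wrapElement(el$seq)
      p <- homologyProfile(w$call, w$genome, ref)
      got <- assignClass(p, w$call, w$genome,
                         ds1Consensus = aux$ds1Consensus)
      expect_identical(got, cl, label = paste(cl, "exemplar", k))
    }
  }
  ## consensus-free fallback still separates Ds1 (short) from Ds-l4
  el <- buildElement("Ds1", ref, aux = aux)
  w <- wrapElement(el$seq)
  p <- homologyProfile(w$call, w$genome, ref)
  expect_identical(assignClass(p, w$call, w$genome, ds1Consensus = NULL),
                   "Ds1")
})

test_that("profile of zero coverage with 11-bp termini at 1 kb is Ds-l4", {
  ref <- smallRef()
  p <- list(term5_len = 11L, term3_len = 11L, str5_cov = 0, str3_cov = 0,
            exon23_cov = 0, exon23_block = 0L, full_cov = 0,
            best_identity = 0)
  call <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 1000))
  expect_identical(assignClass(p, call, NULL, NULL), "Ds-l4")
  ## full coverage at identity 1 is Ac-like by rule 1
  p2 <- p; p2$full_cov <- 1; p2$best_identity <- 1
  expect_identical(assignClass(p2, call, NULL, NULL), "Ac-like")
})

test_that("eroding subterminal homology moves Ds2 away monotonically,
           never towards Ds1", {
  ref <- smallRef()
  refchar <- as.character(refSeq(ref))
  set.seed(44)
  filler <- randDNA(900)
  left <- substr(refchar, 1, 200)
  right <- substr(refchar, nchar(refchar) - 199, nchar(refchar))
  labels <- character()
  for (rate in c(0, 0.05, 0.15, 0.3, 0.45)) {
    l <- paste0(substr(left, 1, 11),
                AcDsTools:::mutateDNA(substr(left, 12, 200), rate))
    r <- paste0(AcDsTools:::mutateDNA(substr(right, 1, 189), rate),
                substr(right, 190, 200))
    w <- wrapElement(paste0(l, filler, r))
    p <- homologyProfile(w$call, w$genome, ref)
    labels <- c(labels, assignClass(p, w$call, w$genome, NULL))
  }
  expect_identical(labels[1], "Ds2")
  expect_false(any(labels == "Ds1"))
  ## once the label leaves Ds2 it never returns
  left2 <- which(labels != "Ds2")
  if (length(left2))
    expect_true(all(labels[min(left2):length(labels)] != "Ds2"))
  expect_identical(labels[length(labels)], "Ds-l4")
})

test_that("catalog classification is deterministic and order-independent", {
  sim <- smallSim()
  g <- simGenome(sim)
  ref <- smallRef()
  calls <- scanElements(g)
  ds1 <- as.character(sim@ds1Consensus[[1]])
  c1 <- classifyCatalog(calls, g, ref, ds1Consensus = ds1)
  perm <- rev(seq_along(calls))
  c2 <- classifyCatalog(calls[perm], g, ref, ds1Consensus = ds1)
  expect_identical(c1$class, rev(c2$class))
  expect_identical(c1$length_bin,
                   AcDsTools:::lengthBin(IRanges::width(calls)))
  tr <- simTruth(sim)
  m <- GenomicRanges::findOverlaps(c1, tr, type = "equal")
  expect_length(m, length(tr))
  expect_identical(c1$class[S4Vectors::queryHits(m)],
                   tr$class[S4Vectors::subjectHits(m)])
})
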