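padWrap <- function(seqchar, pad = 300L) {
  g <- Biostrings::DNAStringSet(c(chr = paste0(randDNA(pad), seqchar,
                                               randDNA(pad))))
  call <- GenomicRanges::GRanges("chr",
    IRanges::IRanges(pad + 1L, pad + nchar(seqchar)))
  call$tsd <- NA_character_
  list(genome = g, call = call)
}

test_that("flank copy number is 1 for unique flanks and scales with
           implanted copies", {
  set.seed(61)
  elem <- paste0("TAGGGATGAAA", randDNA(300), "TTTCATCCCTA")
  w <- padWrap(elem)
  expect_equal(flankCopyNumber(w$call, w$genome), 1)
  ## copy the two flanks 9 extra times each into a larger genome
  gstr <- as.character(w$genome[[1]])
  lf <- substr(gstr, 101, 300)
  rf <- substr(gstr, 301 + nchar(elem), 500 + nchar(elem))
  g10 <- Biostrings::DNAStringSet(c(chr = paste0(
    gstr, paste(replicate(9, paste0(randDNA(40), lf, randDNA(40), rf)),
                collapse = ""))))
  expect_equal(flankCopyNumber(w$call, g10), 10)
  ## invariance under reverse complement of the genome
  grc <- Biostrings::reverseComplement(g10)
  names(grc) <- "chr"
  L <- Biostrings::width(g10)[1]
  callrc <- GenomicRanges::GRanges("chr",
    IRanges::IRanges(L - BiocGenerics::end(w$call) + 1L,
                     L - BiocGenerics::start(w$call) + 1L))
  expect_equal(flankCopyNumber(callrc, grc),
               flankCopyNumber(w$call, g10))
})

test_that("insertion context follows the genic > repetitive >
           intergenic precedence", {
  call <- GenomicRanges::GRanges("chr", IRanges::IRanges(5000, 5400))
  gene150 <- GenomicRanges::GRanges("chr", IRanges::IRanges(5551, 6000))
  ic <- insertionContext(call, gene150, flankCopy = 1)
  expect_identical(ic$category, "genic")
  expect_equal(ic$nearest_gene_distance, 150)
  gene201 <- GenomicRanges::GRanges("chr", IRanges::IRanges(5602, 6000))
  expect_identical(insertionContext(call, gene201, 1)$category,
                   "intergenic")
  expect_identical(insertionContext(call, gene201, 5)$category,
                   "repetitive")
  expect_identical(insertionContext(call, gene150, 5)$category, "genic")
  expect_identical(insertionContext(call, NULL, NA)$category,
                   "intergenic")
})

test_that("context categories partition a simulated catalog correctly", {
  sim <- smallSim()
  g <- simGenome(sim)
  tr <- simTruth(sim)
  ann <- annotateCatalog(tr, g, geneModels = simGenes(sim))
  expect_identical(sort(unique(ann$context)),
                   sort(unique(c("genic", "intergenic"))))
  expected <- ifelse(tr$context == "genic", "genic",
                     ifelse(tr$context == "repeat_array", "repetitive",
                            "intergenic"))
  expect_identical(ann$context, expected)
  tab <- summarizeCounts(ann, "class", "context")
  expect_equal(tab["Total", "Total"], length(tr))
})

test_that("internal features are located, typed and tiled exactly", {
  ref <- smallRef()
  set.seed(62)
  aux <- AcDsTools:::.makeAux(ref)
  geneDb <- Biostrings::DNAStringSet(c(geneA.exon1 = randDNA(400),
                                       geneA.exon2 = randDNA(400)))
  rl <- Biostrings::DNAStringSet(setNames(aux$retro, "retro1#LTR/Copia"))
  ## gene fragment with intron
  el <- buildElement("Ds2", ref, aux = aux, cargo = "gene_fragment",
                     geneDb = geneDb)
  w <- padWrap(el$seq)
  fs <- internalFeatureScan(w$call, w$genome, geneDb = geneDb)
  gf <- fs[fs$kind == "gene_fragment", ]
  expect_equal(nrow(gf), 1L)
  expect_identical(gf$donor, "geneA")
  expect_true(gf$intron_ok)
  ## retro cargo
  el2 <- buildElement("Ds-l4", ref, aux = aux, cargo = "ltr_retro")
  w2 <- padWrap(el2$seq)
  fs2 <- internalFeatureScan(w2$call, w2$genome, repeatLibrary = rl)
  expect_equal(sum(fs2$kind == "ltr_retro"), 1L)
  ## plain filler: one feature covering the whole interior
  el3 <- paste0("TAGGGATGAAA", randDNA(500), "TTTCATCCCTA")
  w3 <- padWrap(el3)
  fs3 <- internalFeatureScan(w3$call, w3$genome, repeatLibrary = rl,
                             geneDb = geneDb)
  expect_identical(fs3$kind, "intergenic_filler")
  expect_equal(fs3$start, 12L)
  expect_equal(fs3$end, nchar(el3) - 11L)
  ## tiling: features cover the interior without gaps or overlaps and
  ## never extend into the TIRs
  for (fs_i in list(fs, fs2, fs3)) {
    len <- sum(fs_i$end - fs_i$start + 1L)
    n <- max(fs_i$end) - min(fs_i$start) + 1L
    expect_equal(len, n)
    expect_gte(min(fs_i$start), 12L)
  }
})

test_that("a nested element is recovered from the interior", {
  set.seed(63)
  inner <- paste0("TAGGGATGAAA", randDNA(180), "TTTCATCCCTA")
  wd <- randDNA(8)
  outer <- paste0("TAGGGATGAAA", randDNA(150), wd, inner, wd,
                  randDNA(150), "TTTCATCCCTA")
  w <- padWrap(outer)
  fs <- internalFeatureScan(w$call, w$genome)
  ne <- fs[fs$kind == "nested_element", ]
  expect_equal(nrow(ne), 1L)
  expect_equal(ne$end - ne$start + 1L, nchar(inner))
})

test_that("the four-segment compound architecture decomposes exactly", {
  ref <- smallRef()
  set.seed(64)
  ce <- buildCompoundElement(ref)
  g <- Biostrings::DNAStringSet(c(chr = paste0(randDNA(100), ce$tsd,
    ce$seq, ce$tsd, randDNA(100))))
  call <- GenomicRanges::GRanges("chr",
    IRanges::IRanges(109L, 108L + nchar(ce$seq)))
  call$tsd <- ce$tsd
  dc <- decomposeCompound(call, g)
  expect_equal(dc$segments$width, c(987L, 663L, 4887L, 807L))
  expect_identical(dc$segments$role,
    c("core_element", "cargo", "cargo", "truncated_duplicate"))
  expect_equal(sum(dc$segments$width), 7344L)
  expect_equal(dc$extra_tsd_positions, c(988L, 1651L, 6538L))
})

test_that("compound segments always tile the element exactly", {
  ref <- smallRef()
  set.seed(65)
  for (i in 1:10) {
    nseg <- sample(2:4, 1)
    core <- sample(500:1200, 1)
    lens <- c(core,
              if (nseg > 2) sample(300:2000, nseg - 2) else integer(),
              sample(300:min(900, core), 1))
    ce <- buildCompoundElement(ref, segLens = as.integer(lens))
    g <- Biostrings::DNAStringSet(c(chr = paste0(randDNA(50), ce$tsd,
      ce$seq, ce$tsd, randDNA(50))))
    call <- GenomicRanges::GRanges("chr",
      IRanges::IRanges(59L, 58L + nchar(ce$seq)))
    call$tsd <- ce$tsd
    dc <- decomposeCompound(call, g)
    segs <- dc$segments
    expect_equal(segs$start[1], 1L)
    expect_equal(segs$end[nrow(segs)], nchar(ce$seq))
    expect_true(all(segs$start[-1] == segs$end[-nrow(segs)] + 1L))
    expect_equal(segs$width, as.integer(lens))
  }
  ## an element without internal structure is a single core segment
  plain <- paste0("TAGGGATGAAA", randDNA(200), "TTTCATCCCTA")
  w <- padWrap(plain)
  w$call$tsd <- randDNA(8)
  dc <- decomposeCompound(w$call, w$genome)
  expect_identical(dc$segments$role, "core_element")
  expect_equal(dc$segments$width, nchar(plain))
})

test_that("empty-site prediction retains exactly one TSD copy", {
  set.seed(66)
  for (i in 1:10) {
    wd <- randDNA(8)
    elem <- paste0("TAGGGATGAAA", randDNA(200), "TTTCATCCCTA")
    g <- Biostrings::DNAStringSet(c(chr = paste0(randDNA(600), wd, elem,
                                                 wd, randDNA(600))))
    call <- GenomicRanges::GRanges("chr",
      IRanges::IRanges(609L, 608L + nchar(elem)))
    call$tsd <- wd
    es <- emptySiteSequence(call, g, flank = 500L)
    expect_equal(nchar(es$sequence), 1008L)
    expect_identical(es$tsd, wd)
    ## the junction retains one TSD copy and no full TIR
    rescan <- scanTIR(Biostrings::DNAStringSet(c(x = es$sequence)),
                      maxMismatch = 0L)
    expect_false(any(BiocGenerics::start(rescan) > 460 &
                     BiocGenerics::start(rescan) < 560))
  }
  ## an element without TSD evidence joins the flanks directly, flagged
  g <- Biostrings::DNAStringSet(c(chr = randDNA(2000)))
  call <- GenomicRanges::GRanges("chr", IRanges::IRanges(800, 1200))
  call$tsd <- NA_character_
  es <- emptySiteSequence(call, g, flank = 100L)
  expect_true(is.na(es$tsd))
  expect_equal(nchar(es$sequence), 200L)
})

test_that("junction reads are classed shared / polymorphic / unmapped", {
  set.seed(67)
  wd <- randDNA(8)
  elem <- paste0("TAGGGATGAAA", randDNA(250), "TTTCATCCCTA")
  host <- randDNA(3000)
  gA <- Biostrings::DNAStringSet(c(chr = paste0(substr(host, 1, 1000), wd,
    elem, wd, substr(host, 1009, 3000))))
  catalog <- scanElements(gA)
  expect_length(catalog, 1L)
  ## a read from the cataloged element's own junction
  readShared <- paste0(substr(host, 911, 1000), wd, substr(elem, 1, 30))
  ## a read from a site where genome A has no element (the TSD of the
  ## foreign insertion is the host word itself, so the flank matches)
  readPoly <- paste0(substr(host, 1911, 2000), substr(elem, 1, 30))
  ## a read from foreign sequence
  readNo <- paste0(randDNA(90), substr(elem, 1, 30))
  st <- matchJunction(c(readShared, readPoly, readNo), catalog, gA)
  expect_identical(st, c("shared", "polymorphic", "unmapped"))
  expect_error(matchJunction(substr(readShared, 1, 30), catalog, gA),
               "shorter")
})
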