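## Independent oracles and shared fixture builders for the test suite.
## Everything here is deliberately naive and separate from the package
## implementation paths it checks.

randDNA <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## brute-force degenerate Hamming scan of every 11-bp window of a
## sequence against both TIR motifs, with the same dual-orientation
## emission semantics as the scanner: a forward five-prime-motif match
## is a five_prime hit of a + element and a three_prime hit of a -
## element, and symmetrically
bruteTirScan <- function(seqchar, maxmm) {
  L <- nchar(seqchar)
  if (L < 11L) return(NULL)
  ch <- strsplit(seqchar, "")[[1]]
  win <- sapply(0:10, function(k) ch[(1 + k):(L - 10 + k)])
  if (is.null(dim(win))) win <- matrix(win, nrow = 1)
  allowed <- list(Y = c("C", "T"), R = c("A", "G"),
                  A = "A", C = "C", G = "G", T = "T")
  mmOf <- function(motif) {
    mv <- strsplit(motif, "")[[1]]
    mm <- integer(nrow(win))
    for (k in 1:11)
      mm <- mm + !(win[, k] %in% allowed[[mv[k]]])
    mm
  }
  out <- NULL
  for (m5 in c(TRUE, FALSE)) {
    motif <- if (m5) "YAGGGATGAAA" else "TTTCATCCCTR"
    mm <- mmOf(motif)
    hasN <- rowSums(matrix(win %in% "N", nrow = nrow(win))) > 0L
    hit <- which(mm <= maxmm & !hasN)
    if (length(hit) == 0L) next
    et <- if (m5) c("five_prime", "three_prime") else
      c("three_prime", "five_prime")
    out <- rbind(out,
      data.frame(start = rep(hit, 2L),
                 strand = rep(c("+", "-"), each = length(hit)),
                 end_type = rep(et, each = length(hit)),
                 mismatches = rep(mm[hit], 2L)))
  }
  if (is.null(out)) return(NULL)
  out[order(out$start, out$strand, out$end_type), ]
}

## quadratic Gotoh local-alignment score oracle: match +1, mismatch -1,
## a gap of length k costs 2 + (k - 1)
swScoreOracle <- function(a, b, match = 1, mismatch = -1,
                          open = 2, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consume b)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (consume a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - ext)
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

## catalog fixture encoding a per-chromosome x per-class count matrix
## as one dummy element per count unit
censusCatalog <- function(counts) {
  chroms <- rep(rownames(counts), rowSums(counts))
  classes <- unlist(lapply(seq_len(nrow(counts)), function(i)
    rep(colnames(counts), counts[i, ])))
  n <- length(chroms)
  gr <- GenomicRanges::GRanges(chroms,
    IRanges::IRanges(seq_len(n) * 1000L, width = 100L))
  gr$class <- classes
  gr
}

## small cached simulation shared across test files
.fixtureEnv <- new.env(parent = emptyenv())

smallSim <- function() {
  if (is.null(.fixtureEnv$sim)) {
    specs <- data.frame(
      class = c("Ds1", "Ds2", "Ds-l3", "Ds-l4", "Ac-like", "Ds1"),
      count = c(3L, 2L, 2L, 3L, 1L, 2L),
      context = c("unique", "unique", "unique", "unique", "unique",
                  "genic"),
      cargo = NA_character_, tir_mismatches = 0L, tsd_destroy = FALSE,
      stringsAsFactors = FALSE)
    .fixtureEnv$sim <- implantGenome(specs,
      makeBackground(length = 4e5, geneCount = 8, repeatCopies = 4,
                     seed = 101),
      seed = 101)
  }
  .fixtureEnv$sim
}

smallRef <- function() {
  if (is.null(.fixtureEnv$ref)) .fixtureEnv$ref <- makeAcReference(101)
  .fixtureEnv$ref
}
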