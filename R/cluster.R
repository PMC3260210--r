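#' Alignment-free k-mer cosine distance matrix
#'
#' `d(i,j) = 1 - cos(x_i, x_j)` over k-mer count vectors
#' ([Biostrings::oligonucleotideFrequency()]). Identical sequences have
#' distance 0; sequences sharing no k-mer have distance 1. Cosine
#' distance is not a metric (the triangle inequality may fail); it is
#' used only as input to neighbor joining.
#'
#' @param seqs named `DNAStringSet` or character vector, each sequence
#'   at least `k` long; at least 2 sequences.
#' @param k k-mer size (default 8).
#' @return symmetric numeric matrix with zero diagonal and sequence
#'   names as dimnames.
#' @export
kmerDistance <- function(seqs, k = 8L) {
  if (is.character(seqs)) {
    nm <- names(seqs)
    seqs <- Biostrings::DNAStringSet(normalizeDNA(seqs))
    names(seqs) <- nm
  }
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  short <- Biostrings::width(seqs) < k
  if (any(short))
    stop("sequence(s) shorter than k: ",
         paste(names(seqs)[short], collapse = ", "))
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  norms <- sqrt(rowSums(counts^2))
  norms[norms == 0] <- 1
  unit <- counts / norms
  sim <- tcrossprod(unit)
  d <- 1 - sim
  d[d < 0] <- 0           # numerical guard
  diag(d) <- 0
  dimnames(d) <- list(names(seqs), names(seqs))
  (d + t(d)) / 2
}

## newick serialization of an internal-node children map
.newick <- function(node, children, labels, lens) {
  if (node <= length(labels)) {
    paste0(labels[node], ":", sprintf("%.10g", lens[node]))
  } else {
    kids <- children[[as.character(node)]]
    inner <- paste(vapply(kids, .newick, character(1),
                          children = children, labels = labels,
                          lens = lens), collapse = ",")
    if (is.na(lens[node]))
      paste0("(", inner, ")")
    else
      paste0("(", inner, "):", sprintf("%.10g", lens[node]))
  }
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei agglomeration: at each step the pair minimizing
#' the Q criterion is joined (ties broken by the lexicographically
#' smallest label pair), branch lengths follow the usual formulas and
#' are clamped at 0 (with a message), and distances to the new node are
#' updated by the reduction formula. The final three nodes are resolved
#' by the closed-form three-point formulas, giving an unrooted tree
#' with a trifurcation. On an additive matrix the tree's path-length
#' matrix reproduces the input exactly (up to clamping).
#'
#' @param d symmetric numeric matrix with zero diagonal and labels as
#'   dimnames; at least 3 taxa.
#' @return an [ape::read.tree()]-style `phylo` object.
#' @export
neighborJoining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be square")
  n0 <- nrow(d)
  if (n0 < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0))
    stop("d must be symmetric with zero diagonal")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n0))
  active <- seq_len(n0)            # node ids
  D <- d
  rownames(D) <- colnames(D) <- as.character(active)
  nextNode <- n0 + 1L
  children <- list()
  lens <- rep(NA_real_, n0)
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    ## tie-break: smallest label pair, lexicographically
    pairLab <- t(apply(idx, 1, function(p)
      sort(c(rownames(D)[p[1]], rownames(D)[p[2]]))))
    ord <- order(pairLab[, 1], pairLab[, 2])
    i <- min(idx[ord[1], ]); j <- max(idx[ord[1], ])
    dij <- D[i, j]
    vi <- clamp(dij / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    vj <- clamp(dij - (dij / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    ni <- as.integer(rownames(D)[i]); nj <- as.integer(rownames(D)[j])
    u <- nextNode; nextNode <- nextNode + 1L
    children[[as.character(u)]] <- c(ni, nj)
    lens[ni] <- vi; lens[nj] <- vj; lens[u] <- NA_real_
    newd <- (D[i, ] + D[j, ] - dij) / 2
    newd <- newd[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, newd), c(newd, 0))
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- as.character(u)
    active <- c(setdiff(active, c(ni, nj)), u)
  }
  ## resolve the last three nodes around a central trifurcation
  ids <- as.integer(rownames(D))
  dab <- D[1, 2]; dac <- D[1, 3]; dbc <- D[2, 3]
  va <- clamp((dab + dac - dbc) / 2)
  vb <- clamp((dab + dbc - dac) / 2)
  vc <- clamp((dac + dbc - dab) / 2)
  u <- nextNode
  children[[as.character(u)]] <- ids
  lens[ids[1]] <- va; lens[ids[2]] <- vb; lens[ids[3]] <- vc
  lens[u] <- NA_real_
  if (clamped) message("negative branch length(s) clamped to 0")
  nwk <- paste0(.newick(u, children, labels, lens), ";")
  ape::read.tree(text = nwk)
}

#' Cut a tree into clusters
#'
#' Removes the `nClusters - 1` longest internal edges of the tree and
#' returns the leaf sets of the resulting connected components
#' (terminal edges are drawn upon only if the tree has fewer internal
#' edges than cuts). The blocks are disjoint and cover all leaves.
#'
#' @param tree a `phylo` object (e.g. from [neighborJoining()]).
#' @param nClusters number of clusters (>= 1, <= number of leaves).
#' @return list of character vectors of leaf labels, ordered by the
#'   smallest member label.
#' @export
cutClusters <- function(tree, nClusters) {
  if (nClusters < 1L) stop("nClusters must be >= 1")
  ntip <- length(tree$tip.label)
  if (nClusters > ntip) stop("nClusters exceeds number of leaves")
  edges <- tree$edge
  lens <- tree$edge.length
  internal <- which(edges[, 2] > ntip)
  ord <- internal[order(-lens[internal])]
  if (length(ord) < nClusters - 1L) {
    terminal <- setdiff(seq_len(nrow(edges)), internal)
    ord <- c(ord, terminal[order(-lens[terminal])])
  }
  drop <- if (nClusters > 1L) ord[seq_len(nClusters - 1L)] else integer()
  keep <- setdiff(seq_len(nrow(edges)), drop)
  ## union-find over remaining edges
  nnode <- max(edges)
  parent <- seq_len(nnode)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (k in keep) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(ntip), find, integer(1))
  groups <- split(tree$tip.label, comp)
  names(groups) <- NULL
  groups[order(vapply(groups, function(g) sort(g)[1], character(1)))]
}
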