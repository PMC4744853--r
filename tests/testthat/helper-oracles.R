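## Independent oracles used across the suite. These deliberately share
## no code with the package implementation.

## Brute-force affine-gap Smith-Waterman (gap of length L costs
## gapOpen + L * gapExt), plain triple-state dynamic programme in R.
swOracle <- function(a, b, submat, gapOpen, gapExt) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)       # match/mismatch state
  X <- matrix(NEG, n + 1, m + 1)     # gap in B (A consumed)
  Y <- matrix(NEG, n + 1, m + 1)     # gap in A (B consumed)
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    X[i + 1, j + 1] <- max(M[i, j + 1] - gapOpen - gapExt,
                           X[i, j + 1] - gapExt)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - gapOpen - gapExt,
                           Y[i + 1, j] - gapExt)
    s <- submat[A[i], B[j]]
    M[i + 1, j + 1] <- max(0,
                           max(M[i, j], X[i, j], Y[i, j]) + s)
    best <- max(best, M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
  }
  best
}

## N50 by direct cumulative enumeration.
n50Oracle <- function(widths) {
  w <- sort(widths, decreasing = TRUE)
  tot <- sum(as.numeric(w))
  run <- 0
  for (x in w) {
    run <- run + x
    if (run >= tot / 2) return(x)
  }
}

## All non-trivial splits of an unrooted tree by brute-force edge
## deletion on an igraph representation (independent of the package's
## postorder accumulation).
splitsOracle <- function(tree) {
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ntip <- length(tr$tip.label)
  edges <- tr$edge
  g <- igraph::graph_from_edgelist(apply(edges, 2, as.character),
                                   directed = FALSE)
  all <- sort(tr$tip.label)
  ref <- all[1]
  out <- character(0)
  for (k in seq_len(nrow(edges))) {
    g2 <- igraph::delete_edges(
      g, igraph::get_edge_ids(g, as.character(edges[k, ])))
    memb <- igraph::components(g2)$membership
    side <- tr$tip.label[which(memb[as.character(seq_len(ntip))] ==
                                 memb[as.character(edges[k, 2])])]
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (ref %in% side) side <- setdiff(all, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

rfOracle <- function(t1, t2) {
  s1 <- splitsOracle(t1); s2 <- splitsOracle(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

randomDnaString <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

randomProteinString <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               n, replace = TRUE), collapse = "")
}

## A tiny annotated genome built directly from sequence parts.
makeGenome <- function(strain, geneSeqs, spacer = 120, gc = 0.4,
                       products = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- function() randomDnaString(spacer, gc)
  parts <- character(0); starts <- integer(0); pos <- 1L
  for (i in seq_along(geneSeqs)) {
    s <- sp()
    parts <- c(parts, s); pos <- pos + nchar(s)
    starts <- c(starts, pos)
    parts <- c(parts, geneSeqs[i]); pos <- pos + nchar(geneSeqs[i])
  }
  parts <- c(parts, sp())
  ctg <- Biostrings::DNAStringSet(setNames(paste(parts, collapse = ""),
                                           "c1"))
  gr <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(starts, width = nchar(geneSeqs)),
    strand = "+")
  gr$gene_id <- paste0(strain, "_g", seq_along(geneSeqs))
  gr$product <- products %||% rep("hypothetical protein",
                                  length(geneSeqs))
  Genome(strain, ctg, gr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Random stop-free ORF.
randomOrf <- function(nCodons, gc = 0.4) {
  stops <- c("TAA", "TAG", "TGA")
  cods <- character(nCodons)
  for (i in seq_len(nCodons)) {
    repeat {
      c3 <- randomDnaString(3, gc)
      if (!(c3 %in% stops)) break
    }
    cods[i] <- c3
  }
  paste0("ATG", paste(cods, collapse = ""), "TAA")
}
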