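#' @include io.R
NULL

## ---------------------------------------------------------------------
## Alignment
## ---------------------------------------------------------------------

.msaMatrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  ch <- as.character(msa)
  if (length(unique(nchar(ch))) != 1L)
    stop("alignment rows must have equal width", call. = FALSE)
  m <- do.call(rbind, strsplit(ch, ""))
  rownames(m) <- names(msa)
  m
}

#' Center-star multiple sequence alignment
#'
#' The center is the sequence maximising the summed pairwise global
#' alignment scores; every other sequence is aligned to the center by
#' global affine-gap alignment and the pairwise alignments are merged
#' column-wise under the "once a gap, always a gap" rule. The aligned
#' width is always at least the longest input.
#'
#' @param seqs An \linkS4class{XStringSet} (DNA or protein) of >= 2
#'   sequences, or >= 1 (a single sequence aligns to itself).
#' @param gapOpen,gapExt Affine gap penalties.
#' @param matrix Substitution matrix name for proteins (default
#'   BLOSUM62); DNA uses match/mismatch +1/-2.
#' @return An \linkS4class{XStringSet} of equal-width aligned rows, in
#'   input order.
#' @export
centerStarMsa <- function(seqs, gapOpen = 10, gapExt = 0.5,
                          matrix = "BLOSUM62") {
  if (length(seqs) == 0L) stop("empty input", call. = FALSE)
  isAa <- is(seqs, "AAStringSet")
  cons <- if (is.null(names(seqs))) as.character(seq_along(seqs))
          else names(seqs)
  if (length(seqs) == 1L) return(seqs)
  subMat <- if (isAa) .getSubMatrix(matrix)
            else .dnaSubMat(match = 1, mismatch = -2)
  n <- length(seqs)
  S <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    aln <- Biostrings::pairwiseAlignment(
      rep(seqs[i], n - i), seqs[(i + 1L):n], type = "global",
      substitutionMatrix = subMat, gapOpening = gapOpen,
      gapExtension = gapExt, scoreOnly = TRUE)
    S[i, (i + 1L):n] <- aln
    S[(i + 1L):n, i] <- aln
  }
  ctr <- which.max(rowSums(S))
  others <- setdiff(seq_len(n), ctr)
  L <- nchar(as.character(seqs[[ctr]]))
  ## per-alignment: gaps inserted in the center before each center
  ## position (slots 1..L+1), and the subject text in each slot
  gapCount <- matrix(0L, n, L + 1L)
  slotText <- matrix("", n, L + 1L)   # insertions relative to center
  alignedToCtr <- matrix("", n, L)    # subject char on center columns
  alignedToCtr[ctr, ] <- strsplit(as.character(seqs[[ctr]]), "")[[1L]]
  for (i in others) {
    aln <- Biostrings::pairwiseAlignment(
      seqs[ctr], seqs[[i]], type = "global",
      substitutionMatrix = subMat, gapOpening = gapOpen,
      gapExtension = gapExt)
    pc <- strsplit(as.character(pattern(aln)), "")[[1L]]
    ps <- strsplit(as.character(subject(aln)), "")[[1L]]
    slot <- 1L
    for (k in seq_along(pc)) {
      if (pc[k] == "-") {
        gapCount[i, slot] <- gapCount[i, slot] + 1L
        slotText[i, slot] <- paste0(slotText[i, slot], ps[k])
      } else {
        alignedToCtr[i, slot] <- ps[k]
        slot <- slot + 1L
      }
    }
  }
  G <- apply(gapCount, 2L, max)
  rows <- vapply(seq_len(n), function(i) {
    parts <- character(0)
    for (j in seq_len(L + 1L)) {
      ins <- slotText[i, j]
      pad <- strrep("-", G[j] - nchar(ins))
      piece <- paste0(pad, ins)
      if (j <= L) {
        chr <- alignedToCtr[i, j]
        if (!nzchar(chr)) chr <- "-"
        piece <- paste0(piece, chr)
      }
      parts <- c(parts, piece)
    }
    .collapse(parts)
  }, "")
  out <- if (isAa) AAStringSet(rows) else DNAStringSet(rows)
  names(out) <- cons
  out
}

#' Pairwise distances from a multiple alignment
#'
#' Distances are computed over comparable sites (both rows non-gap):
#' `p` is the raw mismatch fraction, `poisson` is `-ln(1 - p)` and
#' `jc_nt` the Jukes-Cantor nucleotide correction
#' `-(3/4) ln(1 - (4/3) p)`. Saturated pairs (correction argument <= 0)
#' are reported as `Inf`.
#'
#' @param msa \linkS4class{XStringSet} of aligned rows or a character
#'   matrix.
#' @param model `"p"`, `"poisson"` or `"jc_nt"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distanceMatrix <- function(msa, model = c("p", "poisson", "jc_nt")) {
  model <- match.arg(model)
  m <- .msaMatrix(msa)
  if (nrow(m) < 2L) stop("need at least two rows", call. = FALSE)
  lbl <- rownames(m) %||% as.character(seq_len(nrow(m)))
  ok <- m != "-" & m != "." & m != " "
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(lbl, lbl))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    if (nc == 0L)
      stop(sprintf("no comparable sites between '%s' and '%s'",
                   lbl[i], lbl[j]), call. = FALSE)
    p <- sum(m[i, comp] != m[j, comp]) / nc
    d <- switch(model,
      p = p,
      poisson = if (p >= 1) Inf else -log(1 - p),
      jc_nt = if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3))
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Standard neighbor-joining agglomeration (taxa ordered by label for
#' deterministic tie-breaking); any negative branch length is clamped
#' to zero with the deficit moved to its sister branch.
#'
#' @param D Symmetric distance matrix, zero diagonal, >= 3 taxa, finite
#'   entries (prune saturated taxa first).
#' @return An unrooted \code{ape::phylo} tree.
#' @export
njTree <- function(D) {
  if (!isSymmetric(unname(D)) || any(diag(D) != 0))
    stop("D must be symmetric with zero diagonal", call. = FALSE)
  if (nrow(D) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (any(!is.finite(D)))
    stop("infinite distances present; prune saturated taxa first",
         call. = FALSE)
  ord <- order(rownames(D))
  D <- D[ord, ord]
  tr <- ape::nj(D)
  for (pass in 1:2) {
    neg <- which(tr$edge.length < 0)
    for (k in neg) {
      parent <- tr$edge[k, 1L]
      sibs <- setdiff(which(tr$edge[, 1L] == parent), k)
      if (length(sibs))
        tr$edge.length[sibs[1L]] <-
          tr$edge.length[sibs[1L]] + tr$edge.length[k]
      tr$edge.length[k] <- 0
    }
    if (!length(neg)) break
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

## ---------------------------------------------------------------------
## Bipartitions, RF distance, bootstrap
## ---------------------------------------------------------------------

## Canonical non-trivial splits of an (un)rooted tree, named by the
## child node of the corresponding internal edge.
.treeSplits <- function(tree) {
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  tr <- ape::reorder.phylo(tr, "postorder")
  ntip <- length(tr$tip.label)
  all <- sort(tr$tip.label)
  ref <- all[1L]
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  res <- character(0)
  for (k in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[k, 2L]
    if (ch <= ntip) next
    side <- below[[ch]]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (ref %in% side) side <- setdiff(all, side)
    res[as.character(ch)] <- paste(sort(side), collapse = "|")
  }
  res
}

#' Robinson-Foulds distance between two trees
#'
#' The symmetric-difference count of non-trivial bipartitions, with the
#' normalized value dividing by `2 (n - 3)` (the maximum for binary
#' unrooted trees on `n` shared leaves).
#'
#' @param t1,t2 \code{ape::phylo} trees on the same leaf set.
#' @return List: `raw` (integer), `normalized` (fraction; 0 when n < 4).
#' @export
rfDistance <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2))
    stop("leaf sets differ: only in tree 1 {",
         paste(setdiff(l1, l2), collapse = ","), "}, only in tree 2 {",
         paste(setdiff(l2, l1), collapse = ","), "}", call. = FALSE)
  s1 <- unname(.treeSplits(t1)); s2 <- unname(.treeSplits(t2))
  raw <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  n <- length(l1)
  norm <- if (n > 3L) raw / (2 * (n - 3)) else 0
  list(raw = as.integer(raw), normalized = norm)
}

#' Bootstrap support by alignment-column resampling
#'
#' Resamples alignment columns with replacement `n` times, rebuilds a
#' tree per pseudo-replicate, and attaches to each internal edge of the
#' point-estimate tree the percentage of replicates containing the same
#' bipartition (as integer node labels of the edge's child node).
#'
#' @param msa Aligned \linkS4class{XStringSet} or character matrix.
#' @param treeBuilder Function mapping a character alignment matrix to
#'   a \code{phylo} tree; defaults to neighbor joining on `model`
#'   distances.
#' @param n Number of pseudo-replicates (default 100).
#' @param model Distance model for the default builder.
#' @param seed Optional RNG seed.
#' @return The point-estimate tree with `node.label` support values.
#' @export
bootstrapSupport <- function(msa, treeBuilder = NULL, n = 100L,
                             model = "jc_nt", seed = NULL) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  builder <- treeBuilder %||%
    function(m) njTree(distanceMatrix(m, model = model))
  mat <- .msaMatrix(msa)
  point <- builder(mat)
  ref <- .treeSplits(point)
  counts <- setNames(numeric(length(ref)), unname(ref))
  for (b in seq_len(n)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    tb <- tryCatch(builder(mat[, cols, drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(tb)) next
    sb <- unname(.treeSplits(tb))
    hit <- unname(ref) %in% sb
    counts[unname(ref)[hit]] <- counts[unname(ref)[hit]] + 1
  }
  ntip <- length(point$tip.label)
  labs <- rep("", point$Nnode)
  for (nodeChr in names(ref)) {
    node <- as.integer(nodeChr)
    labs[node - ntip] <- as.character(
      as.integer(round(100 * counts[[ref[[nodeChr]]]] / n)))
  }
  point$node.label <- labs
  point
}

## ---------------------------------------------------------------------
## HGT verdict
## ---------------------------------------------------------------------

## Tips below each node of a rooted tree.
.tipsBelow <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

## Walk rooted ancestors of `focal`; return the smallest ancestor clade
## whose node support passes `supportMin` (NULL = no filter), as
## list(sister=..., support=...). NULL when none qualifies.
.supportedSister <- function(tree, focal, supportMin = NULL) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  below <- .tipsBelow(tree)
  node <- which(tree$tip.label == focal)
  if (!length(node)) stop("focal taxon absent from tree", call. = FALSE)
  path <- node
  while (path[length(path)] != root) {
    par <- tree$edge[tree$edge[, 2L] == path[length(path)], 1L]
    path <- c(path, par)
  }
  for (i in 2:length(path)) {
    anc <- path[i]
    if (anc == root) break
    supp <- NA_real_
    if (!is.null(tree$node.label)) {
      lab <- tree$node.label[anc - ntip]
      supp <- suppressWarnings(as.numeric(lab))
    }
    if (!is.null(supportMin) && (is.na(supp) || supp < supportMin)) next
    sister <- setdiff(below[[anc]], below[[path[i - 1L]]])
    if (!length(sister)) next
    return(list(sister = sister, support = supp))
  }
  NULL
}

#' Three-signal horizontal gene transfer verdict for a locus
#'
#' Combines (a) the composition signal: the locus lies in a called
#' island whose GC deviates from the genome by at least `minDeltaGc`
#' points; (b) the context signal: at least one mobile-element marker
#' or flanking direct-repeat pair; and (c) the phylogenetic signal: the
#' focal taxon's minimal supported sister clade (bootstrap >=
#' `supportMin`) in the gene tree shares no taxon with its sister clade
#' in the species tree pruned to the gene-tree leaf set. Verdict:
#' `supported` with >= 2 signals, `partial` with 1, `none` with 0.
#'
#' @param locus Locus / family identifier (character).
#' @param island `NULL`, or a single-range \linkS4class{GRanges} from
#'   [callIslands()] (optionally with `mge_markers` from
#'   [annotateMgeContext()]).
#' @param geneTree \code{phylo} with bootstrap node labels (see
#'   [bootstrapSupport()]).
#' @param speciesTree \code{phylo}; pruned internally to the gene-tree
#'   taxa.
#' @param focal Tip label of the focal strain (must be in both trees).
#' @param outgroup Optional tip label used to root unrooted trees.
#' @param flankRepeats Optional data.frame from [findFlankRepeats()].
#' @param supportMin Bootstrap threshold for the phylogenetic signal
#'   (default 70, the conventional reporting cutoff).
#' @param minDeltaGc Composition threshold in GC points (default 4).
#' @return An [HgtEvidence-class] object.
#' @export
flagHgt <- function(locus, island = NULL, geneTree, speciesTree, focal,
                    outgroup = NULL, flankRepeats = NULL,
                    supportMin = 70, minDeltaGc = 4) {
  ## composition
  deltaGc <- NA_real_
  gcSignal <- FALSE
  if (!is.null(island) && length(island) == 1L) {
    deltaGc <- island$mean_gc - island$genome_gc
    gcSignal <- isTRUE(abs(deltaGc) >= minDeltaGc)
  }
  ## context
  nMarkers <- 0L
  if (!is.null(island) && !is.null(island$mge_markers))
    nMarkers <- nrow(island$mge_markers[[1L]])
  nRepeats <- if (is.null(flankRepeats)) 0L else nrow(flankRepeats)
  contextSignal <- (nMarkers + nRepeats) > 0L
  contextDetail <- sprintf("%d MGE marker(s), %d flanking repeat pair(s)",
                           nMarkers, nRepeats)
  ## phylogeny
  if (!(focal %in% geneTree$tip.label))
    stop("focal taxon absent from gene tree", call. = FALSE)
  sp <- ape::keep.tip(speciesTree, geneTree$tip.label)
  rootAt <- function(tr) {
    if (!is.null(outgroup) && outgroup %in% tr$tip.label)
      ape::root(tr, outgroup = outgroup, resolve.root = TRUE,
                edgelabel = TRUE)
    else if (ape::is.rooted(tr)) tr
    else stop("tree is unrooted and no outgroup was given", call. = FALSE)
  }
  gt <- rootAt(geneTree)
  spr <- rootAt(sp)
  rf <- rfDistance(geneTree, sp)
  gs <- .supportedSister(gt, focal, supportMin = supportMin)
  ss <- .supportedSister(spr, focal, supportMin = NULL)
  phyloSignal <- !is.null(gs) && !is.null(ss) &&
    length(intersect(gs$sister, ss$sister)) == 0L
  nSig <- sum(gcSignal, contextSignal, phyloSignal)
  new("HgtEvidence", locus = locus,
      gcSignal = gcSignal, contextSignal = contextSignal,
      phyloSignal = phyloSignal,
      deltaGc = if (is.na(deltaGc)) 0 else deltaGc,
      contextDetail = contextDetail,
      rfNormalized = rf$normalized,
      sisterGene = if (is.null(gs)) character() else gs$sister,
      sisterSpecies = if (is.null(ss)) character() else ss$sister,
      sisterSupport = if (is.null(gs)) NA_real_ else gs$support,
      verdict = if (nSig >= 2L) "supported"
                else if (nSig == 1L) "partial" else "none")
}
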