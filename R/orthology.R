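#' @include io.R
NULL

## Karlin-Altschul constants for gapped BLOSUM62 (gap open 11 / extend 1),
## used as fixed configuration: e-values act as a filter here, not a
## calibrated statistic.
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

.bitScore <- function(raw, lambda = .KA_LAMBDA, K = .KA_K) {
  (lambda * raw - log(K)) / log(2)
}

.evalueFromBits <- function(bits, m, n) m * n * 2^(-bits)

.checkProtein <- function(x, name = "sequence") {
  ch <- unique(strsplit(toupper(as.character(x)), "")[[1L]])
  bad <- setdiff(ch, c(AA20, "X"))
  if (length(bad))
    stop(sprintf("non-protein alphabet in %s: %s", name,
                 paste(bad, collapse = "")), call. = FALSE)
  invisible(TRUE)
}

.protSet <- function(x) {
  if (is(x, "Genome")) proteome(x)
  else if (is(x, "AAStringSet")) x
  else AAStringSet(x)
}

#' Optimal local protein alignment with affine gaps
#'
#' Smith-Waterman alignment under a substitution matrix and affine gap
#' penalties (a gap of length L costs `gapOpen + L * gapExt`). The bit
#' score is computed from fixed Karlin-Altschul constants,
#' `bits = (lambda * raw - ln K) / ln 2`, and the e-value (when the
#' database and query residue totals `m` and `n` are supplied) as
#' `m * n * 2^(-bits)`.
#'
#' @param a,b Protein sequences (character or \linkS4class{AAString}).
#' @param matrix Substitution matrix name (e.g. `"BLOSUM62"`,
#'   `"BLOSUM50"`) or a numeric matrix.
#' @param gapOpen,gapExt Affine gap penalties (positive numbers).
#' @param m,n Optional residue totals for the e-value.
#' @return A list: `raw_score`, `bitscore`, `evalue`, `identity`
#'   (identical positions / alignment columns), `qcov`, `scov` (aligned
#'   span / sequence length).
#' @examples
#' localAlign("HEAGAWGHEE", "PAWHEAE", matrix = "BLOSUM50",
#'            gapOpen = 0, gapExt = 8)$raw_score
#' @export
localAlign <- function(a, b, matrix = "BLOSUM62", gapOpen = 11,
                       gapExt = 1, m = NULL, n = NULL) {
  if (!nchar(as.character(a)) || !nchar(as.character(b)))
    stop("empty protein sequence", call. = FALSE)
  .checkProtein(a, "query"); .checkProtein(b, "subject")
  subMat <- if (is.character(matrix)) .getSubMatrix(matrix) else matrix
  aln <- Biostrings::pairwiseAlignment(
    AAString(as.character(a)), AAString(as.character(b)), type = "local",
    substitutionMatrix = subMat, gapOpening = gapOpen,
    gapExtension = gapExt)
  raw <- score(aln)
  bits <- .bitScore(raw)
  ev <- if (!is.null(m) && !is.null(n)) .evalueFromBits(bits, m, n)
        else NA_real_
  cols <- nchar(aln)
  list(raw_score = raw, bitscore = bits, evalue = ev,
       identity = if (cols > 0) nmatch(aln) / cols else 0,
       qcov = (end(pattern(aln)) - start(pattern(aln)) + 1) /
         nchar(as.character(a)),
       scov = (end(subject(aln)) - start(subject(aln)) + 1) /
         nchar(as.character(b)))
}

.getSubMatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

## Shared k-mer prefilter: for each query, subjects sharing at least
## `minShared` distinct k-mers. Mirrors the seeding heuristic of
## word-based search tools; exhaustive comparison is used for small
## problems.
.kmerCandidates <- function(qset, sset, k = 4L, minShared = 8L) {
  kmersOf <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  sk <- lapply(as.character(sset), kmersOf)
  idx <- split(rep(seq_along(sk), lengths(sk)), unlist(sk))
  lapply(as.character(qset), function(q) {
    qk <- kmersOf(q)
    js <- unlist(idx[qk], use.names = FALSE)
    if (is.null(js)) return(integer())
    counts <- tabulate(js, nbins = length(sset))
    which(counts >= minShared)
  })
}

#' Best hit of every query protein in a subject proteome
#'
#' For each query, the subject hit with maximal bit score among those
#' passing the e-value cutoff; ties are broken by higher identity, then
#' lexicographic subject id. Queries with no passing hit are absent from
#' the result. Candidate pairs are seeded by shared k-mers (exhaustive
#' comparison when the problem is small or `prefilter = FALSE`).
#'
#' @param A,B [Genome-class] objects or named \linkS4class{AAStringSet}s
#'   (query and subject proteomes).
#' @param maxEval E-value cutoff (default 1e-6).
#' @param matrix,gapOpen,gapExt Scoring scheme, as in [localAlign()].
#' @param prefilter Use the shared k-mer seed filter (`NA` = automatic:
#'   exhaustive for <= 2500 pairs).
#' @param minSharedKmers Seed threshold for the prefilter.
#' @return data.frame: `query`, `subject`, `raw_score`, `bitscore`,
#'   `evalue`, `identity`, `qcov`, `scov`.
#' @export
bestHits <- function(A, B, maxEval = 1e-6, matrix = "BLOSUM62",
                     gapOpen = 11, gapExt = 1, prefilter = NA,
                     minSharedKmers = 8L) {
  qset <- .protSet(A); sset <- .protSet(B)
  if (!length(qset) || !length(sset))
    stop("empty proteome", call. = FALSE)
  if (is.na(prefilter))
    prefilter <- length(qset) * length(sset) > 2500
  cand <- if (prefilter)
    .kmerCandidates(qset, sset, minShared = minSharedKmers)
  else rep(list(seq_along(sset)), length(qset))
  subMat <- .getSubMatrix(matrix)
  mResidues <- sum(width(sset))
  ## group candidate pairs by subject for vectorised alignment
  qi <- rep(seq_along(cand), lengths(cand))
  si <- unlist(cand, use.names = FALSE)
  if (!length(si)) return(.emptyHits())
  rows <- vector("list", length(unique(si)))
  r <- 0L
  for (j in unique(si)) {
    qs <- qi[si == j]
    aln <- Biostrings::pairwiseAlignment(
      qset[qs], sset[[j]], type = "local", substitutionMatrix = subMat,
      gapOpening = gapOpen, gapExtension = gapExt)
    cols <- nchar(aln)
    bits <- .bitScore(score(aln))
    r <- r + 1L
    rows[[r]] <- data.frame(
      query = names(qset)[qs], subject = names(sset)[j],
      raw_score = score(aln), bitscore = bits,
      evalue = .evalueFromBits(bits, mResidues, width(qset)[qs]),
      identity = ifelse(cols > 0, nmatch(aln) / cols, 0),
      qcov = (end(pattern(aln)) - start(pattern(aln)) + 1) /
        width(qset)[qs],
      scov = (end(subject(aln)) - start(subject(aln)) + 1) /
        width(sset)[j],
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  hits <- hits[hits$evalue <= maxEval, , drop = FALSE]
  if (!nrow(hits)) return(.emptyHits())
  ## best per query: max bitscore, tie -> higher identity, then subject id
  hits <- hits[order(hits$query, -hits$bitscore, -hits$identity,
                     hits$subject), , drop = FALSE]
  hits <- hits[!duplicated(hits$query), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

.emptyHits <- function() {
  data.frame(query = character(), subject = character(),
             raw_score = numeric(), bitscore = numeric(),
             evalue = numeric(), identity = numeric(),
             qcov = numeric(), scov = numeric(), stringsAsFactors = FALSE)
}

#' Bidirectional best hits between two proteomes
#'
#' A pair (a, b) is a BBH iff a's best hit in B is b, b's best hit in A
#' is a, the e-value passes in both directions, and the minimum of query
#' and subject coverage is at least `minCov` in both directions.
#'
#' @param A,B [Genome-class] objects or named \linkS4class{AAStringSet}s.
#' @param minCov Mutual coverage threshold in (0, 1] (default 0.60).
#' @param maxEval E-value cutoff (default 1e-6).
#' @param ... Passed to [bestHits()].
#' @return data.frame: `query` (gene in A), `subject` (gene in B),
#'   `bitscore` (forward direction), `identity`, `min_cov`.
#' @export
bidirectionalBestHits <- function(A, B, minCov = 0.60, maxEval = 1e-6,
                                  ...) {
  if (!is.numeric(minCov) || minCov <= 0 || minCov > 1)
    stop("minCov must lie in (0, 1]", call. = FALSE)
  fwd <- bestHits(A, B, maxEval = maxEval, ...)
  rev <- bestHits(B, A, maxEval = maxEval, ...)
  if (!nrow(fwd) || !nrow(rev)) return(.emptyBbh())
  revBest <- setNames(rev$subject, rev$query)
  keep <- !is.na(revBest[fwd$subject]) & revBest[fwd$subject] == fwd$query
  fwd <- fwd[keep, , drop = FALSE]
  if (!nrow(fwd)) return(.emptyBbh())
  rev <- rev[match(fwd$subject, rev$query), , drop = FALSE]
  mc <- pmin(fwd$qcov, fwd$scov, rev$qcov, rev$scov)
  ok <- mc >= minCov
  out <- data.frame(query = fwd$query, subject = fwd$subject,
                    bitscore = fwd$bitscore, identity = fwd$identity,
                    min_cov = mc, stringsAsFactors = FALSE)[ok, ,
                                                            drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyBbh <- function() {
  data.frame(query = character(), subject = character(),
             bitscore = numeric(), identity = numeric(),
             min_cov = numeric(), stringsAsFactors = FALSE)
}

#' Ortholog families from pairwise BBH sets
#'
#' Families are connected components of the union BBH graph across all
#' genome pairs. If a component contains more than one gene from a
#' strain, the gene with the highest summed bit score to the other
#' members is kept and the rest are re-seated as strain-specific
#' singletons. Genes in no BBH pair become singletons. Category: `core`
#' iff all strains are represented, `specific` iff exactly one, `shared`
#' otherwise.
#'
#' @param genomes Named list of [Genome-class] objects.
#' @param bbhPairs List of data.frames from [bidirectionalBestHits()],
#'   each carrying attributes `strainA` and `strainB` naming the two
#'   genomes (set automatically by [pangenome()]).
#' @return data.frame: `family_id`, `strain_id`, `gene_id`, `category`.
#' @seealso [pangenome()] for the one-call wrapper.
#' @export
buildFamilies <- function(genomes, bbhPairs) {
  strains <- names(genomes)
  nStrains <- length(strains)
  allGenes <- do.call(rbind, lapply(strains, function(s) {
    ids <- names(proteome(genomes[[s]]))
    if (is.null(ids) || !length(ids))
      ids <- features(genomes[[s]])$gene_id
    data.frame(strain_id = s, gene_id = ids, stringsAsFactors = FALSE)
  }))
  key <- function(strain, gene) paste(strain, gene, sep = "\r")
  allGenes$key <- key(allGenes$strain_id, allGenes$gene_id)
  edges <- do.call(rbind, lapply(bbhPairs, function(bb) {
    sA <- attr(bb, "strainA"); sB <- attr(bb, "strainB")
    if (is.null(sA) || is.null(sB))
      stop("bbhPairs entries need strainA/strainB attributes",
           call. = FALSE)
    if (!nrow(bb)) return(NULL)
    data.frame(from = key(sA, bb$query), to = key(sB, bb$subject),
               weight = bb$bitscore, stringsAsFactors = FALSE)
  }))
  memb <- setNames(seq_len(nrow(allGenes)), allGenes$key)
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = allGenes$key))
    memb <- igraph::components(g)$membership[allGenes$key]
  }
  allGenes$component <- as.integer(memb)
  ## paralog resolution: keep the strongest gene per strain per component
  singled <- logical(nrow(allGenes))
  wsum <- rep(0, nrow(allGenes))
  if (!is.null(edges) && nrow(edges)) {
    ix <- match(edges$from, allGenes$key)
    jx <- match(edges$to, allGenes$key)
    for (e in seq_len(nrow(edges))) {
      wsum[ix[e]] <- wsum[ix[e]] + edges$weight[e]
      wsum[jx[e]] <- wsum[jx[e]] + edges$weight[e]
    }
  }
  bySC <- split(seq_len(nrow(allGenes)),
                paste(allGenes$component, allGenes$strain_id))
  for (grp in bySC) {
    if (length(grp) > 1L) {
      keep <- grp[which.max(wsum[grp])]
      singled[setdiff(grp, keep)] <- TRUE
    }
  }
  nextComp <- max(allGenes$component) + seq_len(sum(singled))
  allGenes$component[singled] <- nextComp
  comp <- allGenes$component
  nStrainsPer <- vapply(split(allGenes$strain_id, comp),
                        function(s) length(unique(s)), integer(1))
  compIds <- sort(unique(comp))
  famId <- setNames(sprintf("OG%05d", seq_along(compIds)),
                    as.character(compIds))
  cat0 <- ifelse(nStrainsPer == nStrains, "core",
                 ifelse(nStrainsPer == 1L, "specific", "shared"))
  catByComp <- setNames(cat0, names(nStrainsPer))
  data.frame(family_id = famId[as.character(comp)],
             strain_id = allGenes$strain_id,
             gene_id = allGenes$gene_id,
             category = catByComp[as.character(comp)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pangenome partition counts
#'
#' @param familyTable data.frame from [buildFamilies()].
#' @param cdsCounts Named integer, CDS count per strain (>= 2 strains).
#' @return A [PangenomePartition-class]: pangenome size (families,
#'   singletons included), core size, shared sizes by strain pattern,
#'   strain-specific sizes, and the core fraction as a percentage of the
#'   mean CDS count (rounded to the nearest integer).
#' @examples
#' # printed counts of a three-strain comparison:
#' fams <- data.frame(family_id = "OG1", strain_id = "s1",
#'                    gene_id = "g1", category = "specific")
#' @export
pangenomeCounts <- function(familyTable, cdsCounts) {
  if (!nrow(familyTable)) stop("empty family list", call. = FALSE)
  if (length(cdsCounts) < 2L)
    stop("pangenome partition requires at least two genomes",
         call. = FALSE)
  byFam <- split(familyTable$strain_id, familyTable$family_id)
  pat <- vapply(byFam, function(s)
    paste(sort(unique(s)), collapse = "|"), "")
  nStr <- vapply(byFam, function(s) length(unique(s)), integer(1))
  nStrains <- length(cdsCounts)
  category <- ifelse(nStr == nStrains, "core",
                     ifelse(nStr == 1L, "specific", "shared"))
  core <- sum(category == "core")
  sharedPat <- table(pat[category == "shared"])
  specific <- table(pat[category == "specific"])
  specFull <- setNames(integer(nStrains), names(cdsCounts))
  specFull[names(specific)] <- as.integer(specific)
  counts <- list(
    pangenome = length(byFam), core = core,
    shared_by_pattern = setNames(as.integer(sharedPat), names(sharedPat)),
    specific_by_strain = specFull,
    core_fraction_of_mean_cds = round(100 * core / mean(cdsCounts)))
  ## category is (re)derived here so that counts and table always agree
  familyTable$category <- category[familyTable$family_id]
  new("PangenomePartition", familyTable = familyTable, counts = counts,
      nStrains = as.integer(nStrains))
}

#' One-call pangenome partition of a strain set
#'
#' Runs [bidirectionalBestHits()] for every genome pair, builds families
#' and counts.
#'
#' @param genomes Named list of [Genome-class] objects.
#' @param minCov,maxEval BBH thresholds.
#' @param ... Passed to [bestHits()].
#' @return A [PangenomePartition-class].
#' @export
pangenome <- function(genomes, minCov = 0.60, maxEval = 1e-6, ...) {
  strains <- names(genomes)
  if (length(strains) < 2L) stop("need at least two genomes", call. = FALSE)
  pairs <- utils::combn(strains, 2L, simplify = FALSE)
  bbh <- lapply(pairs, function(p) {
    bb <- bidirectionalBestHits(genomes[[p[1L]]], genomes[[p[2L]]],
                                minCov = minCov, maxEval = maxEval, ...)
    attr(bb, "strainA") <- p[1L]
    attr(bb, "strainB") <- p[2L]
    bb
  })
  fams <- buildFamilies(genomes, bbh)
  cds <- vapply(genomes, function(g) length(features(g)), integer(1))
  if (all(cds == 0L))
    cds <- vapply(genomes, function(g) length(proteome(g)), integer(1))
  pangenomeCounts(fams, cds)
}

#' Synteny conservation between two genomes
#'
#' Over ordered pairs of adjacent core genes in genome A (within
#' contigs), the fraction whose family images are also adjacent (in
#' either orientation) among the core genes of genome B.
#'
#' @param gA,gB [Genome-class] objects.
#' @param familyTable data.frame from [buildFamilies()].
#' @return Fraction in [0, 1].
#' @export
syntenyConservation <- function(gA, gB, familyTable) {
  core <- familyTable[familyTable$category == "core", , drop = FALSE]
  famOf <- function(g) {
    sub <- core[core$strain_id == strainId(g), , drop = FALSE]
    setNames(sub$family_id, sub$gene_id)
  }
  adjPairs <- function(g, fmap) {
    ft <- features(g)
    ft <- ft[ft$gene_id %in% names(fmap)]
    out <- list()
    for (cn in unique(as.character(seqnames(ft)))) {
      f <- ft[as.character(seqnames(ft)) == cn]
      f <- f[order(start(f))]
      if (length(f) < 2L) next
      fams <- fmap[f$gene_id]
      out[[cn]] <- cbind(fams[-length(fams)], fams[-1L])
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  pa <- adjPairs(gA, famOf(gA))
  if (is.null(pa))
    stop("fewer than 2 core genes on every contig of ", strainId(gA),
         "; synteny undefined", call. = FALSE)
  pb <- adjPairs(gB, famOf(gB))
  if (is.null(pb))
    stop("fewer than 2 core genes on every contig of ", strainId(gB),
         "; synteny undefined", call. = FALSE)
  keyB <- unique(c(paste(pb[, 1L], pb[, 2L]), paste(pb[, 2L], pb[, 1L])))
  mean(paste(pa[, 1L], pa[, 2L]) %in% keyB)
}
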