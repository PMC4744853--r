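#' @include io.R
NULL

#' Fragment a genome into consecutive fixed-length windows
#'
#' Consecutive non-overlapping windows per contig; a trailing remainder
#' shorter than `fragLen` is discarded (rather than padded) so that
#' per-fragment statistics stay identically distributed.
#'
#' @param genome A [Genome-class] object.
#' @param fragLen Fragment length in bp (default 1020, the defining
#'   constant of the fragment-based ANI protocol).
#' @return A list: `fragments` (\linkS4class{DNAStringSet}) and `coords`
#'   (data.frame `contig_id`, `start`, `end`, 1-based closed).
#' @export
fragmentGenome <- function(genome, fragLen = 1020L) {
  ctg <- contigs(genome)
  if (max(width(ctg)) < fragLen)
    stop("genome shorter than one fragment", call. = FALSE)
  frags <- list(); coords <- list()
  for (i in seq_along(ctg)) {
    n <- width(ctg)[i] %/% fragLen
    if (n == 0L) next
    starts <- (seq_len(n) - 1L) * fragLen + 1L
    v <- Views(ctg[[i]], start = starts, width = fragLen)
    frags[[length(frags) + 1L]] <- as(v, "DNAStringSet")
    coords[[length(coords) + 1L]] <-
      data.frame(contig_id = names(ctg)[i], start = starts,
                 end = starts + fragLen - 1L, stringsAsFactors = FALSE)
  }
  fr <- do.call(c, frags)
  co <- do.call(rbind, coords)
  names(fr) <- sprintf("frag%05d", seq_along(fr))
  list(fragments = fr, coords = co)
}

## Locate candidate placements of fragments in a subject via exact
## k-mer seeds taken at several offsets, then rescore the candidate
## window by full local dynamic programming. Both strands are searched.
.DNA_SUBMAT <- NULL

.dnaSubMat <- function(match = 1, mismatch = -1) {
  Biostrings::nucleotideSubstitutionMatrix(match = match,
                                           mismatch = mismatch,
                                           baseOnly = TRUE)
}

## One matchPDict pass with seeds at a fixed offset for all unresolved
## fragments; returns candidate subject positions (start of fragment).
.seedPass <- function(frags, subjectSeq, offset, k) {
  seeds <- subseq(frags, start = offset, width = k)
  pd <- Biostrings::PDict(seeds)
  hits <- Biostrings::matchPDict(pd, subjectSeq)
  st <- startIndex(hits)
  vapply(st, function(s) if (is.null(s)) NA_integer_ else s[1L],
         integer(1)) - (offset - 1L)
}

#' Map a fragment to a subject genome
#'
#' Seeded search (exact k-mer seeds at several offsets, both strands)
#' followed by full dynamic-programming local alignment of the fragment
#' against the candidate subject window. Identity is the fraction of
#' identical positions over alignment columns (gap columns included).
#'
#' @param frag A \linkS4class{DNAString} (or character) fragment.
#' @param subject A [Genome-class] or \linkS4class{DNAStringSet}.
#' @param k Seed length (default 18).
#' @param margin Extra subject bases around the candidate window.
#' @return `NULL` when no seed matches; otherwise a list with
#'   `identity`, `aligned_len` (alignment columns), `strand`, `contig`,
#'   `raw_score`.
#' @export
mapFragment <- function(frag, subject, k = 18L, margin = 60L) {
  sset <- if (is(subject, "Genome")) contigs(subject)
          else as(subject, "DNAStringSet")
  frag <- DNAString(as.character(frag))
  fl <- length(frag)
  offsets <- unique(pmax(1L, pmin(fl - k + 1L,
                                  round(seq(1L, fl - k + 1L,
                                            length.out = 5L)))))
  best <- NULL
  for (strand in c("+", "-")) {
    f <- if (strand == "+") frag else reverseComplement(frag)
    for (ci in seq_along(sset)) {
      subj <- sset[[ci]]
      for (off in offsets) {
        seed <- subseq(f, off, width = k)
        m <- Biostrings::matchPattern(seed, subj)
        if (!length(m)) next
        cand <- .rescoreWindow(f, subj, start(m)[1L] - (off - 1L), margin)
        if (is.null(best) || cand$raw_score > best$raw_score) {
          best <- cand
          best$strand <- strand
          best$contig <- names(sset)[ci]
        }
        break  # first matching seed on this strand/contig is enough
      }
    }
  }
  best
}

.rescoreWindow <- function(frag, subj, at, margin) {
  fl <- length(frag)
  ws <- max(1L, at - margin)
  we <- min(length(subj), at + fl - 1L + margin)
  win <- subseq(subj, ws, we)
  aln <- Biostrings::pairwiseAlignment(
    frag, win, type = "local", substitutionMatrix = .dnaSubMat(),
    gapOpening = 2, gapExtension = 1)
  cols <- nchar(aln)
  list(identity = if (cols > 0) nmatch(aln) / cols else 0,
       aligned_len = cols, raw_score = score(aln))
}

## Batch mapping used by aniPair: one matchPDict pass per seed offset
## per strand, falling back across offsets for unresolved fragments.
.mapFragmentsBatch <- function(frags, subjectSeqs, k = 18L, margin = 60L) {
  n <- length(frags)
  identity <- rep(NA_real_, n)
  alignedLen <- rep(NA_integer_, n)
  fl <- width(frags)[1L]
  offsets <- round(seq(1L, fl - k + 1L, length.out = 5L))
  bestScore <- rep(-Inf, n)
  for (ci in seq_along(subjectSeqs)) {
    subj <- subjectSeqs[[ci]]
    for (strandDir in c("+", "-")) {
      f <- if (strandDir == "+") frags else reverseComplement(frags)
      unresolved <- rep(TRUE, n)
      for (off in offsets) {
        if (!any(unresolved)) break
        ii <- which(unresolved)
        pos <- .seedPass(f[ii], subj, off, k)
        hit <- which(!is.na(pos))
        for (h in hit) {
          i <- ii[h]
          cand <- .rescoreWindow(f[[i]], subj, pos[h], margin)
          if (cand$raw_score > bestScore[i]) {
            bestScore[i] <- cand$raw_score
            identity[i] <- cand$identity
            alignedLen[i] <- cand$aligned_len
          }
        }
        unresolved[ii[hit]] <- FALSE
      }
    }
  }
  data.frame(identity = identity, aligned_len = alignedLen)
}

#' Fragment-based ANI of a genome pair
#'
#' The query genome is cut into `fragLen` windows, each mapped to the
#' subject (both strands, seeded search plus local DP rescoring).
#' Fragments are retained when the best hit has identity >= `minId`
#' over an aligned length >= `minFrac * fragLen`; the directed ANI is
#' 100 times the mean identity of retained fragments, and the symmetric
#' ANI the mean of the two directions. When no fragment is retained the
#' directed value is reported as `NA` (undefined), not 0.
#'
#' @param q,s [Genome-class] objects.
#' @param fragLen Fragment length (default 1020 nt).
#' @param minId Identity retention threshold (default 0.30).
#' @param minFrac Aligned-length retention threshold as a fraction of
#'   `fragLen` (default 0.70).
#' @return An [AniResult-class] object.
#' @examples
#' \donttest{
#' pair <- simulateDivergedPair(0.99, lengthBp = 5e4, seed = 1)
#' aniPair(pair$A, pair$B, fragLen = 1020)
#' }
#' @export
aniPair <- function(q, s, fragLen = 1020L, minId = 0.30, minFrac = 0.70) {
  .assertScalarNumber(minId, "minId", 1e-9, 1)
  .assertScalarNumber(minFrac, "minFrac", 1e-9, 1)
  direction <- function(qq, ss) {
    fr <- fragmentGenome(qq, fragLen)
    mp <- .mapFragmentsBatch(fr$fragments, contigs(ss))
    keep <- !is.na(mp$identity) & mp$identity >= minId &
      mp$aligned_len >= minFrac * fragLen
    list(nFrag = length(fr$fragments), nKept = sum(keep),
         ids = mp$identity[keep])
  }
  d1 <- direction(q, s)
  d2 <- direction(s, q)
  a1 <- if (d1$nKept > 0L) 100 * mean(d1$ids) else NA_real_
  a2 <- if (d2$nKept > 0L) 100 * mean(d2$ids) else NA_real_
  sym <- mean(c(a1, a2), na.rm = FALSE)
  new("AniResult", query = strainId(q), subject = strainId(s),
      nFragments = c(d1$nFrag, d2$nFrag),
      nRetained = c(d1$nKept, d2$nKept),
      identities = list(d1$ids, d2$ids),
      aniDirected = c(a1, a2), aniSymmetric = sym)
}

#' Symmetric ANI matrix of a strain set
#'
#' @param genomes Named list of [Genome-class] objects.
#' @param ... Passed to [aniPair()].
#' @return Symmetric numeric matrix (percent, diagonal 100).
#' @export
aniMatrix <- function(genomes, ...) {
  strains <- names(genomes)
  n <- length(strains)
  M <- matrix(100, n, n, dimnames = list(strains, strains))
  if (n < 2L) return(M)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- aniPair(genomes[[i]], genomes[[j]], ...)
    M[i, j] <- M[j, i] <- aniSymmetric(r)
  }
  M
}
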