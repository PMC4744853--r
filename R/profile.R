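#' @include io.R
NULL

#' Build a per-column log-odds profile from a seed alignment
#'
#' Columns with a gap fraction of 0.5 or more are dropped; each kept
#' column scores amino acid `a` as
#' `log2( (count_a + pc * bg_a) / (n + pc) / bg_a )` where `n` is the
#' number of residues observed in the column and `pc` the pseudocount
#' weight. The background is uniform (1/20) or derived from the seed's
#' overall residue frequencies.
#'
#' @param seedMsa Aligned \linkS4class{AAStringSet} (>= 2 rows) or
#'   character matrix.
#' @param pseudocount Pseudocount weight (default 1.0).
#' @param background `"uniform"` or `"seed"`.
#' @param family Family name stored in the model.
#' @return A [ProfileModel-class] object.
#' @export
buildProfile <- function(seedMsa, pseudocount = 1.0,
                         background = c("uniform", "seed"),
                         family = "family") {
  background <- match.arg(background)
  m <- .msaMatrix(seedMsa)
  if (nrow(m) < 2L) stop("seed alignment needs >= 2 rows", call. = FALSE)
  m <- toupper(m)
  isGap <- !(m %in% AA20)
  dim(isGap) <- dim(m)
  keep <- colMeans(isGap) < 0.5
  if (!any(keep))
    stop("no columns left after gap filtering", call. = FALSE)
  m <- m[, keep, drop = FALSE]
  bg <- if (background == "uniform") setNames(rep(1 / 20, 20), AA20)
  else {
    cnt <- table(factor(m[m %in% AA20], levels = AA20))
    f <- (as.numeric(cnt) + 1e-3) / (sum(cnt) + 20e-3)
    setNames(f, AA20)
  }
  W <- ncol(m)
  S <- matrix(0, 20L, W, dimnames = list(AA20, NULL))
  for (j in seq_len(W)) {
    col <- m[, j]
    col <- col[col %in% AA20]
    n <- length(col)
    cnt <- table(factor(col, levels = AA20))
    S[, j] <- log2((as.numeric(cnt) + pseudocount * bg) /
                     (n + pseudocount) / bg)
  }
  new("ProfileModel", family = family, scores = S, background = bg,
      pseudocount = pseudocount)
}

#' Scan a protein with a log-odds profile
#'
#' Computes the best ungapped placement score (sum of column scores)
#' over all offsets. In `"local"` mode the profile must lie fully
#' inside the protein (falling back to glocal when the protein is
#' shorter than the profile); `"glocal"` additionally allows terminal
#' truncation of the profile, scoring only the overlapping columns.
#' Residues outside the 20-letter alphabet contribute 0.
#'
#' @param profile A [ProfileModel-class].
#' @param protein Character or \linkS4class{AAString}.
#' @param mode `"local"` or `"glocal"`.
#' @return List: `family`, `bitscore` (best placement score),
#'   `start`, `end` (aligned span on the protein).
#' @export
scanProtein <- function(profile, protein, mode = c("local", "glocal")) {
  mode <- match.arg(mode)
  p <- toupper(as.character(protein))
  L <- nchar(p)
  if (L < 1L) stop("empty protein", call. = FALSE)
  W <- ncol(profile@scores)
  ri <- match(strsplit(p, "")[[1L]], AA20)   # NA for X etc.
  S <- profile@scores
  best <- -Inf; bestStart <- NA_integer_; bestEnd <- NA_integer_
  score_span <- function(protStart, colStart, len) {
    idx <- ri[protStart:(protStart + len - 1L)]
    cols <- colStart:(colStart + len - 1L)
    valid <- !is.na(idx)
    if (!any(valid)) return(0)
    sum(S[cbind(idx[valid], cols[valid])])
  }
  if (L >= W) {
    nOff <- L - W + 1L
    sc <- numeric(nOff)
    for (j in seq_len(W)) {
      v <- S[, j][ri[j:(j + nOff - 1L)]]
      v[is.na(v)] <- 0
      sc <- sc + v
    }
    k <- which.max(sc)
    best <- sc[k]; bestStart <- k; bestEnd <- k + W - 1L
  }
  if (mode == "glocal" || L < W) {
    ## profile overhangs the protein ends; overlap >= half the profile
    minOv <- max(1L, min(L, ceiling(W / 2)))
    for (ov in seq(minOv, min(L, W - 1L))) {
      s1 <- score_span(1L, W - ov + 1L, ov)          # left truncation
      if (s1 > best) { best <- s1; bestStart <- 1L; bestEnd <- ov }
      s2 <- score_span(L - ov + 1L, 1L, ov)          # right truncation
      if (s2 > best) { best <- s2; bestStart <- L - ov + 1L; bestEnd <- L }
    }
  }
  list(family = profile@family, bitscore = unname(best),
       start = unname(bestStart), end = unname(bestEnd))
}

#' Calibrate profile e-values against a shuffled decoy proteome
#'
#' Decoys are residue-shuffled copies of proteins drawn from the target
#' proteome (composition-matched null). A Gumbel location/scale is
#' fitted to the decoy scores by moment matching
#' (`beta = sd sqrt(6) / pi`, `mu = mean - gamma beta`), and
#' `evalue(s) = nTargets * (1 - exp(-exp(-(s - mu) / beta)))`.
#'
#' @param profile A [ProfileModel-class].
#' @param proteome Named \linkS4class{AAStringSet} (the scan target).
#' @param nDecoys Number of decoys (>= 100).
#' @param seed Optional RNG seed.
#' @return List: `mu`, `beta`, `nTargets`, and `evalue(score)`.
#' @export
calibrateEvalue <- function(profile, proteome, nDecoys = 200L,
                            seed = NULL) {
  if (nDecoys < 100L) stop("nDecoys must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  src <- as.character(proteome)
  ## restrict to proteins at least as long as the profile so that all
  ## decoy scores are full-width placements (length heterogeneity would
  ## otherwise inflate the fitted scale)
  long <- src[nchar(src) >= ncol(profile@scores)]
  if (length(long) >= 3L) src <- long
  pick <- sample(seq_along(src), nDecoys, replace = TRUE)
  scores <- vapply(pick, function(i) {
    sh <- .collapse(sample(strsplit(src[i], "")[[1L]]))
    scanProtein(profile, sh)$bitscore
  }, numeric(1))
  m <- mean(scores); sdv <- stats::sd(scores)
  if (!is.finite(sdv) || sdv < 1e-9)
    stop("degenerate decoy score variance", call. = FALSE)
  beta <- sdv * sqrt(6) / pi
  mu <- m - 0.5772156649 * beta
  nTargets <- length(proteome)
  list(mu = mu, beta = beta, nTargets = nTargets,
       ## -expm1(-y) = 1 - exp(-y), accurate in the extreme tail
       evalue = function(s)
         nTargets * (-expm1(-exp(-(s - mu) / beta))))
}

#' Marker-family presence/absence repertoire across strains
#'
#' Scans every proteome with every profile; a strain is scored `"+"`
#' for a family iff at least one of its proteins passes the calibrated
#' e-value cutoff (calibration is per strain, against its own shuffled
#' proteome).
#'
#' @param genomes Named list of [Genome-class] objects.
#' @param profiles Named list of [ProfileModel-class] objects.
#' @param evalueCut E-value cutoff (default 1e-6).
#' @param nDecoys Decoys per calibration.
#' @param seed Optional RNG seed.
#' @return A [TraitTable-class] (families x strains, `+`/`-`).
#' @export
repertoire <- function(genomes, profiles, evalueCut = 1e-6,
                       nDecoys = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  strains <- names(genomes)
  fams <- vapply(profiles, function(p) p@family, "")
  vals <- matrix("-", nrow = length(profiles), ncol = length(strains))
  for (si in seq_along(strains)) {
    prot <- proteome(genomes[[si]])
    for (pi in seq_along(profiles)) {
      cal <- calibrateEvalue(profiles[[pi]], prot, nDecoys = nDecoys)
      sc <- vapply(seq_along(prot), function(k)
        scanProtein(profiles[[pi]], prot[[k]])$bitscore, numeric(1))
      if (any(cal$evalue(sc) <= evalueCut)) vals[pi, si] <- "+"
    }
  }
  new("TraitTable", strains = strains, traits = unname(fams),
      groups = rep("marker_family", length(profiles)), values = vals,
      symbols = c("+", "-"))
}
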