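#' @include io.R
NULL

#' Sliding-window GC scan of a genome
#'
#' GC percent per window; z-scores are standardised against the mean
#' and standard deviation of all windows of the same genome (each
#' genome is its own compositional background). Contigs shorter than
#' one window are skipped with a message. A uniform genome (window
#' standard deviation 0) yields all-zero z-scores rather than an error.
#'
#' @param genome A [Genome-class] object.
#' @param window Window size in bp (default 5000).
#' @param step Step size in bp (default 500).
#' @return A [WindowScan-class] object.
#' @export
windowScan <- function(genome, window = 5000L, step = 500L) {
  ctg <- contigs(genome)
  tabs <- list()
  for (i in seq_along(ctg)) {
    w <- width(ctg)[i]
    if (w < window) {
      message("skipping contig ", names(ctg)[i],
              " shorter than one window")
      next
    }
    starts <- seq(1L, w - window + 1L, by = step)
    v <- Views(ctg[[i]], start = starts, width = window)
    f <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    acgt <- rowSums(f)
    gc <- ifelse(acgt == 0, NA_real_,
                 100 * (f[, "G"] + f[, "C"]) / acgt)
    tabs[[length(tabs) + 1L]] <-
      data.frame(contig_id = names(ctg)[i], start = starts,
                 end = starts + window - 1L, gc = gc,
                 stringsAsFactors = FALSE)
  }
  if (!length(tabs))
    stop("no contig is at least one window long", call. = FALSE)
  tab <- do.call(rbind, tabs)
  mu <- mean(tab$gc, na.rm = TRUE)
  sdv <- stats::sd(tab$gc, na.rm = TRUE)
  tab$z <- if (is.na(sdv) || sdv == 0) 0 else (tab$gc - mu) / sdv
  new("WindowScan", table = tab, windowBp = as.integer(window),
      stepBp = as.integer(step), genomeMeanGc = mu,
      genomeSdGc = ifelse(is.na(sdv), 0, sdv))
}

#' Call GC-anomalous genomic island candidates
#'
#' Maximal runs of windows with z below the cutoff (low-GC mode, the
#' default) or |z| above |cutoff| (`mode = "abs"`), merged across gaps
#' up to `mergeGap`, trimmed to window boundaries and kept when the
#' merged span is at least `minLen`. Mean GC is recomputed over the
#' exact final span.
#'
#' @param genome The scanned [Genome-class] object.
#' @param scan A [WindowScan-class] from [windowScan()].
#' @param zCut z-score cutoff (must be negative in low-GC mode;
#'   default -3).
#' @param minLen Minimum island span in bp (default 8000).
#' @param mergeGap Maximum gap merged between anomalous windows
#'   (default twice the scan step).
#' @param mode `"low"` (default) or `"abs"`.
#' @return \linkS4class{GRanges} with metadata columns `mean_gc`,
#'   `genome_gc`, `z_min`, `n_windows`.
#' @export
callIslands <- function(genome, scan, zCut = -3, minLen = 8000L,
                        mergeGap = 2L * scan@stepBp,
                        mode = c("low", "abs")) {
  mode <- match.arg(mode)
  if (mode == "low" && zCut >= 0)
    stop("zCut must be negative in low-GC mode", call. = FALSE)
  tab <- scan@table
  sel <- if (mode == "low") tab$z <= zCut else abs(tab$z) >= abs(zCut)
  sel[is.na(sel)] <- FALSE
  genomeGc <- .gcPercentPooled(contigs(genome))
  out <- GRanges()
  for (cn in unique(tab$contig_id)) {
    t0 <- tab[tab$contig_id == cn & sel, , drop = FALSE]
    if (!nrow(t0)) next
    ir <- IRanges::reduce(IRanges(t0$start, t0$end),
                          min.gapwidth = mergeGap + 1L)
    ir <- ir[width(ir) >= minLen]
    if (!length(ir)) next
    gr <- GRanges(cn, ir)
    gr$mean_gc <- vapply(seq_along(ir), function(k) {
      .gcPercentPooled(subseq(contigs(genome)[[cn]],
                              start(ir)[k], end(ir)[k]))
    }, numeric(1))
    gr$genome_gc <- genomeGc
    gr$z_min <- vapply(seq_along(ir), function(k) {
      inwin <- t0$start >= start(ir)[k] & t0$end <= end(ir)[k]
      min(t0$z[inwin])
    }, numeric(1))
    gr$n_windows <- vapply(seq_along(ir), function(k)
      sum(t0$start >= start(ir)[k] & t0$end <= end(ir)[k]), integer(1))
    out <- c(out, gr)
  }
  out
}

#' Default mobile-genetic-element keyword lexicon
#'
#' Lowercase keywords matched case-insensitively as substrings in
#' product annotations; the `"IS"` entry is matched case-sensitively at
#' a word boundary (so `IS643` counts, `island` does not).
#'
#' @return Character vector of keywords.
#' @export
mgeLexicon <- function() {
  c("integrase", "transposase", "insertion sequence", "phage",
    "recombinase", "IS")
}

.matchesLexicon <- function(product, lexicon) {
  hit <- character(0)
  for (kw in lexicon) {
    ok <- if (kw == "IS") grepl("\\bIS[0-9A-Za-z]*\\b", product)
          else grepl(kw, product, ignore.case = TRUE, fixed = FALSE)
    if (ok) hit <- c(hit, kw)
  }
  hit
}

#' Attach mobile-element context markers to island calls
#'
#' Markers are genes overlapping the island or lying within `margin` of
#' it whose product annotation contains a lexicon keyword.
#'
#' @param islands \linkS4class{GRanges} from [callIslands()].
#' @param featureGr \linkS4class{GRanges} of gene features (`gene_id`,
#'   `product` columns).
#' @param lexicon Keyword vector, see [mgeLexicon()].
#' @param margin Context margin in bp (default 5000).
#' @return `islands` with an added `mge_markers` list column of
#'   data.frames (`gene_id`, `keyword`).
#' @export
annotateMgeContext <- function(islands, featureGr, lexicon = mgeLexicon(),
                               margin = 5000L) {
  markers <- vector("list", length(islands))
  for (k in seq_along(islands)) {
    win <- islands[k]
    start(win) <- max(1L, start(win) - margin)
    end(win) <- end(win) + margin
    ov <- featureGr[as.character(seqnames(featureGr)) ==
                      as.character(seqnames(win)) &
                    start(featureGr) <= end(win) &
                    end(featureGr) >= start(win)]
    rows <- list()
    for (j in seq_along(ov)) {
      kw <- .matchesLexicon(ov$product[j], lexicon)
      if (length(kw))
        rows[[length(rows) + 1L]] <-
          data.frame(gene_id = ov$gene_id[j], keyword = kw[1L],
                     stringsAsFactors = FALSE)
    }
    markers[[k]] <- if (length(rows)) do.call(rbind, rows)
                    else data.frame(gene_id = character(),
                                    keyword = character(),
                                    stringsAsFactors = FALSE)
  }
  islands$mge_markers <- markers
  islands
}

#' Exact direct repeats flanking an island
#'
#' Searches for exact maximal direct repeats with one copy wholly
#' inside the left margin and one wholly inside the right margin of the
#' island (repeats straddling a margin boundary are excluded), found by
#' shared-substring indexing and maximal extension within the margins.
#'
#' @param genome A [Genome-class] object.
#' @param island A single-range \linkS4class{GRanges} (or list with
#'   `contig`, `start`, `end`).
#' @param minLen Minimum repeat length (default 15).
#' @param margin Margin width in bp on each side (default 2000).
#' @return data.frame: `left_start`, `right_start` (1-based genome
#'   coordinates), `length`.
#' @export
findFlankRepeats <- function(genome, island, minLen = 15L,
                             margin = 2000L) {
  if (is(island, "GRanges")) {
    stopifnot(length(island) == 1L)
    cn <- as.character(seqnames(island))
    s <- start(island); e <- end(island)
  } else {
    cn <- island$contig; s <- island$start; e <- island$end
  }
  ctg <- contigs(genome)[[cn]]
  ls <- max(1L, s - margin); le <- s - 1L
  rs <- e + 1L; re <- min(length(ctg), e + margin)
  if (le < ls || re < rs) return(.emptyRepeats())
  left <- as.character(subseq(ctg, ls, le))
  right <- as.character(subseq(ctg, rs, re))
  nl <- nchar(left); nr <- nchar(right)
  if (nl < minLen || nr < minLen) return(.emptyRepeats())
  lk <- substring(left, 1:(nl - minLen + 1L), minLen:nl)
  rk <- substring(right, 1:(nr - minLen + 1L), minLen:nr)
  common <- intersect(lk, rk)
  if (!length(common)) return(.emptyRepeats())
  lc <- strsplit(left, "")[[1L]]
  rc <- strsplit(right, "")[[1L]]
  seen <- character(0)
  out <- list()
  for (kmer in common) {
    lpos <- which(lk == kmer)
    rpos <- which(rk == kmer)
    for (i in lpos) for (j in rpos) {
      a <- i; b <- j
      while (a > 1L && b > 1L && lc[a - 1L] == rc[b - 1L]) {
        a <- a - 1L; b <- b - 1L
      }
      ea <- i + minLen - 1L; eb <- j + minLen - 1L
      while (ea < nl && eb < nr && lc[ea + 1L] == rc[eb + 1L]) {
        ea <- ea + 1L; eb <- eb + 1L
      }
      key <- paste(a, b, ea - a + 1L)
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <-
        data.frame(left_start = ls + a - 1L, right_start = rs + b - 1L,
                   length = ea - a + 1L)
    }
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res[order(-res$length, res$left_start), , drop = FALSE]
}

.emptyRepeats <- function() {
  data.frame(left_start = integer(), right_start = integer(),
             length = integer())
}
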