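#' @include io.R
NULL

## ---------------------------------------------------------------------
## Internal element-list representation: a genome is an alternating list
## of spacers and genes; genes carry a family id and a product string.
## This makes gene loss ("excised with its spacer"), gene gain and
## island insertion coordinate-free, with reassembly at the end.
## ---------------------------------------------------------------------

.element <- function(kind, seq, family = NA_character_,
                     product = NA_character_) {
  list(kind = kind, seq = seq, family = family, product = product)
}

.genomeElements <- function(genome) {
  ctg <- contigs(genome)
  ft <- features(genome)
  lapply(seq_along(ctg), function(i) {
    cn <- names(ctg)[i]
    seqc <- as.character(ctg[[i]])
    f <- ft[as.character(seqnames(ft)) == cn]
    f <- f[order(start(f))]
    fam <- if (!is.null(f$family)) f$family else f$gene_id
    els <- list()
    pos <- 1L
    for (k in seq_along(f)) {
      if (start(f)[k] > pos)
        els[[length(els) + 1L]] <-
          .element("spacer", substring(seqc, pos, start(f)[k] - 1L))
      els[[length(els) + 1L]] <-
        .element("gene", substring(seqc, start(f)[k], end(f)[k]),
                 family = fam[k], product = f$product[k])
      pos <- end(f)[k] + 1L
    }
    if (pos <= nchar(seqc))
      els[[length(els) + 1L]] <- .element("spacer", substring(seqc, pos))
    els
  })
}

.assembleFromElements <- function(strainId, contigNames, elementsPerContig,
                                  idSep = "_") {
  seqs <- character(length(elementsPerContig))
  fts <- list()
  for (i in seq_along(elementsPerContig)) {
    els <- elementsPerContig[[i]]
    lens <- vapply(els, function(e) nchar(e$seq), integer(1))
    starts <- cumsum(c(1L, utils::head(lens, -1L)))
    isGene <- vapply(els, function(e) e$kind == "gene", logical(1))
    seqs[i] <- .collapse(vapply(els, `[[`, "", "seq"))
    if (any(isGene)) {
      fam <- vapply(els[isGene], `[[`, "", "family")
      gr <- GRanges(contigNames[i],
                    IRanges(starts[isGene], width = lens[isGene]),
                    strand = "+")
      gr$gene_id <- paste0(gsub("[^A-Za-z0-9._-]", "_", strainId),
                           idSep, fam)
      gr$product <- vapply(els[isGene], `[[`, "", "product")
      gr$family <- fam
      fts[[length(fts) + 1L]] <- gr
    }
  }
  ft <- if (length(fts)) suppressWarnings(do.call(c, fts)) else GRanges()
  Genome(strainId, DNAStringSet(setNames(seqs, contigNames)), ft)
}

## Expected GC fraction of an interior (stop-rejected) codon when each
## base is drawn i.i.d. with per-base GC probability g.
.interiorGcMean <- function(g) {
  b <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
  bases <- names(b)
  tot <- 0; wsum <- 0
  for (x in bases) for (y in bases) for (z in bases) {
    codon <- paste0(x, y, z)
    if (codon %in% STOP_CODONS) next
    p <- b[[x]] * b[[y]] * b[[z]]
    gcc <- sum(c(x, y, z) %in% c("G", "C"))
    tot <- tot + p
    wsum <- wsum + p * gcc
  }
  wsum / tot / 3
}

## Solve the per-base GC probability for interior codons so that the
## whole construct (ATG starts, TAA stops, spacers drawn at `target`)
## has expected GC equal to `target`.
.solveInteriorGc <- function(target, nGenes, nInteriorCodons, nSpacerBases) {
  total <- nSpacerBases + 6 * nGenes + 3 * nInteriorCodons
  need <- (target * (total - nSpacerBases) - nGenes) / (3 * nInteriorCodons)
  if (need <= 0.01 || need >= 0.99)
    stop("requested GC is outside the achievable codon range", call. = FALSE)
  stats::uniroot(function(g) .interiorGcMean(g) - need,
                 interval = c(0.005, 0.995), tol = 1e-7)$root
}

.makeGene <- function(nInteriorCodons, gBase) {
  .collapse(c("ATG", .sampleNonStopCodons(nInteriorCodons, gBase), "TAA"))
}

## ---------------------------------------------------------------------
## Configuration objects
## ---------------------------------------------------------------------

#' Specification of a genomic island to plant
#'
#' Describes a contiguous segment to insert into a recipient strain:
#' length, target GC (possibly equal to the background, for negative
#' controls), number of mobile-element marker genes (products drawn from
#' the integrase/transposase/phage keyword lexicon), optional exact
#' direct repeats flanking the island, and the cargo gene's family id.
#'
#' @param recipient Strain id receiving the island.
#' @param lengthBp Island length in bp (>= 1000).
#' @param gc Island GC fraction.
#' @param nMarkerGenes Number of MGE marker genes (>= 0).
#' @param flankRepeatLen Length of the exact direct repeats placed at
#'   both island ends (0 = none).
#' @param cargoFamilyId Family id of the cargo gene (present in no other
#'   strain unless configured as donor-shared).
#' @param cargoProduct Product annotation of the cargo gene.
#' @return A list of class `islandSpec`.
#' @export
islandSpec <- function(recipient, lengthBp, gc, nMarkerGenes = 2L,
                       flankRepeatLen = 20L, cargoFamilyId = "cargo",
                       cargoProduct = "phosphonate ABC transporter permease") {
  .assertScalarNumber(lengthBp, "lengthBp", 1000, Inf)
  .assertScalarNumber(gc, "gc", 0.01, 0.99)
  .assertScalarNumber(nMarkerGenes, "nMarkerGenes", 0, Inf)
  .assertScalarNumber(flankRepeatLen, "flankRepeatLen", 0, Inf)
  structure(list(recipient = recipient, lengthBp = as.integer(lengthBp),
                 gc = gc, nMarkerGenes = as.integer(nMarkerGenes),
                 flankRepeatLen = as.integer(flankRepeatLen),
                 cargoFamilyId = cargoFamilyId,
                 cargoProduct = cargoProduct),
            class = "islandSpec")
}

#' Configuration of a synthetic conspecific clade
#'
#' The defaults emulate a three-strain conspecific clade at 1/10 scale:
#' 290 core families, 30 two-strain shared families, 12/11/9
#' strain-specific families, ~38% background GC, per-branch divergence
#' calibrated so that pairwise expected per-site identities are
#' 0.9937 / 0.9893 / 0.9888, and one 25-kb low-GC (31.68%) island
#' carrying a cargo gene, two MGE marker genes and 20-bp flanking direct
#' repeats in strain m2-6.
#'
#' @param strains Character vector of strain ids (>= 2).
#' @param nCore Number of core gene families.
#' @param sharedPatterns Named integer vector; names are strain subsets
#'   joined with `|` (e.g. `"m4-4|m2-6"`), values are family counts.
#' @param specific Named integer vector of strain-specific family counts
#'   (one entry per strain).
#' @param geneLenMeanBp,geneLenSdBp Gene length distribution (bp).
#' @param backgroundGc Genome background GC fraction (0.2-0.8).
#' @param branchSubRate Named numeric, per-site substitution probability
#'   on each strain's branch from the common ancestor (each in [0, 0.25]).
#' @param islands List of [islandSpec()] objects.
#' @param seed Integer RNG seed.
#' @return A list of class `cladeConfig`.
#' @examples
#' cfg <- cladeConfig(nCore = 20, sharedPatterns = c("m4-4|m2-6" = 2),
#'                    specific = c("m4-4" = 1, "m2-6" = 1, "p1.1.43" = 1),
#'                    islands = list())
#' @export
cladeConfig <- function(strains = c("m4-4", "m2-6", "p1.1.43"),
                        nCore = 290L,
                        sharedPatterns = c("m4-4|m2-6" = 14L,
                                           "m2-6|p1.1.43" = 8L,
                                           "m4-4|p1.1.43" = 8L),
                        specific = c("m4-4" = 11L, "m2-6" = 9L,
                                     "p1.1.43" = 12L),
                        geneLenMeanBp = 900, geneLenSdBp = 150,
                        backgroundGc = 0.3797,
                        branchSubRate = c("m4-4" = 0.0034069,
                                          "m2-6" = 0.0029030,
                                          "p1.1.43" = 0.0078197),
                        islands = list(islandSpec(
                          recipient = "m2-6", lengthBp = 25000L,
                          gc = 0.3168, nMarkerGenes = 2L,
                          flankRepeatLen = 20L,
                          cargoFamilyId = "phn_cargo")),
                        seed = 20160208L) {
  if (length(strains) < 2L) stop("need at least 2 strains", call. = FALSE)
  .assertScalarNumber(backgroundGc, "backgroundGc", 0.2, 0.8)
  if (!all(names(branchSubRate) %in% strains) ||
      !all(strains %in% names(branchSubRate)))
    stop("branchSubRate must be named by the strains", call. = FALSE)
  if (any(branchSubRate < 0 | branchSubRate > 0.25))
    stop("branch substitution rates must lie in [0, 0.25]", call. = FALSE)
  if (any(c(nCore, sharedPatterns, specific) < 0))
    stop("all family counts must be >= 0", call. = FALSE)
  if (length(sharedPatterns)) {
    pats <- strsplit(names(sharedPatterns), "|", fixed = TRUE)
    ok <- vapply(pats, function(p)
      length(p) >= 2L && length(p) < length(strains) &&
        all(p %in% strains), logical(1))
    if (!all(ok))
      stop("sharedPatterns names must be proper multi-strain subsets ",
           "of the configured strains", call. = FALSE)
  }
  if (!all(names(specific) %in% strains))
    stop("specific counts reference unknown strains", call. = FALSE)
  for (isl in islands) {
    if (!inherits(isl, "islandSpec"))
      stop("islands must be a list of islandSpec objects", call. = FALSE)
    if (!isl$recipient %in% strains)
      stop("island recipient not among strains: ", isl$recipient,
           call. = FALSE)
  }
  structure(list(strains = strains, nCore = as.integer(nCore),
                 sharedPatterns = sharedPatterns,
                 specific = specific,
                 geneLenMeanBp = geneLenMeanBp, geneLenSdBp = geneLenSdBp,
                 backgroundGc = backgroundGc,
                 branchSubRate = branchSubRate[strains],
                 islands = islands, seed = as.integer(seed)),
            class = "cladeConfig")
}

## Family table implied by a clade config (before any islands).
.configFamilies <- function(cfg) {
  fam <- data.frame(family_id = character(), category = character(),
                    pattern = character(), stringsAsFactors = FALSE)
  add <- function(n, prefix, category, pattern) {
    if (n <= 0) return()
    ids <- sprintf("%s%04d", prefix, seq_len(n) + nrow(fam))
    fam <<- rbind(fam, data.frame(family_id = ids, category = category,
                                  pattern = pattern,
                                  stringsAsFactors = FALSE))
  }
  add(cfg$nCore, "fam", "core", paste(cfg$strains, collapse = "|"))
  for (p in names(cfg$sharedPatterns))
    add(cfg$sharedPatterns[[p]], "fam", "shared", p)
  for (s in cfg$strains)
    add(cfg$specific[[s]] %||% 0L, "fam", "specific", s)
  fam
}

## ---------------------------------------------------------------------
## Generation
## ---------------------------------------------------------------------

#' Generate the common ancestor genome of a synthetic clade
#'
#' Builds one contig of open reading frames (ATG start, stop-free
#' interior, TAA stop) separated by 50-500 bp intergenic spacers. The
#' ancestor carries every configured family (core, shared and specific);
#' descendants are derived by branch-specific loss and substitution.
#' Base composition is matched to the configured background GC by
#' solving the interior-codon sampling bias numerically.
#'
#' @param cfg A [cladeConfig()] object.
#' @param seed Optional seed (defaults to `cfg$seed`).
#' @return A [Genome-class] for strain `"ancestor"`; features carry a
#'   `family` metadata column.
#' @export
generateAncestor <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  fam <- .configFamilies(cfg)
  n <- nrow(fam)
  if (n == 0L) stop("configuration defines no gene families", call. = FALSE)
  nCod <- pmax(30L, round(stats::rnorm(n, cfg$geneLenMeanBp / 3,
                                       cfg$geneLenSdBp / 3)))
  spLen <- sample(50:500, n + 1L, replace = TRUE)
  gBase <- .solveInteriorGc(cfg$backgroundGc, n, sum(nCod), sum(spLen))
  els <- vector("list", 2L * n + 1L)
  els[[1L]] <- .element("spacer", .collapse(.sampleBases(spLen[1L],
                                                         cfg$backgroundGc)))
  for (i in seq_len(n)) {
    els[[2L * i]] <- .element("gene", .makeGene(nCod[i], gBase),
                              family = fam$family_id[i],
                              product = "hypothetical protein")
    els[[2L * i + 1L]] <-
      .element("spacer", .collapse(.sampleBases(spLen[i + 1L],
                                                cfg$backgroundGc)))
  }
  .assembleFromElements("ancestor", "chr", list(els))
}

## Per-site substitution with equal exchange rates among the three
## alternative bases; ambiguity codes are left untouched.
.mutateSeq <- function(seq, rate) {
  n <- nchar(seq)
  if (rate <= 0 || n == 0L) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  idx <- which(stats::runif(n) < rate & ch %in% c("A", "C", "G", "T"))
  if (!length(idx)) return(seq)
  alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  pick <- sample.int(3L, length(idx), replace = TRUE)
  ch[idx] <- vapply(seq_along(idx),
                    function(i) alts[[ch[idx[i]]]][pick[i]], "")
  .collapse(ch)
}

## Re-substitute sites whose mutation created an internal stop codon,
## keeping the site different from the ancestral base where possible.
.fixInternalStops <- function(newSeq, oldSeq) {
  n <- nchar(newSeq)
  if (n < 9L || n %% 3L != 0L) return(newSeq)
  starts <- seq(4L, n - 6L, by = 3L)  # interior codons only
  cods <- substring(newSeq, starts, starts + 2L)
  bad <- which(cods %in% STOP_CODONS)
  if (!length(bad)) return(newSeq)
  ch <- strsplit(newSeq, "")[[1L]]
  och <- strsplit(oldSeq, "")[[1L]]
  bases <- c("A", "C", "G", "T")
  for (b in bad) {
    off <- starts[b]
    fixed <- FALSE
    for (p in (off):(off + 2L)) {
      if (ch[p] == och[p]) next
      cand <- sample(setdiff(bases, c(ch[p], och[p])))
      for (x in cand) {
        trial <- ch[off:(off + 2L)]
        trial[p - off + 1L] <- x
        if (!(.collapse(trial) %in% STOP_CODONS)) {
          ch[p] <- x; fixed <- TRUE; break
        }
      }
      if (fixed) break
    }
    if (!fixed) ch[off:(off + 2L)] <- och[off:(off + 2L)]
  }
  .collapse(ch)
}

#' Evolve a genome along one branch
#'
#' Applies i.i.d. per-site substitutions (equal exchange among the three
#' alternative bases), excises lost gene families together with their
#' preceding spacer, and inserts gained genes at random intergenic
#' points. Gene order is otherwise preserved. Substitutions that would
#' create an internal stop codon are re-drawn so that every gene remains
#' an open reading frame.
#'
#' @param ancestor A [Genome-class] whose features carry a `family`
#'   column (as produced by [generateAncestor()]).
#' @param rate Per-site substitution probability in [0, 0.25].
#' @param losses Character vector of family ids to excise.
#' @param gains List of gain specs: `list(family=, nCodons=, gc=,
#'   product=)`; sequences are drawn at the spec's (donor) GC.
#' @param strainId Strain id of the descendant.
#' @param seed Optional RNG seed.
#' @return A [Genome-class] object.
#' @export
evolveGenome <- function(ancestor, rate, losses = character(),
                         gains = list(), strainId = strainId(ancestor),
                         seed = NULL) {
  .assertScalarNumber(rate, "rate", 0, 0.25)
  if (!is.null(seed)) set.seed(seed)
  fams <- features(ancestor)$family %||% features(ancestor)$gene_id
  unknown <- setdiff(losses, fams)
  if (length(unknown))
    stop("losses refer to unknown families: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  elsAll <- .genomeElements(ancestor)
  out <- lapply(elsAll, function(els) {
    ## substitutions
    els <- lapply(els, function(e) {
      old <- e$seq
      e$seq <- .mutateSeq(old, rate)
      if (e$kind == "gene") e$seq <- .fixInternalStops(e$seq, old)
      e
    })
    ## losses: drop gene + preceding spacer
    if (length(losses)) {
      drop <- logical(length(els))
      for (i in seq_along(els)) {
        if (els[[i]]$kind == "gene" && els[[i]]$family %in% losses) {
          drop[i] <- TRUE
          if (i > 1L && els[[i - 1L]]$kind == "spacer") drop[i - 1L] <- TRUE
        }
      }
      els <- els[!drop]
    }
    els
  })
  ## gains: random intergenic insertion points (first contig)
  for (gn in gains) {
    els <- out[[1L]]
    spIdx <- which(vapply(els, function(e)
      e$kind == "spacer" && nchar(e$seq) >= 2L, logical(1)))
    if (!length(spIdx)) stop("no intergenic point available for gain",
                             call. = FALSE)
    at <- sample(spIdx, 1L)
    sp <- els[[at]]$seq
    cut <- sample.int(nchar(sp) - 1L, 1L)
    gene <- .element("gene",
                     .makeGene(gn$nCodons %||% 250L, gn$gc %||% 0.38),
                     family = gn$family,
                     product = gn$product %||% "hypothetical protein")
    before <- if (at > 1L) els[seq_len(at - 1L)] else list()
    after <- if (at < length(els)) els[(at + 1L):length(els)] else list()
    out[[1L]] <- c(before,
                   list(.element("spacer", substring(sp, 1L, cut)), gene,
                        .element("spacer", substring(sp, cut + 1L))),
                   after)
  }
  .assembleFromElements(strainId, names(contigs(ancestor)), out)
}

#' Plant a genomic island into a genome
#'
#' Builds an island sequence at the specified GC (marker genes, one
#' cargo gene, intervening spacers), optionally flanked by exact direct
#' repeats, and inserts it at a random intergenic point of the
#' recipient. Marker products are drawn from the mobile-genetic-element
#' keyword lexicon (integrase / transposase / phage / recombinase).
#'
#' @param genome Recipient [Genome-class].
#' @param spec An [islandSpec()].
#' @param seed Optional RNG seed.
#' @return A list with elements `genome` (recipient with the island) and
#'   `truth` (contig, start, end, gc, marker gene ids, cargo gene id,
#'   repeat length).
#' @export
plantIsland <- function(genome, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (spec$lengthBp > max(width(contigs(genome))))
    stop("island longer than every recipient contig", call. = FALSE)
  markerProducts <- c("integrase", "IS643 transposase",
                      "phage portal protein",
                      "site-specific recombinase")
  nGenes <- spec$nMarkerGenes + 1L
  nCod <- pmax(60L, round(stats::rnorm(nGenes, 240, 30)))
  geneBp <- sum(3L * nCod + 6L)
  repLen <- spec$flankRepeatLen
  spacerTotal <- spec$lengthBp - geneBp
  if (spacerTotal < nGenes + 1L)
    stop("island length too small for its gene content", call. = FALSE)
  ## split spacerTotal into nGenes + 1 parts
  cuts <- sort(sample.int(spacerTotal - 1L, nGenes))
  parts <- diff(c(0L, cuts, spacerTotal))
  gBase <- .solveInteriorGc(spec$gc, nGenes, sum(nCod), spacerTotal)
  ## the direct repeats flank the island: one copy immediately before
  ## the island span and one immediately after it
  rep <- if (repLen > 0L) .collapse(.sampleBases(repLen, spec$gc)) else ""
  els <- list()
  if (nzchar(rep)) els[[1L]] <- .element("spacer", rep)
  famIds <- c(if (spec$nMarkerGenes > 0L)
                paste0(spec$cargoFamilyId, "_mge",
                       seq_len(spec$nMarkerGenes)),
              spec$cargoFamilyId)
  prods <- c(rep_len(markerProducts, spec$nMarkerGenes), spec$cargoProduct)
  for (i in seq_len(nGenes)) {
    els[[length(els) + 1L]] <-
      .element("spacer", .collapse(.sampleBases(parts[i], spec$gc)))
    els[[length(els) + 1L]] <-
      .element("gene", .makeGene(nCod[i], gBase),
               family = famIds[i], product = prods[i])
  }
  els[[length(els) + 1L]] <-
    .element("spacer", .collapse(.sampleBases(parts[nGenes + 1L], spec$gc)))
  if (nzchar(rep)) els[[length(els) + 1L]] <- .element("spacer", rep)

  ## insert into a random host spacer of a contig long enough
  hostEls <- .genomeElements(genome)
  okCtg <- which(width(contigs(genome)) >= spec$lengthBp)
  ci <- if (length(okCtg) == 1L) okCtg else sample(okCtg, 1L)
  host <- hostEls[[ci]]
  spIdx <- which(vapply(host, function(e)
    e$kind == "spacer" && nchar(e$seq) >= 2L, logical(1)))
  at <- sample(spIdx, 1L)
  sp <- host[[at]]$seq
  cut <- sample.int(nchar(sp) - 1L, 1L)
  before <- host[seq_len(at - 1L)]
  after <- if (at < length(host)) host[(at + 1L):length(host)] else list()
  newEls <- c(before, list(.element("spacer", substring(sp, 1L, cut))),
              els, list(.element("spacer", substring(sp, cut + 1L))), after)
  hostEls[[ci]] <- newEls
  out <- .assembleFromElements(strainId(genome), names(contigs(genome)),
                               hostEls)
  insertAt <- sum(vapply(before, function(e) nchar(e$seq), integer(1))) +
    cut + 1L
  startPos <- insertAt + repLen   # island span excludes the repeats
  sid <- gsub("[^A-Za-z0-9._-]", "_", strainId(genome))
  truth <- list(contig = names(contigs(genome))[ci],
                start = startPos, end = startPos + spec$lengthBp - 1L,
                gc = spec$gc,
                marker_gene_ids = if (spec$nMarkerGenes > 0L)
                  paste0(sid, "_", famIds[seq_len(spec$nMarkerGenes)])
                  else character(),
                cargo_gene_id = paste0(sid, "_", spec$cargoFamilyId),
                cargo_family_id = spec$cargoFamilyId,
                marker_family_ids = if (spec$nMarkerGenes > 0L)
                  famIds[seq_len(spec$nMarkerGenes)] else character(),
                flank_repeat_len = repLen,
                recipient = strainId(genome))
  list(genome = out, truth = truth)
}

#' Generate a synthetic clade with planted ground truth
#'
#' Builds the common ancestor, evolves one descendant per strain
#' (branch-specific substitution rates; non-core families excised on the
#' branches of strains outside their pattern), plants the configured
#' islands, and assembles a truth manifest: per-family category and
#' strain pattern, island coordinates, expected pairwise per-site
#' identities (products of per-branch retention), and the generating
#' species tree in Newick form.
#'
#' @param cfg A [cladeConfig()].
#' @param outDir Optional directory: per-strain FASTA/GFF3/protein FASTA
#'   plus `manifest.json` are written there.
#' @return A list with `genomes` (named list of [Genome-class]) and
#'   `manifest`.
#' @examples
#' cfg <- cladeConfig(nCore = 15, sharedPatterns = c("m4-4|m2-6" = 2),
#'                    specific = c("m4-4" = 1, "m2-6" = 1, "p1.1.43" = 1),
#'                    islands = list(), seed = 1)
#' clade <- generateClade(cfg)
#' names(clade$genomes)
#' @export
generateClade <- function(cfg, outDir = NULL) {
  set.seed(cfg$seed)
  fam <- .configFamilies(cfg)
  anc <- generateAncestor(cfg, seed = .subSeed())
  genomes <- list()
  for (s in cfg$strains) {
    keep <- vapply(strsplit(fam$pattern, "|", fixed = TRUE),
                   function(p) s %in% p, logical(1))
    losses <- fam$family_id[!keep]
    genomes[[s]] <- evolveGenome(anc, cfg$branchSubRate[[s]],
                                 losses = losses, strainId = s,
                                 seed = .subSeed())
  }
  islandTruth <- list()
  for (isl in cfg$islands) {
    res <- plantIsland(genomes[[isl$recipient]], isl, seed = .subSeed())
    genomes[[isl$recipient]] <- res$genome
    islandTruth[[length(islandTruth) + 1L]] <- res$truth
    extra <- data.frame(
      family_id = c(res$truth$marker_family_ids, res$truth$cargo_family_id),
      category = "specific", pattern = isl$recipient,
      stringsAsFactors = FALSE)
    fam <- rbind(fam, extra)
  }
  x <- -log(1 - cfg$branchSubRate)
  n <- length(cfg$strains)
  expId <- outer(x, x, `+`)
  expId <- exp(-expId); diag(expId) <- 1
  dimnames(expId) <- list(cfg$strains, cfg$strains)
  tree <- paste0("(", paste(sprintf("%s:%.7f", cfg$strains, x),
                            collapse = ","), ");")
  manifest <- list(strains = cfg$strains,
                   families = fam,
                   islands = islandTruth,
                   expected_identity = expId,
                   species_tree = tree,
                   seed = cfg$seed)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (s in cfg$strains) writeGenome(genomes[[s]], outDir)
    mj <- manifest
    mj$expected_identity <- as.data.frame(expId)
    jsonlite::write_json(mj, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(genomes = genomes, manifest = manifest)
}

#' Simulate a diverged genome pair at a fixed per-site identity
#'
#' Generates an ancestor genome of roughly `lengthBp` and a descendant
#' whose per-site substitution probability equals `1 - identity`
#' (single-branch divergence, so the realized per-site identity is
#' exactly the target in expectation). Used to calibrate ANI recovery.
#'
#' @param identity Target per-site identity (e.g. 0.9937).
#' @param lengthBp Approximate genome length (>= 10 kb).
#' @param gc Background GC fraction.
#' @param seed RNG seed.
#' @return Named list of two [Genome-class] objects `A` and `B`.
#' @export
simulateDivergedPair <- function(identity, lengthBp = 1e6, gc = 0.38,
                                 seed = 1L) {
  .assertScalarNumber(identity, "identity", 0.75, 1)
  set.seed(seed)
  nGenes <- max(5L, round(lengthBp / 1180))
  cfg <- cladeConfig(strains = c("A", "B"), nCore = nGenes,
                     sharedPatterns = setNames(integer(), character()),
                     specific = c(A = 0L, B = 0L),
                     backgroundGc = gc,
                     branchSubRate = c(A = 0, B = 0),
                     islands = list(), seed = .subSeed())
  anc <- generateAncestor(cfg, seed = .subSeed())
  A <- evolveGenome(anc, 0, strainId = "A", seed = .subSeed())
  B <- evolveGenome(anc, 1 - identity, strainId = "B", seed = .subSeed())
  list(A = A, B = B)
}

#' Evolve a sequence along a phylogeny
#'
#' Branch lengths are interpreted as per-site substitution probabilities
#' (each must lie in [0, 0.25]); substitutions pick uniformly among the
#' three alternative bases. Used to build gene families with a known
#' history, including horizontally transferred variants.
#'
#' @param tree An \code{ape::phylo} tree with branch lengths.
#' @param rootSeq Character scalar, the root DNA sequence.
#' @return \linkS4class{DNAStringSet} of tip sequences, named by tip label.
#' @export
evolveSeqAlongTree <- function(tree, rootSeq) {
  if (is.null(tree$edge.length)) stop("tree needs branch lengths",
                                      call. = FALSE)
  if (any(tree$edge.length < 0 | tree$edge.length > 0.25))
    stop("branch lengths (substitution probabilities) must lie in [0, 0.25]",
         call. = FALSE)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- list()
  nodeSeq <- list()
  nodeSeq[[root]] <- rootSeq
  ## traverse edges in preorder
  ord <- order(tree$edge[, 1L])
  for (k in ord) {
    par <- tree$edge[k, 1L]; chd <- tree$edge[k, 2L]
    s <- .mutateSeq(nodeSeq[[par]], tree$edge.length[k])
    nodeSeq[[chd]] <- s
    if (chd <= ntip) seqs[[tree$tip.label[chd]]] <- s
  }
  DNAStringSet(unlist(seqs)[tree$tip.label])
}

#' Build a reference panel around a candidate transferred gene
#'
#' Constructs four reference homologs of a cargo gene such that the
#' focal copy is nearly identical to a distant donor lineage (`r1`)
#' while the species tree places the focal taxon next to `r3`/`r4`:
#' the signature of a horizontally acquired locus. The species tree is
#' `((r1,r2),((r3,r4),focal))` (branch lengths are per-site
#' substitution probabilities); `r2` serves as outgroup for rooting.
#'
#' @param cargoSeq Character or \linkS4class{DNAString}: the cargo CDS.
#' @param focal Focal strain label used as the tip name.
#' @param vertical If `TRUE`, build a congruent (vertically inherited)
#'   panel instead: the focal copy then resembles its species-tree
#'   neighbours `r3`/`r4`.
#' @param seed Optional RNG seed.
#' @return List: `seqs` (\linkS4class{DNAStringSet}: focal + r1..r4),
#'   `speciesTree` (\code{phylo}), `outgroup`, `donor`.
#' @export
hgtLocusPanel <- function(cargoSeq, focal, vertical = FALSE,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cargo <- as.character(cargoSeq)
  ## The reference sequences are generated by walking the gene
  ## genealogy away from the (observed) focal copy; under the
  ## reversible equal-rates model this is equivalent to evolving from
  ## the root. Internal branches are long enough to be recovered with
  ## high bootstrap support.
  if (vertical) {
    ## congruent genealogy: focal groups with r3/r4, (r1,r2) distant
    ancF34 <- .mutateSeq(cargo, 0.01)
    anc34 <- .mutateSeq(ancF34, 0.03)
    r3 <- .mutateSeq(anc34, 0.02); r4 <- .mutateSeq(anc34, 0.02)
    anc12 <- .mutateSeq(ancF34, 0.08)
    r1 <- .mutateSeq(anc12, 0.02); r2 <- .mutateSeq(anc12, 0.02)
  } else {
    ## focal copy acquired from the r1 lineage: (focal,r1) is an
    ## internal edge of the gene genealogy
    ancF1 <- .mutateSeq(cargo, 0.005)
    r1 <- .mutateSeq(ancF1, 0.01)
    anc12 <- .mutateSeq(ancF1, 0.05)
    r2 <- .mutateSeq(anc12, 0.06)
    anc34 <- .mutateSeq(anc12, 0.08)
    r3 <- .mutateSeq(anc34, 0.02); r4 <- .mutateSeq(anc34, 0.02)
  }
  seqs <- DNAStringSet(setNames(c(cargo, r1, r2, r3, r4),
                                c(focal, "r1", "r2", "r3", "r4")))
  tree <- ape::read.tree(text = sprintf(
    "((r1:0.02,r2:0.02):0.04,((r3:0.02,r4:0.02):0.03,%s:0.03):0.04);",
    focal))
  list(seqs = seqs, speciesTree = tree, outgroup = "r2", donor = "r1")
}

#' Simulate a gene family, optionally with a horizontal transfer
#'
#' Evolves a random root sequence along `speciesTree`. If `focal` and
#' `donor` are given, the focal tip's sequence is replaced by a
#' near-identical copy of the donor tip's sequence (divergence
#' `transferRate`), emulating acquisition from the donor lineage; the
#' resulting gene tree places the focal taxon next to the donor instead
#' of its species-tree neighbours.
#'
#' @param speciesTree \code{ape::phylo}; branch lengths are per-site
#'   substitution probabilities.
#' @param nSites Sequence length in bp (multiple of 3 recommended).
#' @param gc GC fraction of the root sequence.
#' @param focal,donor Tip labels (both `NULL` for a vertically inherited
#'   family).
#' @param transferRate Divergence between donor and focal copy.
#' @param seed Optional RNG seed.
#' @return \linkS4class{DNAStringSet} of tip sequences.
#' @export
simulateGeneFamily <- function(speciesTree, nSites = 900L, gc = 0.38,
                               focal = NULL, donor = NULL,
                               transferRate = 0.005, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rootSeq <- .collapse(.sampleBases(nSites, gc))
  seqs <- evolveSeqAlongTree(speciesTree, rootSeq)
  if (!is.null(focal) && !is.null(donor)) {
    stopifnot(focal %in% names(seqs), donor %in% names(seqs))
    seqs[[focal]] <- DNAString(.mutateSeq(as.character(seqs[[donor]]),
                                          transferRate))
  }
  seqs
}
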