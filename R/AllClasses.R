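#' @import methods
#' @import Biostrings
#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
NULL

#' Genome: contigs plus annotated coding features of one strain
#'
#' Container for a single bacterial strain: the assembled contigs, the
#' coding features (as a \linkS4class{GRanges}, 1-based closed
#' coordinates, with metadata columns `gene_id` and `product`), and the
#' translated proteome named by gene id. A validity method enforces that
#' every feature lies on an existing contig, within its bounds, and that
#' gene ids are unique.
#'
#' @slot strainId Character scalar, the strain identifier.
#' @slot contigs \linkS4class{DNAStringSet} of contig sequences.
#' @slot features \linkS4class{GRanges} of coding features.
#' @slot proteome \linkS4class{AAStringSet} of protein products.
#' @seealso [Genome()] for the constructor, [readGenome()], [genomeStats()]
#' @export
setClass("Genome", representation(
  strainId = "character",
  contigs  = "DNAStringSet",
  features = "GRanges",
  proteome = "AAStringSet"
))

setValidity("Genome", function(object) {
  msg <- character()
  if (length(object@strainId) != 1L || !nzchar(object@strainId))
    msg <- c(msg, "strainId must be a non-empty character scalar")
  if (length(object@contigs) == 0L || sum(width(object@contigs)) == 0L)
    msg <- c(msg, "genome must contain sequence")
  cn <- names(object@contigs)
  if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn)))
    msg <- c(msg, "contig names must be unique and non-empty")
  ft <- object@features
  if (length(ft)) {
    if (is.null(ft$gene_id) || anyDuplicated(ft$gene_id))
      msg <- c(msg, "features need unique gene_id metadata")
    bad <- !(as.character(seqnames(ft)) %in% cn)
    if (any(bad)) {
      msg <- c(msg, sprintf("feature contig not in assembly: %s",
                            paste(unique(as.character(seqnames(ft))[bad]),
                                  collapse = ", ")))
    } else {
      lens <- setNames(width(object@contigs), cn)
      out <- start(ft) < 1L | end(ft) > lens[as.character(seqnames(ft))]
      if (any(out))
        msg <- c(msg, sprintf("features outside contig bounds: %s",
                              paste(head(ft$gene_id[out], 3L), collapse = ", ")))
    }
    if (any(end(ft) < start(ft)))
      msg <- c(msg, "feature end before start")
  }
  if (length(object@proteome)) {
    if (is.null(names(object@proteome)))
      msg <- c(msg, "proteome must be named by gene_id")
    if (length(ft) && !all(names(object@proteome) %in% ft$gene_id))
      msg <- c(msg, "proteome names must match feature gene_ids")
  }
  if (length(msg)) msg else TRUE
})

#' AniResult: fragment-based average nucleotide identity of a genome pair
#'
#' Holds the two directed fragment-mapping passes between a pair of
#' genomes and the symmetric summary. A directed value is the mean
#' identity of retained fragments; the symmetric ANI is the mean of the
#' two directed values.
#'
#' @slot query,subject Strain identifiers of the pair.
#' @slot nFragments Integer(2): fragments generated in each direction.
#' @slot nRetained Integer(2): fragments passing the retention filter.
#' @slot identities List of two numeric vectors, per-retained-fragment
#'   identities (fractions) for each direction.
#' @slot aniDirected Numeric(2): directed ANI in percent (NA if no
#'   fragment retained).
#' @slot aniSymmetric Numeric scalar, mean of the directed values.
#' @seealso [aniPair()]
#' @export
setClass("AniResult", representation(
  query = "character", subject = "character",
  nFragments = "integer", nRetained = "integer",
  identities = "list", aniDirected = "numeric", aniSymmetric = "numeric"
))

setValidity("AniResult", function(object) {
  msg <- character()
  if (any(object@nRetained > object@nFragments))
    msg <- c(msg, "retained fragments cannot exceed generated fragments")
  ok <- is.na(object@aniDirected) |
    (object@aniDirected >= 0 & object@aniDirected <= 100)
  if (!all(ok)) msg <- c(msg, "directed ANI must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' PangenomePartition: core/accessory/strain-specific gene families
#'
#' The partition of bidirectional-best-hit graph components into core
#' families (all strains represented), shared accessory families (a
#' proper subset of at least two strains) and strain-specific families
#' (singletons or one-strain components).
#'
#' @slot familyTable data.frame with columns `family_id`, `strain_id`,
#'   `gene_id`, `category` (one row per placed gene).
#' @slot counts Named list: `pangenome`, `core`, `shared_by_pattern`
#'   (named integer, strain-subset patterns), `specific_by_strain`
#'   (named integer), `core_fraction_of_mean_cds` (percent, rounded).
#' @slot nStrains Integer, number of strains compared.
#' @seealso [buildFamilies()], [pangenomeCounts()]
#' @export
setClass("PangenomePartition", representation(
  familyTable = "data.frame", counts = "list", nStrains = "integer"
))

setValidity("PangenomePartition", function(object) {
  msg <- character()
  need <- c("family_id", "strain_id", "gene_id", "category")
  if (!all(need %in% names(object@familyTable)))
    msg <- c(msg, "familyTable must have family_id/strain_id/gene_id/category")
  else {
    if (!all(object@familyTable$category %in% c("core", "shared", "specific")))
      msg <- c(msg, "category must be core/shared/specific")
    key <- paste(object@familyTable$strain_id, object@familyTable$gene_id)
    if (anyDuplicated(key))
      msg <- c(msg, "a gene may belong to only one family")
  }
  if (length(msg)) msg else TRUE
})

#' WindowScan: sliding-window GC profile of a genome
#'
#' @slot table data.frame with columns `contig_id`, `start`, `end`
#'   (1-based closed), `gc` (percent) and `z` (standardised against the
#'   mean and sd of all windows of the genome).
#' @slot windowBp,stepBp Integer window and step sizes.
#' @slot genomeMeanGc,genomeSdGc Numeric summary of the window population.
#' @seealso [windowScan()], [callIslands()]
#' @export
setClass("WindowScan", representation(
  table = "data.frame", windowBp = "integer", stepBp = "integer",
  genomeMeanGc = "numeric", genomeSdGc = "numeric"
))

#' HgtEvidence: three-signal horizontal gene transfer verdict
#'
#' Combines the composition signal (GC-anomalous island), the genomic
#' context signal (mobile-element markers or flanking direct repeats)
#' and the phylogenetic signal (supported displacement of the focal
#' taxon's sister group between gene tree and species tree) into a
#' deterministic verdict: `supported` (>= 2 signals), `partial` (1),
#' `none` (0).
#'
#' @slot locus Character, locus/family identifier.
#' @slot gcSignal,contextSignal,phyloSignal Logical signal flags.
#' @slot deltaGc Numeric, island mean GC minus genome GC (points).
#' @slot contextDetail Character summary of markers/repeats.
#' @slot rfNormalized Numeric, normalized Robinson-Foulds distance
#'   between gene tree and pruned species tree.
#' @slot sisterGene,sisterSpecies Character vectors: the focal taxon's
#'   (supported) sister set in each tree.
#' @slot sisterSupport Numeric, bootstrap support (percent) of the
#'   gene-tree sister split (NA when no supported split exists).
#' @slot verdict Character: supported/partial/none.
#' @seealso [flagHgt()]
#' @export
setClass("HgtEvidence", representation(
  locus = "character",
  gcSignal = "logical", contextSignal = "logical", phyloSignal = "logical",
  deltaGc = "numeric", contextDetail = "character",
  rfNormalized = "numeric",
  sisterGene = "character", sisterSpecies = "character",
  sisterSupport = "numeric", verdict = "character"
))

setValidity("HgtEvidence", function(object) {
  n <- sum(object@gcSignal, object@contextSignal, object@phyloSignal)
  want <- if (n >= 2L) "supported" else if (n == 1L) "partial" else "none"
  if (!identical(object@verdict, want))
    "verdict must derive from the three signal booleans" else TRUE
})

#' ProfileModel: per-column log-odds profile of a protein family
#'
#' @slot family Character, family name.
#' @slot scores Numeric matrix, 20 amino-acid rows by model columns,
#'   log-odds scores in bits.
#' @slot background Named numeric(20), background frequencies (sums to 1).
#' @slot pseudocount Numeric, pseudocount weight used at build time.
#' @seealso [buildProfile()], [scanProtein()]
#' @export
setClass("ProfileModel", representation(
  family = "character", scores = "matrix",
  background = "numeric", pseudocount = "numeric"
))

setValidity("ProfileModel", function(object) {
  msg <- character()
  if (nrow(object@scores) != 20L)
    msg <- c(msg, "scores must have 20 amino-acid rows")
  if (abs(sum(object@background) - 1) > 1e-6)
    msg <- c(msg, "background frequencies must sum to 1")
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "scores must be finite")
  if (length(msg)) msg else TRUE
})

#' TraitTable: strain-by-trait phenotype or genotype matrix
#'
#' Encodes tables of binary (+/-) trait calls per strain, with trait
#' group labels (e.g. biosynthetic pathway, phosphorus source class).
#' Non-binary symbol sets (e.g. regulation states) are allowed via the
#' `symbols` slot but are excluded from binary concordance.
#'
#' @slot strains Character, ordered strain ids (columns).
#' @slot traits Character, ordered trait names (rows).
#' @slot groups Character, per-trait group label.
#' @slot values Character matrix traits x strains.
#' @slot symbols Character, admissible symbols (besides NA).
#' @seealso [readTraitTable()], [concordance()], [summarizeAuxotrophies()]
#' @export
setClass("TraitTable", representation(
  strains = "character", traits = "character", groups = "character",
  values = "matrix", symbols = "character"
))

setValidity("TraitTable", function(object) {
  msg <- character()
  if (!identical(dim(object@values),
                 c(length(object@traits), length(object@strains))))
    msg <- c(msg, "values matrix must be traits x strains")
  if (length(object@groups) != length(object@traits))
    msg <- c(msg, "one group label per trait required")
  v <- object@values
  if (!all(is.na(v) | v %in% object@symbols))
    msg <- c(msg, sprintf("values restricted to {%s, NA}",
                          paste(object@symbols, collapse = ", ")))
  if (length(msg)) msg else TRUE
})
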