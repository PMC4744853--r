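#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname Genome-accessors
setMethod("strainId", "Genome", function(x) x@strainId)

#' @rdname Genome-accessors
setMethod("contigs", "Genome", function(x) x@contigs)

#' @rdname Genome-accessors
setMethod("features", "Genome", function(x) x@features)

#' @rdname Genome-accessors
setMethod("proteome", "Genome", function(x) x@proteome)

setMethod("show", "Genome", function(object) {
  st <- genomeStats(object)
  cat(sprintf(
    "Genome '%s': %d contig(s), %s bp, GC %.2f%%, N50 %s bp, %d CDS\n",
    object@strainId, st$contig_count, format(st$length_bp, big.mark = ","),
    st$gc_percent, format(st$n50_bp, big.mark = ","), st$cds_count))
})

#' @rdname PangenomePartition-accessors
setMethod("families", "PangenomePartition", function(x) x@familyTable)

#' @rdname PangenomePartition-accessors
setMethod("pangenomeSize", "PangenomePartition",
          function(x) x@counts$pangenome)

#' @rdname PangenomePartition-accessors
setMethod("coreSize", "PangenomePartition", function(x) x@counts$core)

setMethod("show", "PangenomePartition", function(object) {
  ct <- object@counts
  cat(sprintf("PangenomePartition: %d strains, %d families\n",
              object@nStrains, ct$pangenome))
  cat(sprintf("  core: %d (%s%% of mean CDS)\n", ct$core,
              ct$core_fraction_of_mean_cds))
  cat(sprintf("  shared accessory: %d   strain-specific: %d\n",
              sum(ct$shared_by_pattern), sum(ct$specific_by_strain)))
})

setMethod("aniSymmetric", "AniResult", function(x) x@aniSymmetric)

setMethod("show", "AniResult", function(object) {
  cat(sprintf("AniResult %s vs %s\n", object@query, object@subject))
  cat(sprintf("  directed: %.2f%% (%d/%d fragments), %.2f%% (%d/%d)\n",
              object@aniDirected[1], object@nRetained[1], object@nFragments[1],
              object@aniDirected[2], object@nRetained[2], object@nFragments[2]))
  cat(sprintf("  symmetric ANI: %.2f%%\n", object@aniSymmetric))
})

setMethod("show", "WindowScan", function(object) {
  cat(sprintf(
    "WindowScan: %d windows of %d bp (step %d), genome GC %.2f%% (sd %.2f)\n",
    nrow(object@table), object@windowBp, object@stepBp,
    object@genomeMeanGc, object@genomeSdGc))
})

setMethod("verdict", "HgtEvidence", function(x) x@verdict)

setMethod("show", "HgtEvidence", function(object) {
  cat(sprintf("HgtEvidence for locus '%s': %s\n", object@locus,
              object@verdict))
  cat(sprintf("  composition: %s (dGC %.2f)\n", object@gcSignal,
              object@deltaGc))
  cat(sprintf("  context:     %s (%s)\n", object@contextSignal,
              object@contextDetail))
  cat(sprintf("  phylogeny:   %s (RF %.2f, sister: %s, support %s)\n",
              object@phyloSignal, object@rfNormalized,
              paste(object@sisterGene, collapse = ","),
              format(object@sisterSupport)))
})

setMethod("show", "ProfileModel", function(object) {
  cat(sprintf("ProfileModel '%s': %d columns, pseudocount %.2f\n",
              object@family, ncol(object@scores), object@pseudocount))
})

setMethod("traitValues", "TraitTable", function(x) {
  v <- x@values
  dimnames(v) <- list(x@traits, x@strains)
  v
})

setMethod("show", "TraitTable", function(object) {
  cat(sprintf("TraitTable: %d traits x %d strains (%d groups)\n",
              length(object@traits), length(object@strains),
              length(unique(object@groups))))
  print(utils::head(traitValues(object), 5L))
})
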