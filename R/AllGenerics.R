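#' @include AllClasses.R
NULL

#' Accessors for Genome objects
#'
#' @param x A [Genome-class] object.
#' @return `strainId` returns the strain identifier, `contigs` the
#'   \linkS4class{DNAStringSet} of contig sequences, `features` the
#'   \linkS4class{GRanges} of coding features, and `proteome` the
#'   \linkS4class{AAStringSet} of translated products (named by gene id).
#' @name Genome-accessors
#' @aliases strainId contigs features proteome
#' @examples
#' g <- demoGenome()
#' strainId(g)
#' length(contigs(g))
NULL

#' @rdname Genome-accessors
#' @export
setGeneric("strainId", function(x) standardGeneric("strainId"))

#' @rdname Genome-accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname Genome-accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname Genome-accessors
#' @export
setGeneric("proteome", function(x) standardGeneric("proteome"))

#' Accessors for pangenome partitions
#'
#' @param x A [PangenomePartition-class] object.
#' @return `families` returns the per-gene family assignment table
#'   (columns `family_id`, `strain_id`, `gene_id`, `category`);
#'   `pangenomeSize` and `coreSize` the respective family counts.
#' @name PangenomePartition-accessors
#' @aliases families pangenomeSize coreSize
NULL

#' @rdname PangenomePartition-accessors
#' @export
setGeneric("families", function(x) standardGeneric("families"))

#' @rdname PangenomePartition-accessors
#' @export
setGeneric("pangenomeSize", function(x) standardGeneric("pangenomeSize"))

#' @rdname PangenomePartition-accessors
#' @export
setGeneric("coreSize", function(x) standardGeneric("coreSize"))

#' Symmetric ANI of an AniResult
#'
#' @param x An [AniResult-class] object.
#' @return Numeric scalar, the symmetric average nucleotide identity in
#'   percent (mean of the two directed values), or `NA` when undefined.
#' @export
setGeneric("aniSymmetric", function(x) standardGeneric("aniSymmetric"))

#' Verdict of an HgtEvidence object
#'
#' @param x An [HgtEvidence-class] object.
#' @return Character scalar: `"supported"`, `"partial"` or `"none"`.
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' Trait matrix of a TraitTable
#'
#' @param x A [TraitTable-class] object.
#' @return Character matrix (traits x strains) over the table's symbol set.
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))
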