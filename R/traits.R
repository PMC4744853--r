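#' @include AllClasses.R
NULL

#' Construct a TraitTable
#'
#' @param values Character matrix, traits in rows, strains in columns.
#' @param strains,traits Row/column identities (defaults taken from
#'   dimnames).
#' @param groups Per-trait group labels (default `"trait"`).
#' @param symbols Admissible symbols (default `+`/`-`).
#' @return A [TraitTable-class] object.
#' @export
traitTable <- function(values, strains = colnames(values),
                       traits = rownames(values),
                       groups = rep("trait", nrow(values)),
                       symbols = c("+", "-")) {
  new("TraitTable", strains = strains, traits = traits, groups = groups,
      values = unname(values), symbols = symbols)
}

#' Read a trait table from TSV
#'
#' Expected layout: a `group` column, a `trait` column, then one column
#' per strain. `#`-prefixed lines are comments. Cells holding symbols
#' outside `symbols` are kept verbatim only if listed in `symbols`,
#' otherwise set to NA (footnote marks are stripped first).
#'
#' @param path TSV path.
#' @param symbols Admissible symbols.
#' @return A [TraitTable-class] object.
#' @export
readTraitTable <- function(path, symbols = c("+", "-")) {
  tb <- .readTsv(path)
  if (!all(c("group", "trait") %in% names(tb)))
    stop("trait TSV needs 'group' and 'trait' columns", call. = FALSE)
  strains <- setdiff(names(tb), c("group", "trait", "note"))
  vals <- as.matrix(tb[, strains, drop = FALSE])
  ## strip footnote marks such as "*", "*a", "**"
  vals[] <- sub("\\*+[a-z]?$", "", vals)
  vals[!(vals %in% symbols)] <- NA_character_
  new("TraitTable", strains = strains, traits = tb$trait,
      groups = tb$group, values = unname(vals), symbols = symbols)
}

#' Predict a trait from gene-family presence
#'
#' A pathway definition is a list of alternative requirement sets (gene
#' family ids); the trait is predicted `"+"` iff at least one
#' alternative set is fully contained in the present families.
#' Prediction is monotone: adding families can never flip `+` to `-`.
#'
#' @param presentFamilies Character vector of present family ids.
#' @param def List of character vectors (alternative requirement sets).
#' @return `"+"` or `"-"`.
#' @examples
#' predictTrait(c("a", "y"), list(c("a", "b")))   # "-"
#' predictTrait(c("a", "b"), list(c("a", "b")))   # "+"
#' @export
predictTrait <- function(presentFamilies, def) {
  if (!length(def)) stop("pathway definition needs >= 1 alternative",
                         call. = FALSE)
  hit <- any(vapply(def, function(s) all(s %in% presentFamilies),
                    logical(1)))
  if (hit) "+" else "-"
}

#' Genotype-phenotype concordance of two trait tables
#'
#' Compares observed and predicted tables cell by cell after aligning
#' strains and traits by name. Cells where either value is NA or
#' outside the binary `+`/`-` set are excluded.
#'
#' @param observed,predicted [TraitTable-class] objects over the same
#'   strains and traits.
#' @return List: `agreement` (logical matrix, NA where excluded),
#'   `inconsistencies` (data.frame `strain`, `trait`, `observed`,
#'   `predicted`), `tallies` (data.frame `strain`, `concordant`,
#'   `discordant`).
#' @export
concordance <- function(observed, predicted) {
  missT <- c(setdiff(observed@traits, predicted@traits),
             setdiff(predicted@traits, observed@traits))
  if (length(missT))
    stop("unmatched trait names: ", paste(unique(missT), collapse = ", "),
         call. = FALSE)
  missS <- c(setdiff(observed@strains, predicted@strains),
             setdiff(predicted@strains, observed@strains))
  if (length(missS))
    stop("unmatched strains: ", paste(unique(missS), collapse = ", "),
         call. = FALSE)
  ov <- traitValues(observed)
  pv <- traitValues(predicted)[observed@traits, observed@strains,
                               drop = FALSE]
  binary <- matrix(ov %in% c("+", "-") & pv %in% c("+", "-"),
                   nrow = nrow(ov), dimnames = dimnames(ov))
  agree <- matrix(NA, nrow(ov), ncol(ov), dimnames = dimnames(ov))
  agree[binary] <- ov[binary] == pv[binary]
  bad <- which(agree == FALSE, arr.ind = TRUE)
  inconsistencies <- data.frame(
    strain = colnames(ov)[bad[, 2L]],
    trait = rownames(ov)[bad[, 1L]],
    observed = ov[bad], predicted = pv[bad],
    stringsAsFactors = FALSE)
  tallies <- data.frame(
    strain = observed@strains,
    concordant = colSums(agree == TRUE, na.rm = TRUE),
    discordant = colSums(agree == FALSE, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  list(agreement = agree, inconsistencies = inconsistencies,
       tallies = tallies)
}

#' Count auxotrophies (negative growth calls) per strain
#'
#' @param observed A [TraitTable-class] of growth evaluations.
#' @param groups Optional group labels to restrict to (default all).
#' @return Named integer vector, count of `"-"` per strain.
#' @export
summarizeAuxotrophies <- function(observed, groups = NULL) {
  v <- traitValues(observed)
  if (!is.null(groups)) v <- v[observed@groups %in% groups, , drop = FALSE]
  res <- colSums(v == "-", na.rm = TRUE)
  setNames(as.integer(res), observed@strains)
}

#' Packaged phenotype/genotype table fixtures
#'
#' Transcriptions of the published strain trait tables shipped with the
#' package: amino-acid growth evaluations and pathway predictions,
#' phosphorus-source utilization, and phosphorus
#' recycling/scavenging/storage gene repertoires. Footnote marks are
#' carried in a `note` column of the underlying TSVs and do not affect
#' the symbols.
#'
#' @param name One of `"aa_observed"`, `"aa_predicted"`, `"p_sources"`,
#'   `"p_strategies"`.
#' @return A [TraitTable-class] object.
#' @examples
#' tab <- traitTableFixture("aa_observed")
#' summarizeAuxotrophies(tab)
#' @export
traitTableFixture <- function(name = c("aa_observed", "aa_predicted",
                                       "p_sources", "p_strategies")) {
  name <- match.arg(name)
  f <- system.file("extdata", paste0(name, ".tsv"), package = "microevo",
                   mustWork = TRUE)
  symbols <- if (name == "p_strategies")
    c("+", "-", "Constitutive", "Induce") else c("+", "-")
  readTraitTable(f, symbols = symbols)
}
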