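#' @include simulate.R orthology.R ani.R islands.R phylo.R profile.R traits.R
NULL

#' Run the full comparative-genomics pipeline on a synthetic clade
#'
#' Orchestrates simulate -> pangenome -> ANI -> islands -> HGT ->
#' marker repertoire -> trait concordance, writing machine-readable
#' reports under `outDir`. All randomness flows from `cfg$seed`, so an
#' identical configuration yields byte-identical reports.
#'
#' Reports written: `pangenome_families.tsv`, `pangenome_counts.tsv`,
#' `ani_matrix.tsv`, `islands.tsv`, `islands.bed` (0-based half-open),
#' `hgt_evidence.tsv`, `repertoire.tsv`, `trait_concordance.tsv` and
#' `run_manifest.json`.
#'
#' @param outDir Output directory (created if needed).
#' @param cfg A [cladeConfig()]; the defaults reproduce the package's
#'   reference three-strain clade.
#' @param aniFragLen ANI fragment length (default 1020).
#' @param window,step,zCut Island-scan parameters.
#' @param supportMin Bootstrap threshold for the HGT phylogenetic
#'   signal.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all intermediate results
#'   (`clade`, `partition`, `ani`, `islands`, `hgt`, `repertoire`,
#'   `traits`).
#' @export
runPipeline <- function(outDir, cfg = cladeConfig(), aniFragLen = 1020L,
                        window = 5000L, step = 500L, zCut = -3,
                        supportMin = 70, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  say("simulating clade (", length(cfg$strains), " strains)")
  clade <- generateClade(cfg)
  genomes <- clade$genomes

  say("pangenome partition")
  part <- pangenome(genomes)
  .writeTsv(families(part), file.path(outDir, "pangenome_families.tsv"))
  ct <- part@counts
  cdf <- data.frame(
    metric = c("pangenome", "core", "shared_accessory", "strain_specific",
               "core_fraction_of_mean_cds_pct"),
    value = c(ct$pangenome, ct$core, sum(ct$shared_by_pattern),
              sum(ct$specific_by_strain), ct$core_fraction_of_mean_cds))
  .writeTsv(cdf, file.path(outDir, "pangenome_counts.tsv"))

  say("ANI matrix")
  ani <- aniMatrix(genomes, fragLen = aniFragLen)
  .writeTsv(data.frame(strain = rownames(ani), round(ani, 2),
                       check.names = FALSE),
            file.path(outDir, "ani_matrix.tsv"))

  say("genomic islands")
  islandRows <- list(); bedRows <- list()
  calls <- list()
  for (s in names(genomes)) {
    scan <- windowScan(genomes[[s]], window = window, step = step)
    isl <- callIslands(genomes[[s]], scan, zCut = zCut)
    if (length(isl))
      isl <- annotateMgeContext(isl, features(genomes[[s]]))
    calls[[s]] <- isl
    for (k in seq_along(isl)) {
      reps <- findFlankRepeats(genomes[[s]], isl[k])
      islandRows[[length(islandRows) + 1L]] <- data.frame(
        strain = s, contig = as.character(seqnames(isl))[k],
        start = start(isl)[k], end = end(isl)[k],
        mean_gc = round(isl$mean_gc[k], 2),
        genome_gc = round(isl$genome_gc[k], 2),
        z_min = round(isl$z_min[k], 2),
        n_mge_markers = nrow(isl$mge_markers[[k]]),
        n_flank_repeats = nrow(reps), stringsAsFactors = FALSE)
      bedRows[[length(bedRows) + 1L]] <- data.frame(
        chrom = as.character(seqnames(isl))[k],
        chromStart = start(isl)[k] - 1L,  # BED is 0-based half-open
        chromEnd = end(isl)[k],
        name = sprintf("%s_island%d", s, k))
    }
  }
  islandTab <- if (length(islandRows)) do.call(rbind, islandRows)
               else data.frame()
  .writeTsv(islandTab, file.path(outDir, "islands.tsv"))
  bed <- if (length(bedRows)) do.call(rbind, bedRows) else data.frame()
  utils::write.table(bed, file.path(outDir, "islands.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  say("HGT evidence")
  hgtRows <- list(); hgt <- list()
  for (tr in clade$manifest$islands) {
    s <- tr$recipient
    g <- genomes[[s]]
    ft <- features(g)
    cargo <- ft[ft$gene_id == tr$cargo_gene_id]
    cargoSeq <- as.character(.featureSeqs(contigs(g), cargo)[[1L]])
    panel <- hgtLocusPanel(cargoSeq, focal = s, seed = .subSeed())
    msa <- centerStarMsa(panel$seqs)
    gt <- bootstrapSupport(msa, n = 100L, seed = .subSeed())
    isl <- calls[[s]]
    hit <- if (length(isl))
      isl[start(isl) <= tr$end & end(isl) >= tr$start] else GRanges()
    island <- if (length(hit)) hit[1L] else NULL
    reps <- if (!is.null(island)) findFlankRepeats(g, island) else NULL
    ev <- flagHgt(tr$cargo_family_id, island = island, geneTree = gt,
                  speciesTree = panel$speciesTree, focal = s,
                  outgroup = panel$outgroup, flankRepeats = reps,
                  supportMin = supportMin)
    hgt[[tr$cargo_family_id]] <- ev
    hgtRows[[length(hgtRows) + 1L]] <- data.frame(
      locus = ev@locus, strain = s,
      gc_signal = ev@gcSignal, delta_gc = round(ev@deltaGc, 2),
      context_signal = ev@contextSignal, context = ev@contextDetail,
      phylo_signal = ev@phyloSignal,
      rf_normalized = round(ev@rfNormalized, 3),
      sister = paste(ev@sisterGene, collapse = ","),
      sister_support = ev@sisterSupport,
      verdict = ev@verdict, stringsAsFactors = FALSE)
  }
  .writeTsv(if (length(hgtRows)) do.call(rbind, hgtRows)
            else data.frame(), file.path(outDir, "hgt_evidence.tsv"))

  say("marker repertoire")
  profs <- .cladeMarkerProfiles(clade, genomes)
  rep <- if (length(profs))
    repertoire(genomes, profs, seed = .subSeed()) else NULL
  if (!is.null(rep))
    .writeTsv(data.frame(family = rep@traits, traitValues(rep),
                         check.names = FALSE),
              file.path(outDir, "repertoire.tsv"))

  say("trait concordance")
  traits <- .cladeTraitConcordance(clade, part)
  .writeTsv(traits$tallies, file.path(outDir, "trait_concordance.tsv"))

  jsonlite::write_json(
    list(seed = cfg$seed, strains = cfg$strains,
         n_core = cfg$nCore,
         package_version = as.character(utils::packageVersion("microevo")),
         parameters = list(ani_frag_len = aniFragLen, window = window,
                           step = step, z_cut = zCut,
                           support_min = supportMin)),
    file.path(outDir, "run_manifest.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  invisible(list(clade = clade, partition = part, ani = ani,
                 islands = calls, hgt = hgt, repertoire = rep,
                 traits = traits))
}

## Profiles for the planted cargo families plus one core family,
## seeded from per-strain sequence variants of each family.
.cladeMarkerProfiles <- function(clade, genomes) {
  man <- clade$manifest
  famSeqs <- function(fam) {
    out <- list()
    for (s in names(genomes)) {
      pr <- proteome(genomes[[s]])
      gid <- paste0(gsub("[^A-Za-z0-9._-]", "_", s), "_", fam)
      if (gid %in% names(pr)) out[[s]] <- as.character(pr[[gid]])
    }
    out
  }
  mkProfile <- function(fam) {
    seqs <- famSeqs(fam)
    if (length(seqs) < 1L) return(NULL)
    aa <- AAStringSet(unlist(seqs))
    if (length(aa) == 1L) aa <- c(aa, aa)   # self-seed for singletons
    buildProfile(centerStarMsa(aa), family = fam)
  }
  cargo <- vapply(man$islands, `[[`, "", "cargo_family_id")
  coreFams <- man$families$family_id[man$families$category == "core"]
  fams <- c(cargo, utils::head(coreFams, 1L))
  profs <- lapply(fams, mkProfile)
  names(profs) <- fams
  profs[!vapply(profs, is.null, logical(1))]
}

## Self-consistency concordance: family-presence traits observed from
## the manifest vs predicted from the recovered partition.
.cladeTraitConcordance <- function(clade, part) {
  man <- clade$manifest
  fams <- man$families
  acc <- fams[fams$category != "core", , drop = FALSE]
  acc <- utils::head(acc, 12L)
  strains <- man$strains
  obs <- matrix("-", nrow(acc), length(strains),
                dimnames = list(acc$family_id, strains))
  for (i in seq_len(nrow(acc))) {
    pres <- strsplit(acc$pattern[i], "|", fixed = TRUE)[[1L]]
    obs[i, pres] <- "+"
  }
  ft <- families(part)
  pred <- matrix("-", nrow(acc), length(strains),
                 dimnames = dimnames(obs))
  for (i in seq_len(nrow(acc))) {
    gidSuffix <- paste0("_", acc$family_id[i])
    for (s in strains) {
      present <- any(ft$strain_id == s &
                       endsWith(ft$gene_id, gidSuffix))
      if (present) pred[i, s] <- "+"
    }
  }
  concordance(traitTable(obs), traitTable(pred))
}
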