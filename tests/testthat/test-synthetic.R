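smallCfg <- function(seed = 11, islands = list(), ...) {
  cladeConfig(nCore = 25, sharedPatterns = c("m4-4|m2-6" = 3),
              specific = c("m4-4" = 2, "m2-6" = 1, "p1.1.43" = 2),
              islands = islands, seed = seed, ...)
}

test_that("ancestor genes are clean ORFs at the requested composition", {
  cfg <- cladeConfig(nCore = 100, sharedPatterns = c("m4-4|m2-6" = 0),
                     specific = c("m4-4" = 0, "m2-6" = 0, "p1.1.43" = 0),
                     islands = list(), seed = 2)
  anc <- generateAncestor(cfg)
  expect_equal(length(features(anc)), 100L)
  prot <- proteome(anc)
  expect_false(any(grepl("\\*", as.character(prot))))
  expect_true(all(startsWith(as.character(prot), "M")))
  ## realized GC within one point of the 37.97% target (~120 kb genome)
  gc <- genomeStats(anc)$gc_percent
  expect_lt(abs(gc - 37.97), 1.0)
  ## intergenic spacers between 50 and 500 bp
  ft <- features(anc)
  gaps <- GenomicRanges::start(ft)[-1] -
    GenomicRanges::end(ft)[-length(ft)] - 1L
  expect_true(all(gaps >= 50 & gaps <= 500))
})

test_that("clade generation is deterministic under a fixed seed", {
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  generateClade(smallCfg(seed = 5), outDir = d1)
  generateClade(smallCfg(seed = 5), outDir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("zero-rate evolution with no gain or loss is the identity", {
  anc <- generateAncestor(smallCfg(seed = 3))
  d <- evolveGenome(anc, 0, strainId = "x")
  expect_identical(as.character(contigs(anc)[[1]]),
                   as.character(contigs(d)[[1]]))
  expect_equal(length(features(anc)), length(features(d)))
})

test_that("substitution rate is realized as per-site identity", {
  cfg <- cladeConfig(nCore = 120, sharedPatterns = c("m4-4|m2-6" = 0),
                     specific = c("m4-4" = 0, "m2-6" = 0, "p1.1.43" = 0),
                     islands = list(), seed = 8)
  anc <- generateAncestor(cfg)
  d <- evolveGenome(anc, 0.01, strainId = "x", seed = 9)
  a <- strsplit(as.character(contigs(anc)[[1]]), "")[[1]]
  b <- strsplit(as.character(contigs(d)[[1]]), "")[[1]]
  expect_equal(length(a), length(b))
  ident <- mean(a == b)
  expect_gt(length(a), 1e5)
  expect_lt(abs(ident - 0.99), 0.002)   # binomial CI at >= 100 kb
  ## descendant genes remain clean ORFs
  expect_false(any(grepl("\\*", as.character(proteome(d)))))
})

test_that("gene loss excises the gene and its spacer; gains insert", {
  anc <- generateAncestor(smallCfg(seed = 4))
  fams <- features(anc)$family
  lost <- fams[c(3, 10)]
  d <- evolveGenome(anc, 0, losses = lost, strainId = "x", seed = 1)
  expect_false(any(features(d)$family %in% lost))
  expect_equal(length(features(d)), length(features(anc)) - 2L)
  expect_lt(sum(GenomicRanges::width(contigs(d))),
            sum(GenomicRanges::width(contigs(anc))))
  expect_error(evolveGenome(anc, 0, losses = "nope"), "unknown famil")
  expect_error(evolveGenome(anc, 0.3), "rate")
  g <- evolveGenome(anc, 0, gains = list(list(family = "new1",
                                              nCodons = 100, gc = 0.30)),
                    strainId = "x", seed = 2)
  expect_true("new1" %in% features(g)$family)
  expect_equal(length(features(g)), length(features(anc)) + 1L)
})

test_that("planted islands realize their GC and flanking repeats", {
  anc <- generateAncestor(cladeConfig(
    nCore = 120, sharedPatterns = c("m4-4|m2-6" = 0),
    specific = c("m4-4" = 0, "m2-6" = 0, "p1.1.43" = 0),
    islands = list(), seed = 21))
  spec <- islandSpec("ancestor", lengthBp = 15000, gc = 0.315,
                     nMarkerGenes = 2, flankRepeatLen = 20,
                     cargoFamilyId = "cargoX")
  res <- plantIsland(anc, spec, seed = 22)
  tr <- res$truth
  ctg <- contigs(res$genome)[[tr$contig]]
  islSeq <- Biostrings::DNAStringSet(
    Biostrings::subseq(ctg, tr$start, tr$end))
  f <- Biostrings::letterFrequency(islSeq, c("A", "C", "G", "T"))
  gc <- 100 * (f[, "C"] + f[, "G"]) / sum(f)
  expect_lt(abs(gc - 31.5), 1.0)
  ## identical 20-mers immediately flanking the span
  left <- as.character(Biostrings::subseq(ctg, tr$start - 20,
                                          tr$start - 1))
  right <- as.character(Biostrings::subseq(ctg, tr$end + 1,
                                           tr$end + 20))
  expect_identical(left, right)
  ## marker and cargo genes inside the span
  ft <- features(res$genome)
  inIsl <- ft[ft$gene_id %in% c(tr$marker_gene_ids, tr$cargo_gene_id)]
  expect_equal(length(inIsl), 3L)
  expect_true(all(GenomicRanges::start(inIsl) >= tr$start &
                    GenomicRanges::end(inIsl) <= tr$end))
  expect_error(
    plantIsland(anc, islandSpec("ancestor", lengthBp = 1e7, gc = 0.3)),
    "longer than")
})

test_that("clade manifests match the configured family structure", {
  cl <- generateClade(smallCfg(seed = 13))
  man <- cl$manifest
  tab <- table(man$families$category)
  expect_equal(unname(tab[["core"]]), 25L)
  expect_equal(unname(tab[["shared"]]), 3L)
  expect_equal(unname(tab[["specific"]]), 5L)
  ## every manifest family is realized in exactly the patterned strains
  for (i in seq_len(nrow(man$families))) {
    fam <- man$families$family_id[i]
    pat <- strsplit(man$families$pattern[i], "|", fixed = TRUE)[[1]]
    carried <- vapply(man$strains, function(s)
      fam %in% features(cl$genomes[[s]])$family, logical(1))
    expect_identical(sort(names(carried)[carried]), sort(pat))
  }
  ## expected identities follow the branch retention products
  x <- -log(1 - smallCfg(seed = 13)$branchSubRate)
  expect_equal(man$expected_identity["m4-4", "m2-6"],
               exp(-(x[["m4-4"]] + x[["m2-6"]])))
  tr <- ape::read.tree(text = man$species_tree)
  expect_setequal(tr$tip.label, man$strains)
})

test_that("halving family counts roughly halves the dataset size", {
  big <- cladeConfig(nCore = 120, sharedPatterns = c("m4-4|m2-6" = 12),
                     specific = c("m4-4" = 6, "m2-6" = 6, "p1.1.43" = 6),
                     islands = list(), seed = 31)
  small <- cladeConfig(nCore = 60, sharedPatterns = c("m4-4|m2-6" = 6),
                       specific = c("m4-4" = 3, "m2-6" = 3,
                                    "p1.1.43" = 3),
                       islands = list(), seed = 31)
  sz <- function(cfg) sum(vapply(generateClade(cfg)$genomes, function(g)
    sum(GenomicRanges::width(contigs(g))), numeric(1)))
  ratio <- sz(small) / sz(big)
  expect_lt(abs(ratio - 0.5), 0.05)
})

test_that("sequence evolution along a tree respects the branch rates", {
  tre <- ape::read.tree(text = "((a:0.0,b:0.05):0.0,(c:0.1,d:0.1):0.0);")
  set.seed(5)
  root <- randomDnaString(20000, 0.4)
  tips <- evolveSeqAlongTree(tre, root)
  idTo <- function(tip) {
    s <- strsplit(as.character(tips[[tip]]), "")[[1]]
    mean(s == strsplit(root, "")[[1]])
  }
  expect_equal(idTo("a"), 1)
  expect_lt(abs(idTo("b") - 0.95), 0.01)
  expect_lt(abs(idTo("c") - 0.90), 0.01)
  expect_error(
    evolveSeqAlongTree(ape::read.tree(text = "(a:0.5,b:0.1,c:0.1);"),
                       root), "0.25")
})
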