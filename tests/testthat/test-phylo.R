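test_that("center-star alignment handles identity and planted insertions", {
  aa <- Biostrings::AAStringSet(c(a = "MKVLHEAG", b = "MKVLHEAG",
                                  c = "MKVLHEAG"))
  m <- centerStarMsa(aa)
  expect_false(any(grepl("-", as.character(m))))
  expect_equal(unique(nchar(as.character(m))), 8L)
  ## planted 2-residue insertion: width 12, gapped in the short rows
  aa2 <- Biostrings::AAStringSet(c(a = "MKVLHEAGAW", b = "MKVLHEAGAW",
                                   c = "MKVLWWHEAGAW"))
  m2 <- centerStarMsa(aa2)
  expect_equal(unique(nchar(as.character(m2))), 12L)
  expect_equal(sum(strsplit(as.character(m2[["a"]]), "")[[1]] == "-"), 2L)
  expect_equal(sum(strsplit(as.character(m2[["c"]]), "")[[1]] == "-"), 0L)
  expect_error(centerStarMsa(Biostrings::AAStringSet()), "empty")
})

test_that("aligned width is never below the longest input", {
  set.seed(71)
  for (rep in 1:8) {
    n <- sample(3:6, 1)
    seqs <- Biostrings::AAStringSet(setNames(
      vapply(seq_len(n), function(i)
        randomProteinString(sample(20:40, 1)), ""),
      paste0("s", seq_len(n))))
    m <- centerStarMsa(seqs)
    expect_equal(length(unique(nchar(as.character(m)))), 1L)
    expect_gte(unique(nchar(as.character(m))),
               max(Biostrings::width(seqs)))
  }
})

test_that("distance models follow their closed forms", {
  m <- rbind(a = strsplit(strrep("A", 100), "")[[1]],
             b = strsplit(paste0(strrep("C", 10), strrep("A", 90)),
                          "")[[1]])
  expect_equal(distanceMatrix(m, "p")["a", "b"], 0.10)
  expect_equal(distanceMatrix(m, "poisson")["a", "b"], -log(0.9),
               tolerance = 1e-9)
  expect_equal(distanceMatrix(m, "poisson")["a", "b"], 0.10536,
               tolerance = 1e-4)
  expect_equal(distanceMatrix(m, "jc_nt")["a", "b"],
               -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-9)
  ## identical rows
  m2 <- rbind(a = m[1, ], b = m[1, ])
  expect_true(all(distanceMatrix(m2, "jc_nt") == 0))
  ## saturation
  m3 <- rbind(a = strsplit(strrep("ACGT", 25), "")[[1]],
              b = strsplit(strrep("CATG", 25), "")[[1]])
  expect_true(is.infinite(distanceMatrix(m3, "jc_nt")["a", "b"]))
  ## no comparable sites
  m4 <- rbind(a = c("A", "-"), b = c("-", "C"))
  expect_error(distanceMatrix(m4, "p"), "comparable")
})

test_that("neighbor joining recovers additive trees exactly", {
  tre <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):1);")
  D <- ape::cophenetic.phylo(tre)
  nt <- njTree(D)
  expect_equal(rfDistance(nt, tre)$raw, 0L)
  expect_setequal(round(nt$edge.length, 9), c(1, 2, 3, 4, 2))
  ## three taxa: unique resolution via the three-point formulas
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- njTree(D3)
  expect_setequal(round(t3$edge.length, 9), c(1, 2, 3))
  ## random additive matrices from random trees, exact recovery
  set.seed(72)
  for (rep in 1:6) {
    tr <- ape::rtree(sample(5:10, 1))
    tr$edge.length <- tr$edge.length + 0.1
    rec <- njTree(ape::cophenetic.phylo(tr))
    expect_equal(rfDistance(rec, tr)$raw, 0L)
  }
  ## ultrametric 8-taxon matrix
  tr8 <- ape::rcoal(8)
  expect_equal(rfDistance(njTree(ape::cophenetic.phylo(tr8)), tr8)$raw,
               0L)
  expect_error(njTree(matrix(c(0, Inf, Inf, 0), 2, 2)), "3 taxa")
  D[1, 2] <- D[2, 1] <- Inf
  expect_error(njTree(D), "saturated")
})

test_that("RF distance equals brute-force bipartition enumeration", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rfDistance(t1, t1), list(raw = 0L, normalized = 0))
  expect_equal(rfDistance(t1, t2), list(raw = 2L, normalized = 1))
  ## caterpillar vs balanced 6-taxon
  cat6 <- ape::read.tree(text = "(a,(b,(c,(d,(e,f)))));")
  bal6 <- ape::read.tree(text = "((a,b),((c,d),(e,f)));")
  expect_equal(rfDistance(cat6, bal6)$raw, rfOracle(cat6, bal6))
  set.seed(73)
  for (rep in 1:8) {
    x <- ape::rtree(6); y <- ape::rtree(6)
    expect_equal(rfDistance(x, y)$raw, rfOracle(x, y))
    ## cross-check against an independent library implementation
    expect_equal(rfDistance(x, y)$raw,
                 as.integer(phangorn::RF.dist(x, y)))
  }
  bad <- ape::rtree(6); bad$tip.label <- paste0("z", 1:6)
  expect_error(rfDistance(ape::rtree(6), bad), "differ")
})

test_that("RF distance is a metric on a fixed leaf set", {
  set.seed(74)
  trees <- replicate(6, ape::rtree(6), simplify = FALSE)
  for (i in 1:6) expect_equal(rfDistance(trees[[i]], trees[[i]])$raw, 0L)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(rfDistance(trees[[i]], trees[[j]])$raw,
                 rfDistance(trees[[j]], trees[[i]])$raw)
  }
  for (k in 1:10) {
    ijk <- sample(6, 3)
    dij <- rfDistance(trees[[ijk[1]]], trees[[ijk[2]]])$raw
    djk <- rfDistance(trees[[ijk[2]]], trees[[ijk[3]]])$raw
    dik <- rfDistance(trees[[ijk[1]]], trees[[ijk[3]]])$raw
    expect_lte(dik, dij + djk)
  }
})

test_that("bootstrap supports behave on degenerate and signal columns", {
  ## perfectly repeated informative columns: every support 100
  colA <- c(a = "A", b = "A", c = "C", d = "C", e = "G", f = "G")
  m <- do.call(cbind, rep(list(colA), 60))
  tr <- bootstrapSupport(m, n = 50, model = "p", seed = 75)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
  expect_true(all(sup[!is.na(sup)] == round(sup[!is.na(sup)])))
  expect_error(bootstrapSupport(m, n = 0), ">= 1")
})

test_that("deep splits outrank shallow conflicted splits", {
  deep <- c(a = "A", b = "A", c = "C", d = "C", e = "C", f = "C")
  sh1 <- c(a = "T", b = "T", c = "G", d = "G", e = "T", f = "T")
  sh2 <- c(a = "T", b = "T", c = "T", d = "G", e = "G", f = "T")
  m <- cbind(do.call(cbind, rep(list(deep), 200)),
             do.call(cbind, rep(list(sh1), 2)),
             do.call(cbind, rep(list(sh2), 2)))
  wins <- 0
  for (s in 1:5) {
    tr <- bootstrapSupport(m, n = 60, model = "p", seed = 75 + s)
    splits <- microevo:::.treeSplits(tr)
    sup <- setNames(suppressWarnings(as.numeric(
      tr$node.label[as.integer(names(splits)) - length(tr$tip.label)])),
      splits)
    deepKey <- "c|d|e|f"   # canonical form of the a,b | c,d,e,f split
    dsup <- sup[[deepKey]]
    ssup <- max(sup[setdiff(names(sup), deepKey)], na.rm = TRUE)
    if (!is.na(dsup) && dsup > ssup) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("bootstrap supports are stable under column permutation", {
  set.seed(76)
  deep <- c(a = "A", b = "A", c = "C", d = "C", e = "G", f = "G")
  m <- do.call(cbind, rep(list(deep), 80))
  perm <- m[, sample(ncol(m))]
  t1 <- bootstrapSupport(m, n = 40, model = "p", seed = 77)
  t2 <- bootstrapSupport(perm, n = 40, model = "p", seed = 78)
  s1 <- sort(suppressWarnings(na.omit(as.numeric(t1$node.label))))
  s2 <- sort(suppressWarnings(na.omit(as.numeric(t2$node.label))))
  expect_equal(s1, s2)
})

test_that("HGT verdict integrates the three signals correctly", {
  set.seed(79)
  cargo <- randomDnaString(900, 0.32)
  pan <- hgtLocusPanel(cargo, focal = "m2-6", seed = 80)
  gt <- bootstrapSupport(centerStarMsa(pan$seqs), n = 100, seed = 81)
  ## phylogenetic signal alone: partial
  ev <- flagHgt("locus", island = NULL, geneTree = gt,
                speciesTree = pan$speciesTree, focal = "m2-6",
                outgroup = pan$outgroup)
  expect_true(ev@phyloSignal)
  expect_gte(ev@sisterSupport, 70)
  expect_identical(verdict(ev), "partial")
  ## add composition + context: supported
  island <- GenomicRanges::GRanges("c1", IRanges::IRanges(1000, 26000))
  island$mean_gc <- 31.7; island$genome_gc <- 38.0; island$z_min <- -5
  island$mge_markers <- list(data.frame(gene_id = "g1",
                                        keyword = "transposase"))
  ev2 <- flagHgt("locus", island = island, geneTree = gt,
                 speciesTree = pan$speciesTree, focal = "m2-6",
                 outgroup = pan$outgroup)
  expect_identical(verdict(ev2), "supported")
  expect_true(ev2@gcSignal && ev2@contextSignal && ev2@phyloSignal)
  ## congruent gene tree: no phylogenetic signal
  panV <- hgtLocusPanel(cargo, focal = "m2-6", vertical = TRUE,
                        seed = 82)
  gtV <- bootstrapSupport(centerStarMsa(panV$seqs), n = 100, seed = 83)
  evV <- flagHgt("locus", island = NULL, geneTree = gtV,
                 speciesTree = panV$speciesTree, focal = "m2-6",
                 outgroup = panV$outgroup)
  expect_false(evV@phyloSignal)
  expect_identical(verdict(evV), "none")
  expect_error(flagHgt("x", NULL, gt, pan$speciesTree, focal = "zz",
                       outgroup = "r2"), "focal")
})

test_that("adding a positive signal never downgrades the verdict", {
  set.seed(84)
  cargo <- randomDnaString(600, 0.32)
  pan <- hgtLocusPanel(cargo, focal = "f", seed = 85)
  gt <- bootstrapSupport(centerStarMsa(pan$seqs), n = 60, seed = 86)
  island <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 20000))
  island$mean_gc <- 31; island$genome_gc <- 38; island$z_min <- -5
  islandCtx <- island
  islandCtx$mge_markers <- list(data.frame(gene_id = "g",
                                           keyword = "integrase"))
  rank <- c(none = 0, partial = 1, supported = 2)
  v0 <- verdict(flagHgt("x", NULL, gt, pan$speciesTree, "f",
                        outgroup = "r2", supportMin = 101))
  v1 <- verdict(flagHgt("x", island, gt, pan$speciesTree, "f",
                        outgroup = "r2", supportMin = 101))
  v2 <- verdict(flagHgt("x", islandCtx, gt, pan$speciesTree, "f",
                        outgroup = "r2", supportMin = 101))
  v3 <- verdict(flagHgt("x", islandCtx, gt, pan$speciesTree, "f",
                        outgroup = "r2", supportMin = 70))
  expect_true(rank[v0] <= rank[v1])
  expect_true(rank[v1] <= rank[v2])
  expect_true(rank[v2] <= rank[v3])
})
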