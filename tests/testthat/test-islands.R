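## One moderately sized genome with a planted low-GC island, reused
## across the blocks in this file.
islandFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      anc <- generateAncestor(cladeConfig(
        nCore = 330, sharedPatterns = c("m4-4|m2-6" = 0),
        specific = c("m4-4" = 0, "m2-6" = 0, "p1.1.43" = 0),
        islands = list(), seed = 61))
      spec <- islandSpec("ancestor", lengthBp = 25000, gc = 0.3168,
                         nMarkerGenes = 2, flankRepeatLen = 20,
                         cargoFamilyId = "cargoZ")
      cache <<- plantIsland(anc, spec, seed = 62)
    }
    cache
  }
})

test_that("window scan standardises GC against the genome background", {
  set.seed(51)
  g <- Genome("u", Biostrings::DNAStringSet(
    c(c1 = randomDnaString(5000, 0.4))))
  sc <- windowScan(g, window = 5000, step = 500)
  expect_equal(nrow(sc@table), 1L)
  expect_equal(sc@table$z, 0)           # single window: sd undefined -> 0
  g2 <- Genome("u", Biostrings::DNAStringSet(
    c(c1 = randomDnaString(60000, 0.4), tiny = randomDnaString(800, 0.4))))
  expect_message(sc2 <- windowScan(g2), "skipping contig")
  expect_true(all(sc2@table$contig_id == "c1"))
  expect_lt(abs(mean(sc2@table$z)), 1e-8)
})

test_that("a planted low-GC island produces strongly negative windows", {
  fx <- islandFixture()
  sc <- windowScan(fx$genome)
  expect_lt(min(sc@table$z), -4)
})

test_that("island calls recover the planted span and composition", {
  fx <- islandFixture()
  g <- fx$genome; tr <- fx$truth
  sc <- windowScan(g)
  isl <- callIslands(g, sc)
  expect_equal(length(isl), 1L)
  expect_lte(abs(GenomicRanges::start(isl) - tr$start), 5000)
  expect_lte(abs(GenomicRanges::end(isl) - tr$end), 5000)
  expect_lt(abs(isl$mean_gc - 31.68), 0.5)
  expect_error(callIslands(g, sc, zCut = 1), "negative")
})

test_that("a control island at background GC is not called", {
  anc <- generateAncestor(cladeConfig(
    nCore = 150, sharedPatterns = c("m4-4|m2-6" = 0),
    specific = c("m4-4" = 0, "m2-6" = 0, "p1.1.43" = 0),
    islands = list(), seed = 63))
  ctl <- plantIsland(anc, islandSpec("ancestor", lengthBp = 20000,
                                     gc = 0.3797, nMarkerGenes = 2,
                                     flankRepeatLen = 20,
                                     cargoFamilyId = "ctl"), seed = 64)
  isl <- callIslands(ctl$genome, windowScan(ctl$genome))
  expect_equal(length(isl), 0L)
})

test_that("null genomes yield no calls at default thresholds", {
  set.seed(52)
  calls <- 0L
  for (rep in 1:20) {
    g <- Genome("null", Biostrings::DNAStringSet(
      c(c1 = randomDnaString(60000, 0.38))))
    calls <- calls + length(callIslands(g, windowScan(g)))
  }
  expect_equal(calls, 0L)
})

test_that("islands separated by more than the merge gap stay distinct", {
  set.seed(53)
  low <- function(n) randomDnaString(n, 0.29)
  bg <- function(n) randomDnaString(n, 0.38)
  seqc <- paste0(bg(150000), low(10000), bg(12000), low(10000),
                 bg(150000))
  g <- Genome("two", Biostrings::DNAStringSet(c(c1 = seqc)))
  isl <- callIslands(g, windowScan(g))
  expect_equal(length(isl), 2L)
})

test_that("MGE context annotation honours lexicon and margin", {
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    c(12000, 20000, 4900, 1000, 30100), width = 900))
  gr$gene_id <- paste0("g", 1:5)
  gr$product <- c("IS643 transposase", "hypothetical protein",
                  "integrase", "phage portal protein",
                  "site-specific recombinase")
  island <- GenomicRanges::GRanges("c1", IRanges::IRanges(10000, 25000))
  island$mean_gc <- 31; island$genome_gc <- 38; island$z_min <- -5
  out <- annotateMgeContext(island, gr, margin = 5000)
  mk <- out$mge_markers[[1]]
  ## inside: g1; within 5 kb: g3 (ends 5799, 4.2 kb away);
  ## g4 ends 1899 (8.1 kb away) and g5 starts 30100 (5.1 kb away): out;
  ## g2 inside but 'hypothetical protein' carries no keyword
  expect_setequal(mk$gene_id, c("g1", "g3"))
  expect_true("transposase" %in% mk$keyword || "IS" %in% mk$keyword)
  ## a word-boundary IS hit does not fire on lowercase 'island'
  gr2 <- gr[2]; gr2$product <- "island biosynthesis protein"
  out2 <- annotateMgeContext(island, gr2)
  expect_equal(nrow(out2$mge_markers[[1]]), 0L)
})

test_that("flanking direct repeats are found exactly and only in margins", {
  set.seed(54)
  rep20 <- randomDnaString(20, 0.4)
  left <- randomDnaString(5000, 0.4)
  isl <- randomDnaString(9000, 0.3)
  right <- randomDnaString(5000, 0.4)
  seqc <- paste0(left, rep20, isl, rep20, right)
  g <- Genome("r", Biostrings::DNAStringSet(c(c1 = seqc)))
  island <- list(contig = "c1", start = 5021, end = 5020 + 9000)
  fr <- findFlankRepeats(g, island)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$left_start, 5001)
  expect_equal(fr$right_start, 14021)
  expect_equal(fr$length, 20L)
  ## a copy straddling the outer margin edge is excluded
  island2 <- list(contig = "c1", start = 5021 + 1990, end = 5020 + 9000)
  fr2 <- findFlankRepeats(g, island2, margin = 2000)
  expect_false(any(fr2$length >= 20))
})

test_that("random flanks contain no spurious 15-mers", {
  set.seed(55)
  hits <- 0L
  for (rep in 1:30) {
    g <- Genome("r", Biostrings::DNAStringSet(
      c(c1 = randomDnaString(14000, 0.4))))
    fr <- findFlankRepeats(g, list(contig = "c1", start = 5001,
                                   end = 9000))
    hits <- hits + nrow(fr)
  }
  expect_equal(hits, 0L)
})

test_that("island mean GC equals the pooled GC of the extracted span", {
  fx <- islandFixture()
  g <- fx$genome
  isl <- callIslands(g, windowScan(g))
  sub <- Biostrings::subseq(contigs(g)[[1]],
                            GenomicRanges::start(isl)[1],
                            GenomicRanges::end(isl)[1])
  f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(sub),
                                   c("A", "C", "G", "T"))
  expect_equal(isl$mean_gc[1], 100 * (f[, "C"] + f[, "G"]) / sum(f),
               ignore_attr = TRUE)
})
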