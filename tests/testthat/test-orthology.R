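test_that("local alignment equals brute-force DP on textbook and random cases", {
  b50 <- local({e <- new.env(); data("BLOSUM50", package = "Biostrings",
                                    envir = e); get("BLOSUM50", e)})
  b62 <- local({e <- new.env(); data("BLOSUM62", package = "Biostrings",
                                    envir = e); get("BLOSUM62", e)})
  ## classic worked example: linear gap penalty 8 per residue
  expect_equal(localAlign("HEAGAWGHEE", "PAWHEAE", matrix = "BLOSUM50",
                          gapOpen = 0, gapExt = 8)$raw_score,
               swOracle("HEAGAWGHEE", "PAWHEAE", b50, 0, 8))
  expect_equal(localAlign("HEAGAWGHEE", "PAWHEAE", matrix = "BLOSUM50",
                          gapOpen = 0, gapExt = 8)$raw_score, 28)
  set.seed(14)
  for (rep in 1:12) {
    a <- randomProteinString(sample(3:12, 1))
    b <- randomProteinString(sample(3:12, 1))
    expect_equal(localAlign(a, b)$raw_score, swOracle(a, b, b62, 11, 1),
                 info = paste(a, b))
  }
})

test_that("identical sequences align with full identity and coverage", {
  a <- randomProteinString(100)
  h <- localAlign(a, a)
  expect_equal(h$identity, 1)
  expect_equal(h$qcov, 1)
  expect_equal(h$scov, 1)
  expect_error(localAlign("MKV", "MKB4"), "non-protein")
  expect_error(localAlign("", "MKV"), "empty")
})

test_that("best hits find exact copies and break ties lexicographically", {
  set.seed(3)
  qs <- Biostrings::AAStringSet(setNames(
    vapply(1:6, function(i) randomProteinString(120), ""),
    paste0("q", 1:6)))
  decoys <- Biostrings::AAStringSet(setNames(
    vapply(1:4, function(i) randomProteinString(120), ""),
    paste0("d", 1:4)))
  subj <- c(Biostrings::AAStringSet(setNames(as.character(qs),
                                             paste0("copy_", names(qs)))),
            decoys)
  bh <- bestHits(qs, subj)
  expect_equal(nrow(bh), 6L)
  expect_identical(bh$subject[match(names(qs), bh$query)],
                   paste0("copy_", names(qs)))
  ## two identical subjects: lexicographically smaller id wins
  s2 <- Biostrings::AAStringSet(setNames(
    rep(as.character(qs[[1]]), 2), c("zz", "aa")))
  bh2 <- bestHits(qs[1], s2)
  expect_identical(bh2$subject, "aa")
})

test_that("random decoys fall above the e-value threshold", {
  set.seed(99)
  misses <- 0
  for (rep in 1:100) {
    a <- randomProteinString(50); b <- randomProteinString(50)
    h <- localAlign(a, b, m = 5000, n = 50)
    if (h$evalue <= 1e-6) misses <- misses + 1
  }
  expect_lte(misses, 1)
})

test_that("BBH pairs identical proteomes completely and symmetrically", {
  set.seed(21)
  A <- Biostrings::AAStringSet(setNames(
    vapply(1:8, function(i) randomProteinString(100), ""),
    paste0("a", 1:8)))
  B <- Biostrings::AAStringSet(setNames(as.character(A),
                                        paste0("b", 1:8)))
  bb <- bidirectionalBestHits(A, B)
  expect_equal(nrow(bb), 8L)
  bb2 <- bidirectionalBestHits(B, A)
  expect_setequal(paste(bb$query, bb$subject),
                  paste(bb2$subject, bb2$query))
  expect_error(bidirectionalBestHits(A, B, minCov = 0), "minCov")
})

test_that("coverage below the mutual threshold excludes a pair", {
  set.seed(22)
  full <- randomProteinString(200)
  A <- Biostrings::AAStringSet(c(a1 = full))
  B <- Biostrings::AAStringSet(c(b1 = substr(full, 1, 110)))  # 55% cover
  expect_equal(nrow(bidirectionalBestHits(A, B, minCov = 0.6)), 0L)
  expect_equal(nrow(bidirectionalBestHits(A, B, minCov = 0.5)), 1L)
})

test_that("tightening thresholds never enlarges the BBH set", {
  set.seed(31)
  mk <- function(pfx, n) Biostrings::AAStringSet(setNames(
    vapply(seq_len(n), function(i) randomProteinString(sample(60:140, 1)), ""),
    paste0(pfx, seq_len(n))))
  A <- mk("a", 10)
  ## B: 6 mutated copies of A + 4 decoys
  bseq <- vapply(1:6, function(i) {
    s <- strsplit(as.character(A[[i]]), "")[[1]]
    k <- sample(seq_along(s), round(length(s) * 0.3))
    s[k] <- sample(c("A","C","D","E","F","G","H","I","K","L"),
                   length(k), TRUE)
    paste(s, collapse = "")
  }, "")
  B <- c(Biostrings::AAStringSet(setNames(bseq, paste0("b", 1:6))),
         mk("d", 4))
  n1 <- nrow(bidirectionalBestHits(A, B, minCov = 0.5, maxEval = 1e-3))
  n2 <- nrow(bidirectionalBestHits(A, B, minCov = 0.7, maxEval = 1e-3))
  n3 <- nrow(bidirectionalBestHits(A, B, minCov = 0.5, maxEval = 1e-9))
  expect_lte(n2, n1)
  expect_lte(n3, n1)
})

test_that("families follow connected components with paralog resolution", {
  g1 <- makeGenome("s1", randomOrf(60), seed = 1)
  g2 <- makeGenome("s2", randomOrf(60), seed = 2)
  g3 <- makeGenome("s3", randomOrf(60), seed = 3)
  genomes <- list(s1 = g1, s2 = g2, s3 = g3)
  bb <- function(sa, sb, qa, qb, bits = 100) {
    d <- data.frame(query = qa, subject = qb, bitscore = bits,
                    identity = 1, min_cov = 1)
    attr(d, "strainA") <- sa; attr(d, "strainB") <- sb
    d
  }
  ## chain a-b, b-c with no a-c edge: still one core family
  fams <- buildFamilies(genomes, list(
    bb("s1", "s2", "s1_g1", "s2_g1"),
    bb("s2", "s3", "s2_g1", "s3_g1"),
    local({d <- data.frame(query = character(), subject = character(),
                           bitscore = numeric(), identity = numeric(),
                           min_cov = numeric())
           attr(d, "strainA") <- "s1"; attr(d, "strainB") <- "s3"; d})))
  expect_equal(length(unique(fams$family_id)), 1L)
  expect_true(all(fams$category == "core"))
  ## triangle across three strains: one core family
  fams2 <- buildFamilies(genomes, list(
    bb("s1", "s2", "s1_g1", "s2_g1"),
    bb("s2", "s3", "s2_g1", "s3_g1"),
    bb("s1", "s3", "s1_g1", "s3_g1")))
  expect_equal(length(unique(fams2$family_id)), 1L)
  ## paralog resolution: weaker in-strain duplicate re-seated as singleton
  g1b <- makeGenome("s1", c(randomOrf(60), randomOrf(60)), seed = 4)
  genomes2 <- list(s1 = g1b, s2 = g2)
  fams3 <- buildFamilies(genomes2, list(
    local({d <- data.frame(query = c("s1_g1", "s1_g2"),
                           subject = c("s2_g1", "s2_g1"),
                           bitscore = c(200, 90), identity = 1,
                           min_cov = 1)
           attr(d, "strainA") <- "s1"; attr(d, "strainB") <- "s2"; d})))
  byFam <- split(fams3$gene_id, fams3$family_id)
  big <- byFam[[which(lengths(byFam) == 2)]]
  expect_setequal(big, c("s1_g1", "s2_g1"))
  expect_equal(fams3$category[fams3$gene_id == "s1_g2"], "specific")
  ## conservation: every gene placed exactly once
  expect_equal(nrow(fams3), 3L)
  expect_false(anyDuplicated(paste(fams3$strain_id, fams3$gene_id)) > 0)
})

test_that("pangenome counts reproduce the printed-count arithmetic", {
  ## worked example from the published three-strain comparison:
  ## 2,893 core families, CDS counts 3,556 / 3,500 / 3,530
  mk <- function(n, strains, prefix) {
    do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(family_id = sprintf("%s%05d", prefix, i),
                 strain_id = strains,
                 gene_id = paste0(strains, "_", prefix, i),
                 category = NA_character_)))
  }
  fams <- rbind(mk(2893, c("m4-4", "m2-6", "p1.1.43"), "core"),
                mk(700, c("m4-4", "m2-6"), "sh12"),
                mk(351, c("m2-6", "p1.1.43"), "sh23"),
                mk(472, "p1.1.43", "sp"))
  cds <- c("m4-4" = 3556, "m2-6" = 3500, "p1.1.43" = 3530)
  part <- pangenomeCounts(fams, cds)
  expect_equal(part@counts$core_fraction_of_mean_cds, 82)
  expect_equal(pangenomeSize(part), 4416L)
  expect_equal(pangenomeSize(part) - coreSize(part), 1523L)
  expect_error(pangenomeCounts(fams[0, ], cds), "empty")
  expect_error(pangenomeCounts(fams, cds[1]), "two genomes")
})

test_that("synteny conservation matches hand enumeration", {
  set.seed(77)
  orfs <- vapply(1:10, function(i) randomOrf(50), "")
  gA <- makeGenome("A", orfs, seed = 5)
  gB <- makeGenome("B", orfs[c(1, 2, 3, 4, 6, 7, 5, 8, 9, 10)], seed = 6)
  ## map gene i of A to the gene of B holding the same sequence
  famTab <- rbind(
    data.frame(family_id = paste0("f", 1:10), strain_id = "A",
               gene_id = paste0("A_g", 1:10), category = "core"),
    data.frame(family_id = paste0("f", c(1, 2, 3, 4, 6, 7, 5, 8, 9, 10)),
               strain_id = "B", gene_id = paste0("B_g", 1:10),
               category = "core"))
  expect_equal(syntenyConservation(gA, gA, famTab), 1.0)
  ## relocating gene 5 breaks adjacencies (4,5), (5,6) and (7,8): 6/9
  expect_equal(syntenyConservation(gA, gB, famTab), 6 / 9)
  one <- makeGenome("A", orfs[1], seed = 5)
  expect_error(syntenyConservation(one, gB, famTab), "undefined")
})

test_that("BBH recovers manifest core pairing on a small clade", {
  cl <- generateClade(cladeConfig(
    nCore = 30, sharedPatterns = c("m4-4|m2-6" = 3),
    specific = c("m4-4" = 2, "m2-6" = 2, "p1.1.43" = 2),
    islands = list(), seed = 41))
  A <- cl$genomes[["m4-4"]]; B <- cl$genomes[["m2-6"]]
  bb <- bidirectionalBestHits(A, B)
  man <- cl$manifest$families
  both <- man$family_id[vapply(strsplit(man$pattern, "|", fixed = TRUE),
                               function(p) all(c("m4-4", "m2-6") %in% p),
                               logical(1))]
  want <- paste(paste0("m4-4_", both), paste0("m2-6_", both))
  got <- paste(bb$query, bb$subject)
  recall <- mean(want %in% got)
  precision <- mean(got %in% want)
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)
})
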