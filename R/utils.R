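## Internal helpers shared across modules.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

## GC percent of sequences, N (and other ambiguity codes) excluded from
## numerator and denominator: 100 * (G + C) / (A + C + G + T).
.gcPercent <- function(x) {
  if (is(x, "DNAString")) x <- DNAStringSet(list(x))
  if (is.character(x)) x <- DNAStringSet(x)
  f <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  acgt <- rowSums(f)
  gc <- f[, "G"] + f[, "C"]
  ifelse(acgt == 0, NA_real_, 100 * gc / acgt)
}

## Pooled GC over a whole set of sequences (single number).
.gcPercentPooled <- function(x) {
  if (is(x, "DNAString")) x <- DNAStringSet(list(x))
  f <- colSums(Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T")))
  tot <- sum(f)
  if (tot == 0) return(NA_real_)
  100 * (f[["G"]] + f[["C"]]) / tot
}

## Sample `n` bases i.i.d. with GC fraction `gc` (A/T and G/C symmetric).
.sampleBases <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

.collapse <- function(x) paste(x, collapse = "")

STOP_CODONS <- c("TAA", "TAG", "TGA")

## Sample `n` codons i.i.d. at per-base GC fraction `gc`, rejecting stop
## codons (resampled until none remain).
.sampleNonStopCodons <- function(n, gc) {
  if (n <= 0L) return(character(0))
  codons <- paste0(.sampleBases(n, gc), .sampleBases(n, gc),
                   .sampleBases(n, gc))
  repeat {
    bad <- which(codons %in% STOP_CODONS)
    if (!length(bad)) break
    codons[bad] <- paste0(.sampleBases(length(bad), gc),
                          .sampleBases(length(bad), gc),
                          .sampleBases(length(bad), gc))
  }
  codons
}

## Translate a CDS nucleotide sequence (bacterial code, table 11),
## forcing the initiator to M and stripping the terminal stop.
.translateCds <- function(dna) {
  aa <- as.character(Biostrings::translate(
    dna, genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  aa <- sub("\\*$", "", aa)
  ifelse(nchar(aa) > 0, paste0("M", substring(aa, 2L)), aa)
}

## Spawn a reproducible sub-seed from the session RNG (kept < 2^31).
.subSeed <- function() sample.int(.Machine$integer.max - 1L, 1L)

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

.readTsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}
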