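#' @include AllClasses.R utils.R
NULL

#' Read sequence records from a FASTA file
#'
#' Reads nucleotide or protein FASTA, uppercases the sequences and
#' validates the alphabet (DNA: A, C, G, T, N; protein: the 20 standard
#' amino acids plus X). Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param moltype `"dna"` or `"protein"`.
#' @return A \linkS4class{DNAStringSet} or \linkS4class{AAStringSet}.
#' @examples
#' f <- tempfile(fileext = ".fna")
#' writeLines(c(">a", "acgt"), f)
#' readFastaRecords(f, "dna")
#' @export
readFastaRecords <- function(path, moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  ## keep only the first word of each FASTA header as the id
  names(x) <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(names(x)))) stop("FASTA record with empty id", call. = FALSE)
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  if (any(width(x) == 0L))
    stop("empty sequence for record: ",
         paste(names(x)[width(x) == 0L], collapse = ", "), call. = FALSE)
  chars <- Biostrings::uniqueLetters(x)
  chars <- unique(toupper(chars))
  allowed <- if (moltype == "dna") c("A", "C", "G", "T", "N")
             else c(AA20, "X")
  bad <- setdiff(chars, allowed)
  if (length(bad)) {
    per <- vapply(x, function(s) {
      any(strsplit(toupper(as.character(s)), "")[[1]] %in% bad)
    }, logical(1))
    stop(sprintf("illegal %s characters (%s) in record(s): %s", moltype,
                 paste(bad, collapse = ""),
                 paste(names(x)[per], collapse = ", ")), call. = FALSE)
  }
  seqs <- toupper(as.character(x))
  if (moltype == "dna") DNAStringSet(setNames(seqs, names(x)))
  else AAStringSet(setNames(seqs, names(x)))
}

#' Write sequence records to FASTA
#'
#' @param x An XStringSet (named).
#' @param path Output path.
#' @param width Line-wrap width (default 80 columns).
#' @return `path`, invisibly.
#' @export
writeFastaRecords <- function(x, path, width = 80L) {
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read gene features from GFF3 or a plain TSV table
#'
#' GFF3 input follows the standard 1-based inclusive convention and is
#' returned as a \linkS4class{GRanges} (1-based closed, the native
#' Bioconductor convention used throughout the package). The TSV dialect
#' expects columns `contig_id`, `gene_id`, `start`, `end`, `strand`,
#' `product` (1-based inclusive).
#'
#' @param path Path to the feature file.
#' @param dialect `"gff3"` or `"tsv_table"`.
#' @return \linkS4class{GRanges} with metadata columns `gene_id`, `product`.
#' @export
readFeatures <- function(path, dialect = c("gff3", "tsv_table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type %in% c("CDS", "gene") | is.na(gr$type)]
    gid <- gr$ID %||% gr$Name
    if (is.null(gid)) stop("GFF3 features lack ID attributes", call. = FALSE)
    prod <- gr$product %||% rep(NA_character_, length(gr))
    mcols(gr) <- NULL
    gr$gene_id <- as.character(gid)
    gr$product <- ifelse(is.na(prod), "hypothetical protein",
                         as.character(prod))
  } else {
    tb <- .readTsv(path)
    need <- c("contig_id", "gene_id", "start", "end", "strand", "product")
    if (!all(need %in% names(tb)))
      stop("tsv_table needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    gr <- GRanges(tb$contig_id, IRanges(tb$start, tb$end),
                  strand = tb$strand)
    gr$gene_id <- tb$gene_id
    gr$product <- tb$product
  }
  if (any(end(gr) < start(gr)))
    stop("feature with end before start", call. = FALSE)
  if (anyDuplicated(gr$gene_id))
    stop("duplicate gene ids: ",
         paste(unique(gr$gene_id[duplicated(gr$gene_id)]), collapse = ", "),
         call. = FALSE)
  gr
}

#' Write gene features as GFF3
#'
#' @param gr \linkS4class{GRanges} with `gene_id` and `product` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFeatures <- function(gr, path) {
  out <- gr
  mcols(out) <- NULL
  out$source <- "microevo"
  out$type <- "CDS"
  out$phase <- 0L   # features are whole CDS, frame starts at the span
  out$ID <- gr$gene_id
  out$product <- gr$product
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Construct a Genome object
#'
#' When `proteome` is omitted, protein products are derived by
#' translating each feature span (reverse-complemented for minus-strand
#' features) with the bacterial genetic code (table 11); the initiator
#' codon is rendered as M and the terminal stop is stripped.
#'
#' @param strainId Strain identifier.
#' @param contigs Named \linkS4class{DNAStringSet}.
#' @param features \linkS4class{GRanges} with `gene_id`, `product` columns.
#' @param proteome Optional named \linkS4class{AAStringSet}.
#' @return A validated [Genome-class] object.
#' @examples
#' g <- demoGenome()
#' genomeStats(g)
#' @export
Genome <- function(strainId, contigs,
                   features = GRanges(), proteome = NULL) {
  if (is.null(proteome)) {
    if (length(features)) {
      cds <- .featureSeqs(contigs, features)
      proteome <- AAStringSet(setNames(.translateCds(cds), features$gene_id))
    } else proteome <- AAStringSet()
  }
  new("Genome", strainId = strainId, contigs = contigs,
      features = features, proteome = proteome)
}

## Extract (strand-aware) nucleotide sequences of features.
.featureSeqs <- function(contigs, features) {
  seqs <- subseq(contigs[as.character(seqnames(features))],
                 start(features), end(features))
  minus <- as.logical(strand(features) == "-")
  if (any(minus)) seqs[minus] <- reverseComplement(seqs[minus])
  setNames(seqs, features$gene_id)
}

#' Read a genome from FASTA + feature annotation
#'
#' @param fastaPath Contig FASTA.
#' @param featurePath GFF3 (or TSV) feature file; may be `NULL` for an
#'   unannotated genome.
#' @param proteomePath Optional protein FASTA (ids matching gene ids);
#'   if absent, proteins are derived by translation.
#' @param strainId Strain identifier; defaults to the FASTA basename.
#' @param dialect Feature dialect passed to [readFeatures()].
#' @return A [Genome-class] object.
#' @export
readGenome <- function(fastaPath, featurePath = NULL, proteomePath = NULL,
                       strainId = NULL, dialect = "gff3") {
  strainId <- strainId %||%
    sub("\\.(fa|fna|fasta)$", "", basename(fastaPath))
  ctg <- readFastaRecords(fastaPath, "dna")
  ft <- if (is.null(featurePath)) GRanges()
        else readFeatures(featurePath, dialect)
  prot <- if (is.null(proteomePath)) NULL
          else readFastaRecords(proteomePath, "protein")
  Genome(strainId, ctg, ft, prot)
}

#' Write a genome as FASTA + GFF3 + protein FASTA
#'
#' Produces `<strain>.fna`, `<strain>.gff3` and `<strain>.faa` under
#' `dir` (created if needed).
#'
#' @param genome A [Genome-class] object.
#' @param dir Output directory.
#' @return Named character vector of the three paths, invisibly.
#' @export
writeGenome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, strainId(genome))
  paths <- c(fna = paste0(base, ".fna"), gff = paste0(base, ".gff3"),
             faa = paste0(base, ".faa"))
  writeFastaRecords(contigs(genome), paths["fna"])
  writeFeatures(features(genome), paths["gff"])
  writeFastaRecords(proteome(genome), paths["faa"])
  invisible(paths)
}

#' Assembly summary statistics
#'
#' GC is computed as 100 (G + C) / (A + C + G + T); N bases are excluded
#' from both numerator and denominator. N50 is the length of the contig
#' at which the cumulative descending-sorted contig length first reaches
#' half the assembly total (ties resolved towards the larger contig by
#' the descending sort).
#'
#' @param genome A [Genome-class] object.
#' @return A list with `length_bp`, `gc_percent`, `contig_count`,
#'   `n50_bp`, `cds_count`.
#' @export
genomeStats <- function(genome) {
  ctg <- contigs(genome)
  if (length(ctg) == 0L) stop("empty genome", call. = FALSE)
  gc <- .gcPercentPooled(ctg)
  if (is.na(gc))
    warning("genome contains no called (A/C/G/T) bases; GC undefined")
  w <- sort(width(ctg), decreasing = TRUE)
  n50 <- w[which(cumsum(as.numeric(w)) >= sum(as.numeric(w)) / 2)[1L]]
  list(length_bp = sum(width(ctg)), gc_percent = gc,
       contig_count = length(ctg), n50_bp = n50,
       cds_count = length(features(genome)))
}

#' Read / write phylogenetic trees in Newick format
#'
#' Thin wrappers over \pkg{ape}. Round trips preserve topology, tip
#' labels and branch lengths to printed precision.
#'
#' @param path Newick file path.
#' @return `readNewick` returns an \code{ape::phylo} tree.
#' @export
readNewick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("newick parse error in ", path,
                                          ": ", conditionMessage(e),
                                          call. = FALSE))
  if (is.null(tr)) stop("newick parse error in ", path, call. = FALSE)
  tr
}

#' @rdname readNewick
#' @param tree An \code{ape::phylo} tree.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' A tiny built-in genome for examples
#'
#' Deterministic two-gene, one-contig genome used in documentation
#' examples and smoke tests.
#'
#' @return A [Genome-class] object.
#' @export
demoGenome <- function() {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
  set.seed(7L)
  gene <- function(n) .collapse(c("ATG", .sampleNonStopCodons(n, 0.45), "TAA"))
  g1 <- gene(30L); g2 <- gene(40L)
  g2rc <- as.character(reverseComplement(DNAString(g2)))
  sp <- .collapse(.sampleBases(60L, 0.45))
  seq <- paste0(sp, g1, sp, g2rc, sp)
  ctg <- DNAStringSet(setNames(seq, "ctg1"))
  s1 <- nchar(sp) + 1L
  s2 <- nchar(sp) * 2L + nchar(g1) + 1L
  ft <- GRanges("ctg1", IRanges(c(s1, s2),
                                width = c(nchar(g1), nchar(g2))),
                strand = c("+", "-"))
  ft$gene_id <- c("demo_0001", "demo_0002")
  ft$product <- c("hypothetical protein", "DNA polymerase III subunit")
  Genome("demo", ctg, ft)
}
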