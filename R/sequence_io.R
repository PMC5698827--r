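#' Read DNA sequences from a FASTA file
#'
#' Reads a FASTA file into a [Biostrings::DNAStringSet]. Sequences are
#' uppercased, RNA-style `U` is mapped to `T`, and any character outside the
#' `A/C/G/T/N` alphabet is rejected, so downstream code can rely on a clean
#' DNA alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one element per record, in file
#'   order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">frag1", "acgtACGT", ">frag2", "TTTAAA"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (any(Biostrings::width(raw) == 0L)) {
    bad <- names(raw)[Biostrings::width(raw) == 0L][1L]
    stop("empty sequence for FASTA record '", bad, "' in ", path)
  }
  seqs <- toupper(as.character(raw))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    i <- which(bad)[1L]
    ch <- regmatches(seqs[i], regexpr("[^ACGTN]", seqs[i]))
    stop("record '", names(raw)[i], "' contains character '", ch,
         "' outside the A/C/G/T/N alphabet")
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(raw)
  out
}

#' Write DNA sequences to a FASTA file
#'
#' @param x A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) {
    x <- Biostrings::DNAStringSet(x)
  }
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read gene annotations from a GFF3 file
#'
#' Imports `gene`/`CDS` features as a [GenomicRanges::GRanges] (1-based
#' inclusive coordinates, the Bioconductor convention). Features without a
#' defined strand are rejected: a gene model must have an orientation for
#' reading-frame arithmetic to make sense.
#'
#' @param path Path to a GFF3 file.
#' @param featureTypes Feature types to keep; others are dropped. When no
#'   feature carries a `type` column all records are kept.
#' @return A `GRanges` of gene annotations.
#' @export
readGff3 <- function(path, featureTypes = c("gene", "CDS")) {
  if (!file.exists(path)) {
    stop("GFF3 file not found: ", path)
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("malformed GFF3 in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(gr) && !is.null(gr$type)) {
    gr <- gr[as.character(gr$type) %in% featureTypes]
  }
  if (any(GenomicRanges::strand(gr) == "*")) {
    stop("GFF3 feature with undefined strand '.' in ", path,
         "; gene annotations must be stranded")
  }
  gr
}

#' Write gene annotations to a GFF3 file
#'
#' @param genes A [GenomicRanges::GRanges] of gene annotations.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGff3 <- function(genes, path) {
  if (is.null(genes$type)) {
    genes$type <- "gene"
  }
  if (is.null(genes$source)) {
    genes$source <- "MetaGeneDSN"
  }
  rtracklayer::export(genes, path, format = "gff3")
  invisible(path)
}

#' Cut a genome into fixed-length fragments
#'
#' Simulates error-free shotgun reads: fragment start positions are drawn
#' uniformly at random (with replacement) and each fragment is reported from a
#' random strand, so the number of fragments is `floor(coverage * genomeLen /
#' fragLen)` and the expected per-base coverage equals `coverage`.
#'
#' @param genome A [Biostrings::DNAString], single-element `DNAStringSet`, or
#'   character scalar.
#' @param fragLen Fragment length in bp.
#' @param coverage Fold genome coverage (expected), > 0.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   fragment set.
#' @param genomeId Identifier recorded as fragment provenance; defaults to the
#'   name of `genome` or `"genome"`.
#' @return A `DNAStringSet` of fragments whose `mcols()` carry `genome_id`,
#'   `start` (1-based start of the genomic window) and `strand`. A `-` strand
#'   fragment is the reverse complement of its genomic window.
#' @examples
#' g <- Biostrings::DNAString(paste(rep("ACGT", 500), collapse = ""))
#' frags <- fragmentGenome(g, fragLen = 120, coverage = 1, seed = 7)
#' length(frags)  # floor(2000 / 120)
#' @export
fragmentGenome <- function(genome, fragLen, coverage = 1, seed = NULL,
                           genomeId = NULL) {
  if (is.character(genome)) {
    genome <- Biostrings::DNAString(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    if (length(genome) != 1L) {
      stop("fragmentGenome() expects a single genome sequence")
    }
    genomeId <- genomeId %||% names(genome)
    genome <- genome[[1L]]
  }
  genomeId <- genomeId %||% "genome"
  fragLen <- as.integer(fragLen)
  stopifnot(fragLen >= 1L, coverage > 0)
  glen <- length(genome)
  if (glen < fragLen) {
    stop("genome (", glen, " bp) is shorter than fragLen (", fragLen, " bp)")
  }
  n <- as.integer(floor(coverage * glen / fragLen))
  withSeed(seed, {
    starts <- sample.int(glen - fragLen + 1L, n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
  })
  v <- Biostrings::Views(genome, start = starts, width = fragLen)
  frags <- methods::as(v, "DNAStringSet")
  neg <- strands == "-"
  if (any(neg)) {
    frags[neg] <- Biostrings::reverseComplement(frags[neg])
  }
  names(frags) <- sprintf("frag_%06d", seq_len(n))
  S4Vectors::mcols(frags) <- S4Vectors::DataFrame(
    genome_id = rep(genomeId, n),
    start = starts,
    strand = strands
  )
  frags
}
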