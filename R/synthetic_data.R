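# Synthetic prokaryote-like genomes with planted codon-biased genes.
#
# The simulator emulates the construction of labeled training data from
# annotated genomes: non-overlapping genes (ATG start, codon-biased body,
# terminal stop) are planted on both strands, separated by neutral
# intergenic sequence, and the exact annotation is returned alongside the
# sequence so that extracted ORFs can be labeled coding/noncoding. It is
# error-free by design: no sequencing-error model is applied to fragments.

#' Specification of a synthetic prokaryote-like genome
#'
#' @param genomeLen Genome length in bp.
#' @param geneDensity Target fraction of the genome covered by genes, in
#'   `[0, 1)`. `0` produces a pure intergenic genome.
#' @param geneLenMin Minimum gene length in bp (multiple of 3, >= 60).
#' @param geneLenMean Mean gene length in bp.
#' @param codonBias Named probability vector over the 64 codons used to draw
#'   gene-body codons. The default concentrates `favoredMass` of the
#'   probability on `nFavoredCodons` randomly chosen sense codons (a strong,
#'   clean codon-usage signal) and puts zero mass on stop codons. Mass on
#'   stop codons is permitted: [uniformCodonBias()] uses it to build a null
#'   genome whose "genes" are statistically identical to intergenic sequence.
#' @param nFavoredCodons,favoredMass Shape of the default codon bias.
#' @param stopWeights Sampling weights of the terminal stop codon
#'   (`TAA/TAG/TGA`).
#' @param intergenic Named nucleotide probabilities of intergenic sequence.
#' @param genomeId Sequence name used in annotations and provenance.
#' @param seed Integer seed; fixes both the default codon bias and the
#'   genome realization.
#' @return A list of class `SyntheticGenomeSpec`.
#' @export
syntheticGenomeSpec <- function(genomeLen = 100000L, geneDensity = 0.6,
                                geneLenMin = 90L, geneLenMean = 600L,
                                codonBias = NULL, nFavoredCodons = 8L,
                                favoredMass = 0.8,
                                stopWeights = c(TAA = 1, TAG = 1, TGA = 1) / 3,
                                intergenic = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                                genomeId = "synthetic_genome",
                                seed = 1L) {
  stopifnot(genomeLen >= 1L, geneDensity >= 0, geneDensity < 1,
            geneLenMin >= 60L, geneLenMin %% 3L == 0L,
            geneLenMean >= geneLenMin)
  if (abs(sum(intergenic) - 1) > 1e-9) {
    stop("intergenic nucleotide probabilities must sum to 1")
  }
  if (is.null(codonBias)) {
    sense <- setdiff(CODONS64, STOP_CODONS)
    fav <- withSeed(seed, sample(sense, nFavoredCodons))
    codonBias <- setNames(numeric(64L), CODONS64)
    codonBias[fav] <- favoredMass / nFavoredCodons
    rest <- setdiff(sense, fav)
    codonBias[rest] <- (1 - favoredMass) / length(rest)
  }
  if (is.null(names(codonBias)) || !setequal(names(codonBias), CODONS64)) {
    stop("codonBias must be named with all 64 codons")
  }
  codonBias <- codonBias[CODONS64]
  if (abs(sum(codonBias) - 1) > 1e-9) {
    stop("codonBias must sum to 1")
  }
  structure(list(genomeLen = as.integer(genomeLen),
                 geneDensity = geneDensity,
                 geneLenMin = as.integer(geneLenMin),
                 geneLenMean = as.integer(geneLenMean),
                 codonBias = codonBias,
                 stopWeights = stopWeights / sum(stopWeights),
                 intergenic = intergenic / sum(intergenic),
                 genomeId = genomeId,
                 seed = as.integer(seed)),
            class = "SyntheticGenomeSpec")
}

#' Uniform codon bias equal to uniform intergenic composition
#'
#' Assigns probability 1/64 to every codon, stop codons included. Genes drawn
#' from this bias are statistically indistinguishable from uniform intergenic
#' sequence (apart from their forced ATG start and terminal stop), so labels
#' carry no sequence signal: the null condition for calibration experiments.
#'
#' @return Named 64-vector of codon probabilities.
#' @export
uniformCodonBias <- function() {
  setNames(rep(1 / 64, 64L), CODONS64)
}

#' Generate a synthetic genome with planted genes and exact annotation
#'
#' Walks along the genome alternating intergenic gaps (exponential lengths
#' matching the target gene density) and genes (gamma-distributed lengths
#' rounded to codons, ATG start, codon-biased body, terminal stop), each gene
#' on a random strand. Deterministic given `spec$seed`.
#'
#' @param spec A [syntheticGenomeSpec()].
#' @return A list: `sequence` (a [Biostrings::DNAString]) and `genes` (a
#'   [GenomicRanges::GRanges] with one range per planted gene, `type =
#'   "gene"`).
#' @export
generateGenome <- function(spec) {
  stopifnot(inherits(spec, "SyntheticGenomeSpec"))
  glen <- spec$genomeLen
  bases <- names(spec$intergenic)
  pieces <- character(0)
  geneStart <- integer(0); geneEnd <- integer(0); geneStrand <- character(0)
  withSeed(spec$seed + 1L, {
    gapMean <- if (spec$geneDensity > 0) {
      spec$geneLenMean * (1 - spec$geneDensity) / spec$geneDensity
    } else {
      Inf
    }
    pos <- 1L
    while (pos <= glen) {
      gap <- if (is.finite(gapMean)) as.integer(round(rexp(1L, 1 / gapMean)))
             else glen - pos + 1L
      gap <- min(gap, glen - pos + 1L)
      if (gap > 0L) {
        pieces <- c(pieces, paste(
          sample(bases, gap, replace = TRUE, prob = spec$intergenic),
          collapse = ""))
        pos <- pos + gap
      }
      if (pos > glen || !is.finite(gapMean)) break
      nc <- max(spec$geneLenMin %/% 3L,
                as.integer(round(rgamma(1L, shape = 4,
                                        scale = spec$geneLenMean / 4) / 3)))
      len <- 3L * nc
      if (pos + len - 1L > glen) break  # no room left for a whole gene
      body <- if (nc > 2L) {
        sample(CODONS64, nc - 2L, replace = TRUE, prob = spec$codonBias)
      } else {
        character(0)
      }
      stopCodon <- sample(STOP_CODONS, 1L, prob = spec$stopWeights)
      geneSeq <- paste(c("ATG", body, stopCodon), collapse = "")
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") {
        geneSeq <- revcompChar(geneSeq)
      }
      pieces <- c(pieces, geneSeq)
      geneStart <- c(geneStart, pos)
      geneEnd <- c(geneEnd, pos + len - 1L)
      geneStrand <- c(geneStrand, strand)
      pos <- pos + len
    }
  })
  seq <- paste(pieces, collapse = "")
  if (nchar(seq) < glen) {
    # top up with intergenic sequence (deterministic continuation)
    extra <- withSeed(spec$seed + 2L, paste(
      sample(bases, glen - nchar(seq), replace = TRUE,
             prob = spec$intergenic), collapse = ""))
    seq <- paste0(seq, extra)
  }
  genes <- GenomicRanges::GRanges(
    seqnames = rep(spec$genomeId, length(geneStart)),
    ranges = IRanges::IRanges(start = geneStart,
                              end = geneEnd),
    strand = geneStrand
  )
  genes$type <- rep("gene", length(genes))
  genes$ID <- sprintf("gene_%04d", seq_along(genes))
  list(sequence = Biostrings::DNAString(seq), genes = genes)
}

#' Build a fully labeled synthetic ORF dataset end to end
#'
#' Runs the complete pipeline on a synthetic genome: genome generation,
#' fragmentation, six-frame ORF extraction, annotation-based labeling, and
#' feature fusion. The result is ready for [trainDsn()] / [kfoldCv()].
#'
#' @param spec A [syntheticGenomeSpec()].
#' @param fragLen Fragment length in bp (e.g. 700 or 120).
#' @param coverage Fold genome coverage of the fragmenting.
#' @param seed Seed for the fragmenting.
#' @param minLen Minimum ORF length in bp.
#' @param minOverlapFrac In-frame overlap fraction for a coding label.
#' @param groups Feature groups (see [featureNames()]).
#' @param deduplicate Keep one candidate per genomic ORF locus (see
#'   [deduplicateOrfs()]); the default, since overlapping fragments
#'   re-observe the same ORF and cross-validation folds must not share such
#'   near-duplicates.
#' @return A [SummarizedExperiment::SummarizedExperiment]: assay `features`
#'   (features x ORFs), `colData` the labeled ORF table, and the spec in
#'   `metadata()`.
#' @export
makeLabeledDataset <- function(spec, fragLen = 700L, coverage = 1,
                               seed = 1L, minLen = 60L,
                               minOverlapFrac = 0.8, groups = "all",
                               deduplicate = TRUE) {
  genome <- generateGenome(spec)
  frags <- fragmentGenome(genome$sequence, fragLen = fragLen,
                          coverage = coverage, seed = seed,
                          genomeId = spec$genomeId)
  orfs <- extractOrfs(frags, minLen = minLen)
  if (deduplicate) {
    orfs <- deduplicateOrfs(orfs)
  }
  orfs <- labelOrfs(orfs, genome$genes, minOverlapFrac = minOverlapFrac)
  X <- featureMatrix(orfs, groups = groups)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = X),
    colData = orfs,
    metadata = list(spec = spec, fragLen = fragLen, coverage = coverage,
                    nGenes = length(genome$genes))
  )
}
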