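# The fused 119-dimensional ORF descriptor:
#   [ ORFC(1) | MCU(64) | MAU(21) | ZCPS(9) | ZCPD(24) ]
#
# ORFC  - ORF length coverage l/L
# MCU   - monocodon usage over the 64 codons (stop codons included)
# MAU   - monoamino acid usage over 20 amino acids + STOP
# ZCPS  - Z-curve transform of codon-position-specific nucleotide frequencies
# ZCPD  - Z-curve transform of phase-specific dinucleotide frequencies
#
# All frequencies are taken over "countable" codons, i.e. codons without N;
# the stop codon, when present, counts like any other codon.

.codonsOf <- function(sequence) {
  n <- nchar(sequence) %/% 3L
  substring(sequence, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
}

.countableCodons <- function(orf) {
  codons <- .codonsOf(orf$sequence)
  codons[!grepl("N", codons, fixed = TRUE)]
}

# Accept either a one-row ORF table slice or a list(sequence=, l=, L=).
.asOrf <- function(orf) {
  if (is.character(orf) && length(orf) == 1L) {
    return(list(sequence = orf, l = nchar(orf), L = nchar(orf)))
  }
  as.list(orf)
}

#' ORF coverage: length proportion of the ORF within its fragment
#'
#' Coding ORFs tend to be longer than spurious noncoding ORFs, so the ratio
#' `l / L` of ORF length to fragment length is itself informative.
#'
#' @param orf A one-row ORF table slice (or list with `l` and `L`).
#' @return A single number in `(0, 1]`.
#' @export
orfCoverage <- function(orf) {
  orf <- .asOrf(orf)
  l <- as.numeric(orf$l)
  L <- as.numeric(orf$L)
  stopifnot(l >= 1)
  if (l > L) {
    stop("ORF length l (", l, ") exceeds fragment length L (", L, ")")
  }
  l / L
}

#' Monocodon usage: 64 codon frequencies of an ORF
#'
#' Frequencies of each codon among the ORF's countable (non-ambiguous) codons,
#' in fixed lexicographic DNA order `AAA`..`TTT`. Stop codons are counted like
#' any other codon.
#'
#' @param orf A one-row ORF table slice, or a coding-strand sequence string.
#' @return Named numeric vector of length 64 summing to 1.
#' @export
monocodonUsage <- function(orf) {
  orf <- .asOrf(orf)
  codons <- .countableCodons(orf)
  if (length(codons) == 0L) {
    stop("ORF has no countable (non-N) codons")
  }
  counts <- tabulate(match(codons, CODONS64), nbins = 64L)
  setNames(counts / length(codons), CODONS64)
}

#' Monoamino acid usage: 20 amino acid + STOP frequencies of an ORF
#'
#' Codons are translated with the standard genetic code; frequencies are
#' relative to the total countable codons, in fixed order `A,C,D,...,Y,STOP`.
#'
#' @inheritParams monocodonUsage
#' @return Named numeric vector of length 21 summing to 1.
#' @export
monoaminoUsage <- function(orf) {
  orf <- .asOrf(orf)
  codons <- .countableCodons(orf)
  if (length(codons) == 0L) {
    stop("ORF has no countable (non-N) codons")
  }
  aaIdx <- codonToAminoIndex()[match(codons, CODONS64)]
  counts <- tabulate(aaIdx, nbins = 21L)
  setNames(counts / length(codons), AMINO21)
}

#' Codon-position nucleotide and phase dinucleotide frequencies
#'
#' Tallies, over an ORF's countable codons, the frequency of each base at
#' codon positions 1, 2 and 3, and of each dinucleotide at the intra-codon
#' phases 1-2 and 2-3. These are the raw counts behind the Z-curve
#' descriptors.
#'
#' @inheritParams monocodonUsage
#' @return A list with `pos` (4x3 matrix of base frequencies by codon
#'   position), `p12` and `p23` (named 16-vectors of dinucleotide
#'   frequencies), and `n` (countable codon count).
#' @export
codonPositionCounts <- function(orf) {
  orf <- .asOrf(orf)
  codons <- .countableCodons(orf)
  if (length(codons) == 0L) {
    stop("ORF has no countable (non-N) codons")
  }
  n <- length(codons)
  bases <- c("A", "C", "G", "T")
  pos <- matrix(0, nrow = 4L, ncol = 3L, dimnames = list(bases, NULL))
  for (i in 1:3) {
    b <- substring(codons, i, i)
    pos[, i] <- tabulate(match(b, bases), nbins = 4L) / n
  }
  d12 <- substring(codons, 1L, 2L)
  d23 <- substring(codons, 2L, 3L)
  p12 <- setNames(tabulate(match(d12, DINUCS16), nbins = 16L) / n, DINUCS16)
  p23 <- setNames(tabulate(match(d23, DINUCS16), nbins = 16L) / n, DINUCS16)
  list(pos = pos, p12 = p12, p23 = p23, n = n)
}

#' Z-curve parameters of codon-position-specific nucleotide frequencies
#'
#' For each codon position `i` the three Z-curve axes contrast purine vs
#' pyrimidine (`x`), amino vs keto (`y`) and weak vs strong (`z`) base
#' frequencies:
#' `x_i = (a_i + g_i) - (c_i + t_i)`,
#' `y_i = (a_i + c_i) - (g_i + t_i)`,
#' `z_i = (a_i + t_i) - (g_i + c_i)`.
#'
#' @param counts Output of [codonPositionCounts()].
#' @return Named numeric vector of length 9 in order
#'   `x1,y1,z1,x2,y2,z2,x3,y3,z3`, each entry in `[-1, 1]`.
#' @export
zcurvePositionSpecific <- function(counts) {
  out <- numeric(9L)
  nm <- character(9L)
  for (i in 1:3) {
    a <- counts$pos["A", i]; c_ <- counts$pos["C", i]
    g <- counts$pos["G", i]; t <- counts$pos["T", i]
    out[3 * i - 2] <- (a + g) - (c_ + t)
    out[3 * i - 1] <- (a + c_) - (g + t)
    out[3 * i] <- (a + t) - (g + c_)
    nm[(3 * i - 2):(3 * i)] <- paste0(c("x", "y", "z"), i)
  }
  setNames(out, nm)
}

#' Z-curve parameters of phase-specific dinucleotide frequencies
#'
#' For phases `k` in `{12, 23}` and a leading base `M`, the axes contrast the
#' base following `M`:
#' `x_k(M) = [p_k(MA) + p_k(MG)] - [p_k(MC) + p_k(MT)]`,
#' `y_k(M) = [p_k(MA) + p_k(MC)] - [p_k(MG) + p_k(MT)]`,
#' `z_k(M) = [p_k(MA) + p_k(MT)] - [p_k(MC) + p_k(MG)]`.
#'
#' @param counts Output of [codonPositionCounts()].
#' @return Named numeric vector of length 24: `(x,y,z)` for `M = A,C,G,T` at
#'   phase 12, then the same at phase 23; each entry in `[-1, 1]`.
#' @export
zcurvePhaseDinucleotide <- function(counts) {
  out <- numeric(24L)
  nm <- character(24L)
  j <- 0L
  for (k in c("12", "23")) {
    p <- if (k == "12") counts$p12 else counts$p23
    for (M in c("A", "C", "G", "T")) {
      pa <- p[paste0(M, "A")]; pc <- p[paste0(M, "C")]
      pg <- p[paste0(M, "G")]; pt <- p[paste0(M, "T")]
      out[j + 1L] <- (pa + pg) - (pc + pt)
      out[j + 2L] <- (pa + pc) - (pg + pt)
      out[j + 3L] <- (pa + pt) - (pc + pg)
      nm[(j + 1L):(j + 3L)] <- paste0(c("x", "y", "z"), k, "_", M)
      j <- j + 3L
    }
  }
  setNames(out, nm)
}

#' Names of the feature groups and their columns
#'
#' The fused vector has a fixed, documented component order:
#' `orfc` (1), `mcu` (64), `mau` (21), `zcps` (9), `zcpd` (24) -- 119 in all.
#'
#' @param groups Feature groups to include, a subset of
#'   `c("orfc","mcu","mau","zcps","zcpd")` or `"all"`.
#' @return Character vector of feature names in fused order.
#' @export
featureNames <- function(groups = "all") {
  groups <- .normalizeGroups(groups)
  nm <- list(
    orfc = "orfc",
    mcu = paste0("mcu_", CODONS64),
    mau = paste0("mau_", AMINO21),
    zcps = paste0("zcps_", paste0(rep(c("x", "y", "z"), 3),
                                  rep(1:3, each = 3))),
    zcpd = paste0("zcpd_", paste0(rep(c("x", "y", "z"), 8),
                                  rep(rep(c("12", "23"), each = 12), 1),
                                  "_",
                                  rep(rep(c("A", "C", "G", "T"), each = 3), 2)))
  )
  unlist(nm[groups], use.names = FALSE)
}

.FEATURE_GROUPS <- c("orfc", "mcu", "mau", "zcps", "zcpd")

.normalizeGroups <- function(groups) {
  if (identical(groups, "all") || is.null(groups)) {
    return(.FEATURE_GROUPS)
  }
  groups <- unique(match.arg(groups, .FEATURE_GROUPS, several.ok = TRUE))
  if (!length(groups)) stop("feature group selection is empty")
  # keep canonical fused order regardless of how groups were listed
  .FEATURE_GROUPS[.FEATURE_GROUPS %in% groups]
}

#' Fuse the four descriptors of one ORF into a single feature vector
#'
#' Concatenates ORF coverage, monocodon usage, monoamino acid usage and the
#' two Z-curve descriptor blocks, in that fixed order (119 dimensions for the
#' full set).
#'
#' @param orf A one-row ORF table slice from [extractOrfs()].
#' @param groups Feature groups to include (see [featureNames()]).
#' @return Named numeric vector, 119 entries for `groups = "all"`.
#' @export
fuseFeatures <- function(orf, groups = "all") {
  orf <- .asOrf(orf)
  groups <- .normalizeGroups(groups)
  parts <- list()
  needCounts <- any(c("zcps", "zcpd") %in% groups)
  counts <- if (needCounts) codonPositionCounts(orf) else NULL
  for (g in groups) {
    parts[[g]] <- switch(g,
      orfc = c(orfc = orfCoverage(orf)),
      mcu = setNames(monocodonUsage(orf), paste0("mcu_", CODONS64)),
      mau = setNames(monoaminoUsage(orf), paste0("mau_", AMINO21)),
      zcps = setNames(zcurvePositionSpecific(counts),
                      featureNames("zcps")),
      zcpd = setNames(zcurvePhaseDinucleotide(counts),
                      featureNames("zcpd"))
    )
  }
  unlist(parts, use.names = TRUE, recursive = FALSE) |>
    setNames(featureNames(groups))
}

# Tabulate per-ORF category counts in one pass: idx is a category index
# (1..k) for every codon, orfIdx the owning ORF. Returns a k x n matrix.
.tallyByOrf <- function(idx, orfIdx, k, n) {
  matrix(tabulate((orfIdx - 1L) * k + idx, nbins = k * n), nrow = k)
}

#' Feature matrix for a table of candidate ORFs
#'
#' Computes the fused descriptor of every candidate (equal to row-wise
#' [fuseFeatures()], but tallied in a single vectorized pass) and returns
#' features in rows and ORFs in columns -- the features-by-samples
#' orientation used by [trainDsn()] and by `SummarizedExperiment`.
#'
#' @param orfs ORF table from [extractOrfs()].
#' @param groups Feature groups to include (see [featureNames()]).
#' @return Numeric matrix, `length(featureNames(groups))` rows by `nrow(orfs)`
#'   columns, with ORF ids as column names.
#' @export
featureMatrix <- function(orfs, groups = "all") {
  groups <- .normalizeGroups(groups)
  nms <- featureNames(groups)
  n <- nrow(orfs)
  if (n == 0L) {
    return(matrix(numeric(0), nrow = length(nms), ncol = 0L,
                  dimnames = list(nms, character(0))))
  }
  codonsList <- lapply(orfs$sequence, .codonsOf)
  orfIdx <- rep.int(seq_len(n), lengths(codonsList))
  cod <- unlist(codonsList, use.names = FALSE)
  ok <- !grepl("N", cod, fixed = TRUE)
  cod <- cod[ok]
  orfIdx <- orfIdx[ok]
  nCodon <- tabulate(orfIdx, nbins = n)
  if (any(nCodon == 0L)) {
    stop("ORF '", orfs$orf_id[which(nCodon == 0L)[1L]],
         "' has no countable (non-N) codons")
  }
  nrep <- function(k) rep(nCodon, each = k)
  blocks <- list()
  codIdx <- match(cod, CODONS64)
  if ("orfc" %in% groups) {
    blocks$orfc <- matrix(as.numeric(orfs$l) / as.numeric(orfs$L), 1L)
  }
  if ("mcu" %in% groups || "mau" %in% groups) {
    mcuCounts <- .tallyByOrf(codIdx, orfIdx, 64L, n)
    if ("mcu" %in% groups) blocks$mcu <- mcuCounts / nrep(64L)
    if ("mau" %in% groups) {
      aaAgg <- rowsum(mcuCounts, codonToAminoIndex())  # 21 x n, sorted idx
      blocks$mau <- aaAgg / nrep(21L)
    }
  }
  if (any(c("zcps", "zcpd") %in% groups)) {
    bases <- c("A", "C", "G", "T")
    if ("zcps" %in% groups) {
      zc <- matrix(0, 9L, n)
      for (i in 1:3) {
        P <- .tallyByOrf(match(substring(cod, i, i), bases),
                         orfIdx, 4L, n) / nrep(4L)
        zc[3 * i - 2, ] <- (P[1, ] + P[3, ]) - (P[2, ] + P[4, ])
        zc[3 * i - 1, ] <- (P[1, ] + P[2, ]) - (P[3, ] + P[4, ])
        zc[3 * i, ] <- (P[1, ] + P[4, ]) - (P[3, ] + P[2, ])
      }
      blocks$zcps <- zc
    }
    if ("zcpd" %in% groups) {
      zd <- matrix(0, 24L, n)
      j <- 0L
      for (k in c("12", "23")) {
        d <- if (k == "12") substring(cod, 1L, 2L) else substring(cod, 2L, 3L)
        P <- .tallyByOrf(match(d, DINUCS16), orfIdx, 16L, n) / nrep(16L)
        for (m in 0:3) {  # leading base A,C,G,T occupies rows 4m+1..4m+4
          pa <- P[4 * m + 1, ]; pc <- P[4 * m + 2, ]
          pg <- P[4 * m + 3, ]; pt <- P[4 * m + 4, ]
          zd[j + 1L, ] <- (pa + pg) - (pc + pt)
          zd[j + 2L, ] <- (pa + pc) - (pg + pt)
          zd[j + 3L, ] <- (pa + pt) - (pc + pg)
          j <- j + 3L
        }
      }
      blocks$zcpd <- zd
    }
  }
  X <- do.call(rbind, blocks[groups[groups %in% names(blocks)]])
  dimnames(X) <- list(nms, orfs$orf_id)
  X
}

#' Write a feature matrix to TSV
#'
#' One row per ORF: `orf_id` followed by the named feature columns.
#'
#' @param X Feature matrix from [featureMatrix()] (features x ORFs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFeatureTsv <- function(X, path) {
  df <- data.frame(orf_id = colnames(X), t(X), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
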