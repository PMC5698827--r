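# Independent oracles: deliberately naive second implementations used to
# cross-check the package's vectorized code paths.

BASES <- c("A", "C", "G", "T")
ALL_CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES,
                              function(ab, c) paste0(ab, c)))
ALL_CODONS <- sort(ALL_CODONS)  # lexicographic AAA..TTT
STOPS <- c("TAA", "TAG", "TGA")

splitCodons <- function(seq) {
  n <- nchar(seq) %/% 3
  vapply(seq_len(n), function(i) substr(seq, 3 * i - 2, 3 * i), "")
}

# Plain loop-and-count codon tally (64 counts in AAA..TTT order).
naiveCodonTally <- function(codons) {
  counts <- setNames(rep(0L, 64), ALL_CODONS)
  for (cd in codons) {
    if (grepl("N", cd, fixed = TRUE)) next
    counts[cd] <- counts[cd] + 1L
  }
  counts
}

# Dinucleotide tally at intra-codon phase 1-2 or 2-3.
naiveDinucTally <- function(codons, phase = c("12", "23")) {
  phase <- match.arg(phase)
  dn <- sort(as.vector(outer(BASES, BASES, paste0)))
  counts <- setNames(rep(0L, 16), dn)
  for (cd in codons) {
    if (grepl("N", cd, fixed = TRUE)) next
    d <- if (phase == "12") substr(cd, 1, 2) else substr(cd, 2, 3)
    counts[d] <- counts[d] + 1L
  }
  counts
}

# 21 x 64 aggregation matrix from the standard genetic code, amino acids in
# alphabetical one-letter order then STOP.
mcuToMauMatrix <- function() {
  aa <- Biostrings::GENETIC_CODE[ALL_CODONS]
  aa[aa == "*"] <- "STOP"
  lev <- c(sort(setdiff(unique(aa), "STOP")), "STOP")
  M <- matrix(0, nrow = 21, ncol = 64, dimnames = list(lev, ALL_CODONS))
  for (j in seq_along(aa)) M[aa[j], j] <- 1
  M
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Exhaustive complete-ORF scanner: tests every start-codon position on both
# strands of the raw string; keeps (strand, forward-strand start/end) of each
# segment-first start .. next in-frame stop pair. Position logic is entirely
# independent of the package's codon-vector scanner.
exhaustiveCompleteOrfs <- function(seq, minLen = 60,
                                   startCodons = c("ATG", "GTG", "TTG")) {
  L <- nchar(seq)
  found <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (p in seq_len(L - 2)) {
      if (!substr(s, p, p + 2) %in% startCodons) next
      # walk back in-frame: first start/stop met decides segment-firstness
      isFirst <- TRUE
      q <- p - 3
      while (q >= 1) {
        cd <- substr(s, q, q + 2)
        if (cd %in% STOPS) break
        if (cd %in% startCodons) { isFirst <- FALSE; break }
        q <- q - 3
      }
      if (!isFirst) next
      # walk forward to the next in-frame stop
      q <- p + 3
      stopEnd <- NA
      while (q + 2 <= L) {
        if (substr(s, q, q + 2) %in% STOPS) { stopEnd <- q + 2; break }
        q <- q + 3
      }
      if (is.na(stopEnd)) next
      l <- stopEnd - p + 1
      if (l < minLen) next
      if (strand == "+") {
        found[[length(found) + 1]] <- c(strand, p, stopEnd, l)
      } else {
        found[[length(found) + 1]] <- c(strand, L - stopEnd + 1, L - p + 1, l)
      }
    }
  }
  if (!length(found)) {
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0), l = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, found), stringsAsFactors = FALSE)
  names(df) <- c("strand", "start", "end", "l")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$l <- as.integer(df$l)
  df[order(df$strand, df$start), , drop = FALSE]
}

# Confusion counts via table(), independent of computeMetrics internals.
confusionOracle <- function(pred, truth, positive = "coding") {
  p <- factor(pred == positive, levels = c(TRUE, FALSE))
  t <- factor(truth == positive, levels = c(TRUE, FALSE))
  tab <- table(p, t)
  c(TP = tab[1, 1], FP = tab[1, 2], FN = tab[2, 1], TN = tab[2, 2])
}

randomDnaSeq <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# A random ORF table row suitable for the feature functions.
randomOrfRow <- function(nCodons, L = NULL) {
  seq <- randomDnaSeq(3 * nCodons)
  l <- 3 * nCodons
  list(sequence = seq, l = l, L = if (is.null(L)) l else L)
}

# Small, fast training configuration for tests.
tinyConfig <- function(seed = 1L, nModules = 2L, hiddenUnits = 16L) {
  dsnTrainConfig(nModules = nModules, hiddenUnits = hiddenUnits,
                 rbm = list(epochs = 3L, batchSize = 50L),
                 fineTune = list(epochs = 5L),
                 seed = seed)
}
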