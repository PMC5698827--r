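# Internal helpers shared across modules.

STOP_CODONS <- c("TAA", "TAG", "TGA")
DEFAULT_START_CODONS <- c("ATG", "GTG", "TTG")

# 64 codons in lexicographic DNA order AAA..TTT; fixed feature order.
allCodons <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}
CODONS64 <- allCodons()

# 16 dinucleotides AA..TT, same ordering convention.
allDinucs <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2)
}
DINUCS16 <- allDinucs()

# 20 amino acids in alphabetical one-letter order, then STOP.
AMINO21 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
             "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "STOP")

.pkgCache <- new.env(parent = emptyenv())

# Codon -> index into AMINO21 via the standard genetic code.
codonToAminoIndex <- function() {
  if (is.null(.pkgCache$aaIdx)) {
    gc <- Biostrings::GENETIC_CODE
    aa <- unname(gc[CODONS64])
    aa[aa == "*"] <- "STOP"
    .pkgCache$aaIdx <- match(aa, AMINO21)
  }
  .pkgCache$aaIdx
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
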