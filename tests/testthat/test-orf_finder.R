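test_that("a stop- and start-free fragment yields six whole-frame ORFs", {
  polyA <- strrep("A", 120)
  orfs <- extractOrfs(polyA)
  expect_identical(nrow(orfs), 6L)
  expect_true(all(!orfs$has_start & !orfs$has_stop))
  # whole-codon counts per frame offset: 40, 39, 39 codons
  byFrame <- as.data.frame(orfs)[order(orfs$strand, orfs$frame), ]
  expect_identical(byFrame$l, rep(c(120L, 117L, 117L), 2))
  # reverse strand of poly-A reads poly-T: still no stop or start
  expect_setequal(orfs$strand, c("+", "-"))
})

test_that("a short gene-bearing fragment yields the hand-enumerated ORF", {
  orfs <- extractOrfs("CCATGAAATAACC", minLen = 9)
  complete <- orfs[orfs$complete, , drop = FALSE]
  expect_identical(nrow(complete), 1L)
  expect_identical(complete$strand, "+")
  expect_identical(complete$sequence, "ATGAAATAA")
  expect_identical(complete$l, 9L)
  expect_identical(c(complete$start, complete$end), c(3L, 11L))
  expect_true(complete$has_start && complete$has_stop)
})

test_that("fragments shorter than the minimum ORF length yield nothing", {
  set.seed(4)
  expect_identical(nrow(extractOrfs(randomDnaSeq(59))), 0L)
  expect_identical(nrow(extractOrfs(randomDnaSeq(30))), 0L)
})

test_that("ORF invariants hold on random fragments", {
  set.seed(11)
  for (rep in 1:40) {
    L <- sample(60:400, 1)
    orfs <- extractOrfs(randomDnaSeq(L))
    if (nrow(orfs) == 0) next
    expect_true(all(orfs$l >= 60 & orfs$l <= orfs$L))
    expect_true(all(orfs$l %% 3 == 0))
    expect_true(all(orfs$l == orfs$end - orfs$start + 1))
    expect_identical(orfs$complete, orfs$has_start & orfs$has_stop)
    lastCodon <- substring(orfs$sequence, orfs$l - 2, orfs$l)
    expect_true(all(lastCodon[orfs$has_stop] %in% c("TAA", "TAG", "TGA")))
    firstCodon <- substring(orfs$sequence, 1, 3)
    expect_true(all(firstCodon[orfs$has_start] %in% c("ATG", "GTG", "TTG")))
    # complete ORFs on one (strand, frame) never overlap
    comp <- as.data.frame(orfs[orfs$complete, , drop = FALSE])
    for (grp in split(comp, paste(comp$strand, comp$frame))) {
      if (nrow(grp) < 2) next
      grp <- grp[order(grp$start), ]
      expect_true(all(grp$start[-1] > grp$end[-nrow(grp)]))
    }
  }
})

test_that("extraction commutes with reverse complementation", {
  set.seed(23)
  for (rep in 1:15) {
    s <- randomDnaSeq(200)
    a <- as.data.frame(extractOrfs(s))
    b <- as.data.frame(extractOrfs(revcomp(s)))
    expect_identical(nrow(a), nrow(b))
    if (nrow(a) == 0) next
    # same coding sequences, strands swapped, coordinates mirrored
    keyA <- a[order(a$sequence, a$start), ]
    bMirror <- data.frame(
      sequence = b$sequence,
      strand = ifelse(b$strand == "+", "-", "+"),
      start = 200L - b$end + 1L,
      end = 200L - b$start + 1L
    )
    keyB <- bMirror[order(bMirror$sequence, bMirror$start), ]
    expect_identical(keyA$sequence, keyB$sequence)
    expect_identical(keyA$strand, keyB$strand)
    expect_identical(keyA$start, keyB$start)
    expect_identical(keyA$end, keyB$end)
  }
})

test_that("complete ORFs agree with an exhaustive position-by-position scan", {
  set.seed(31)
  for (rep in 1:60) {
    s <- randomDnaSeq(200)
    got <- as.data.frame(extractOrfs(s))
    got <- got[got$complete, c("strand", "start", "end", "l")]
    got <- got[order(got$strand, got$start), , drop = FALSE]
    rownames(got) <- NULL
    want <- exhaustiveCompleteOrfs(s, minLen = 60)
    rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("candidates with many ambiguous codons are dropped", {
  # 20 codons of which 3 (15%) contain N: above the 10% tolerance
  s <- paste0(strrep("GCA", 17), strrep("GNA", 3))
  orfsAmbig <- extractOrfs(s)
  expect_identical(
    nrow(orfsAmbig[orfsAmbig$strand == "+" & orfsAmbig$frame == 0, ]), 0L)
  # 1 of 20 (5%): kept, N codon flagged
  s2 <- paste0(strrep("GCA", 19), "GNA")
  orfs <- extractOrfs(s2)
  fwd0 <- orfs[orfs$strand == "+" & orfs$frame == 0, ]
  expect_identical(nrow(fwd0), 1L)
  expect_identical(fwd0$n_ambig, 1L)
})

test_that("labeling requires provenance and honors strand, frame, overlap", {
  orf <- S4Vectors::DataFrame(
    orf_id = "o1", fragment_id = "f", strand = "+", frame = 0L,
    start = 251L, end = 550L, l = 300L, L = 600L,
    has_start = TRUE, has_stop = TRUE, complete = TRUE, n_ambig = 0L,
    sequence = strrep("GCA", 100), label = "unknown")
  gene <- GenomicRanges::GRanges("g1", IRanges::IRanges(101, 400),
                                 strand = "+")
  expect_error(labelOrfs(orf, gene), "provenance")

  orf$src_genome <- "g1"; orf$src_start <- 1L; orf$src_strand <- "+"
  # 150 of 300 bp overlap in frame ((251-101) %% 3 == 0): 50%
  expect_identical(labelOrfs(orf, gene, minOverlapFrac = 0.8)$label,
                   "noncoding")
  expect_identical(labelOrfs(orf, gene, minOverlapFrac = 0.4)$label,
                   "coding")

  # exact coincidence is always coding
  orf2 <- orf
  orf2$start <- 101L; orf2$end <- 400L; orf2$l <- 300L
  expect_identical(labelOrfs(orf2, gene, 0.8)$label, "coding")

  # same interval on the opposite strand is noncoding
  geneMinus <- GenomicRanges::GRanges("g1", IRanges::IRanges(101, 400),
                                      strand = "-")
  expect_identical(labelOrfs(orf2, geneMinus, 0.8)$label, "noncoding")

  # out-of-frame full overlap is noncoding
  gene2 <- GenomicRanges::GRanges("g1", IRanges::IRanges(100, 400),
                                  strand = "+")
  expect_identical(labelOrfs(orf2, gene2, 0.8)$label, "noncoding")
})

test_that("labeling maps minus-strand fragments back to the genome", {
  set.seed(7)
  genome <- Biostrings::DNAString(paste0(
    randomDnaSeq(100), "ATG", strrep("GCT", 40), "TAA", randomDnaSeq(97)))
  gene <- GenomicRanges::GRanges("genome",
                                 IRanges::IRanges(101, 226), strand = "+")
  frags <- fragmentGenome(genome, 320, coverage = 40, seed = 5)
  orfs <- labelOrfs(extractOrfs(frags), gene)
  # every complete ORF whose coding sequence is the gene must be coding
  geneSeq <- paste0("ATG", strrep("GCT", 40), "TAA")
  hits <- orfs[orfs$sequence == geneSeq, ]
  expect_gt(nrow(hits), 0L)
  expect_true(all(hits$label == "coding"))
  expect_true(any(S4Vectors::mcols(frags)$strand[
    match(hits$fragment_id, names(frags))] == "-"))
})

test_that("deduplication keeps one candidate per genomic ORF locus", {
  set.seed(61)
  genome <- Biostrings::DNAString(randomDnaSeq(4000))
  # overlapping fragments re-observe the same loci many times
  frags <- fragmentGenome(genome, 400, coverage = 10, seed = 3)
  orfs <- extractOrfs(frags)
  dedup <- deduplicateOrfs(orfs)
  expect_lt(nrow(dedup), nrow(orfs))
  # no two complete survivors share a genomic span
  g <- MetaGeneDSN:::.orfGenomeCoords(as.data.frame(dedup))
  comp <- dedup$complete
  expect_identical(anyDuplicated(paste(g$gstart, g$gend, g$gstrand)[comp]),
                   0L)
  # deduplication is idempotent and keeps the longest observation
  expect_identical(nrow(deduplicateOrfs(dedup)), nrow(dedup))
  expect_gte(mean(dedup$l), mean(orfs$l))
})

test_that("ORF tables export and re-import as TSV", {
  orfs <- extractOrfs("CCATGAAATAACC", minLen = 9)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeOrfTable(orfs, tsv)
  back <- read.delim(tsv)
  expect_identical(nrow(back), nrow(orfs))
  expect_identical(back$l, orfs$l)
  expect_true(all(c("fragment_id", "strand", "frame", "start", "end",
                    "has_start", "has_stop", "l", "L", "label") %in%
                    names(back)))
})
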