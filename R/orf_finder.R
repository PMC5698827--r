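# Six-frame candidate ORF enumeration on short fragments.
#
# A fragment truncates genes at its ends, so in addition to complete ORFs
# (start codon .. stop codon) three incomplete forms are emitted per reading
# frame: missing the upstream end (frame's first codon .. first stop), missing
# the downstream end (start codon .. frame's last whole codon), or missing
# both (the whole frame when it contains neither a stop nor a start).

# Scan one coding-strand orientation of a fragment. Returns a list of ORF
# descriptors in codon-index coordinates for each frame offset 0..2.
.scanCodingStrand <- function(seqChar, minLen, startCodons) {
  n <- nchar(seqChar)
  out <- vector("list", 3L)
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 1L) next
    first <- frame + 1L + 3L * (seq_len(ncod) - 1L)
    codons <- substring(seqChar, first, first + 2L)
    isStop <- codons %in% STOP_CODONS
    isStart <- codons %in% startCodons
    stops <- which(isStop)
    orfs <- list()
    prev <- 0L
    for (st in stops) {
      span <- if (st > prev + 1L) (prev + 1L):(st - 1L) else integer(0)
      fs <- span[isStart[span]][1L]
      if (!is.na(fs)) {
        # complete: first start after the previous stop, through this stop
        orfs[[length(orfs) + 1L]] <- list(i0 = fs, i1 = st,
                                          hasStart = TRUE, hasStop = TRUE)
      } else if (prev == 0L) {
        # upstream-incomplete: frame's first codon through its first stop
        orfs[[length(orfs) + 1L]] <- list(i0 = 1L, i1 = st,
                                          hasStart = FALSE, hasStop = TRUE)
      }
      prev <- st
    }
    if (prev < ncod) {
      tailSpan <- (prev + 1L):ncod
      fs <- tailSpan[isStart[tailSpan]][1L]
      if (!is.na(fs)) {
        # downstream-incomplete: start codon through the frame's last codon
        orfs[[length(orfs) + 1L]] <- list(i0 = fs, i1 = ncod,
                                          hasStart = TRUE, hasStop = FALSE)
      } else if (length(stops) == 0L) {
        # both ends missing: the frame holds no stop and no chosen start
        orfs[[length(orfs) + 1L]] <- list(i0 = 1L, i1 = ncod,
                                          hasStart = FALSE, hasStop = FALSE)
      }
    }
    if (length(orfs)) {
      keep <- vapply(orfs, function(o) 3L * (o$i1 - o$i0 + 1L) >= minLen,
                     logical(1))
      orfs <- orfs[keep]
    }
    if (length(orfs)) {
      out[[frame + 1L]] <- list(frame = frame, codons = codons, orfs = orfs)
    }
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Enumerate candidate ORFs in all six frames of each fragment
#'
#' Scans both strands of every fragment in three frame offsets each. Per
#' stop-to-stop segment at most one ORF is reported (from the segment's first
#' start codon), so nested shorter ORFs are not emitted. An ORF span includes
#' its stop codon, and the stop codon counts as one of its codons. Codons
#' containing `N` stay in the span but are flagged as ambiguous; candidates
#' with more than `maxAmbigFrac` ambiguous codons are dropped.
#'
#' @param fragments A [Biostrings::DNAStringSet] of fragments (e.g. from
#'   [fragmentGenome()] or [readFasta()]), a single `DNAString`, or a character
#'   vector. Provenance columns (`genome_id`, `start`, `strand`) in `mcols()`
#'   are propagated so [labelOrfs()] can map candidates back to the genome.
#' @param minLen Minimum ORF length in bp (default 60); shorter candidates are
#'   discarded.
#' @param startCodons Start codon set; defaults to the prokaryotic
#'   `ATG/GTG/TTG`.
#' @param maxAmbigFrac Maximum tolerated fraction of N-containing codons.
#' @return A [S4Vectors::DataFrame] with one row per candidate ORF:
#'   `orf_id`, `fragment_id`, `strand` and `frame` (offset 0..2 in reading
#'   direction), `start`/`end` (1-based inclusive on the fragment's forward
#'   strand), `l` (ORF length, bp), `L` (fragment length, bp), `has_start`,
#'   `has_stop`, `complete`, `n_ambig`, `sequence` (coding-strand sequence),
#'   `label` (initially `"unknown"`), and provenance columns when available.
#' @examples
#' orfs <- extractOrfs("CCATGAAATAACC", minLen = 9)
#' orfs[, c("strand", "frame", "start", "end", "l", "complete")]
#' @export
extractOrfs <- function(fragments, minLen = 60L,
                        startCodons = DEFAULT_START_CODONS,
                        maxAmbigFrac = 0.1) {
  if (is.character(fragments) || methods::is(fragments, "DNAString")) {
    fragments <- Biostrings::DNAStringSet(fragments)
  }
  if (is.null(names(fragments))) {
    names(fragments) <- sprintf("frag_%06d", seq_along(fragments))
  }
  minLen <- as.integer(minLen)
  src <- S4Vectors::mcols(fragments)
  hasSrc <- !is.null(src) && all(c("genome_id", "start", "strand") %in%
                                   colnames(src))
  seqsFwd <- as.character(fragments)
  rows <- vector("list", length(fragments))
  for (f in seq_along(fragments)) {
    fid <- names(fragments)[f]
    L <- nchar(seqsFwd[f])
    fragRows <- list()
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqsFwd[f] else revcompChar(seqsFwd[f])
      frames <- .scanCodingStrand(s, minLen, startCodons)
      for (fr in frames) {
        for (o in fr$orfs) {
          codons <- fr$codons[o$i0:o$i1]
          nAmbig <- sum(grepl("N", codons, fixed = TRUE))
          if (nAmbig > maxAmbigFrac * length(codons)) next
          cs <- fr$frame + 3L * (o$i0 - 1L) + 1L
          ce <- fr$frame + 3L * o$i1
          if (strand == "+") {
            start <- cs; end <- ce
          } else {
            start <- L - ce + 1L; end <- L - cs + 1L
          }
          fragRows[[length(fragRows) + 1L]] <- data.frame(
            orf_id = sprintf("%s|%s%d|%d", fid, strand, fr$frame, start),
            fragment_id = fid,
            strand = strand,
            frame = fr$frame,
            start = start,
            end = end,
            l = ce - cs + 1L,
            L = L,
            has_start = o$hasStart,
            has_stop = o$hasStop,
            complete = o$hasStart && o$hasStop,
            n_ambig = nAmbig,
            sequence = paste(codons, collapse = ""),
            label = "unknown",
            stringsAsFactors = FALSE
          )
        }
      }
    }
    if (length(fragRows)) {
      df <- do.call(rbind, fragRows)
      if (hasSrc) {
        df$src_genome <- src$genome_id[f]
        df$src_start <- src$start[f]
        df$src_strand <- src$strand[f]
      }
      rows[[f]] <- df
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(S4Vectors::DataFrame(
      orf_id = character(0), fragment_id = character(0), strand = character(0),
      frame = integer(0), start = integer(0), end = integer(0), l = integer(0),
      L = integer(0), has_start = logical(0), has_stop = logical(0),
      complete = logical(0), n_ambig = integer(0), sequence = character(0),
      label = character(0)
    ))
  }
  out <- S4Vectors::DataFrame(do.call(rbind, rows))
  rownames(out) <- out$orf_id
  out
}

# Map ORF fragment coordinates to genome coordinates. Returns a data.frame
# with gstart/gend (1-based inclusive) and gstrand.
.orfGenomeCoords <- function(orfs) {
  need <- c("src_genome", "src_start", "src_strand")
  if (!all(need %in% colnames(orfs))) {
    stop("ORFs carry no source provenance (src_genome/src_start/src_strand); ",
         "labeling requires fragments produced by fragmentGenome()")
  }
  plus <- orfs$src_strand == "+"
  gstart <- ifelse(plus,
                   orfs$src_start + orfs$start - 1L,
                   orfs$src_start + orfs$L - orfs$end)
  gend <- ifelse(plus,
                 orfs$src_start + orfs$end - 1L,
                 orfs$src_start + orfs$L - orfs$start)
  gstrand <- ifelse(plus == (orfs$strand == "+"), "+", "-")
  data.frame(genome = orfs$src_genome, gstart = gstart, gend = gend,
             gstrand = gstrand, stringsAsFactors = FALSE)
}

#' Label candidate ORFs as coding or noncoding from a genome annotation
#'
#' A candidate is labeled `coding` when, mapped back to genome coordinates, it
#' overlaps an annotated gene on the same strand and in the same reading frame
#' over at least `minOverlapFrac` of the ORF's length; otherwise `noncoding`.
#'
#' @param orfs ORF table from [extractOrfs()], with provenance columns.
#' @param genes A [GenomicRanges::GRanges] of gene annotations (e.g. from
#'   [readGff3()] or [generateGenome()]).
#' @param minOverlapFrac Minimum in-frame overlap as a fraction of ORF length
#'   (default 0.8).
#' @return `orfs` with its `label` column filled with `"coding"` /
#'   `"noncoding"`.
#' @export
labelOrfs <- function(orfs, genes, minOverlapFrac = 0.8) {
  if (nrow(orfs) == 0L) return(orfs)
  gc <- .orfGenomeCoords(orfs)
  orfGr <- GenomicRanges::GRanges(
    seqnames = gc$genome,
    ranges = IRanges::IRanges(start = gc$gstart, end = gc$gend),
    strand = gc$gstrand
  )
  hits <- GenomicRanges::findOverlaps(orfGr, genes, ignore.strand = FALSE)
  lab <- rep("noncoding", nrow(orfs))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    gStrand <- as.character(GenomicRanges::strand(genes))[s]
    # in-frame: codon grid anchored at the gene's 5' end
    inFrame <- ifelse(
      gStrand == "+",
      (gc$gstart[q] - GenomicRanges::start(genes)[s]) %% 3L == 0L,
      (GenomicRanges::end(genes)[s] - gc$gend[q]) %% 3L == 0L
    )
    ovl <- IRanges::width(IRanges::pintersect(
      IRanges::IRanges(gc$gstart[q], gc$gend[q]),
      IRanges::IRanges(GenomicRanges::start(genes)[s],
                       GenomicRanges::end(genes)[s])
    ))
    ok <- inFrame & (ovl / orfs$l[q] >= minOverlapFrac)
    lab[unique(q[ok])] <- "coding"
  }
  orfs$label <- lab
  orfs
}

#' Keep one candidate per genomic ORF locus
#'
#' Fragments drawn at random from a genome overlap, so the same genomic ORF
#' is re-observed in several fragments, truncated differently at the
#' fragment ends. For training and cross-validation such near-duplicates are
#' not independent samples: folds that share them leak information. This
#' filter groups candidates by their genomic anchor -- the 3' in-frame stop
#' when present, else the 5' start, else the exact genomic span -- and keeps
#' the longest observation of each locus.
#'
#' @param orfs ORF table from [extractOrfs()] with provenance columns.
#' @return The filtered ORF table.
#' @export
deduplicateOrfs <- function(orfs) {
  if (nrow(orfs) == 0L) return(orfs)
  g <- .orfGenomeCoords(orfs)
  plus <- g$gstrand == "+"
  anchor <- ifelse(orfs$has_stop,
                   paste0("stop", ifelse(plus, g$gend, -g$gstart)),
            ifelse(orfs$has_start,
                   paste0("start", ifelse(plus, -g$gstart, g$gend)),
                   paste0("span", g$gstart, "_", g$gend)))
  key <- paste(g$genome, g$gstrand, anchor)
  ord <- order(-orfs$l, orfs$orf_id)
  keep <- sort(ord[!duplicated(key[ord])])
  orfs[keep, , drop = FALSE]
}

#' Write an ORF table to TSV
#'
#' Exports the candidate table (without the sequence column unless requested)
#' as tab-separated text.
#'
#' @param orfs ORF table from [extractOrfs()].
#' @param path Output path.
#' @param includeSequence Keep the coding-strand sequence column?
#' @return `path`, invisibly.
#' @export
writeOrfTable <- function(orfs, path, includeSequence = FALSE) {
  df <- as.data.frame(orfs)
  if (!includeSequence) {
    df$sequence <- NULL
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
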