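#' Match a window against an IUPAC consensus
#'
#' TRUE iff every window nucleotide lies in the IUPAC class at that
#' position. An `N` in the *window* matches nothing — not even a consensus
#' `N` — so assembly gaps can never satisfy a motif.
#'
#' @param consensus IUPAC consensus string.
#' @param window nucleotide string of the same length over `{A,C,G,T,N}`.
#' @return Logical scalar.
#' @examples
#' iupacMatch("GGTCR", "GGTCA")  # TRUE
#' iupacMatch("GGTCR", "GGTCC")  # FALSE
#' @export
iupacMatch <- function(consensus, window) {
  consensus <- toupper(consensus); window <- toupper(window)
  if (nchar(consensus) != nchar(window))
    ncceUsageError("consensus (%d nt) and window (%d nt) differ in length",
                   nchar(consensus), nchar(window))
  cc <- strsplit(consensus, "")[[1]]
  ww <- strsplit(window, "")[[1]]
  for (i in seq_along(cc)) {
    cls <- IUPAC_CLASSES[[cc[i]]]
    if (is.null(cls))
      ncceUsageError("illegal consensus letter '%s'", cc[i])
    if (!ww[i] %in% cls) return(FALSE)
  }
  TRUE
}

## reverse-complement of an IUPAC string (kept as character)
revcompIupac <- function(s) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(toupper(s), "")[[1]]), collapse = ""))
}

#' Scan a genome for all matches of an IUPAC consensus on both strands
#'
#' Every plus-strand window matching the consensus is reported on strand
#' `+`, and every window whose reverse complement matches on strand `-`; a
#' window matching both ways yields two hits. Windows containing `N` never
#' match. When `regions` is given, only hits lying entirely inside at least
#' one region are returned. Hits are sorted by (chrom, start, strand) and
#' carry the plus-strand matched sequence and the doubled-coordinate center
#' `center2 = start + end - 1` (0-based half-open coordinates), which is
#' integral even for even-length motifs.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param motif a [MotifDefinition-class].
#' @param regions optional [GenomicRanges::GRanges] restricting the scan;
#'   must lie within chromosome bounds.
#' @return A stranded GRanges with metadata columns `motifId`,
#'   `matchedSeq`, `center2`, `elementId` (NA until
#'   [assignContainers()] runs).
#' @export
scanMotif <- function(genome, motif, regions = NULL) {
  stopifnot(is(motif, "MotifDefinition"))
  if (!is.null(regions) && length(regions)) {
    rn <- as.character(GenomicRanges::seqnames(regions))
    if (any(!rn %in% names(genome)))
      ncceUsageError("region chromosome '%s' absent from genome",
                     setdiff(rn, names(genome))[1])
    lens <- Biostrings::width(genome)[match(rn, names(genome))]
    if (any(GenomicRanges::end(regions) > lens) ||
        any(GenomicRanges::start(regions) < 1L))
      ncceUsageError("region outside chromosome bounds")
  }
  cons <- consensus(motif)
  hitsOne <- function(pattern, strandChar) {
    m <- Biostrings::vmatchPattern(pattern, genome, fixed = FALSE)
    irl <- as(m, "IRangesList")
    n <- sum(lengths(irl))
    GenomicRanges::GRanges(rep(names(genome), lengths(irl)),
                           unlist(irl, use.names = FALSE),
                           strand = rep(strandChar, n))
  }
  plus <- hitsOne(cons, "+")
  minus <- hitsOne(revcompIupac(cons), "-")
  gr <- c(plus, minus)
  if (length(gr)) {
    seqs <- character(length(gr))
    sq <- as.character(GenomicRanges::seqnames(gr))
    for (chr in unique(sq)) {
      idx <- which(sq == chr)
      seqs[idx] <- as.character(Biostrings::Views(
        genome[[chr]], GenomicRanges::start(gr)[idx],
        GenomicRanges::end(gr)[idx]))
    }
    keep <- !grepl("N", seqs, fixed = TRUE)
    gr <- gr[keep]; seqs <- seqs[keep]
    if (!is.null(regions)) {
      inside <- IRanges::overlapsAny(gr, regions, type = "within",
                                     ignore.strand = TRUE)
      gr <- gr[inside]; seqs <- seqs[inside]
    }
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      motifId = rep(motifId(motif), length(gr)),
      matchedSeq = seqs,
      center2 = start0(gr) + end0(gr) - 1L,
      elementId = rep(NA_character_, length(gr)))
    o <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr),
               as.character(GenomicRanges::strand(gr)))
    gr <- gr[o]
  } else {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      motifId = character(), matchedSeq = character(),
      center2 = integer(), elementId = character())
  }
  gr
}

#' Restrict motif hits to conserved elements above a score threshold
#'
#' Keeps only hits fully contained in at least one element whose
#' conservation score strictly exceeds `minScore` (the screen's log-odds
#' cutoff, default 300), and stamps each kept hit with the containing
#' element's id. A hit inside k qualifying elements is emitted k times,
#' once per container, because pairing is per-container.
#'
#' @param hits GRanges from [scanMotif()].
#' @param elements conserved-element GRanges from [readConservedBed()].
#' @param minScore strict lower bound on the element score.
#' @return The contained hits, with `elementId` filled, sorted by
#'   (chrom, start, strand, elementId).
#' @export
assignContainers <- function(hits, elements, minScore = 300) {
  ok <- elements[S4Vectors::mcols(elements)$score > minScore]
  if (!length(hits) || !length(ok)) return(hits[integer(0)])
  ov <- GenomicRanges::findOverlaps(hits, ok, type = "within",
                                    ignore.strand = TRUE)
  out <- hits[S4Vectors::queryHits(ov)]
  S4Vectors::mcols(out)$elementId <-
    S4Vectors::mcols(ok)$elementId[S4Vectors::subjectHits(ov)]
  o <- order(as.character(GenomicRanges::seqnames(out)),
             GenomicRanges::start(out),
             as.character(GenomicRanges::strand(out)),
             S4Vectors::mcols(out)$elementId)
  out[o]
}
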