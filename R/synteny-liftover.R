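## Expand a chain into maximal ungapped runs of aligned bases.
## Coordinates: query in plus-strand space; target in chain space (which is
## the reversed target sequence when tStrand == "-"). Blocks separated by
## zero gaps on both sides are merged into one run.
chainSegments <- function(chain) {
  b <- chain@blocks
  n <- nrow(b)
  qs <- qe <- ts <- te <- integer(n)
  qpos <- chain@qStart; tpos <- chain@tStart
  for (i in seq_len(n)) {
    qs[i] <- qpos; qe[i] <- qpos + b[i, 1]
    ts[i] <- tpos; te[i] <- tpos + b[i, 1]
    qpos <- qpos + b[i, 1] + b[i, 2]
    tpos <- tpos + b[i, 1] + b[i, 3]
  }
  ## merge zero-gap-adjacent runs
  if (n > 1L) {
    newRun <- c(TRUE, qs[-1] != qe[-n] | ts[-1] != te[-n])
    run <- cumsum(newRun)
    qs <- tapply(qs, run, min); qe <- tapply(qe, run, max)
    ts <- tapply(ts, run, min); te <- tapply(te, run, max)
  }
  data.frame(qs = as.integer(qs), qe = as.integer(qe),
             ts = as.integer(ts), te = as.integer(te))
}

#' Map a query-genome interval to the target genome through chains
#'
#' Walks the blocks of the highest-scoring chain whose query span contains
#' the interval (ties broken by lowest chain id). The interval must fall
#' entirely within one ungapped block run; an interval that is uncovered or
#' crosses an alignment gap is unmappable and yields `NULL` (a value, not
#' an error). Minus-strand targets are reported on the plus strand of the
#' target chromosome, as BED requires, with `strandFlipped = TRUE`.
#'
#' @param chains list of [ChainAlignment-class].
#' @param chrom query chromosome.
#' @param s0,e0 query interval, 0-based half-open.
#' @return `NULL`, or a list with `chrom`, `start0`, `end0` (target,
#'   0-based half-open, plus strand), `chainId`, `strandFlipped`,
#'   `contiguous = TRUE`.
#' @export
mapInterval <- function(chains, chrom, s0, e0) {
  if (s0 >= e0) ncceUsageError("empty interval [%d,%d)", s0, e0)
  cand <- Filter(function(ch) ch@qChrom == chrom && ch@qStart <= s0 &&
                   e0 <= ch@qEnd, chains)
  if (!length(cand)) return(NULL)
  sc <- vapply(cand, function(ch) ch@score, numeric(1))
  id <- vapply(cand, function(ch) ch@chainId, integer(1))
  ch <- cand[[order(-sc, id)[1]]]
  seg <- chainSegments(ch)
  hit <- which(seg$qs <= s0 & e0 <= seg$qe)
  if (!length(hit)) return(NULL)
  k <- hit[1]
  tS <- seg$ts[k] + (s0 - seg$qs[k])
  tE <- tS + (e0 - s0)
  if (ch@tStrand == "-") {
    list(chrom = ch@tChrom, start0 = ch@tSize - tE, end0 = ch@tSize - tS,
         chainId = ch@chainId, strandFlipped = TRUE, contiguous = TRUE)
  } else {
    list(chrom = ch@tChrom, start0 = tS, end0 = tE,
         chainId = ch@chainId, strandFlipped = FALSE, contiguous = TRUE)
  }
}

#' Invert a chain (swap query and target genomes)
#'
#' The inverted chain maps target coordinates back to the query; mapping an
#' interval through a chain and back through its inversion is the identity
#' on every contiguously mapped interval. The new query strand is `+` by
#' construction (coordinates are rewritten onto the plus strand when the
#' original target strand was `-`).
#'
#' @param chain a [ChainAlignment-class].
#' @return The inverted [ChainAlignment-class].
#' @export
invertChain <- function(chain) {
  seg <- chainSegments(chain)
  if (chain@tStrand == "+") {
    nqs <- seg$ts; nqe <- seg$te; nts <- seg$qs; nte <- seg$qe
    qStart <- chain@tStart; qEnd <- chain@tEnd
    tStart <- chain@qStart; tEnd <- chain@qEnd
  } else {
    ## new query = old target on plus strand: flip and reverse the order;
    ## new target = old query in reversed (minus-strand) space
    ord <- rev(seq_len(nrow(seg)))
    nqs <- chain@tSize - seg$te[ord]; nqe <- chain@tSize - seg$ts[ord]
    nts <- chain@qSize - seg$qe[ord]; nte <- chain@qSize - seg$qs[ord]
    qStart <- chain@tSize - chain@tEnd; qEnd <- chain@tSize - chain@tStart
    tStart <- chain@qSize - chain@qEnd; tEnd <- chain@qSize - chain@qStart
  }
  n <- length(nqs)
  size <- nqe - nqs
  dq <- c(nqs[-1] - nqe[-n], 0L)
  dt <- c(nts[-1] - nte[-n], 0L)
  chainAlignment(chain@chainId, chain@score,
                 chain@tChrom, chain@tSize, qStart, qEnd,
                 chain@qChrom, chain@qSize, chain@tStrand, tStart, tEnd,
                 cbind(size, dq, dt))
}

#' Verify cross-species synteny of composite elements
#'
#' A composite element is syntenically conserved iff both of its motif
#' intervals map contiguously to the target genome and the target sequence
#' at each mapped interval still matches the corresponding consensus on
#' either strand (a strand flip from the chain is expected and allowed).
#' Motif correspondence — not merely successful coordinate conversion — is
#' required. Query-side coordinates are never mutated. Target-side spacing
#' is not re-checked unless `strictTargetSpacing` is set.
#'
#' @param ces a [CompositeElements-class] with all elements `untested`.
#' @param chains list of [ChainAlignment-class] (query -> target).
#' @param targetGenome target [Biostrings::DNAStringSet].
#' @param motifs named list of [MotifDefinition-class] keyed by motif id,
#'   covering every motif id used by `ces`.
#' @param strictTargetSpacing also require the class spacing window on the
#'   mapped target centers.
#' @return `ces` with `syntenyStatus` set to `pass`/`fail` and extra
#'   metadata columns `nkxMapped`, `partnerMapped` (target interval or
#'   `"unmapped"`) and `failReason`.
#' @export
verifySynteny <- function(ces, chains, targetGenome, motifs,
                          strictTargetSpacing = FALSE) {
  mc <- S4Vectors::mcols(ces)
  if (length(ces) && any(mc$syntenyStatus != "untested"))
    ncceUsageError("verifySynteny expects untested elements")
  need <- unique(c(mc$nkxMotifId, mc$partnerMotifId))
  miss <- setdiff(need, names(motifs))
  if (length(ces) && length(miss))
    ncceUsageError("no MotifDefinition for motif id(s): %s",
                   paste(miss, collapse = ", "))
  n <- length(ces)
  status <- character(n); reason <- character(n)
  nkxMapped <- character(n); partnerMapped <- character(n)
  chromv <- as.character(GenomicRanges::seqnames(ces))
  fmt <- function(m) sprintf("%s:%d-%d", m$chrom, m$start0, m$end0)
  checkSide <- function(m, motifIdv) {
    ## mapped interval must exist, land on a known target chromosome, and
    ## still match the consensus on either strand
    if (is.null(m)) return("unmapped")
    if (!m$chrom %in% names(targetGenome))
      ncceDataError("chain target chromosome '%s' absent from target genome",
                    m$chrom)
    if (m$end0 > length(targetGenome[[m$chrom]]))
      ncceDataError("mapped interval beyond end of target chromosome '%s'",
                    m$chrom)
    seq <- as.character(Biostrings::subseq(targetGenome[[m$chrom]],
                                           m$start0 + 1L, m$end0))
    cons <- consensus(motifs[[motifIdv]])
    if (nchar(seq) != nchar(cons)) return("length")
    if (iupacMatch(cons, seq) || iupacMatch(revcompIupac(cons), seq))
      "ok" else "motif_lost"
  }
  for (i in seq_len(n)) {
    mN <- mapInterval(chains, chromv[i], mc$nkxStart[i], mc$nkxEnd[i])
    mP <- mapInterval(chains, chromv[i], mc$partnerStart[i], mc$partnerEnd[i])
    nkxMapped[i] <- if (is.null(mN)) "unmapped" else fmt(mN)
    partnerMapped[i] <- if (is.null(mP)) "unmapped" else fmt(mP)
    rN <- checkSide(mN, mc$nkxMotifId[i])
    rP <- checkSide(mP, mc$partnerMotifId[i])
    r <- character(0)
    if (rN != "ok") r <- c(r, paste0("nkx_", rN))
    if (rP != "ok") r <- c(r, paste0("partner_", rP))
    if (!length(r) && strictTargetSpacing) {
      tc2N <- mN$start0 + mN$end0 - 1L
      tc2P <- mP$start0 + mP$end0 - 1L
      win <- if (mc$classLabel[i] == "WIDE-CONTROL") wideControlWindow()
             else ncceWindow()
      tsp2 <- abs(tc2N - tc2P)
      if (mN$chrom != mP$chrom ||
          tsp2 < 2 * win@minBp || tsp2 > 2 * win@maxBp)
        r <- "target_spacing"
    }
    status[i] <- if (length(r)) "fail" else "pass"
    reason[i] <- paste(r, collapse = ";")
  }
  mc$syntenyStatus <- status
  mc$nkxMapped <- nkxMapped
  mc$partnerMapped <- partnerMapped
  mc$failReason <- reason
  S4Vectors::mcols(ces) <- mc
  ces
}

#' Keep only syntenically conserved composite elements
#'
#' @param ces a [CompositeElements-class]; every element must have been
#'   tested (any `untested` element is a usage error, forcing the pipeline
#'   order scan -> pair -> lift).
#' @return The `pass` subset, order preserved.
#' @export
filterConserved <- function(ces) {
  st <- syntenyStatus(ces)
  if (any(st == "untested"))
    ncceUsageError("%d element(s) still untested; run verifySynteny first",
                   sum(st == "untested"))
  ces[st == "pass"]
}

#' Write the per-element synteny report
#'
#' @param ces tested [CompositeElements-class] (after [verifySynteny()]).
#' @param path output TSV path.
#' @export
writeSyntenyReport <- function(ces, path) {
  mc <- S4Vectors::mcols(ces)
  df <- data.frame(
    ce_id = mc$ceId,
    nkx_mapped = if (length(ces)) mc$nkxMapped else character(),
    partner_mapped = if (length(ces)) mc$partnerMapped else character(),
    synteny = mc$syntenyStatus,
    fail_reason = if (length(ces)) mc$failReason else character())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
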