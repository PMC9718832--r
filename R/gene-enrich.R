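#' Assign each composite element to its nearest gene
#'
#' Distance is measured from the element midpoint — the mean of the two
#' motif centers, handled as an exact rational on a quadrupled coordinate
#' scale — to the gene TSS, on the same chromosome only. Ties go to the
#' lexicographically smallest gene id. An element on a chromosome with no
#' gene raises a per-element warning and stays unassigned (NA), excluded
#' from gene sets downstream.
#'
#' @param ces a [CompositeElements-class].
#' @param genes gene GRanges from [readGeneTable()].
#' @return `ces` with the `nearestGene` metadata column filled.
#' @export
assignNearestGenes <- function(ces, genes) {
  mc <- S4Vectors::mcols(ces)
  n <- length(ces)
  out <- rep(NA_character_, n)
  if (n == 0L) return(ces)
  gchrom <- as.character(GenomicRanges::seqnames(genes))
  gid <- S4Vectors::mcols(genes)$geneId
  gtss4 <- 4 * as.numeric(S4Vectors::mcols(genes)$tss0)
  chromv <- as.character(GenomicRanges::seqnames(ces))
  ## midpoint x4 = sum of the two doubled centers (exact integer)
  mid4 <- (mc$nkxStart + mc$nkxEnd - 1) + (mc$partnerStart + mc$partnerEnd - 1)
  for (i in seq_len(n)) {
    on <- which(gchrom == chromv[i])
    if (!length(on)) {
      warning(sprintf("element %s: no gene on chromosome %s; unassigned",
                      mc$ceId[i], chromv[i]))
      next
    }
    d <- abs(mid4[i] - gtss4[on])
    best <- on[d == min(d)]
    out[i] <- min(gid[best])  # lexicographic tie-break
  }
  mc$nearestGene <- out
  S4Vectors::mcols(ces) <- mc
  ces
}

#' Nearest gene for a single composite element
#'
#' Scalar convenience wrapper around [assignNearestGenes()].
#'
#' @param ce a length-1 [CompositeElements-class].
#' @param genes gene GRanges.
#' @return The gene id, or NA with a warning when the chromosome has no
#'   gene.
#' @export
nearestGene <- function(ce, genes) {
  if (length(ce) != 1L)
    ncceUsageError("nearestGene expects a single element; got %d", length(ce))
  nearestGeneId(assignNearestGenes(ce, genes))
}

#' Build one deduplicated gene set per composite class
#'
#' Gene-level, not element-level: several elements sharing a nearest gene
#' contribute that gene once. Control classes are expected to have been
#' subjected to the same conservation and synteny filters as the composite
#' class before this step. Unassigned elements are skipped.
#'
#' @param cesByClass named list of [CompositeElements-class] (after
#'   [filterConserved()] and [assignNearestGenes()]).
#' @param genes gene GRanges; elements with unfilled `nearestGene` are
#'   assigned here first when `genes` is supplied.
#' @return Named list of character vectors (sorted unique gene ids), one
#'   per class.
#' @export
buildGeneSets <- function(cesByClass, genes = NULL) {
  out <- lapply(names(cesByClass), function(lbl) {
    ces <- cesByClass[[lbl]]
    if (!is.null(genes) && length(ces) &&
        all(is.na(nearestGeneId(ces))))
      ces <- assignNearestGenes(ces, genes)
    ids <- nearestGeneId(ces)
    ids <- sort(unique(ids[!is.na(ids)]))
    if (!length(ids) && lbl == "NCCE")
      warning("composite-element gene set is empty")
    ids
  })
  setNames(out, names(cesByClass))
}

#' Term enrichment of a test gene set against a control gene set
#'
#' For every term annotated to at least one gene of the disjointified union
#' (genes present in both sets are dropped from both, with a message), the
#' 2x2 table (in-test/has-term vs in-control/has-term) is tested with the
#' one-sided exact hypergeometric test for *greater* enrichment in the test
#' set. Odds ratios get a +0.5 Haldane correction when any cell is zero.
#' q-values are Benjamini-Hochberg across all tested terms of this
#' comparison. Results are sorted by q then p.
#'
#' @param test,control character vectors of gene ids.
#' @param termMap data.frame with columns `termId`, `geneId` (flat map; no
#'   ontology propagation).
#' @param controlLabel label recorded in the result rows.
#' @return data.frame with columns `termId`, `termName`, `countTest`,
#'   `countControl`, `testSize`, `controlSize`, `oddsRatio`, `p`, `q`,
#'   `controlLabel`.
#' @export
enrichTerms <- function(test, control, termMap, controlLabel = "control") {
  shared <- intersect(test, control)
  if (length(shared)) {
    message(sprintf("%d gene(s) in both sets dropped from both", length(shared)))
    test <- setdiff(test, shared)
    control <- setdiff(control, shared)
  }
  test <- unique(test); control <- unique(control)
  if (!length(test) || !length(control))
    ncceUsageError("empty %s set after removing shared genes",
                   if (length(test)) "control" else "test")
  universe <- c(test, control)
  tm <- termMap[termMap$geneId %in% universe, , drop = FALSE]
  if (!nrow(tm))
    ncceUsageError("term map covers no gene of the test or control set")
  terms <- sort(unique(tm$termId))
  nT <- length(test); nC <- length(control)
  rows <- lapply(terms, function(tt) {
    g <- tm$geneId[tm$termId == tt]
    a <- sum(test %in% g)            # test, has term
    c_ <- sum(control %in% g)        # control, has term
    b <- nT - a; d <- nC - c_
    ## one-sided exact tail: P(X >= a), X ~ Hypergeom(a+c, b+d, a+b)
    p <- stats::phyper(a - 1, a + c_, b + d, nT, lower.tail = FALSE)
    or <- if (a == 0 || b == 0 || c_ == 0 || d == 0)
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    else (a * d) / (b * c_)
    data.frame(termId = tt, termName = tt, countTest = a, countControl = c_,
               testSize = nT, controlSize = nC, oddsRatio = or, p = p)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$controlLabel <- controlLabel
  res <- res[order(res$q, res$p, res$termId), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write an enrichment report
#'
#' @param res data.frame from [enrichTerms()].
#' @param path output TSV path.
#' @export
writeEnrichmentTsv <- function(res, path) {
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
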