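#' Doubled center-to-center spacing between two motif hits
#'
#' Returns `|center2(A) - center2(B)|`, i.e. twice the bp distance between
#' the motif centers. Working on the doubled scale keeps the spacing exact
#' (integral) when motif lengths have different parities. Symmetric and
#' translation-invariant.
#'
#' @param hitA,hitB single motif hits (GRanges of length 1 with a `center2`
#'   metadata column, as produced by [scanMotif()]).
#' @return Integer `spacing2`; divide by 2 for bp.
#' @examples
#' ## a 7-mer at [10,17) and a 5-mer at [20,25): centers 13 and 22, 9 bp
#' @export
centerSpacing <- function(hitA, hitB) {
  if (as.character(GenomicRanges::seqnames(hitA)) !=
      as.character(GenomicRanges::seqnames(hitB)))
    ncceUsageError("center spacing is undefined across chromosomes")
  abs(S4Vectors::mcols(hitA)$center2 - S4Vectors::mcols(hitB)$center2)
}

## deterministic composite-element id from coordinates, strands and class
makeCeId <- function(classLabel, chrom, nkxS, nkxE, nkxStrand,
                     pS, pE, pStrand) {
  sprintf("%s|%s:%d-%d(%s)+%d-%d(%s)",
          classLabel, chrom, nkxS, nkxE, nkxStrand, pS, pE, pStrand)
}

#' Pair NKX-anchor hits with partner hits inside shared conserved elements
#'
#' Emits every (NKX, partner) pair that shares a container element id, has
#' non-overlapping hit intervals, and whose center-to-center spacing lies
#' inside the window (bounds inclusive). Orientation-agnostic: the NKX hit
#' may be upstream or downstream of its partner. Pairs that differ only in
#' the strand of one hit over the same two intervals (palindromic double
#' matches) are collapsed to one element whose recorded strand for each hit
#' prefers the `+` representative. Output is sorted and carries
#' deterministic ce-ids.
#'
#' @param nkxHits,partnerHits GRanges from [assignContainers()] (every hit
#'   must carry an `elementId`).
#' @param window a [SpacingWindow-class].
#' @param classLabel the composite class to emit; must be compatible with
#'   the window's label (`NCCE` window for NCCE and the scrambled classes,
#'   `WIDE-CONTROL` window for the wide-spacing control).
#' @return A [CompositeElements-class] object with `syntenyStatus`
#'   `"untested"` and `nearestGene` NA.
#' @export
pairHits <- function(nkxHits, partnerHits, window, classLabel) {
  stopifnot(is(window, "SpacingWindow"))
  if (!classLabel %in% NCCE_CLASSES)
    ncceUsageError("unknown class label '%s'", classLabel)
  wantLabel <- if (classLabel == "WIDE-CONTROL") "WIDE-CONTROL" else "NCCE"
  if (window@label != wantLabel)
    ncceUsageError("class '%s' requires the %s spacing window, got %s",
                   classLabel, wantLabel, window@label)
  emptyOk <- function(h) length(h) == 0L
  if (!emptyOk(nkxHits) && anyNA(S4Vectors::mcols(nkxHits)$elementId) ||
      !emptyOk(partnerHits) && anyNA(S4Vectors::mcols(partnerHits)$elementId))
    ncceUsageError("all hits must carry a container element id; run assignContainers first")
  if (emptyOk(nkxHits) || emptyOk(partnerHits))
    return(newCompositeElements(NULL))

  nk <- data.frame(chrom = as.character(GenomicRanges::seqnames(nkxHits)),
                   s = start0(nkxHits), e = end0(nkxHits),
                   strand = as.character(GenomicRanges::strand(nkxHits)),
                   c2 = S4Vectors::mcols(nkxHits)$center2,
                   motif = S4Vectors::mcols(nkxHits)$motifId,
                   el = S4Vectors::mcols(nkxHits)$elementId)
  pt <- data.frame(chrom = as.character(GenomicRanges::seqnames(partnerHits)),
                   s = start0(partnerHits), e = end0(partnerHits),
                   strand = as.character(GenomicRanges::strand(partnerHits)),
                   c2 = S4Vectors::mcols(partnerHits)$center2,
                   motif = S4Vectors::mcols(partnerHits)$motifId,
                   el = S4Vectors::mcols(partnerHits)$elementId)
  pairs <- merge(nk, pt, by = "el", suffixes = c(".n", ".p"))
  if (!nrow(pairs)) return(newCompositeElements(NULL))
  pairs <- pairs[pairs$chrom.n == pairs$chrom.p, , drop = FALSE]
  sp2 <- abs(pairs$c2.n - pairs$c2.p)
  disjoint <- pairs$e.n <= pairs$s.p | pairs$e.p <= pairs$s.n
  inWin <- sp2 >= 2 * window@minBp & sp2 <= 2 * window@maxBp
  pairs <- pairs[disjoint & inWin, , drop = FALSE]
  if (!nrow(pairs)) return(newCompositeElements(NULL))
  sp2 <- abs(pairs$c2.n - pairs$c2.p)

  ## collapse strand-only duplicates over identical interval pairs:
  ## group by (element, both intervals); prefer '+' strand representatives
  key <- with(pairs, paste(el, chrom.n, s.n, e.n, s.p, e.p, sep = "|"))
  o <- order(key, pairs$strand.n != "+", pairs$strand.p != "+")
  pairs <- pairs[o, , drop = FALSE]; key <- key[o]; sp2 <- sp2[o]
  first <- !duplicated(key)
  pairs <- pairs[first, , drop = FALSE]; sp2 <- sp2[first]

  df <- data.frame(
    chrom = pairs$chrom.n,
    ceId = makeCeId(classLabel, pairs$chrom.n, pairs$s.n, pairs$e.n,
                    pairs$strand.n, pairs$s.p, pairs$e.p, pairs$strand.p),
    classLabel = classLabel, spacing2 = as.integer(sp2),
    elementId = pairs$el,
    nkxStart = pairs$s.n, nkxEnd = pairs$e.n,
    nkxStrand = pairs$strand.n, nkxMotifId = pairs$motif.n,
    partnerStart = pairs$s.p, partnerEnd = pairs$e.p,
    partnerStrand = pairs$strand.p, partnerMotifId = pairs$motif.p,
    syntenyStatus = "untested", nearestGene = NA_character_)
  df <- df[order(df$chrom, pmin(df$nkxStart, df$partnerStart), df$ceId), ,
           drop = FALSE]
  df <- df[!duplicated(df$ceId), , drop = FALSE]
  newCompositeElements(df)
}

#' Build every composite-element class from per-role hit sets
#'
#' NCCE = NKX x COUP at the 6-16 bp window; WIDE-CONTROL = NKX x COUP at
#' 30-60 bp; SCRAMBLE-k = NKX x SCRAMBLE-k at 6-16 bp. Classes are built
#' independently, so one locus may appear in several classes.
#'
#' @param hitSets named list of GRanges keyed by role (`NKX`, `COUP`,
#'   `SCRAMBLE-1`, `SCRAMBLE-2`, `SCRAMBLE-3`); every role must be present
#'   (empty GRanges are fine).
#' @param ncceWin,wideWin spacing windows; defaults [ncceWindow()] and
#'   [wideControlWindow()].
#' @return Named list of [CompositeElements-class], one per class.
#' @export
buildAllClasses <- function(hitSets, ncceWin = ncceWindow(),
                            wideWin = wideControlWindow()) {
  missing <- setdiff(MOTIF_ROLES, names(hitSets))
  if (length(missing))
    ncceUsageError("missing hit set for role(s): %s",
                   paste(missing, collapse = ", "))
  out <- list(
    "NCCE" = pairHits(hitSets$NKX, hitSets$COUP, ncceWin, "NCCE"),
    "WIDE-CONTROL" = pairHits(hitSets$NKX, hitSets$COUP, wideWin,
                              "WIDE-CONTROL"),
    "SCRAMBLE-1" = pairHits(hitSets$NKX, hitSets$`SCRAMBLE-1`, ncceWin,
                            "SCRAMBLE-1"),
    "SCRAMBLE-2" = pairHits(hitSets$NKX, hitSets$`SCRAMBLE-2`, ncceWin,
                            "SCRAMBLE-2"),
    "SCRAMBLE-3" = pairHits(hitSets$NKX, hitSets$`SCRAMBLE-3`, ncceWin,
                            "SCRAMBLE-3"))
  out
}
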