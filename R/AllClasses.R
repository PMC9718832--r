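## IUPAC nucleotide classes. N is deliberately expanded to {A,C,G,T} only:
## an N residue in the *genome* never satisfies any consensus position,
## including a consensus N, so assembly gaps can never fake a motif.
IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' MotifDefinition: a named IUPAC consensus with a pairing role
#'
#' The unit of "what to search". The role decides which pairing rules may
#' consume the motif's hits: `NKX` hits anchor every composite class, `COUP`
#' hits partner in the composite and wide-spacing control classes, and the
#' three `SCRAMBLE-*` roles partner in the scrambled-motif control classes.
#'
#' @slot motifId character scalar, unique identifier.
#' @slot consensus IUPAC consensus string (length >= 4) over
#'   `ACGTRYSWKMBDHVN`.
#' @slot role one of `NKX`, `COUP`, `SCRAMBLE-1`, `SCRAMBLE-2`, `SCRAMBLE-3`.
#' @export
setClass("MotifDefinition", representation(
  motifId = "character", consensus = "character", role = "character"
))

setValidity("MotifDefinition", function(object) {
  msgs <- character()
  if (length(object@motifId) != 1L || !nzchar(object@motifId))
    msgs <- c(msgs, "motifId must be a non-empty string")
  if (length(object@consensus) != 1L || nchar(object@consensus) < 4L)
    msgs <- c(msgs, "consensus must be a single string of length >= 4")
  else {
    bad <- setdiff(strsplit(object@consensus, "")[[1]], names(IUPAC_CLASSES))
    if (length(bad))
      msgs <- c(msgs, sprintf("illegal consensus letter(s): %s",
                              paste(unique(bad), collapse = ",")))
  }
  if (length(object@role) != 1L || !object@role %in% MOTIF_ROLES)
    msgs <- c(msgs, sprintf("role must be one of %s",
                            paste(MOTIF_ROLES, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a MotifDefinition
#'
#' @param motifId unique identifier string.
#' @param consensus IUPAC consensus (>= 4 letters).
#' @param role pairing role; see [MotifDefinition-class].
#' @return A [MotifDefinition-class] object.
#' @examples
#' motifDefinition("COUP", "GGTCR", "COUP")
#' @export
motifDefinition <- function(motifId, consensus, role) {
  new("MotifDefinition", motifId = as.character(motifId),
      consensus = toupper(as.character(consensus)), role = as.character(role))
}

setMethod("show", "MotifDefinition", function(object) {
  cat(sprintf("MotifDefinition %s [%s]: %s\n",
              object@motifId, object@role, object@consensus))
})

#' @describeIn motifDefinition accessor for the motif identifier.
#' @param x a `MotifDefinition`.
#' @export
motifId <- function(x) x@motifId
#' @describeIn motifDefinition accessor for the consensus string.
#' @export
consensus <- function(x) x@consensus
#' @describeIn motifDefinition accessor for the pairing role.
#' @export
motifRole <- function(x) x@role

#' Built-in motif definitions
#'
#' The COUP-TFII half-site `GGTC(A/G)` and the three scrambled-control
#' consensi `GTAC(G/C)`, `AGTC(G/C)` and `TGGA(C/T)` are fixed by the screen
#' design. The NKX homeodomain consensus has no single canonical form;
#' `TNAAGTG` is the package default and is meant to be overridden through a
#' motif configuration file (see [readMotifConfig()]) whenever a different
#' homeodomain model is wanted.
#'
#' @return Named list of [MotifDefinition-class] objects keyed by motif id.
#' @examples
#' names(builtinMotifs())
#' @export
builtinMotifs <- function() {
  defs <- list(
    motifDefinition("NKX",        "TNAAGTG", "NKX"),
    motifDefinition("COUP",       "GGTCR",   "COUP"),
    motifDefinition("SCRAMBLE-1", "GTACS",   "SCRAMBLE-1"),
    motifDefinition("SCRAMBLE-2", "AGTCS",   "SCRAMBLE-2"),
    motifDefinition("SCRAMBLE-3", "TGGAY",   "SCRAMBLE-3")
  )
  setNames(defs, vapply(defs, motifId, character(1)))
}

#' SpacingWindow: an inclusive center-to-center spacing range in bp
#'
#' Spacing is measured between motif centers. Both bounds are inclusive,
#' and half-integer spacings (an even-length motif paired with an odd-length
#' one) are inside the window iff `minBp <= spacing <= maxBp` as rationals.
#'
#' @slot minBp,maxBp numeric bounds in bp, `0 < minBp <= maxBp`.
#' @slot label `"NCCE"` or `"WIDE-CONTROL"` (the scrambled classes reuse the
#'   `NCCE` window).
#' @export
setClass("SpacingWindow", representation(
  minBp = "numeric", maxBp = "numeric", label = "character"
))

setValidity("SpacingWindow", function(object) {
  msgs <- character()
  if (!(length(object@minBp) == 1L && length(object@maxBp) == 1L &&
        object@minBp > 0 && object@minBp <= object@maxBp))
    msgs <- c(msgs, "need 0 < minBp <= maxBp")
  if (!object@label %in% c("NCCE", "WIDE-CONTROL"))
    msgs <- c(msgs, "label must be 'NCCE' or 'WIDE-CONTROL'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpacingWindow
#' @param minBp,maxBp inclusive bounds in bp.
#' @param label window label (`"NCCE"` or `"WIDE-CONTROL"`).
#' @return A [SpacingWindow-class] object.
#' @export
spacingWindow <- function(minBp, maxBp, label)
  new("SpacingWindow", minBp = minBp, maxBp = maxBp, label = label)

## The composite-element window and the wide-spacing control window are the
## named constants of the screen: 6-16 bp and 30-60 bp between motif
## centers, bounds inclusive.
#' @rdname spacingWindow
#' @export
ncceWindow <- function() spacingWindow(6, 16, "NCCE")
#' @rdname spacingWindow
#' @export
wideControlWindow <- function() spacingWindow(30, 60, "WIDE-CONTROL")

setMethod("show", "SpacingWindow", function(object) {
  cat(sprintf("SpacingWindow %s: [%g, %g] bp (inclusive)\n",
              object@label, object@minBp, object@maxBp))
})

#' ChainAlignment: one blockwise query-to-target genome alignment
#'
#' Follows the UCSC chain model. The *query* genome is the genome being
#' scanned (the one coordinates are lifted FROM); its strand is always `+`.
#' The target strand may be `-`, in which case target block coordinates live
#' on the reversed target sequence and are flipped to plus-strand
#' coordinates only at mapping time.
#'
#' Blocks are an n x 3 integer matrix with columns `size`, `dq` (gap on the
#' query after the block) and `dt` (gap on the target); the last row has
#' `dq = dt = 0`.
#'
#' @slot chainId integer id (unique within a file).
#' @slot score numeric chain score.
#' @slot qChrom,qSize,qStart,qEnd query chromosome, length and span.
#' @slot tChrom,tSize,tStrand,tStart,tEnd target chromosome, length, strand
#'   and span (in chain coordinate space).
#' @slot blocks integer matrix, columns `size`, `dq`, `dt`.
#' @export
setClass("ChainAlignment", representation(
  chainId = "integer", score = "numeric",
  qChrom = "character", qSize = "integer", qStart = "integer", qEnd = "integer",
  tChrom = "character", tSize = "integer", tStrand = "character",
  tStart = "integer", tEnd = "integer",
  blocks = "matrix"
))

setValidity("ChainAlignment", function(object) {
  b <- object@blocks
  msgs <- character()
  if (!is.numeric(b) || ncol(b) != 3L || nrow(b) < 1L)
    return("blocks must be a numeric matrix with columns size, dq, dt")
  if (any(b[, 1] <= 0)) msgs <- c(msgs, "block sizes must be > 0")
  if (any(b[, 2:3] < 0)) msgs <- c(msgs, "gaps must be >= 0")
  if (b[nrow(b), 2] != 0 || b[nrow(b), 3] != 0)
    msgs <- c(msgs, "final block must have dq = dt = 0")
  if (sum(b[, 1]) + sum(b[, 2]) != object@qEnd - object@qStart)
    msgs <- c(msgs, sprintf("chain %d: blocks + query gaps != query span",
                            object@chainId))
  if (sum(b[, 1]) + sum(b[, 3]) != object@tEnd - object@tStart)
    msgs <- c(msgs, sprintf("chain %d: blocks + target gaps != target span",
                            object@chainId))
  if (!object@tStrand %in% c("+", "-"))
    msgs <- c(msgs, "target strand must be '+' or '-'")
  if (object@qEnd > object@qSize || object@tEnd > object@tSize)
    msgs <- c(msgs, "span exceeds chromosome size")
  if (length(msgs)) msgs else TRUE
})

chainAlignment <- function(chainId, score, qChrom, qSize, qStart, qEnd,
                           tChrom, tSize, tStrand, tStart, tEnd, blocks) {
  blocks <- matrix(as.integer(blocks), ncol = 3L,
                   dimnames = list(NULL, c("size", "dq", "dt")))
  new("ChainAlignment", chainId = as.integer(chainId), score = as.numeric(score),
      qChrom = qChrom, qSize = as.integer(qSize),
      qStart = as.integer(qStart), qEnd = as.integer(qEnd),
      tChrom = tChrom, tSize = as.integer(tSize), tStrand = tStrand,
      tStart = as.integer(tStart), tEnd = as.integer(tEnd), blocks = blocks)
}

setMethod("show", "ChainAlignment", function(object) {
  cat(sprintf("ChainAlignment #%d score=%g  %s:[%d,%d) -> %s(%s):[%d,%d)  %d block(s)\n",
              object@chainId, object@score, object@qChrom, object@qStart,
              object@qEnd, object@tChrom, object@tStrand, object@tStart,
              object@tEnd, nrow(object@blocks)))
})

## mcols every CompositeElements object must carry
CE_MCOLS <- c("ceId", "classLabel", "spacing2", "elementId",
              "nkxStart", "nkxEnd", "nkxStrand", "nkxMotifId",
              "partnerStart", "partnerEnd", "partnerStrand", "partnerMotifId",
              "syntenyStatus", "nearestGene")

#' CompositeElements: paired-motif candidate elements as a GRanges
#'
#' Extends [GenomicRanges::GRanges]. Each range spans from the leftmost to
#' the rightmost base of its two motif hits; metadata columns carry the hit
#' coordinates (0-based half-open, as written to disk), strands, the doubled
#' center spacing `spacing2` (twice the bp distance between motif centers,
#' kept integral so even-length motifs have exact centers), the container
#' conserved-element id, the class label, the synteny status
#' (`untested`/`pass`/`fail`) and the nearest gene id (NA until assigned).
#'
#' @export
setClass("CompositeElements", contains = "GRanges")

setValidity("CompositeElements", function(object) {
  mc <- S4Vectors::mcols(object)
  missing <- setdiff(CE_MCOLS, colnames(mc))
  if (length(missing))
    return(sprintf("missing metadata column(s): %s",
                   paste(missing, collapse = ", ")))
  msgs <- character()
  if (length(object)) {
    if (!all(mc$classLabel %in% NCCE_CLASSES))
      msgs <- c(msgs, "unknown class label")
    if (!all(mc$syntenyStatus %in% c("untested", "pass", "fail")))
      msgs <- c(msgs, "syntenyStatus must be untested/pass/fail")
    ovl <- !(mc$nkxEnd <= mc$partnerStart | mc$partnerEnd <= mc$nkxStart)
    if (any(ovl))
      msgs <- c(msgs, "motif hit intervals must not overlap")
    sp <- abs((mc$nkxStart + mc$nkxEnd - 1) -
              (mc$partnerStart + mc$partnerEnd - 1))
    if (!all(sp == mc$spacing2))
      msgs <- c(msgs, "spacing2 inconsistent with hit coordinates")
  }
  if (length(msgs)) msgs else TRUE
})

## internal constructor from a data.frame of 0-based hit coordinates
newCompositeElements <- function(df) {
  if (is.null(df) || nrow(df) == 0L) {
    gr <- GenomicRanges::GRanges()
    mc <- S4Vectors::DataFrame(
      ceId = character(), classLabel = character(), spacing2 = integer(),
      elementId = character(), nkxStart = integer(), nkxEnd = integer(),
      nkxStrand = character(), nkxMotifId = character(),
      partnerStart = integer(), partnerEnd = integer(),
      partnerStrand = character(), partnerMotifId = character(),
      syntenyStatus = character(), nearestGene = character())
    S4Vectors::mcols(gr) <- mc
    return(new("CompositeElements", gr))
  }
  start0 <- pmin(df$nkxStart, df$partnerStart)
  end0 <- pmax(df$nkxEnd, df$partnerEnd)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(start0 + 1L, end0))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[, CE_MCOLS, drop = FALSE])
  new("CompositeElements", gr)
}

setMethod("show", "CompositeElements", function(object) {
  cat(sprintf("CompositeElements with %d element(s)\n", length(object)))
  if (length(object)) {
    cl <- table(S4Vectors::mcols(object)$classLabel)
    st <- table(S4Vectors::mcols(object)$syntenyStatus)
    cat("  classes:", paste(sprintf("%s=%d", names(cl), cl), collapse = " "), "\n")
    cat("  synteny:", paste(sprintf("%s=%d", names(st), st), collapse = " "), "\n")
  }
  invisible(callNextMethod())
})

#' @describeIn CompositeElements-class class labels of the elements.
#' @param x a `CompositeElements` object.
#' @export
ceClass <- function(x) S4Vectors::mcols(x)$classLabel
#' @describeIn CompositeElements-class center-to-center spacing in bp
#'   (possibly half-integral).
#' @export
ceSpacingBp <- function(x) S4Vectors::mcols(x)$spacing2 / 2
#' @describeIn CompositeElements-class synteny status vector.
#' @export
syntenyStatus <- function(x) S4Vectors::mcols(x)$syntenyStatus
#' @describeIn CompositeElements-class nearest gene ids (NA when unassigned).
#' @export
nearestGeneId <- function(x) S4Vectors::mcols(x)$nearestGene
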