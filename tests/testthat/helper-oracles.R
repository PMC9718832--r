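## Independent brute-force oracles. These deliberately share no code with
## the package: plain character vectors, window loops and enumeration.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracleRevcomp <- function(s)
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))

## every window of seq matching cons on either strand; N never matches
oracleScan <- function(seqStr, cons) {
  ch <- strsplit(seqStr, "")[[1]]
  L <- nchar(cons)
  n <- length(ch)
  out <- NULL
  for (strand in c("+", "-")) {
    pat <- strsplit(if (strand == "+") cons else oracleRevcomp(cons), "")[[1]]
    if (n >= L) for (i in seq_len(n - L + 1L)) {
      w <- ch[i:(i + L - 1L)]
      ok <- TRUE
      for (j in seq_len(L)) {
        if (w[j] == "N" || !w[j] %in% ORACLE_IUPAC[[pat[j]]]) { ok <- FALSE; break }
      }
      if (ok) out <- rbind(out, data.frame(start0 = i - 1L, end0 = i - 1L + L,
                                           strand = strand))
    }
  }
  if (is.null(out)) data.frame(start0 = integer(), end0 = integer(),
                               strand = character())
  else out[order(out$start0, out$strand), , drop = FALSE]
}

## brute-force pairing over the full cross product, deduplicated by the
## unordered interval pair, spacing window inclusive, overlap excluded
oraclePairs <- function(nkx, partner, minBp, maxBp) {
  keys <- character()
  if (nrow(nkx)) for (i in seq_len(nrow(nkx))) {
    if (nrow(partner)) for (j in seq_len(nrow(partner))) {
      if (nkx$el[i] != partner$el[j]) next
      if (nkx$chrom[i] != partner$chrom[j]) next
      c2n <- nkx$s[i] + nkx$e[i] - 1L
      c2p <- partner$s[j] + partner$e[j] - 1L
      sp2 <- abs(c2n - c2p)
      if (sp2 < 2 * minBp || sp2 > 2 * maxBp) next
      if (!(nkx$e[i] <= partner$s[j] || partner$e[j] <= nkx$s[i])) next
      keys <- c(keys, paste(nkx$el[i], nkx$s[i], nkx$e[i],
                            partner$s[j], partner$e[j], sep = "|"))
    }
  }
  sort(unique(keys))
}

## expand a chain into a per-base query -> target(plus) lookup
oracleBaseMap <- function(chain) {
  b <- chain@blocks
  qpos <- chain@qStart; tpos <- chain@tStart
  map <- rep(NA_integer_, chain@qSize)
  for (i in seq_len(nrow(b))) {
    for (k in seq_len(b[i, 1])) {
      tc <- tpos + k - 1L
      map[qpos + k] <- if (chain@tStrand == "-") chain@tSize - tc - 1L else tc
    }
    qpos <- qpos + b[i, 1] + b[i, 2]
    tpos <- tpos + b[i, 1] + b[i, 3]
  }
  map  # map[x + 1] = target plus-strand base of query base x (0-based)
}

## map an interval through the per-base table: defined only when every base
## maps and the images are consecutive (either direction)
oracleMapInterval <- function(chain, s0, e0) {
  map <- oracleBaseMap(chain)
  vals <- map[(s0 + 1L):e0]
  if (anyNA(vals)) return(NULL)
  d <- diff(vals)
  if (length(d) && !(all(d == 1L) || all(d == -1L))) return(NULL)
  if (length(vals) > 1L && length(unique(abs(d))) > 1L) return(NULL)
  list(start0 = min(vals), end0 = max(vals) + 1L)
}

## exact one-sided p by enumeration of all 2x2 tables with fixed margins
oracleExactP <- function(a, b, c_, d) {
  rowT <- a + b; colT <- a + c_; n <- a + b + c_ + d
  xs <- max(0L, colT - (n - rowT)):min(rowT, colT)
  probs <- vapply(xs, function(x)
    choose(colT, x) * choose(n - colT, rowT - x) / choose(n, rowT), numeric(1))
  sum(probs[xs >= a])
}

## random valid chain over a query chromosome
randomChain <- function(qlen, nBlocks = 3L, minus = FALSE, chainId = 1L,
                        score = 1000) {
  sizes <- sample(5:40, nBlocks, replace = TRUE)
  dq <- c(sample(0:10, nBlocks - 1L, replace = TRUE), 0L)
  dt <- c(sample(0:10, nBlocks - 1L, replace = TRUE), 0L)
  qStart <- sample(0:5, 1L)
  qEnd <- qStart + sum(sizes) + sum(dq)
  stopifnot(qEnd <= qlen)
  tStart <- sample(0:5, 1L)
  tEnd <- tStart + sum(sizes) + sum(dt)
  tSize <- tEnd + sample(0:5, 1L)
  new("ChainAlignment", chainId = as.integer(chainId), score = score,
      qChrom = "chrQ", qSize = as.integer(qlen),
      qStart = as.integer(qStart), qEnd = as.integer(qEnd),
      tChrom = "chrT", tSize = as.integer(tSize),
      tStrand = if (minus) "-" else "+",
      tStart = as.integer(tStart), tEnd = as.integer(tEnd),
      blocks = matrix(as.integer(c(sizes, dq, dt)), ncol = 3,
                      dimnames = list(NULL, c("size", "dq", "dt"))))
}

randSeq <- function(n, letters = c("A", "C", "G", "T"))
  paste(sample(letters, n, replace = TRUE), collapse = "")

## build a motif-hit GRanges from 0-based coordinates
makeHits <- function(chrom, s0, e0, strand, motif = "M", el = NA_character_) {
  gr <- GenomicRanges::GRanges(rep_len(chrom, length(s0)),
                               IRanges::IRanges(s0 + 1L, e0),
                               strand = rep_len(strand, length(s0)))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    motifId = rep_len(motif, length(gr)),
    matchedSeq = rep_len(NA_character_, length(gr)),
    center2 = s0 + e0 - 1L,
    elementId = rep_len(el, length(gr)))
  gr
}

## one-block identity chain over [0, len) on both genomes
identityChain <- function(len, chrom = "chr1", chainId = 1L, score = 1000) {
  new("ChainAlignment", chainId = as.integer(chainId), score = score,
      qChrom = chrom, qSize = as.integer(len), qStart = 0L,
      qEnd = as.integer(len),
      tChrom = chrom, tSize = as.integer(len), tStrand = "+",
      tStart = 0L, tEnd = as.integer(len),
      blocks = matrix(c(as.integer(len), 0L, 0L), ncol = 3,
                      dimnames = list(NULL, c("size", "dq", "dt"))))
}
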