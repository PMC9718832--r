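test_that("center spacing is exact doubled-coordinate arithmetic", {
  a <- makeHits("chr1", 10L, 17L, "+")   # 7-mer, center 13, center2 = 26
  b <- makeHits("chr1", 20L, 25L, "+")   # 5-mer, center 22, center2 = 44
  expect_equal(centerSpacing(a, b), 18L) # 9 bp
  expect_equal(centerSpacing(b, a), 18L) # symmetric
  expect_equal(centerSpacing(a, a), 0L)
  other <- makeHits("chr2", 10L, 17L, "+")
  expect_error(centerSpacing(a, other), class = "ncceUsageError")

  ## brute-force midpoint computation in floating point, 200 random pairs
  set.seed(11)
  for (i in 1:200) {
    s1 <- sample(0:500, 1); l1 <- sample(4:9, 1)
    s2 <- sample(0:500, 1); l2 <- sample(4:9, 1)
    h1 <- makeHits("chr1", s1, s1 + l1, "+")
    h2 <- makeHits("chr1", s2, s2 + l2, "+")
    midA <- s1 + (l1 - 1) / 2
    midB <- s2 + (l2 - 1) / 2
    expect_identical(as.numeric(centerSpacing(h1, h2)), 2 * abs(midA - midB))
  }
})

test_that("pairing respects the inclusive spacing window and overlap exclusion", {
  mkPair <- function(spacingBp) {
    ## NKX 7-mer at fixed position; 5-mer partner downstream at the spacing
    nkx <- makeHits("chr1", 100L, 107L, "+", motif = "NKX", el = "e1")
    pS <- 100L + 1L + spacingBp
    coup <- makeHits("chr1", pS, pS + 5L, "+", motif = "COUP", el = "e1")
    pairHits(nkx, coup, ncceWindow(), "NCCE")
  }
  expect_length(mkPair(6L), 1L)    # lower bound inclusive
  expect_length(mkPair(16L), 1L)   # upper bound inclusive
  expect_length(mkPair(5L), 0L)    # below window (also overlapping)
  expect_length(mkPair(17L), 0L)   # above window
  ## 17 bp is outside the wide-control window too
  nkx <- makeHits("chr1", 100L, 107L, "+", motif = "NKX", el = "e1")
  coup <- makeHits("chr1", 118L, 123L, "+", motif = "COUP", el = "e1")
  expect_length(pairHits(nkx, coup, wideControlWindow(), "WIDE-CONTROL"), 0L)

  ## spacing recorded on the doubled scale
  ce <- mkPair(10L)
  expect_equal(S4Vectors::mcols(ce)$spacing2, 20L)
  expect_equal(ceSpacingBp(ce), 10)
})

test_that("pairing is orientation-agnostic and restricted to shared elements", {
  ## partner upstream of the anchor
  coup <- makeHits("chr1", 100L, 105L, "+", motif = "COUP", el = "e1")
  nkx <- makeHits("chr1", 113L, 120L, "-", motif = "NKX", el = "e1")
  ce <- pairHits(nkx, coup, ncceWindow(), "NCCE")
  expect_length(ce, 1L)
  ## different elements never pair, even when adjacent in coordinates
  coup2 <- makeHits("chr1", 100L, 105L, "+", motif = "COUP", el = "e2")
  expect_length(pairHits(nkx, coup2, ncceWindow(), "NCCE"), 0L)
  ## window label must match the class
  expect_error(pairHits(nkx, coup, wideControlWindow(), "NCCE"),
               class = "ncceUsageError")
  ## hits without containers are a usage error
  loose <- makeHits("chr1", 100L, 105L, "+", motif = "COUP")
  expect_error(pairHits(nkx, loose, ncceWindow(), "NCCE"),
               class = "ncceUsageError")
})

test_that("strand-only duplicates collapse to one element with a + representative", {
  nkx <- makeHits("chr1", c(100L, 100L), c(107L, 107L), c("-", "+"),
                  motif = "NKX", el = "e1")
  coup <- makeHits("chr1", 110L, 115L, "+", motif = "COUP", el = "e1")
  ce <- pairHits(nkx, coup, ncceWindow(), "NCCE")
  expect_length(ce, 1L)
  expect_equal(S4Vectors::mcols(ce)$nkxStrand, "+")
})

test_that("pairing equals brute-force enumeration over the cross product", {
  ## the 2 x 3 compatible case enumerates to 6
  nkx <- makeHits("chr1", c(100L, 130L), c(107L, 137L), "+",
                  motif = "NKX", el = "e1")
  coup <- makeHits("chr1", c(112L, 118L, 145L), c(117L, 123L, 150L), "+",
                   motif = "COUP", el = "e1")
  win <- spacingWindow(1, 60, "NCCE")
  ce <- pairHits(nkx, coup, win, "NCCE")
  expect_length(ce, 6L)

  ## randomized instances up to 50 hits vs the oracle
  set.seed(13)
  for (rep in 1:60) {
    nN <- sample(1:6, 1); nP <- sample(1:8, 1)
    mkDf <- function(k, len) {
      s <- sample(0:300, k)
      data.frame(chrom = "chr1", s = s, e = s + len,
                 el = sample(c("e1", "e2"), k, replace = TRUE))
    }
    ndf <- mkDf(nN, 7L); pdf <- mkDf(nP, 5L)
    lo <- sample(1:10, 1); hi <- lo + sample(0:30, 1)
    nkxH <- makeHits("chr1", ndf$s, ndf$e,
                     sample(c("+", "-"), nN, replace = TRUE),
                     motif = "NKX", el = ndf$el)
    coupH <- makeHits("chr1", pdf$s, pdf$e,
                      sample(c("+", "-"), nP, replace = TRUE),
                      motif = "COUP", el = pdf$el)
    got <- pairHits(nkxH, coupH, spacingWindow(lo, hi, "NCCE"), "NCCE")
    mc <- S4Vectors::mcols(got)
    gotKeys <- sort(paste(mc$elementId, mc$nkxStart, mc$nkxEnd,
                          mc$partnerStart, mc$partnerEnd, sep = "|"))
    wantKeys <- oraclePairs(ndf, pdf, lo, hi)
    expect_equal(gotKeys, wantKeys)
  }
})

test_that("class builder wires roles to windows and reports missing roles", {
  nkx <- makeHits("chr1", 100L, 107L, "+", motif = "NKX", el = "e1")
  coup <- makeHits("chr1", 110L, 115L, "+", motif = "COUP", el = "e1")
  scr <- makeHits("chr1", 140L, 145L, "+", motif = "SCRAMBLE-1", el = "e1")
  empty <- makeHits("chr1", integer(0), integer(0), character(0))
  sets <- list(NKX = nkx, COUP = coup, "SCRAMBLE-1" = scr,
               "SCRAMBLE-2" = empty, "SCRAMBLE-3" = empty)
  classes <- buildAllClasses(sets)
  expect_named(classes, c("NCCE", "WIDE-CONTROL", "SCRAMBLE-1",
                          "SCRAMBLE-2", "SCRAMBLE-3"))
  expect_length(classes$NCCE, 1L)
  expect_length(classes$`WIDE-CONTROL`, 0L)
  ## scramble partner at 36 bp: outside the composite window
  expect_length(classes$`SCRAMBLE-1`, 0L)

  ## empty COUP: composite and wide classes empty, scrambles unaffected
  sets$COUP <- empty
  sets$`SCRAMBLE-1` <- makeHits("chr1", 115L, 120L, "+",
                                motif = "SCRAMBLE-1", el = "e1")
  classes <- buildAllClasses(sets)
  expect_length(classes$NCCE, 0L)
  expect_length(classes$`SCRAMBLE-1`, 1L)

  expect_error(buildAllClasses(sets[-1]), "NKX", class = "ncceUsageError")
})

test_that("no emitted pair spans two elements or has intersecting intervals", {
  set.seed(17)
  for (rep in 1:20) {
    k <- sample(5:20, 1)
    s <- sample(0:400, k)
    el <- sample(c("e1", "e2", "e3"), k, replace = TRUE)
    nkxH <- makeHits("chr1", s, s + 7L, "+", motif = "NKX", el = el)
    s2 <- sample(0:400, k)
    coupH <- makeHits("chr1", s2, s2 + 5L, "+", motif = "COUP",
                      el = sample(c("e1", "e2", "e3"), k, replace = TRUE))
    ce <- pairHits(nkxH, coupH, ncceWindow(), "NCCE")
    if (!length(ce)) next
    mc <- S4Vectors::mcols(ce)
    expect_true(all(mc$nkxEnd <= mc$partnerStart |
                      mc$partnerEnd <= mc$nkxStart))
    expect_true(all(mc$spacing2 >= 12 & mc$spacing2 <= 32))
  }
})
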