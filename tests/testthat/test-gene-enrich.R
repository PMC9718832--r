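mkGenes <- function(chrom, tss0, ids, strand = "+") {
  len <- 100L
  strand <- rep_len(strand, length(tss0))
  s0 <- ifelse(strand == "+", tss0, tss0 - len + 1L)
  e0 <- ifelse(strand == "+", tss0 + len, tss0 + 1L)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1L, e0),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    geneId = ids, symbol = toupper(ids), tss0 = as.integer(tss0))
  gr
}

## a single composite whose midpoint sits at `mid` (integer bp)
mkCe <- function(mid, chrom = "chr1") {
  ## hit centers at mid -8 and mid +8: the element midpoint is exactly `mid`
  nkx <- makeHits(chrom, mid - 11L, mid - 4L, "+", motif = "NKX", el = "e1")
  coup <- makeHits(chrom, mid + 6L, mid + 11L, "+", motif = "COUP", el = "e1")
  ce <- pairHits(nkx, coup, ncceWindow(), "NCCE")
  stopifnot(length(ce) == 1L)
  ce
}

test_that("nearest gene is the minimal TSS distance with lexicographic ties", {
  ## midpoint 500: gene at 400 beats gene at 700
  genes <- mkGenes("chr1", c(400L, 700L), c("gB", "gA"))
  expect_equal(nearestGene(mkCe(500L), genes), "gB")
  ## equidistant TSSs at 400 and 600: lexicographically smaller id wins
  genes <- mkGenes("chr1", c(400L, 600L), c("gB", "gA"))
  expect_equal(nearestGene(mkCe(500L), genes), "gA")
  ## genes on other chromosomes are never considered
  genes <- mkGenes(c("chr1", "chr2"), c(9000L, 500L), c("far", "near"))
  expect_equal(nearestGene(mkCe(500L), genes), "far")
  ## no gene on the chromosome: warning, element unassigned
  genes <- mkGenes("chr2", 500L, "g1")
  expect_warning(id <- nearestGene(mkCe(500L), genes), "no gene")
  expect_true(is.na(id))
})

test_that("assignment equals brute-force all-pairs minimization", {
  set.seed(7)
  nGenes <- 50L
  gchrom <- sample(c("chr1", "chr2"), nGenes, replace = TRUE)
  gtss <- sample(0:100000, nGenes)
  ids <- sprintf("g%02d", sample(nGenes))
  genes <- mkGenes(gchrom, gtss, ids)
  for (rep in 1:200) {
    chrom <- sample(c("chr1", "chr2"), 1)
    mid <- sample(100:99000, 1)
    got <- suppressWarnings(nearestGene(mkCe(mid, chrom), genes))
    ## brute force on the quadrupled scale used by the package contract
    on <- which(gchrom == chrom)
    d <- abs(4 * mid - 4 * gtss[on])
    want <- min(ids[on[d == min(d)]])
    expect_equal(got, want)
  }
})

test_that("gene sets deduplicate at the gene level", {
  genes <- mkGenes("chr1", c(500L, 5000L), c("g1", "g2"))
  ces <- suppressWarnings(do.call(c, lapply(c(480L, 520L, 5100L), function(m)
    assignNearestGenes(mkCe(m), genes))))
  sets <- buildGeneSets(list(NCCE = ces))
  expect_equal(sets$NCCE, c("g1", "g2"))
  ## empty class: empty set with a warning, pipeline proceeds
  empty <- pairHits(makeHits("chr1", integer(0), integer(0), character(0)),
                    makeHits("chr1", integer(0), integer(0), character(0)),
                    ncceWindow(), "NCCE")
  expect_warning(sets <- buildGeneSets(list(NCCE = empty)), "empty")
  expect_length(sets$NCCE, 0L)
})

test_that("enrichment p-values equal exact enumeration of 2x2 tables", {
  ## the (8,2,2,8) table against direct enumeration
  test <- sprintf("t%02d", 1:10)
  control <- sprintf("c%02d", 1:10)
  tm <- data.frame(termId = "T1", geneId = c(test[1:8], control[1:2]))
  res <- enrichTerms(test, control, tm)
  expect_equal(res$p, oracleExactP(8, 2, 2, 8))
  expect_equal(res$countTest, 8L)

  ## random universes up to 30 genes, every term checked
  set.seed(37)
  for (rep in 1:60) {
    nT <- sample(2:15, 1); nC <- sample(2:15, 1)
    test <- sprintf("t%02d", seq_len(nT))
    control <- sprintf("c%02d", seq_len(nC))
    univ <- c(test, control)
    nTerm <- sample(1:4, 1)
    tm <- do.call(rbind, lapply(seq_len(nTerm), function(k) {
      members <- univ[runif(length(univ)) < runif(1)]
      if (!length(members)) members <- sample(univ, 1)
      data.frame(termId = sprintf("T%d", k), geneId = members)
    }))
    res <- enrichTerms(test, control, tm)
    for (i in seq_len(nrow(res))) {
      a <- res$countTest[i]; c_ <- res$countControl[i]
      expect_equal(res$p[i], oracleExactP(a, nT - a, c_, nC - c_),
                   tolerance = 1e-12)
    }
  }
})

test_that("degenerate tables take the Haldane branch without dividing by zero", {
  test <- c("a", "b"); control <- c("c", "d")
  tm <- data.frame(termId = "T1", geneId = c("a", "b", "c", "d"))
  res <- enrichTerms(test, control, tm)
  expect_equal(res$p, 1)
  expect_true(is.finite(res$oddsRatio))
  expect_equal(res$oddsRatio, (2.5 * 0.5) / (0.5 * 2.5))
})

test_that("shared genes are dropped from both sets before testing", {
  test <- c("a", "b", "s"); control <- c("c", "d", "s")
  tm <- data.frame(termId = "T1", geneId = c("a", "b", "c"))
  expect_message(res <- enrichTerms(test, control, tm), "dropped")
  expect_equal(res$testSize, 2L)
  expect_equal(res$controlSize, 2L)
  expect_error(suppressMessages(enrichTerms(c("s"), c("s", "x"), tm)),
               class = "ncceUsageError")
})

test_that("swapping test and control reverses the one-sided direction", {
  set.seed(41)
  test <- sprintf("t%02d", 1:12)
  control <- sprintf("c%02d", 1:9)
  tm <- data.frame(termId = "T1",
                   geneId = c(sample(test, 7), sample(control, 2)))
  fwd <- enrichTerms(test, control, tm)
  rev_ <- enrichTerms(control, test, tm)
  ## P(X >= a) + P(X' >= c) = 1 + P(X == a) for the swapped margins
  a <- fwd$countTest; c_ <- fwd$countControl
  pEq <- oracleExactP(a, 12 - a, c_, 9 - c_) -
    oracleExactP(a + 1, 12 - a - 1, c_ - 1, 9 - c_ + 1)
  expect_equal(fwd$p + rev_$p, 1 + pEq, tolerance = 1e-12)
})

test_that("q-values are a monotone BH transform within [0,1]", {
  set.seed(43)
  test <- sprintf("t%02d", 1:15)
  control <- sprintf("c%02d", 1:15)
  univ <- c(test, control)
  tm <- do.call(rbind, lapply(1:12, function(k)
    data.frame(termId = sprintf("T%02d", k),
               geneId = univ[runif(30) < 0.4])))
  res <- enrichTerms(test, control, tm)
  expect_true(all(res$q >= 0 & res$q <= 1))
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  expect_true(all(res$q[o] >= res$p[o] - 1e-12))  # BH never shrinks below p
})

test_that("an engineered enriched term ranks first with q below 0.05", {
  set.seed(47)
  nPer <- 45L
  test <- sprintf("t%02d", seq_len(nPer))
  control <- sprintf("c%02d", seq_len(nPer))
  univ <- c(test, control)
  rows <- list()
  ## planted term: 80% of test genes, 10% of control genes
  rows[[1]] <- data.frame(termId = "PLANTED",
                          geneId = c(test[runif(nPer) < 0.8],
                                     control[runif(nPer) < 0.1]))
  for (k in 1:20)
    rows[[k + 1]] <- data.frame(termId = sprintf("BG%02d", k),
                                geneId = univ[runif(2 * nPer) < 0.15])
  tm <- do.call(rbind, rows)
  res <- enrichTerms(test, control, tm)
  expect_equal(res$termId[1], "PLANTED")
  expect_lt(res$q[1], 0.05)
})
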