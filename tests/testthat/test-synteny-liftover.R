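test_that("identity-chain mapping is the identity", {
  ch <- identityChain(1000L)
  m <- mapInterval(list(ch), "chr1", 10L, 17L)
  expect_equal(m[c("chrom", "start0", "end0")],
               list(chrom = "chr1", start0 = 10L, end0 = 17L))
  expect_false(m$strandFlipped)
  expect_true(m$contiguous)
})

test_that("intervals crossing an alignment gap are unmappable", {
  ## 5-bp target insertion after query base 12 splits [10,17)
  ch <- new("ChainAlignment", chainId = 1L, score = 100,
            qChrom = "chr1", qSize = 100L, qStart = 0L, qEnd = 100L,
            tChrom = "chr1", tSize = 105L, tStrand = "+",
            tStart = 0L, tEnd = 105L,
            blocks = matrix(c(12L, 88L, 0L, 0L, 5L, 0L), ncol = 3,
                            dimnames = list(NULL, c("size", "dq", "dt"))))
  expect_null(mapInterval(list(ch), "chr1", 10L, 17L))
  ## but intervals inside one block map fine
  expect_equal(mapInterval(list(ch), "chr1", 0L, 12L)$end0, 12L)
  expect_equal(mapInterval(list(ch), "chr1", 20L, 30L)$start0, 25L)
  ## uncovered chromosome maps to nothing, not an error
  expect_null(mapInterval(list(ch), "chrX", 10L, 17L))
})

test_that("zero-gap adjacent blocks form one contiguous run", {
  ch <- new("ChainAlignment", chainId = 1L, score = 100,
            qChrom = "chr1", qSize = 50L, qStart = 0L, qEnd = 50L,
            tChrom = "chr1", tSize = 50L, tStrand = "+",
            tStart = 0L, tEnd = 50L,
            blocks = matrix(c(20L, 30L, 0L, 0L, 0L, 0L), ncol = 3,
                            dimnames = list(NULL, c("size", "dq", "dt"))))
  m <- mapInterval(list(ch), "chr1", 15L, 25L)  # straddles the block join
  expect_equal(m$start0, 15L)
})

test_that("minus-strand chains match a per-base expansion oracle", {
  set.seed(19)
  for (rep in 1:120) {
    minus <- rep %% 2 == 0
    ch <- randomChain(qlen = 200L, nBlocks = sample(2:5, 1), minus = minus)
    s0 <- sample(0:190, 1)
    e0 <- s0 + sample(1:10, 1)
    if (e0 > 200) next
    got <- mapInterval(list(ch), "chrQ", s0, e0)
    want <- oracleMapInterval(ch, s0, e0)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(got$start0, want$start0)
      expect_equal(got$end0, want$end0)
      expect_equal(got$end0 - got$start0, e0 - s0)  # length preserved
      expect_equal(got$strandFlipped, minus)
    }
  }
})

test_that("among covering chains the highest score wins, ties to lowest id", {
  mk <- function(id, score, shift) {
    new("ChainAlignment", chainId = as.integer(id), score = score,
        qChrom = "chr1", qSize = 100L, qStart = 0L, qEnd = 100L,
        tChrom = "chr1", tSize = 200L, tStrand = "+",
        tStart = as.integer(shift), tEnd = as.integer(shift + 100L),
        blocks = matrix(c(100L, 0L, 0L), ncol = 3,
                        dimnames = list(NULL, c("size", "dq", "dt"))))
  }
  chains <- list(mk(2, 500, 50), mk(1, 900, 0), mk(3, 900, 10))
  m <- mapInterval(chains, "chr1", 10L, 15L)
  expect_equal(m$chainId, 1L)   # 900 ties broken by lowest id
  expect_equal(m$start0, 10L)
})

test_that("inverse-chain round trips are the identity on mapped intervals", {
  set.seed(23)
  for (rep in 1:60) {
    ch <- randomChain(qlen = 200L, nBlocks = sample(2:5, 1),
                      minus = rep %% 2 == 0)
    inv <- invertChain(ch)
    expect_true(validObject(inv, test = TRUE))
    for (k in 1:5) {
      s0 <- sample(0:195, 1); e0 <- s0 + sample(1:5, 1)
      m <- mapInterval(list(ch), "chrQ", s0, e0)
      if (is.null(m)) next
      back <- mapInterval(list(inv), m$chrom, m$start0, m$end0)
      expect_false(is.null(back))
      expect_equal(back$chrom, "chrQ")
      expect_equal(back$start0, s0)
      expect_equal(back$end0, e0)
    }
  }
})

test_that("chain mapping agrees with rtracklayer liftOver on a shared file", {
  skip_if_not_installed("rtracklayer")
  set.seed(29)
  f <- withr::local_tempfile(fileext = ".chain")
  chains <- lapply(1:3, function(i)
    randomChain(qlen = 200L, nBlocks = 3L, minus = i == 2, chainId = i,
                score = 1000 - i))
  ## rtracklayer requires distinct query chromosomes per chain file entry
  chains <- lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]
    initialize(ch, qChrom = paste0("chrQ", i))
  })
  writeChainFile(chains, f, comment = FALSE)
  lo <- rtracklayer::import.chain(f)
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    for (k in 1:40) {
      s0 <- sample(0:195, 1); e0 <- s0 + sample(1:6, 1)
      mine <- mapInterval(list(ch), ch@qChrom, s0, e0)
      gr <- GenomicRanges::GRanges(ch@qChrom,
                                   IRanges::IRanges(s0 + 1L, e0))
      theirs <- unlist(rtracklayer::liftOver(gr, lo))
      if (is.null(mine)) {
        ## liftOver reports split (gap-crossing) maps; we require contiguity,
        ## so agreement means: no single full-length mapped interval
        expect_true(length(theirs) != 1L ||
                      sum(GenomicRanges::width(theirs)) < e0 - s0)
      } else {
        expect_equal(length(theirs), 1L)
        expect_equal(GenomicRanges::start(theirs) - 1L, mine$start0)
        expect_equal(GenomicRanges::end(theirs), mine$end0)
      }
    }
  }
})

test_that("synteny verification demands contiguous mapping and motif survival", {
  motifs <- builtinMotifs()
  ## query: NKX at [10,17), COUP at [23,28) (12 bp center spacing), in e1
  set.seed(31)
  qseq <- paste0(randSeq(10), "TTAAGTG", randSeq(6), "GGTCA", randSeq(22))
  query <- Biostrings::DNAStringSet(c(chr1 = qseq))
  nkx <- makeHits("chr1", 10L, 17L, "+", motif = "NKX", el = "e1")
  coup <- makeHits("chr1", 23L, 28L, "+", motif = "COUP", el = "e1")
  ce <- pairHits(nkx, coup, ncceWindow(), "NCCE")
  expect_length(ce, 1L)

  ## identical target under an identity chain: pass
  idc <- list(identityChain(50L))
  v <- verifySynteny(ce, idc, query, motifs)
  expect_equal(syntenyStatus(v), "pass")
  expect_length(filterConserved(v), 1L)

  ## point mutation destroying the target COUP site: fail
  mut <- sub("GGTCA", "GGTTA", qseq)
  v <- verifySynteny(ce, idc, Biostrings::DNAStringSet(c(chr1 = mut)), motifs)
  expect_equal(syntenyStatus(v), "fail")
  expect_match(S4Vectors::mcols(v)$failReason, "partner_motif_lost")

  ## NKX interval falling in a chain gap: unmappable, hence fail
  gapped <- new("ChainAlignment", chainId = 1L, score = 10,
                qChrom = "chr1", qSize = 50L, qStart = 0L, qEnd = 50L,
                tChrom = "chr1", tSize = 15L, tStrand = "+",
                tStart = 0L, tEnd = 15L,
                blocks = matrix(c(12L, 3L, 35L, 0L, 0L, 0L), ncol = 3,
                                dimnames = list(NULL, c("size", "dq", "dt"))))
  v <- verifySynteny(ce, list(gapped), query, motifs)
  expect_equal(syntenyStatus(v), "fail")
  expect_match(S4Vectors::mcols(v)$failReason, "nkx_unmapped")

  ## a strand-flipped target still passes (motif matches on either strand)
  flipSeq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(qseq)))
  flipped <- new("ChainAlignment", chainId = 1L, score = 10,
                 qChrom = "chr1", qSize = 50L, qStart = 0L, qEnd = 50L,
                 tChrom = "chr1", tSize = 50L, tStrand = "-",
                 tStart = 0L, tEnd = 50L,
                 blocks = matrix(c(50L, 0L, 0L), ncol = 3,
                                 dimnames = list(NULL, c("size", "dq", "dt"))))
  v <- verifySynteny(ce, list(flipped),
                     Biostrings::DNAStringSet(c(chr1 = flipSeq)), motifs)
  expect_equal(syntenyStatus(v), "pass")

  ## pipeline-order contract
  expect_error(filterConserved(ce), class = "ncceUsageError")
  expect_error(verifySynteny(v, idc, query, motifs), class = "ncceUsageError")
  ## chain pointing at an unknown chromosome is a data error
  badChain <- initialize(identityChain(50L), tChrom = "chrZ")
  expect_error(verifySynteny(ce, list(badChain), query, motifs),
               class = "ncceDataError")
})

test_that("conserved filtering keeps the pass subset in order", {
  nkx <- makeHits("chr1", c(10L, 60L, 110L, 160L, 210L) ,
                  c(17L, 67L, 117L, 167L, 217L), "+", motif = "NKX", el = "e1")
  coup <- makeHits("chr1", c(23L, 73L, 123L, 173L, 223L),
                   c(28L, 78L, 128L, 178L, 228L), "+", motif = "COUP", el = "e1")
  ces <- pairHits(nkx, coup, ncceWindow(), "NCCE")
  expect_length(ces, 5L)
  mc <- S4Vectors::mcols(ces)
  mc$syntenyStatus <- c("pass", "fail", "pass", "fail", "pass")
  S4Vectors::mcols(ces) <- mc
  kept <- filterConserved(ces)
  expect_length(kept, 3L)
  expect_equal(S4Vectors::mcols(kept)$ceId,
               S4Vectors::mcols(ces)$ceId[c(1, 3, 5)])
  mc$syntenyStatus <- "fail"
  S4Vectors::mcols(ces) <- mc
  expect_length(filterConserved(ces), 0L)
})
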