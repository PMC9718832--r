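#' Configuration for the synthetic two-genome generator
#'
#' The generator emulates the inputs of the genome-wide screen at desk
#' scale: conserved islands embedded in background sequence, planted
#' NKX/partner motif pairs at controlled center-to-center spacings, a
#' blockwise chain relating the query genome to a target genome derived
#' from it, gene models with defined TSS, and a term map with engineered
#' enrichment in genes near the planted composite elements.
#'
#' @param seed integer root seed; every randomised component derives its
#'   own stream from it via [childSeed()].
#' @param genomeLength total query genome length in bp.
#' @param chromCount number of chromosomes (length split evenly).
#' @param elementCount number of conserved elements.
#' @param elementLengthRange integer range of element lengths in bp.
#' @param scoreRange integer range of conservation scores; spans the
#'   screen's threshold of 300 so sub-threshold elements exist.
#' @param plantedCounts named integer vector of planted composites per
#'   class (`NCCE`, `WIDE-CONTROL`, `SCRAMBLE-1..3`).
#' @param plantSpacings optional named list (class -> integer bp spacings,
#'   recycled over that class's plants); default samples uniformly over the
#'   class window.
#' @param syntenyBreakRate probability in `[0,1]` that a planted composite
#'   receives a targeted point mutation in the target genome destroying one
#'   of its motifs.
#' @param subthresholdDecoys number of NKX-COUP pairs planted in elements
#'   whose score is *exactly* 300 (must never be recovered under the strict
#'   threshold).
#' @param decoySpacings integer bp spacings (outside both windows, >= 7)
#'   for additional NKX-COUP decoy plants that no class may recover.
#' @param chainIndelsPerChrom indels per chromosome in the chain, placed
#'   strictly between conserved elements.
#' @param indelSizeRange indel size range in bp.
#' @param invertChroms chromosome names whose chain (and target sequence)
#'   is inverted, exercising the minus-strand mapping path.
#' @param geneCount total genes; must exceed the number of planted
#'   composites (each planted composite gets a dedicated nearest gene).
#' @param geneTssJitter max initial |TSS - composite midpoint| in bp for
#'   planted genes.
#' @param termCount number of terms; the first is the engineered enriched
#'   term.
#' @param enrichedTermProb named probabilities `c(ncce = , other = )` of
#'   enriched-term membership for genes nearest planted composites vs all
#'   other genes.
#' @param backgroundTermProb membership probability for non-enriched terms.
#' @param backgroundGC background GC fraction of the query genome.
#' @param minScore conservation threshold used by the self-scan.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 42L,
                             genomeLength = 1e6,
                             chromCount = 2L,
                             elementCount = 200L,
                             elementLengthRange = c(150L, 400L),
                             scoreRange = c(150L, 500L),
                             plantedCounts = c("NCCE" = 10L, "WIDE-CONTROL" = 10L,
                                               "SCRAMBLE-1" = 10L, "SCRAMBLE-2" = 10L,
                                               "SCRAMBLE-3" = 10L),
                             plantSpacings = NULL,
                             syntenyBreakRate = 0,
                             subthresholdDecoys = 0L,
                             decoySpacings = integer(0),
                             chainIndelsPerChrom = 3L,
                             indelSizeRange = c(1L, 20L),
                             invertChroms = character(0),
                             geneCount = 80L,
                             geneTssJitter = 300L,
                             termCount = 30L,
                             enrichedTermProb = c(ncce = 0.8, other = 0.1),
                             backgroundTermProb = 0.15,
                             backgroundGC = 0.41,
                             minScore = 300) {
  cfg <- list(seed = as.integer(seed), genomeLength = as.integer(genomeLength),
              chromCount = as.integer(chromCount),
              elementCount = as.integer(elementCount),
              elementLengthRange = as.integer(elementLengthRange),
              scoreRange = as.integer(scoreRange),
              plantedCounts = plantedCounts,
              plantSpacings = plantSpacings,
              syntenyBreakRate = syntenyBreakRate,
              subthresholdDecoys = as.integer(subthresholdDecoys),
              decoySpacings = as.integer(decoySpacings),
              chainIndelsPerChrom = as.integer(chainIndelsPerChrom),
              indelSizeRange = as.integer(indelSizeRange),
              invertChroms = invertChroms,
              geneCount = as.integer(geneCount),
              geneTssJitter = as.integer(geneTssJitter),
              termCount = as.integer(termCount),
              enrichedTermProb = enrichedTermProb,
              backgroundTermProb = backgroundTermProb,
              backgroundGC = backgroundGC,
              minScore = minScore)
  class(cfg) <- "SimulationConfig"
  missing <- setdiff(NCCE_CLASSES, names(cfg$plantedCounts))
  if (length(missing))
    ncceConfigError("plantedCounts missing class(es): %s",
                    paste(missing, collapse = ", "))
  if (any(cfg$plantedCounts < 0) || cfg$subthresholdDecoys < 0)
    ncceConfigError("planted counts must be >= 0")
  if (cfg$syntenyBreakRate < 0 || cfg$syntenyBreakRate > 1)
    ncceConfigError("syntenyBreakRate must be in [0,1]")
  probs <- c(cfg$enrichedTermProb, cfg$backgroundTermProb, cfg$backgroundGC)
  if (any(probs < 0 | probs > 1))
    ncceConfigError("probabilities must be in [0,1]")
  if (any(cfg$decoySpacings >= 6 & cfg$decoySpacings <= 16) ||
      any(cfg$decoySpacings >= 30 & cfg$decoySpacings <= 60))
    ncceConfigError("decoy spacings must lie outside both class windows")
  nPlants <- sum(cfg$plantedCounts) + cfg$subthresholdDecoys +
    length(cfg$decoySpacings)
  if (cfg$geneCount <= sum(cfg$plantedCounts))
    ncceConfigError("geneCount must exceed the number of planted composites")
  if (nPlants > cfg$elementCount)
    ncceConfigError("more plants (%d) than conserved elements (%d)",
                    nPlants, cfg$elementCount)
  cfg
}

## sample a concrete realization of an IUPAC consensus
sampleInstance <- function(cons) {
  paste(vapply(strsplit(cons, "")[[1]],
               function(ch) {
                 cls <- IUPAC_CLASSES[[ch]]
                 cls[sample.int(length(cls), 1L)]
               }, character(1)), collapse = "")
}

randomSeq <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

## replace seq[s0, s0+nchar(piece)) (0-based) with piece
spliceIn <- function(seqStr, s0, piece) {
  paste0(substr(seqStr, 1, s0), piece,
         substr(seqStr, s0 + nchar(piece) + 1, nchar(seqStr)))
}

#' Generate a complete synthetic screen bundle
#'
#' Deterministic given the config seed: repeated calls produce
#' byte-identical files. Plants every configured composite wholly inside a
#' conserved element scoring above the threshold (decoys excepted), derives
#' the target genome from the query through the generated chain with
#' per-composite synteny-breaking mutations at the configured rate,
#' self-scans its own output so chance motif pairs enter the truth manifest
#' (keeping recovery metrics exact without distorting the background),
#' places a dedicated nearest gene at every planted composite, and writes
#' the term map with the engineered enrichment. Infeasible packings fail
#' with a config error before any file is written.
#'
#' @param config a [simulationConfig()].
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and the
#'   `manifest` (also written as JSON).
#' @export
generateBundle <- function(config, outDir) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  motifs <- builtinMotifs()

  ## --- query genome -------------------------------------------------
  set.seed(childSeed(cfg$seed, "genome"))
  chromNames <- paste0("chr", seq_len(cfg$chromCount))
  base <- cfg$genomeLength %/% cfg$chromCount
  chromLens <- rep(base, cfg$chromCount)
  chromLens[1] <- chromLens[1] + cfg$genomeLength - sum(chromLens)
  query <- lapply(chromLens, randomSeq, gc = cfg$backgroundGC)
  names(query) <- chromNames

  ## --- conserved elements (non-overlapping, packed per chromosome) --
  set.seed(childSeed(cfg$seed, "elements"))
  margin <- 50L; minGap <- 20L
  nEl <- cfg$elementCount
  perChrom <- diff(round(seq(0, nEl, length.out = cfg$chromCount + 1)))
  els <- NULL
  for (ci in seq_len(cfg$chromCount)) {
    k <- perChrom[ci]
    if (k == 0L) next
    lens <- sample(seq(cfg$elementLengthRange[1], cfg$elementLengthRange[2]),
                   k, replace = TRUE)
    leftover <- chromLens[ci] - 2L * margin - sum(lens) - (k - 1L) * minGap
    if (leftover < 0L)
      ncceConfigError("infeasible packing: %d elements do not fit on %s",
                      k, chromNames[ci])
    cuts <- floor(leftover * diff(c(0, sort(runif(k)), 1)))[seq_len(k)]
    pos <- margin
    for (j in seq_len(k)) {
      s0 <- as.integer(pos + cuts[j])
      els <- rbind(els, data.frame(chrom = chromNames[ci], s0 = s0,
                                   e0 = s0 + lens[j]))
      pos <- s0 + lens[j] + minGap
    }
  }
  els$score <- sample(seq(cfg$scoreRange[1], cfg$scoreRange[2]),
                      nrow(els), replace = TRUE)
  els$elementId <- sprintf("el%04d", seq_len(nrow(els)))

  ## --- plant composites ---------------------------------------------
  set.seed(childSeed(cfg$seed, "plants"))
  plantPlan <- data.frame(class = character(), spacing = integer(),
                          origin = character())
  for (cl in NCCE_CLASSES) {
    k <- cfg$plantedCounts[[cl]]
    if (k == 0L) next
    sp <- if (!is.null(cfg$plantSpacings[[cl]]))
      rep_len(cfg$plantSpacings[[cl]], k)
    else if (cl == "WIDE-CONTROL") sample(30:60, k, replace = TRUE)
    else sample(6:16, k, replace = TRUE)
    plantPlan <- rbind(plantPlan, data.frame(class = cl, spacing = sp,
                                             origin = "planted"))
  }
  if (cfg$subthresholdDecoys > 0L)
    plantPlan <- rbind(plantPlan, data.frame(
      class = "NCCE", spacing = sample(6:16, cfg$subthresholdDecoys,
                                       replace = TRUE),
      origin = "decoy-subthreshold"))
  if (length(cfg$decoySpacings))
    plantPlan <- rbind(plantPlan, data.frame(
      class = "NCCE", spacing = cfg$decoySpacings, origin = "decoy-spacing"))

  nPlants <- nrow(plantPlan)
  hosts <- sample(nrow(els), nPlants)   # one plant per element, all distinct
  ## hosting elements must clear the threshold (decoy elements sit at it)
  for (i in seq_len(nPlants)) {
    h <- hosts[i]
    els$score[h] <- if (plantPlan$origin[i] == "decoy-subthreshold")
      as.integer(cfg$minScore)
    else sample(seq(as.integer(cfg$minScore) + 1L, cfg$scoreRange[2]), 1L)
  }

  plants <- NULL
  for (i in seq_len(nPlants)) {
    h <- hosts[i]
    cl <- plantPlan$class[i]; s <- plantPlan$spacing[i]
    nkxDef <- motifs$NKX
    pDef <- motifs[[classPartnerRole(cl)]]
    Ln <- nchar(consensus(nkxDef)); Lp <- nchar(consensus(pDef))
    if ((Ln - Lp) %% 2L != 0L)
      ncceConfigError("motif lengths of NKX and %s differ in parity; integer spacings are not placeable",
                      motifId(pDef))
    elLen <- els$e0[h] - els$s0[h]
    pad <- 3L
    placed <- FALSE
    for (try in 1:50) {
      downstream <- runif(1) < 0.5
      if (downstream) {
        bOff <- (Ln - Lp) %/% 2L + s          # partner start - nkx start
        span <- max(Ln, bOff + Lp)
        if (elLen - 2L * pad - span < 0L) { next }
        aRel <- pad + sample.int(elLen - 2L * pad - span + 1L, 1L) - 1L
        nkxS <- els$s0[h] + aRel; pS <- nkxS + bOff
      } else {
        aOff <- (Lp - Ln) %/% 2L + s          # nkx start - partner start
        span <- max(Lp, aOff + Ln)
        if (elLen - 2L * pad - span < 0L) { next }
        bRel <- pad + sample.int(elLen - 2L * pad - span + 1L, 1L) - 1L
        pS <- els$s0[h] + bRel; nkxS <- pS + aOff
      }
      nkxStrand <- sample(c("+", "-"), 1L)
      pStrand <- sample(c("+", "-"), 1L)
      nkxInst <- sampleInstance(consensus(nkxDef))
      pInst <- sampleInstance(consensus(pDef))
      ch <- els$chrom[h]
      trial <- query[[ch]]
      trial <- spliceIn(trial, nkxS,
                        if (nkxStrand == "+") nkxInst else revcompIupac(nkxInst))
      trial <- spliceIn(trial, pS,
                        if (pStrand == "+") pInst else revcompIupac(pInst))
      ## overlapping plants (sub-6-bp decoy spacings) may clash: both motifs
      ## must still read correctly from the final sequence
      readN <- substr(trial, nkxS + 1L, nkxS + Ln)
      readP <- substr(trial, pS + 1L, pS + Lp)
      okN <- iupacMatch(consensus(nkxDef),
                        if (nkxStrand == "+") readN else revcompIupac(readN))
      okP <- iupacMatch(consensus(pDef),
                        if (pStrand == "+") readP else revcompIupac(readP))
      if (okN && okP) {
        query[[ch]] <- trial
        sp2 <- abs((2L * nkxS + Ln - 1L) - (2L * pS + Lp - 1L))
        stopifnot(sp2 == 2L * s)
        plants <- rbind(plants, data.frame(
          class = cl, origin = plantPlan$origin[i],
          chrom = ch, elementId = els$elementId[h],
          nkxStart = nkxS, nkxEnd = nkxS + Ln, nkxStrand = nkxStrand,
          nkxMotifId = motifId(nkxDef),
          partnerStart = pS, partnerEnd = pS + Lp, partnerStrand = pStrand,
          partnerMotifId = motifId(pDef),
          spacing2 = sp2))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      ncceConfigError("could not place a %s plant with spacing %d in element %s",
                      cl, s, els$elementId[h])
  }

  ## --- chain + target genome ----------------------------------------
  set.seed(childSeed(cfg$seed, "chain"))
  chains <- list(); targetChain <- list(); indelsByChrom <- list()
  for (ci in seq_len(cfg$chromCount)) {
    chn <- chromNames[ci]; qlen <- chromLens[ci]
    ce <- els[els$chrom == chn, , drop = FALSE]
    ce <- ce[order(ce$s0), , drop = FALSE]
    ## candidate inter-element gaps, padded so no indel touches an element
    pad <- 10L
    gapS <- c(0L, ce$e0) + pad
    gapE <- c(ce$s0, qlen) - pad
    okGap <- which(gapE - gapS > cfg$indelSizeRange[2] + 2L)
    nI <- min(cfg$chainIndelsPerChrom, length(okGap))
    ev <- NULL
    if (nI > 0L) {
      pick <- sort(sample(okGap, nI))
      for (g in pick) {
        sz <- sample(seq(cfg$indelSizeRange[1], cfg$indelSizeRange[2]), 1L)
        p <- gapS[g] + sample.int(gapE[g] - gapS[g] - sz, 1L)
        if (runif(1) < 0.5) ev <- rbind(ev, data.frame(q = p, dq = sz, dt = 0L))
        else ev <- rbind(ev, data.frame(q = p, dq = 0L, dt = sz))
      }
    }
    ## build target (chain-space) sequence and block list
    pieces <- character(); blocks <- NULL
    qpos <- 0L
    evn <- if (is.null(ev)) 0L else nrow(ev)
    for (j in seq_len(evn)) {
      size <- ev$q[j] - qpos
      blocks <- rbind(blocks, c(size, ev$dq[j], ev$dt[j]))
      pieces <- c(pieces, substr(query[[chn]], qpos + 1L, qpos + size))
      if (ev$dt[j] > 0L) pieces <- c(pieces, randomSeq(ev$dt[j], cfg$backgroundGC))
      qpos <- ev$q[j] + ev$dq[j]
    }
    blocks <- rbind(blocks, c(qlen - qpos, 0L, 0L))
    pieces <- c(pieces, substr(query[[chn]], qpos + 1L, qlen))
    tseq <- paste(pieces, collapse = "")
    tlen <- nchar(tseq)
    inverted <- chn %in% cfg$invertChroms
    chains[[ci]] <- chainAlignment(ci, 1000 + ci, chn, qlen, 0L, qlen,
                                   chn, tlen, if (inverted) "-" else "+",
                                   0L, tlen, blocks)
    targetChain[[chn]] <- tseq
    indelsByChrom[[chn]] <- ev
  }

  ## target chain-space position of a query position inside an element
  tpos <- function(chrom, x) {
    ev <- indelsByChrom[[chrom]]
    if (is.null(ev)) return(x)
    x - sum(ev$dq[ev$q + ev$dq <= x]) + sum(ev$dt[ev$q <= x])
  }

  ## --- targeted synteny-breaking mutations --------------------------
  set.seed(childSeed(cfg$seed, "breaks"))
  plants$expectedSynteny <- NA_character_
  mutations <- NULL   # chain-space target positions mutated, per chromosome
  for (i in seq_len(nrow(plants))) {
    if (plants$origin[i] != "planted") { plants$expectedSynteny[i] <- "decoy"; next }
    if (runif(1) >= cfg$syntenyBreakRate) { plants$expectedSynteny[i] <- "pass"; next }
    side <- if (runif(1) < 0.5) "nkx" else "partner"
    s0 <- if (side == "nkx") plants$nkxStart[i] else plants$partnerStart[i]
    e0 <- if (side == "nkx") plants$nkxEnd[i] else plants$partnerEnd[i]
    cons <- consensus(motifs[[if (side == "nkx") plants$nkxMotifId[i]
                              else plants$partnerMotifId[i]]])
    chn <- plants$chrom[i]
    ts0 <- tpos(chn, s0)
    sub <- substr(targetChain[[chn]], ts0 + 1L, ts0 + (e0 - s0))
    done <- FALSE
    for (off in sample(seq_len(nchar(sub)))) {
      for (b in sample(c("A", "C", "G", "T"))) {
        if (substr(sub, off, off) == b) next
        mut <- sub
        substr(mut, off, off) <- b
        if (!iupacMatch(cons, mut) && !iupacMatch(revcompIupac(cons), mut)) {
          targetChain[[chn]] <- spliceIn(targetChain[[chn]], ts0, mut)
          mutations <- rbind(mutations,
                             data.frame(chrom = chn, t0 = ts0 + off - 1L))
          done <- TRUE
          break
        }
      }
      if (done) break
    }
    if (!done)
      ncceConfigError("could not break motif for plant %d", i)
    plants$expectedSynteny[i] <- "fail"
  }

  ## finalize target genome (apply inversions after mutations: chain space
  ## of a '-' chain is the reversed target sequence)
  target <- targetChain
  for (chn in cfg$invertChroms)
    target[[chn]] <- revcompIupac(target[[chn]])

  ## --- self-scan: the truth manifest includes chance composites -----
  queryDss <- Biostrings::DNAStringSet(unlist(query))
  elGr <- granges0(els$chrom, els$s0, els$e0)
  S4Vectors::mcols(elGr) <- S4Vectors::DataFrame(elementId = els$elementId,
                                                 score = els$score)
  hitSets <- lapply(motifs, function(m)
    assignContainers(scanMotif(queryDss, m), elGr, cfg$minScore))
  names(hitSets) <- vapply(motifs, motifRole, character(1))
  found <- buildAllClasses(hitSets)

  ceKey <- function(class, chrom, ns, ne, ps, pe)
    paste(class, chrom, ns, ne, ps, pe, sep = "|")
  plantKeys <- ceKey(plants$class, plants$chrom, plants$nkxStart,
                     plants$nkxEnd, plants$partnerStart, plants$partnerEnd)
  composites <- plants[plants$origin == "planted", , drop = FALSE]
  decoys <- plants[plants$origin != "planted", , drop = FALSE]
  for (cl in NCCE_CLASSES) {
    fc <- found[[cl]]
    if (!length(fc)) next
    mc <- S4Vectors::mcols(fc)
    keys <- ceKey(mc$classLabel, as.character(GenomicRanges::seqnames(fc)),
                  mc$nkxStart, mc$nkxEnd, mc$partnerStart, mc$partnerEnd)
    if (any(keys %in% plantKeys[plants$origin != "planted"]))
      stop("internal: decoy plant recovered by self-scan")
    new <- which(!(keys %in% plantKeys))
    if (length(new))
      composites <- rbind(composites, data.frame(
        class = cl, origin = "chance",
        chrom = as.character(GenomicRanges::seqnames(fc))[new],
        elementId = mc$elementId[new],
        nkxStart = mc$nkxStart[new], nkxEnd = mc$nkxEnd[new],
        nkxStrand = mc$nkxStrand[new], nkxMotifId = mc$nkxMotifId[new],
        partnerStart = mc$partnerStart[new], partnerEnd = mc$partnerEnd[new],
        partnerStrand = mc$partnerStrand[new],
        partnerMotifId = mc$partnerMotifId[new],
        spacing2 = mc$spacing2[new],
        expectedSynteny = NA_character_))
  }
  ## planted composites must all be recoverable
  foundKeys <- unlist(lapply(NCCE_CLASSES, function(cl) {
    fc <- found[[cl]]; mc <- S4Vectors::mcols(fc)
    if (!length(fc)) return(character(0))
    ceKey(mc$classLabel, as.character(GenomicRanges::seqnames(fc)),
          mc$nkxStart, mc$nkxEnd, mc$partnerStart, mc$partnerEnd)
  }))
  pk <- ceKey(composites$class, composites$chrom, composites$nkxStart,
              composites$nkxEnd, composites$partnerStart, composites$partnerEnd)
  if (!all(pk %in% foundKeys))
    stop("internal: planted composite not recovered by self-scan")

  ## expected synteny of chance composites: indels never touch elements, so
  ## every in-element interval maps contiguously; the motif survives unless
  ## a break mutation landed inside it (checked directly on the target)
  for (i in which(is.na(composites$expectedSynteny))) {
    ok <- TRUE
    for (side in c("nkx", "partner")) {
      s0 <- composites[[paste0(side, "Start")]][i]
      e0 <- composites[[paste0(side, "End")]][i]
      cons <- consensus(motifs[[composites[[paste0(side, "MotifId")]][i]]])
      chn <- composites$chrom[i]
      ts0 <- tpos(chn, s0)
      sub <- substr(targetChain[[chn]], ts0 + 1L, ts0 + (e0 - s0))
      if (!iupacMatch(cons, sub) && !iupacMatch(revcompIupac(cons), sub))
        ok <- FALSE
    }
    composites$expectedSynteny[i] <- if (ok) "pass" else "fail"
  }

  ## --- genes ---------------------------------------------------------
  set.seed(childSeed(cfg$seed, "genes"))
  planted <- composites[composites$origin == "planted", , drop = FALSE]
  mid4 <- function(df) (df$nkxStart + df$nkxEnd - 1) +
    (df$partnerStart + df$partnerEnd - 1)
  pm4 <- mid4(planted)
  nBg <- cfg$geneCount - nrow(planted)
  gtss <- integer(0); gchrom <- character(0); isPlantGene <- logical(0)
  for (i in seq_len(nrow(planted))) {
    jit <- sample(seq(-cfg$geneTssJitter, cfg$geneTssJitter), 1L)
    t0 <- as.integer(round(pm4[i] / 4) + jit)
    t0 <- max(10L, min(t0, chromLens[match(planted$chrom[i], chromNames)] - 10L))
    gtss <- c(gtss, t0); gchrom <- c(gchrom, planted$chrom[i])
    isPlantGene <- c(isPlantGene, TRUE)
  }
  for (i in seq_len(nBg)) {
    ci <- sample(cfg$chromCount, 1L)
    t0 <- sample(seq(10L, chromLens[ci] - 10L), 1L)
    gtss <- c(gtss, t0); gchrom <- c(gchrom, chromNames[ci])
    isPlantGene <- c(isPlantGene, FALSE)
  }
  ## enforce: each planted composite's dedicated gene is its unique nearest
  ## (shrink the jitter towards the midpoint until the assignment holds)
  nearestIdx <- function() {
    vapply(seq_len(nrow(composites)), function(i) {
      on <- which(gchrom == composites$chrom[i])
      d <- abs(mid4(composites)[i] - 4 * gtss[on])
      cand <- on[d == min(d)]
      cand[which.min(gtss[cand])]   # provisional: ids assigned later
    }, integer(1))
  }
  pIdx <- which(composites$origin == "planted")
  for (pass in 1:25) {
    ni <- nearestIdx()
    bad <- which(ni[pIdx] != seq_len(nrow(planted)))
    if (!length(bad)) break
    for (j in bad) {
      cur <- gtss[j] - as.integer(round(pm4[j] / 4))
      gtss[j] <- as.integer(round(pm4[j] / 4) + cur %/% 2L)
    }
  }
  ni <- nearestIdx()
  if (any(ni[pIdx] != seq_len(nrow(planted))))
    stop("internal: planted nearest-gene uniqueness not achievable")
  ## gene ids in genomic order (ids must not leak which genes are planted)
  o <- order(match(gchrom, chromNames), gtss)
  gchrom <- gchrom[o]; gtss <- gtss[o]; isPlantGene <- isPlantGene[o]
  rankOf <- match(seq_along(o), o)   # old index -> new position
  geneIds <- sprintf("g%04d", seq_along(gtss))
  strand <- sample(c("+", "-"), length(gtss), replace = TRUE)
  glen <- sample(500:3000, length(gtss), replace = TRUE)
  gs0 <- ifelse(strand == "+", gtss, pmax(0L, gtss - glen + 1L))
  ge0 <- ifelse(strand == "+",
                pmin(gtss + glen, chromLens[match(gchrom, chromNames)]),
                gtss + 1L)
  genesDf <- data.frame(geneId = geneIds, symbol = toupper(geneIds),
                        chrom = gchrom, s0 = as.integer(gs0),
                        e0 = as.integer(ge0), strand = strand,
                        tss0 = as.integer(gtss))
  ## expected assignment, by direct minimisation with the lexicographic tie
  expectedGene <- vapply(seq_len(nrow(composites)), function(i) {
    on <- which(genesDf$chrom == composites$chrom[i])
    d <- abs(mid4(composites)[i] - 4 * genesDf$tss0[on])
    min(genesDf$geneId[on[d == min(d)]])
  }, character(1))
  composites$expectedGene <- expectedGene

  ## --- term map -------------------------------------------------------
  set.seed(childSeed(cfg$seed, "terms"))
  termIds <- sprintf("T%03d", seq_len(cfg$termCount))
  enriched <- termIds[1]
  nccePass <- composites$class == "NCCE" & composites$expectedSynteny == "pass"
  genesNearNcce <- sort(unique(composites$expectedGene[nccePass]))
  rows <- list()
  for (g in genesDf$geneId) {
    pEnr <- if (g %in% genesNearNcce) cfg$enrichedTermProb[["ncce"]]
            else cfg$enrichedTermProb[["other"]]
    if (runif(1) < pEnr)
      rows[[length(rows) + 1L]] <- data.frame(termId = enriched, geneId = g)
    hit <- runif(cfg$termCount - 1L) < cfg$backgroundTermProb
    for (tt in termIds[-1][hit])
      rows[[length(rows) + 1L]] <- data.frame(termId = tt, geneId = g)
  }
  termMap <- do.call(rbind, rows)
  termMap <- termMap[order(termMap$termId, termMap$geneId), , drop = FALSE]
  rownames(termMap) <- NULL

  ## --- write the bundle ----------------------------------------------
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    queryFasta = file.path(outDir, "query.fa"),
    targetFasta = file.path(outDir, "target.fa"),
    conservedBed = file.path(outDir, "conserved.bed"),
    chain = file.path(outDir, "alignment.chain"),
    geneTable = file.path(outDir, "genes.tsv"),
    termMap = file.path(outDir, "terms.tsv"),
    manifest = file.path(outDir, "manifest.json"))
  writeGenomeFasta(queryDss, paths$queryFasta)
  writeGenomeFasta(Biostrings::DNAStringSet(unlist(target)), paths$targetFasta)
  writeConservedBed(elGr, paths$conservedBed)
  writeChainFile(chains, paths$chain)
  geneGr <- granges0(genesDf$chrom, genesDf$s0, genesDf$e0, genesDf$strand)
  S4Vectors::mcols(geneGr) <- S4Vectors::DataFrame(
    geneId = genesDf$geneId, symbol = genesDf$symbol, tss0 = genesDf$tss0)
  writeGeneTable(geneGr, paths$geneTable)
  writeTermMap(termMap, paths$termMap)

  rownames(composites) <- NULL
  rownames(decoys) <- NULL
  classCounts <- vapply(NCCE_CLASSES, function(cl)
    sum(composites$class == cl), integer(1))
  manifest <- list(
    schema_version = 1L,
    seed = cfg$seed,
    genome = list(chroms = chromNames, lengths = chromLens),
    class_counts = as.list(classCounts),
    composites = composites,
    decoys = decoys[, setdiff(colnames(decoys), "expectedSynteny"),
                    drop = FALSE],
    genes_near_ncce = genesNearNcce,
    enriched_terms = enriched)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(list(paths = paths, manifest = manifest))
}

#' Read a truth manifest written by [generateBundle()]
#'
#' @param path manifest JSON path.
#' @return The manifest as a list (data.frame-valued `composites`/`decoys`).
#' @export
readManifest <- function(path) {
  if (!file.exists(path))
    ncceIOError("manifest not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Score pipeline output against the truth manifest
#'
#' Composites are matched to manifest entries by exact coordinates (class,
#' chromosome and both motif intervals). Reports per-class sensitivity and
#' precision at the pairing stage, the synteny confusion counts and the
#' post-filter sensitivity/precision, nearest-gene assignment accuracy over
#' matched conserved elements, the composite gene set compared to the
#' manifest's, and the rank (by q) of the engineered enriched term in the
#' wide-spacing control comparison.
#'
#' @param results a run list as returned by [runScreen()].
#' @param manifest manifest list from [readManifest()] or
#'   [generateBundle()].
#' @return A list of metrics; `$perClass` is a data.frame with columns
#'   `class`, `pairSensitivity`, `pairPrecision`, `conservedSensitivity`,
#'   `conservedPrecision`.
#' @export
evaluateAgainstManifest <- function(results, manifest) {
  man <- manifest$composites
  if (is.null(man) || !nrow(man))
    ncceDataError("manifest contains no composites")
  if (!any(unlist(lapply(results$composites, function(x)
    as.character(GenomicRanges::seqnames(x)))) %in% man$chrom) &&
    sum(vapply(results$composites, length, integer(1))) > 0)
    ncceDataError("pipeline output and manifest share no chromosome names; wrong genome?")
  key <- function(class, chrom, ns, ne, ps, pe)
    paste(class, chrom, ns, ne, ps, pe, sep = "|")
  manKey <- key(man$class, man$chrom, man$nkxStart, man$nkxEnd,
                man$partnerStart, man$partnerEnd)
  grKeys <- function(gr) {
    if (!length(gr)) return(character(0))
    mc <- S4Vectors::mcols(gr)
    key(mc$classLabel, as.character(GenomicRanges::seqnames(gr)),
        mc$nkxStart, mc$nkxEnd, mc$partnerStart, mc$partnerEnd)
  }
  rate <- function(num, den) if (den == 0) 1 else num / den
  perClass <- NULL
  confusion <- c(tp = 0L, fn = 0L, fp = 0L, tn = 0L)
  geneOk <- 0L; geneTot <- 0L
  for (cl in NCCE_CLASSES) {
    mk <- manKey[man$class == cl]
    fk <- grKeys(results$composites[[cl]])
    pairSens <- rate(sum(mk %in% fk), length(mk))
    pairPrec <- rate(sum(fk %in% mk), length(fk))
    mkPass <- manKey[man$class == cl & man$expectedSynteny == "pass"]
    ck <- grKeys(results$conserved[[cl]])
    consSens <- rate(sum(mkPass %in% ck), length(mkPass))
    consPrec <- rate(sum(ck %in% mkPass), length(ck))
    perClass <- rbind(perClass, data.frame(
      class = cl, pairSensitivity = pairSens, pairPrecision = pairPrec,
      conservedSensitivity = consSens, conservedPrecision = consPrec))
    ## synteny confusion + gene accuracy over matched elements
    tested <- results$tested[[cl]]
    if (!is.null(tested) && length(tested)) {
      tk <- grKeys(tested)
      m <- match(tk, manKey)
      ok <- !is.na(m)
      pred <- syntenyStatus(tested)[ok]
      exp_ <- man$expectedSynteny[m[ok]]
      confusion["tp"] <- confusion["tp"] + sum(pred == "pass" & exp_ == "pass")
      confusion["fn"] <- confusion["fn"] + sum(pred == "fail" & exp_ == "pass")
      confusion["fp"] <- confusion["fp"] + sum(pred == "pass" & exp_ == "fail")
      confusion["tn"] <- confusion["tn"] + sum(pred == "fail" & exp_ == "fail")
    }
    cons <- results$conserved[[cl]]
    if (!is.null(cons) && length(cons)) {
      ck2 <- grKeys(cons)
      m <- match(ck2, manKey)
      ok <- !is.na(m) & !is.na(nearestGeneId(cons))
      geneTot <- geneTot + sum(ok)
      geneOk <- geneOk +
        sum(nearestGeneId(cons)[ok] == man$expectedGene[m[ok]])
    }
  }
  geneSetMatch <- identical(sort(results$geneSets$NCCE),
                            sort(manifest$genes_near_ncce))
  enrRank <- NA_real_; enrQ <- NA_real_
  enr <- results$enrichment[["WIDE-CONTROL"]]
  if (!is.null(enr) && nrow(enr)) {
    pos <- match(manifest$enriched_terms[1], enr$termId)
    if (!is.na(pos)) { enrRank <- pos; enrQ <- enr$q[pos] }
  }
  list(perClass = perClass,
       syntenyConfusion = as.list(confusion),
       geneAssignmentAccuracy = rate(geneOk, geneTot),
       geneSetMatch = geneSetMatch,
       enrichedTermRank = enrRank,
       enrichedTermQ = enrQ,
       allPerfect = all(perClass$pairSensitivity == 1) &&
         all(perClass$pairPrecision == 1) &&
         all(perClass$conservedSensitivity == 1) &&
         all(perClass$conservedPrecision == 1))
}
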