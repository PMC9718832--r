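## All files use 0-based half-open coordinates (BED convention). In memory
## the package uses GRanges/IRanges (1-based closed); these readers/writers
## are the only place the conversion happens.

start0 <- function(gr) GenomicRanges::start(gr) - 1L
end0   <- function(gr) GenomicRanges::end(gr)

granges0 <- function(chrom, s0, e0, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1L, e0), strand = strand)
}

#' Read a genome FASTA file
#'
#' Residues are uppercased and U is mapped to T on read; anything outside
#' `{A,C,G,T,N,U}` is rejected with the offending line number. Duplicate
#' record names are rejected.
#'
#' @param path path to a FASTA file (wrapped or unwrapped, >= 1 record).
#' @return A named [Biostrings::DNAStringSet].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt"), fa)
#' readGenomeFasta(fa)
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path))
    ncceIOError("FASTA file not found: %s", path)
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr))
    ncceFormatError("%s: no FASTA records found", path)
  if (!hdr[match(TRUE, nzchar(lines))])
    ncceFormatError("%s: sequence data before first header", path)
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- sub("\\s.*$", "", names_)
  if (any(!nzchar(names_)))
    ncceFormatError("%s: empty record name at line %d",
                    path, which(hdr)[!nzchar(names_)][1])
  dup <- duplicated(names_)
  if (any(dup))
    ncceFormatError("%s: duplicate FASTA header '%s'", path, names_[dup][1])
  body <- toupper(lines)
  body <- chartr("U", "T", body)
  seqLines <- !hdr & nzchar(lines)
  bad <- seqLines & grepl("[^ACGTN]", body)
  if (any(bad)) {
    ln <- which(bad)[1]
    res <- regmatches(body[ln], regexpr("[^ACGTN]", body[ln]))
    ncceFormatError("%s: illegal residue '%s' at line %d", path, res, ln)
  }
  rec <- cumsum(hdr)
  seqs <- vapply(seq_along(names_), function(i)
    paste(body[seqLines & rec == i], collapse = ""), character(1))
  Biostrings::DNAStringSet(setNames(seqs, names_))
}

#' Write a genome FASTA file
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(genome)) {
    writeLines(paste0(">", names(genome)[i]), con)
    s <- as.character(genome[[i]])
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read conserved elements from a BED5+ file
#'
#' Columns: chrom, start, end, name, score (tab-separated; additional
#' columns are ignored). Intervals are 0-based half-open and preserved
#' verbatim in file order; elements are never merged. The score is on the
#' conservation-track log-odds scale.
#'
#' @param path path to the BED file.
#' @return A strandless [GenomicRanges::GRanges] with metadata columns
#'   `elementId` and `score`.
#' @export
readConservedBed <- function(path) {
  if (!file.exists(path))
    ncceIOError("BED file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track|browser)", lines)
  if (!any(keep)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(elementId = character(),
                                                 score = numeric())
    return(gr)
  }
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L))
    ncceFormatError("%s: line %d has %d column(s); >= 5 required",
                    path, idx[nf < 5L][1], nf[nf < 5L][1])
  chrom <- vapply(fields, `[[`, character(1), 1L)
  s0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  e0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  nm <- vapply(fields, `[[`, character(1), 4L)
  sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5L)))
  if (anyNA(s0) || anyNA(e0))
    ncceFormatError("%s: non-integer coordinate at line %d",
                    path, idx[is.na(s0) | is.na(e0)][1])
  if (anyNA(sc))
    ncceFormatError("%s: non-numeric score at line %d", path, idx[is.na(sc)][1])
  if (any(s0 >= e0))
    ncceFormatError("%s: start >= end at line %d", path, idx[s0 >= e0][1])
  if (any(s0 < 0))
    ncceFormatError("%s: negative start at line %d", path, idx[s0 < 0][1])
  gr <- granges0(chrom, s0, e0)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(elementId = nm, score = sc)
  gr
}

#' @rdname readConservedBed
#' @param elements GRanges as returned by `readConservedBed`.
#' @param path output path.
#' @export
writeConservedBed <- function(elements, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(elements)),
    start = start0(elements), end = end0(elements),
    name = S4Vectors::mcols(elements)$elementId,
    score = S4Vectors::mcols(elements)$score)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write motif hits as BED6
#'
#' name = motif id, score = 0, strand column used. Coordinates are 0-based
#' half-open on disk.
#'
#' @param hits motif-hit GRanges (see [scanMotif()]).
#' @param path output path.
#' @export
writeHitsBed <- function(hits, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(hits)),
    start = start0(hits), end = end0(hits),
    name = if (length(hits)) S4Vectors::mcols(hits)$motifId else character(),
    score = rep(0L, length(hits)),
    strand = as.character(GenomicRanges::strand(hits)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read alignments from a UCSC chain file
#'
#' The header line is `chain score c1 s1 + st1 en1 c2 s2 strand2 st2 en2 id`
#' followed by block triples `size dgap1 dgap2`, chains separated by blank
#' lines; `#` lines are skipped. With the default `query-first` direction
#' the FIRST sequence of each header is the query genome — the genome being
#' scanned, whose coordinates are lifted FROM (the UCSC over.chain layout).
#' `target-first` reads files written the other way round; such chains are
#' inverted on read so the in-memory object is always query-first.
#'
#' @param path chain file path.
#' @param direction `"query-first"` (default) or `"target-first"`.
#' @return List of [ChainAlignment-class] objects.
#' @export
readChainFile <- function(path, direction = c("query-first", "target-first")) {
  direction <- match.arg(direction)
  if (!file.exists(path))
    ncceIOError("chain file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (f[1] != "chain" || length(f) != 13L)
      ncceFormatError("%s: malformed chain header at line %d", path, i)
    hd <- f
    i <- i + 1L
    blocks <- NULL
    repeat {
      if (i > length(lines) || !nzchar(trimws(lines[i]))) break
      b <- suppressWarnings(as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (anyNA(b) || !length(b) %in% c(1L, 3L))
        ncceFormatError("%s: malformed block line at line %d", path, i)
      if (length(b) == 1L) b <- c(b, 0L, 0L)
      blocks <- rbind(blocks, b)
      i <- i + 1L
    }
    if (is.null(blocks))
      ncceFormatError("%s: chain %s has no blocks", path, hd[13])
    num <- suppressWarnings(as.numeric(hd[c(2, 4, 6, 7, 9, 11, 12, 13)]))
    if (anyNA(num))
      ncceFormatError("%s: non-numeric field in chain header '%s'",
                      path, paste(hd, collapse = " "))
    mk <- function(qFirst) {
      if (qFirst) {
        if (hd[5] != "+")
          ncceFormatError("%s: chain %s: query strand must be '+'", path, hd[13])
        chainAlignment(hd[13], hd[2], hd[3], hd[4], hd[6], hd[7],
                       hd[8], hd[9], hd[10], hd[11], hd[12],
                       blocks)
      } else {
        ## file lists target first: parse in the written layout, then invert
        ## so the second sequence becomes the (plus-strand) query. The
        ## inversion also rewrites minus-strand coordinates.
        if (hd[5] != "+")
          ncceFormatError("%s: chain %s: first strand must be '+'", path, hd[13])
        ch <- chainAlignment(hd[13], hd[2], hd[3], hd[4], hd[6], hd[7],
                             hd[8], hd[9], hd[10], hd[11], hd[12], blocks)
        invertChain(ch)
      }
    }
    ch <- tryCatch(mk(direction == "query-first"), error = function(e) {
      if (inherits(e, "ncceError")) stop(e)
      ncceFormatError("%s: invalid chain %s: %s", path, hd[13],
                      conditionMessage(e))
    })
    chains[[length(chains) + 1L]] <- ch
  }
  chains
}

#' Write alignments to a UCSC chain file
#'
#' Written query-first: the first sequence of every header is the query
#' genome (lifted FROM). A leading comment line documents this orientation;
#' set `comment = FALSE` for consumers that reject comment lines.
#'
#' @param chains list of [ChainAlignment-class].
#' @param path output path.
#' @param comment write the orientation comment line.
#' @export
writeChainFile <- function(chains, path, comment = TRUE) {
  out <- character()
  if (comment)
    out <- "# chain orientation: query-first (first sequence = genome lifted FROM)"
  for (ch in chains) {
    out <- c(out, sprintf("chain %s %s %d + %d %d %s %d %s %d %d %d",
                          format(ch@score, scientific = FALSE, trim = TRUE),
                          ch@qChrom, ch@qSize, ch@qStart, ch@qEnd,
                          ch@tChrom, ch@tSize, ch@tStrand, ch@tStart, ch@tEnd,
                          ch@chainId))
    b <- ch@blocks
    n <- nrow(b)
    if (n > 1L)
      out <- c(out, sprintf("%d %d %d", b[-n, 1], b[-n, 2], b[-n, 3]))
    out <- c(out, sprintf("%d", b[n, 1]), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a gene table
#'
#' Tab-separated with header `gene_id symbol chrom start end strand`;
#' coordinates 0-based half-open, strand `+` or `-` only. The TSS is
#' `start` on `+` genes and `end - 1` on `-` genes.
#'
#' @param path gene table path.
#' @return A stranded [GenomicRanges::GRanges] with metadata columns
#'   `geneId`, `symbol`, `tss0` (0-based TSS position).
#' @export
readGeneTable <- function(path) {
  if (!file.exists(path))
    ncceIOError("gene table not found: %s", path)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "gene_id\tsymbol\tchrom\tstart\tend\tstrand")
    ncceFormatError("%s: missing or malformed gene-table header", path)
  body <- lines[-1][nzchar(lines[-1])]
  if (!length(body)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      geneId = character(), symbol = character(), tss0 = integer())
    return(gr)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- lengths(fields) != 6L
  if (any(bad))
    ncceFormatError("%s: line %d does not have 6 columns", path,
                    which(bad)[1] + 1L)
  geneId <- vapply(fields, `[[`, character(1), 1L)
  symbol <- vapply(fields, `[[`, character(1), 2L)
  chrom <- vapply(fields, `[[`, character(1), 3L)
  s0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 4L)))
  e0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 5L)))
  strand <- vapply(fields, `[[`, character(1), 6L)
  if (anyNA(s0) || anyNA(e0) || any(s0 >= e0))
    ncceFormatError("%s: bad coordinates at line %d", path,
                    which(is.na(s0) | is.na(e0) | s0 >= e0)[1] + 1L)
  if (any(!strand %in% c("+", "-")))
    ncceFormatError("%s: strand must be '+' or '-' at line %d", path,
                    which(!strand %in% c("+", "-"))[1] + 1L)
  if (anyDuplicated(geneId))
    ncceFormatError("%s: duplicate gene id '%s'", path,
                    geneId[duplicated(geneId)][1])
  gr <- granges0(chrom, s0, e0, strand)
  tss0 <- ifelse(strand == "+", s0, e0 - 1L)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(geneId = geneId,
                                               symbol = symbol,
                                               tss0 = as.integer(tss0))
  gr
}

#' @rdname readGeneTable
#' @param genes gene GRanges as returned by `readGeneTable`.
#' @export
writeGeneTable <- function(genes, path) {
  df <- data.frame(
    gene_id = if (length(genes)) S4Vectors::mcols(genes)$geneId else character(),
    symbol = if (length(genes)) S4Vectors::mcols(genes)$symbol else character(),
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = start0(genes), end = end0(genes),
    strand = as.character(GenomicRanges::strand(genes)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a term-to-gene annotation map
#'
#' Tab-separated, header `term_id gene_id`, many-to-many. Duplicate
#' (term, gene) rows are deduplicated with a warning.
#'
#' @param path term map path.
#' @return A data.frame with columns `termId`, `geneId`.
#' @export
readTermMap <- function(path) {
  if (!file.exists(path))
    ncceIOError("term map not found: %s", path)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "term_id\tgene_id")
    ncceFormatError("%s: missing or malformed term-map header", path)
  body <- lines[-1][nzchar(lines[-1])]
  if (!length(body))
    return(data.frame(termId = character(), geneId = character()))
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- lengths(fields) != 2L
  if (any(bad))
    ncceFormatError("%s: line %d does not have 2 columns", path,
                    which(bad)[1] + 1L)
  df <- data.frame(termId = vapply(fields, `[[`, character(1), 1L),
                   geneId = vapply(fields, `[[`, character(1), 2L))
  dup <- duplicated(df)
  if (any(dup)) {
    warning(sprintf("%s: %d duplicate (term, gene) row(s) removed",
                    path, sum(dup)))
    df <- df[!dup, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' @rdname readTermMap
#' @param termMap data.frame with columns `termId`, `geneId`.
#' @export
writeTermMap <- function(termMap, path) {
  df <- data.frame(term_id = termMap$termId, gene_id = termMap$geneId)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif configuration file
#'
#' YAML (a `motifs:` list with `motif_id`, `role`, `consensus` entries, or a
#' top-level list of such entries) or TSV (header
#' `motif_id role consensus`), chosen by file extension. This is the hook
#' for overriding the default NKX homeodomain consensus.
#'
#' @param path path to a `.yaml`/`.yml` or `.tsv` motif config.
#' @return Named list of [MotifDefinition-class] keyed by motif id.
#' @export
readMotifConfig <- function(path) {
  if (!file.exists(path))
    ncceIOError("motif config not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    y <- yaml::read_yaml(path)
    entries <- if (!is.null(y$motifs)) y$motifs else y
    defs <- lapply(entries, function(e) {
      if (is.null(e$motif_id) || is.null(e$role) || is.null(e$consensus))
        ncceFormatError("%s: motif entry needs motif_id, role, consensus", path)
      motifDefinition(e$motif_id, e$consensus, e$role)
    })
  } else {
    lines <- readLines(path)
    if (!length(lines) || lines[1] != "motif_id\trole\tconsensus")
      ncceFormatError("%s: missing or malformed motif-config header", path)
    body <- lines[-1][nzchar(lines[-1])]
    fields <- strsplit(body, "\t", fixed = TRUE)
    bad <- lengths(fields) != 3L
    if (any(bad))
      ncceFormatError("%s: line %d does not have 3 columns", path,
                      which(bad)[1] + 1L)
    defs <- lapply(fields, function(f) motifDefinition(f[1], f[3], f[2]))
  }
  setNames(defs, vapply(defs, motifId, character(1)))
}

#' Write composite elements as a tab-separated report
#'
#' One row per element: span, id, class, decimal bp spacing, both hit
#' intervals with strands and motif ids, container element, synteny status
#' and nearest gene. `readCompositeTsv` is its loss-less inverse.
#'
#' @param ces a [CompositeElements-class] object.
#' @param path output path.
#' @export
writeCompositeTsv <- function(ces, path) {
  mc <- S4Vectors::mcols(ces)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ces)),
    start = start0(ces), end = end0(ces),
    ce_id = mc$ceId, class = mc$classLabel,
    spacing_bp = mc$spacing2 / 2,
    nkx_start = mc$nkxStart, nkx_end = mc$nkxEnd,
    nkx_strand = mc$nkxStrand, nkx_motif = mc$nkxMotifId,
    partner_start = mc$partnerStart, partner_end = mc$partnerEnd,
    partner_strand = mc$partnerStrand, partner_motif = mc$partnerMotifId,
    element_id = mc$elementId, synteny = mc$syntenyStatus,
    nearest_gene = ifelse(is.na(mc$nearestGene), ".", mc$nearestGene))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCompositeTsv
#' @export
readCompositeTsv <- function(path) {
  if (!file.exists(path))
    ncceIOError("composite report not found: %s", path)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!nrow(df)) return(newCompositeElements(NULL))
  newCompositeElements(data.frame(
    chrom = df$chrom,
    ceId = df$ce_id, classLabel = df$class,
    spacing2 = as.integer(round(df$spacing_bp * 2)),
    elementId = df$element_id,
    nkxStart = df$nkx_start, nkxEnd = df$nkx_end,
    nkxStrand = df$nkx_strand, nkxMotifId = df$nkx_motif,
    partnerStart = df$partner_start, partnerEnd = df$partner_end,
    partnerStrand = df$partner_strand, partnerMotifId = df$partner_motif,
    syntenyStatus = df$synteny,
    nearestGene = ifelse(df$nearest_gene == ".", NA_character_,
                         df$nearest_gene)))
}
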