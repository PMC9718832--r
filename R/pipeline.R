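#' Assemble a run configuration
#'
#' Collects input paths and every tunable of the screen with its default:
#' spacing windows, the strict conservation threshold, chain direction,
#' optional strict target-side spacing, and the motif set (built-ins unless
#' a motif config file overrides them — the NKX consensus in particular is
#' meant to be overridden that way). The effective, fully resolved
#' configuration is serialized into the output directory by [runScreen()]
#' so a run can be reproduced from it alone.
#'
#' @param queryFasta,targetFasta,conservedBed,chain,geneTable,termMap input
#'   file paths.
#' @param outDir output directory.
#' @param motifConfig optional motif config path (see [readMotifConfig()]).
#' @param minScore strict lower bound on conservation scores.
#' @param chainDirection `"query-first"` or `"target-first"`.
#' @param strictTargetSpacing re-apply the spacing window on target centers.
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(queryFasta, targetFasta, conservedBed, chain,
                      geneTable, termMap, outDir,
                      motifConfig = NULL, minScore = 300,
                      chainDirection = "query-first",
                      strictTargetSpacing = FALSE) {
  cfg <- list(queryFasta = queryFasta, targetFasta = targetFasta,
              conservedBed = conservedBed, chain = chain,
              geneTable = geneTable, termMap = termMap, outDir = outDir,
              motifConfig = motifConfig, minScore = minScore,
              chainDirection = chainDirection,
              strictTargetSpacing = strictTargetSpacing,
              ncceWindow = c(6, 16), wideWindow = c(30, 60))
  class(cfg) <- "RunConfig"
  cfg
}

resolveMotifs <- function(cfg) {
  if (is.null(cfg$motifConfig)) return(builtinMotifs())
  user <- readMotifConfig(cfg$motifConfig)
  roles <- vapply(user, motifRole, character(1))
  if (anyDuplicated(roles))
    ncceUsageError("motif config assigns role '%s' twice",
                   roles[duplicated(roles)][1])
  defs <- builtinMotifs()
  byRole <- setNames(defs, vapply(defs, motifRole, character(1)))
  for (m in user) byRole[[motifRole(m)]] <- m
  setNames(unname(byRole), vapply(byRole, motifId, character(1)))
}

stageSummary <- function(stage, counts) {
  c(list(stage = stage), as.list(counts))
}

#' Run the complete screen
#'
#' Stage order is fixed: scan -> pair -> lift -> assign -> enrich. Each
#' stage writes plain TSV/BED outputs into `outDir` along with a
#' machine-readable stage summary (counts in and out of every filter), and
#' the effective configuration (including the NKX consensus actually used)
#' is written first. All outputs are deterministic: rerunning on unchanged
#' inputs reproduces byte-identical files.
#'
#' @param cfg a [runConfig()].
#' @return Invisibly, a list with per-class `composites` (paired,
#'   untested), `tested` (after synteny), `conserved` (pass-only, with
#'   nearest genes), `geneSets`, `enrichment` (one data.frame per control
#'   class), `summaries`, and `outputs` (file paths).
#' @export
runScreen <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  motifs <- resolveMotifs(cfg)
  eff <- cfg
  eff$motifs <- lapply(motifs, function(m)
    list(motif_id = motifId(m), role = motifRole(m),
         consensus = consensus(m)))
  jsonlite::write_json(unclass(eff), file.path(cfg$outDir, "effective-config.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)

  query <- readGenomeFasta(cfg$queryFasta)
  target <- readGenomeFasta(cfg$targetFasta)
  elements <- readConservedBed(cfg$conservedBed)
  chains <- readChainFile(cfg$chain, cfg$chainDirection)
  genes <- readGeneTable(cfg$geneTable)
  termMap <- readTermMap(cfg$termMap)
  summaries <- list()

  ## scan: all motifs, both strands, then restrict to conserved containers
  byRole <- list()
  scanCounts <- list()
  for (m in motifs) {
    raw <- scanMotif(query, m)
    kept <- assignContainers(raw, elements, cfg$minScore)
    byRole[[motifRole(m)]] <- kept
    scanCounts[[motifRole(m)]] <- c(hits = length(raw), contained = length(kept),
                                    dropped = length(raw) - length(kept))
    writeHitsBed(kept, file.path(cfg$outDir,
                                 sprintf("hits_%s.bed", motifRole(m))))
  }
  summaries$scan <- stageSummary("scan", list(perRole = scanCounts))

  ## pair
  ncceWin <- spacingWindow(cfg$ncceWindow[1], cfg$ncceWindow[2], "NCCE")
  wideWin <- spacingWindow(cfg$wideWindow[1], cfg$wideWindow[2], "WIDE-CONTROL")
  composites <- buildAllClasses(byRole, ncceWin, wideWin)
  for (cl in names(composites))
    writeCompositeTsv(composites[[cl]],
                      file.path(cfg$outDir, sprintf("pairs_%s.tsv", cl)))
  summaries$pair <- stageSummary("pair",
    list(counts = lapply(composites, length)))

  ## lift + conservation filter
  tested <- lapply(composites, function(ces)
    verifySynteny(ces, chains, target, motifs,
                  strictTargetSpacing = cfg$strictTargetSpacing))
  conserved <- lapply(tested, filterConserved)
  for (cl in names(tested))
    writeSyntenyReport(tested[[cl]],
                       file.path(cfg$outDir, sprintf("synteny_%s.tsv", cl)))
  summaries$lift <- stageSummary("lift", list(
    counts = lapply(names(tested), function(cl)
      list(tested = length(tested[[cl]]), pass = length(conserved[[cl]]),
           fail = length(tested[[cl]]) - length(conserved[[cl]])))))

  ## assign nearest genes
  conserved <- lapply(conserved, assignNearestGenes, genes = genes)
  for (cl in names(conserved))
    writeCompositeTsv(conserved[[cl]],
                      file.path(cfg$outDir, sprintf("conserved_%s.tsv", cl)))
  geneSets <- suppressWarnings(buildGeneSets(conserved))
  summaries$assign <- stageSummary("assign",
    list(setSizes = lapply(geneSets, length)))

  ## enrichment of the composite gene set against every control class
  enrichment <- list()
  controls <- setdiff(NCCE_CLASSES, "NCCE")
  for (cl in controls) {
    enrichment[[cl]] <- tryCatch({
      res <- enrichTerms(geneSets$NCCE, geneSets[[cl]], termMap,
                         controlLabel = cl)
      writeEnrichmentTsv(res, file.path(cfg$outDir,
                                        sprintf("enrichment_vs_%s.tsv", cl)))
      res
    }, ncceUsageError = function(e) {
      warning(sprintf("enrichment vs %s skipped: %s", cl, conditionMessage(e)))
      NULL
    })
  }
  summaries$enrich <- stageSummary("enrich",
    list(controls = lapply(enrichment, function(x)
      if (is.null(x)) 0L else nrow(x))))

  jsonlite::write_json(summaries, file.path(cfg$outDir, "stage-summaries.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(composites = composites, tested = tested,
                 conserved = conserved, geneSets = geneSets,
                 enrichment = enrichment, summaries = summaries,
                 outputs = list(dir = cfg$outDir)))
}

## exit codes by failure kind
exitCodeFor <- function(e) {
  if (inherits(e, "ncceUsageError") || inherits(e, "ncceConfigError")) 2L
  else if (inherits(e, "ncceFormatError")) 3L
  else if (inherits(e, "ncceDataError") || inherits(e, "ncceIOError")) 4L
  else 1L
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `run-all` and `evaluate` (the
#' individual stages are exposed through [runScreen()]'s outputs, which are
#' plain TSV/BED files that can be inspected or diffed in isolation).
#' Designed to be called from the thin `inst/scripts/ncce` wrapper; returns
#' the process exit code instead of calling `quit()` so it can be tested
#' in-process.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit code: 0 success, 2 usage/config error, 3 format
#'   error, 4 data/IO error.
#' @export
ncceMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ncce <command> [options]",
    "  simulate  --seed INT --out DIR [--break-rate X] [--genome-length N]",
    "  run-all   --query FA --target FA --conserved BED --chain CHAIN",
    "            --genes TSV --terms TSV --out DIR [--motif-config FILE]",
    "            [--min-score X] [--chain-direction query-first|target-first]",
    "            [--strict-target-spacing]",
    "  evaluate  --run DIR --manifest JSON --out FILE", sep = "\n")
  if (!length(args)) { message(usage); return(2L) }
  cmd <- args[1]; rest <- args[-1]
  opt <- function(name, default = NULL, flag = FALSE) {
    i <- which(rest == paste0("--", name))
    if (!length(i)) return(if (flag) FALSE else default)
    if (flag) return(TRUE)
    if (i[1] == length(rest)) ncceUsageError("--%s needs a value", name)
    rest[i[1] + 1L]
  }
  req <- function(name) {
    v <- opt(name)
    if (is.null(v)) ncceUsageError("missing required input --%s", name)
    v
  }
  run <- function(expr) {
    tryCatch({ expr; 0L }, ncceError = function(e) {
      message("error: ", conditionMessage(e)); exitCodeFor(e)
    })
  }
  switch(cmd,
    "simulate" = run({
      cfg <- simulationConfig(
        seed = as.integer(req("seed")),
        genomeLength = as.numeric(opt("genome-length", 1e6)),
        syntenyBreakRate = as.numeric(opt("break-rate", 0)))
      generateBundle(cfg, req("out"))
    }),
    "run-all" = run({
      cfg <- runConfig(req("query"), req("target"), req("conserved"),
                       req("chain"), req("genes"), req("terms"), req("out"),
                       motifConfig = opt("motif-config"),
                       minScore = as.numeric(opt("min-score", 300)),
                       chainDirection = opt("chain-direction", "query-first"),
                       strictTargetSpacing = opt("strict-target-spacing",
                                                 flag = TRUE))
      runScreen(cfg)
    }),
    "evaluate" = run({
      runDir <- req("run")
      manifest <- readManifest(req("manifest"))
      results <- list(
        composites = setNames(lapply(NCCE_CLASSES, function(cl)
          readCompositeTsv(file.path(runDir, sprintf("pairs_%s.tsv", cl)))),
          NCCE_CLASSES),
        tested = NULL,
        conserved = setNames(lapply(NCCE_CLASSES, function(cl)
          readCompositeTsv(file.path(runDir, sprintf("conserved_%s.tsv", cl)))),
          NCCE_CLASSES),
        geneSets = NULL, enrichment = NULL)
      results$geneSets <- buildGeneSets(results$conserved)
      metrics <- evaluateAgainstManifest(results, manifest)
      jsonlite::write_json(metrics, req("out"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }),
    { message("unknown command '", cmd, "'\n", usage); 2L })
}
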