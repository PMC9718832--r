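#' @import methods
#' @importFrom stats runif rbinom setNames phyper p.adjust
#' @importFrom utils read.table write.table
#' @importFrom tools file_ext
#' @importClassesFrom GenomicRanges GRanges
NULL

## Structured conditions. Every user-facing failure is raised with one of
## these classes so callers (and the CLI) can map failure kind -> exit code.
ncceStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "ncceError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ncceIOError     <- function(fmt, ...) ncceStop("ncceIOError", fmt, ...)
ncceFormatError <- function(fmt, ...) ncceStop("ncceFormatError", fmt, ...)
ncceUsageError  <- function(fmt, ...) ncceStop("ncceUsageError", fmt, ...)
ncceDataError   <- function(fmt, ...) ncceStop("ncceDataError", fmt, ...)
ncceConfigError <- function(fmt, ...) ncceStop("ncceConfigError", fmt, ...)

#' Derive a child RNG seed from a root seed and a component label
#'
#' Each randomised component of the synthetic-data generator draws from its
#' own stream, seeded deterministically from the root seed and a fixed label,
#' so adding or reordering components never perturbs the others.
#'
#' @param seed integer root seed.
#' @param label character scalar naming the component.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
childSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

## known class labels, in canonical order
NCCE_CLASSES <- c("NCCE", "WIDE-CONTROL", "SCRAMBLE-1", "SCRAMBLE-2", "SCRAMBLE-3")
MOTIF_ROLES  <- c("NKX", "COUP", "SCRAMBLE-1", "SCRAMBLE-2", "SCRAMBLE-3")

## partner role consumed by each composite class (NKX is always the anchor)
classPartnerRole <- function(classLabel) {
  switch(classLabel,
    "NCCE" = "COUP", "WIDE-CONTROL" = "COUP",
    "SCRAMBLE-1" = "SCRAMBLE-1", "SCRAMBLE-2" = "SCRAMBLE-2",
    "SCRAMBLE-3" = "SCRAMBLE-3",
    ncceUsageError("unknown composite class '%s'", classLabel))
}
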