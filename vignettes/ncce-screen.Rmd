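---
title: "Screening for conserved NKX-COUP-TFII composite elements"
author: "ncceScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for conserved NKX-COUP-TFII composite elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncceScan)
```

## The model

COUP-TFII is a nuclear receptor that binds direct repeats of the
half-site `GGTC(A/G)`; NKX-family homeodomain factors bind short AT-rich
consensi. A *composite element* in the sense of this package is a
conserved genomic locus where an NKX motif and a partner motif co-occur
at a center-to-center spacing compatible with a DNA-templated
NKX/COUP-TFII heterodimer: close enough to touch, far enough apart not to
overlap. The screen operationalizes this as four filters applied in fixed
order:

1. motif presence (exact IUPAC consensus match, both strands);
2. conservation (hit fully inside a conserved element with log-odds
   score strictly greater than 300);
3. spacing (center-to-center distance within an inclusive window:
   6–16 bp for the composite class, 30–60 bp for the wide-spacing
   negative control, 6–16 bp against scrambled partner motifs for the
   three scrambled controls);
4. synteny (both motifs map contiguously through a chain alignment to a
   second genome and still match their consensus there, on either
   strand).

Surviving elements are assigned to nearest-TSS genes, and the composite
gene set is tested for term enrichment against each control gene set.
The controls are matched by construction: wide-spacing pairs share both
motifs but are unlikely to template a heterodimer; scrambled pairs share
the NKX anchor and base composition of the partner but not its identity.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| COUP consensus | `GGTCR` | IUPAC | the canonical half-site, `GGTC(A/G)` |
| NKX consensus | `TNAAGTG` | IUPAC | a documented stand-in; homeodomain models vary, so this is deliberately config-overridable (`readMotifConfig()`) and recorded in the effective config of every run |
| scrambled partners | `GTACS`, `AGTCS`, `TGGAY` | IUPAC | permutations of the half-site with matched length/composition |
| conservation cutoff | 300, strict `>` | log-odds | elements scoring exactly 300 are excluded |
| composite window | [6, 16] inclusive | bp between centers | excludes overlap of a 7-mer/5-mer pair and covers the spacings that seed the heterodimer biochemically |
| control window | [30, 60] inclusive | bp | same motifs, heterodimer-incompetent spacing |
| chain direction | query-first | — | the first header sequence is the genome being scanned (lifted FROM); `target-first` files are inverted on read |

Spacing uses doubled coordinates (`center2 = 2*start + len - 1`) so
even-length motifs have exact integer centers and no floating point
enters the window comparison; a half-integer spacing is inside the
window iff the rational inequality holds. Both window bounds are read as
inclusive; 6 and 16 bp are retained, 5 and 17 bp are not. These bounds
are named constants (`ncceWindow()`, `wideControlWindow()`), not
scattered literals.

## Numerical and procedural choices

**Consensus scanning, not PWM scoring.** The motif definitions are
degenerate consensi, and no calibrated score threshold accompanies them;
exact IUPAC matching keeps the screen parameter-free and reproducible. A
PWM mode would be an extension, not a default. An `N` in the genome never
satisfies any consensus position — including consensus `N` — so assembly
gaps cannot fake motifs.

**Chain mapping.** An interval maps only if it lies inside one ungapped
block run (zero-gap-adjacent blocks are merged); any gap crossing makes
it unmappable, a conservative stand-in for liftOver's partial-match
behaviour. When several chains cover an interval the highest-scoring one
wins, ties to the lowest chain id — deterministic by construction.
Minus-strand targets are reported on the plus strand, as BED requires.
Mapping is single-direction (query to target); reciprocal-best filtering
is not applied and the synteny report says nothing about the reverse
direction. Target-side spacing is *not* re-checked by default — synteny
requires motif correspondence, not spacing conservation — but
`strictTargetSpacing` re-applies the window on target centers.

**Pairing.** Pairing is restricted to hits sharing a conserved-element
container (motifs are searched within conserved regions, so a pair
spanning two elements is not a composite); a hit inside k qualifying
elements participates once per container. Strand combinations are
unrestricted; palindromic double matches are collapsed by their unordered
interval pair with the plus-strand representative recorded, which is what
makes composite ids deterministic.

**Nearest gene.** Distance is midpoint-to-TSS, with the midpoint kept as
an exact rational on a quadrupled scale. Ties break to the
lexicographically smallest gene id. Elements on a gene-less chromosome
are warned about and excluded from gene sets. Gene sets are gene-level:
two composites sharing a nearest gene contribute it once.

**Enrichment.** The claim being tested is "enriched *compared to
controls*", so the test is a two-set exact comparison (test vs control
gene set), not a test-versus-genome hypergeometric. Genes in both sets
are dropped from both (logged). The one-sided p-value is the exact
hypergeometric tail; odds ratios take a +0.5 Haldane correction when any
cell is zero; BH correction runs across all terms of one control
comparison. The term map is flat — no ontology propagation.

## What the synthetic generator emulates

`generateBundle()` produces: background sequence at a configurable GC
fraction; non-overlapping conserved elements with scores spanning the
300 cutoff; planted composites of every class, one per element, with
concrete motif instances (degenerate positions sampled uniformly, random
strands and orientation) at controlled spacings; a target genome derived
from the query through a generated chain (indels placed strictly between
conserved elements; whole-chromosome inversions optional) with targeted
point mutations destroying planted motifs at the configured break rate;
gene models whose TSSs make each planted composite's dedicated gene its
unique nearest; and a term map in which one term is enriched among genes
near planted composites (membership probability 0.8 vs 0.1, background
terms at 0.15).

Chance motif pairs arising in the random background are *not*
rejection-sampled away: the generator self-scans its own output and adds
them to the truth manifest, so recovery metrics stay exact against a
realistic background. Each randomised component draws from its own
stream derived from the root seed by a fixed label, so adding a component
never perturbs the others, and bundles are byte-identical per seed.

What it does **not** emulate: nucleotide evolution (the target genome is
a literal transform of the query plus targeted mutations), realistic
conservation-score distributions, gene density and TSS clustering of real
genomes, or ontology structure. Perfect recovery on bundles therefore
demonstrates the pipeline's correctness — that every filter implements
its contract exactly — not that the motif definitions would recover the
biological element set in a real genome, which depends on inputs the
package takes as given (the conservation track, the chain quality and the
homeodomain consensus).

## Problem sizes and calibration checks

The default bundle is a 1 Mb query genome over 2 chromosomes with 200
conserved elements and 10 planted composites per class — large enough
that chance pairs occur (and are tracked), small enough that the full
screen runs in seconds. The test suite checks each core operation
against an independent brute-force oracle (window-by-window scan,
cross-product pair enumeration, all-pairs distance minimisation,
per-base chain expansion) on hundreds of random instances, and checks
enrichment p-values against full enumeration of 2×2 tables on universes
up to 30 genes.

Null calibration of the exact test deserves a note: one-sided exact
tests are conservative on coarse supports, so the null rejection
fraction at 0.05 can sit well below 0.05 for small gene sets (about
0.028 at 40+40 genes). The calibration check therefore simulates
term maps over two 1000-gene sets with membership probability 0.5, where
the attainable significance levels are dense and the expected rejection
fraction (~0.047) sits inside the exact binomial 99% band around the
nominal level. This is a property of the discrete test, not a tuning of
the check.

## Known limitations

- Exact consensus matching: a single mismatch (or an N) removes a hit;
  there is no mismatch tolerance.
- The default NKX consensus is a stand-in; results at real loci hinge on
  the homeodomain model supplied through the motif config.
- Conservation input is a pre-called element track; per-base conservation
  scores are out of scope.
- Synteny is two-genome and single-direction; no multi-species support.
- Enrichment treats the term map as flat and independent; parent-term
  propagation and term-term correlation are the caller's concern.

## Session info

```{r}
sessionInfo()
```
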