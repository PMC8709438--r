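---
title: "Comparing bacterial methylomes across cell states with bacmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing bacterial methylomes across cell states with bacmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacmeth)
```

## The biological problem

Rhizobia such as *Rhizobium leguminosarum* live in two radically
different states: free-living soil bacteria, and terminally
differentiated bacteroids inside legume nodule cells — enlarged,
non-dividing, nitrogen-fixing, with increased DNA content. DNA
methylation is the main epigenetic channel available to bacteria, and
three methylated motifs dominate the RCAM1026 methylome: the
CcrM-family cell-cycle motif `GANTC` (N6-methyladenine at position 2),
`GATC` (N4-methylcytosine at position 4), and the
restriction–modification target `GGCGCC` (N4-methylcytosine at
position 3). All three are palindromic under the IUPAC complement, so
each genomic locus carries a methylatable base on both strands.

bacmeth takes a finished assembly (one chromosome plus plasmids), a
gene annotation with COG categories, and per-site modified-base call
tables per condition, and produces the comparisons that matter for
this biology: where the motifs are, how methylated each motif is in
each state on each replicon, whether promoter-borne motifs concentrate
in particular functional categories, and how replicon stoichiometry
differs between states.

## Models and conventions

### Coordinates and palindromic sites

Internally every interval is 0-based half-open on the forward strand;
GFF3/report output is 1-based inclusive and BED/bedGraph output
0-based half-open. A palindromic motif match is **one occurrence**
carrying two strand-specific modified-base coordinates (for `GATC` at
`[s, s+4)`: the + strand C at `s+3`, the − strand C at `s`). Counting
is therefore site-level — consistent in magnitude with per-replicon
motif tables for this genome — while methylation keeps the two strand
calls as **separate observations**, because hemimethylation is exactly
the signal the cell-cycle motifs are expected to show. Output metadata
records this convention on every run.

Overlapping matches are all reported (no greedy rule), and matches
spanning the origin of a circular replicon are found by scanning the
sequence extended with its first `len − 1` bases. Reference positions
with ambiguity codes never match.

### Methylation summaries

The per-site statistic is the percent of modified reads,
`100 · modified / coverage`. Sites with coverage below `min_coverage`
(default **5 reads**; the source data put no threshold on record, and
5 is a conventional floor for per-site nanopore percentages) are
excluded everywhere. All cross-site summaries — genome-wide, windowed,
and per-motif — are **unweighted means of per-site percentages**: the
plotted quantity in methylome figures is a per-position percentage, so
each site gets one vote regardless of its depth. Window profiles
default to **width 5000 bp** (the sliding-window size used in
genome-wide methylation plots) with **step 1000 bp**; both are
configuration, and tiling windows (`step = width`) make the windowed
means aggregate exactly to the genome-wide mean.

### Promoters and enrichment

A promoter is the **100 bp immediately upstream of the start codon**,
strand-aware. On circular replicons the window wraps across the origin
rather than clipping — replicons are circular molecules and the origin
is an arbitrary rotation point; on linear sequences it clips. Promoters
are not trimmed when they run into an upstream gene, since the
definition is purely positional. An occurrence is "in" a promoter when
its full match interval overlaps it by ≥ 1 base (not only the modified
position), and a gene's foreground status is per gene: it either has a
motif in its promoter or not, however many hits there are.

Enrichment uses the upper-tail hypergeometric probability
`P(X >= k)`, `X ~ Hypergeom(N, K, n)`, with the **background universe
restricted to genes carrying at least one COG category** — unannotated
genes cannot enter the foreground-versus-category cross table, and
including them would only dilute `N` with uninformative rows; the
choice is recorded in the output. Genes with several categories count
once in each (standard COG practice). The test is one-sided
over-representation by default (depletion behind a flag), adjusted by
Benjamini–Hochberg across tested categories. Note that BH-adjusted
values are *not* idempotent under re-adjustment; the tests assert the
true guarantees (adjusted ≥ raw, rank preservation).

### Copy number

Per condition, each replicon's arithmetic mean depth is divided by the
chromosome's; with native-DNA long-read libraries no normalisation is
applied, so the ratio directly estimates relative copy number. The
mean is untrimmed by default (the ratio is defined on plain means);
a trimmed-mean option exists for tracks with origin/terminus coverage
waves or mapping artefacts. Ratios are reported to two decimals.

## The synthetic-data generator

`simulate_bundle()` generates: an i.i.d. random genome at per-replicon
GC contents; non-overlapping stranded genes with COG letters drawn from
a frequency table; per-position read depth `Poisson(mean_depth ×
copy_ratio)`; and per-site modified-read counts `Binomial(coverage,
p)`, where `p` is the motif's methylation probability at scanned
modified sites (the longer pattern wins coincident sites) and the
base-specific background elsewhere. Every unambiguous genome position
yields exactly one call site: an A site on the strand reading A, or a
C site on the strand reading C.

The packaged profiles (`rcam1026_profile()`) carry the published
RCAM1026 methylome parameters: GGCGCC at 0.98 in both states;
bacteroid backgrounds A = 0.75 and C = 0.46 versus a culture C
background of 0.38; bacteroid GANTC at 0.98 and GATC at 0.50 on the
chromosome / 0.40 on plasmids; culture copy ratios 0.58 / 0.50 / 0.48 /
0.60 (symbiotic plasmid) and bacteroid ratios 0.91 / 0.94 / 0.97 /
0.59. Three culture-state values are only described qualitatively in
the source data and are package choices, fixed once: GANTC baseline
**0.55** (culture GANTC shows a position-dependent pattern rather than
a single level), adenine background **0.40** (adenine methylation is
reported as much lower in the free-living state), and GATC **0.25**
(reported only as below the cytosine background).

The default problem size is a 500-kb chromosome with 63/66/84/27-kb
plasmids at the published GC contents and 50× depth — large enough
that every per-motif estimate rests on hundreds to thousands of sites
(binomial standard errors well under one percentage point) while a
full two-condition bundle simulates in seconds.

What the generator does **not** emulate — and hence what passing
recovery tests do not show about real data: position-dependent
methylation (the Ori→Ter "bow" of cell-cycle methylation; a
`position_effect` hook accepts a user function but nothing is built
in), phase variation across the population, read-length/mappability
structure in coverage, correlated errors between neighbouring sites,
and basecaller-specific biases of modified-base models. Recovery on
simulation validates the aggregation arithmetic and the pipeline
plumbing, not the upstream calling.

## Numerical and degenerate-input choices

- Percentages are reported to two decimals; tests compare with
  absolute tolerances, never string equality.
- A replicon consisting only of ambiguous bases has undefined GC
  content (error), as does a base with no included site
  (genome-wide) — per-replicon gaps are `NA`.
- Call records with `modified > coverage`, unknown replicons, or
  out-of-range positions are dropped with a logged count; structurally
  malformed lines are an error naming the line.
- `mod_type = "any"` lets pooled cytosine calls match either 4mC or
  5mC motifs when the caller does not separate them.
- Windows are clipped at the replicon end; empty windows are emitted
  with `n_sites = 0` so tracks stay rectangular.
- The motif-in-promoter count tallies distinct occurrences overlapping
  at least one promoter (an occurrence straddling two promoters counts
  once per promoter in the per-gene table but once in the per-replicon
  count).

## Known limitations

- Site-level palindromic counting is a convention, not ground truth;
  per-strand counts can be obtained by scanning the two strands of a
  non-palindromic alias. Published per-replicon counts may follow
  either convention.
- The copy-number estimate assumes uniform mappability and no GC
  bias; it is a ratio of plain means by design.
- Enrichment p-values inherit the usual caveats of the hypergeometric
  model: genes are treated as exchangeable and promoter sharing
  between neighbouring genes is ignored.

## A minimal run

```{r example, eval = FALSE}
bundle <- simulate_bundle(seed = 42)
occ <- bundle$occurrences
count_by_replicon(occ, bundle$assembly)
mm <- lapply(bundle$tables, motif_methylation, occurrences = occ,
             assembly = bundle$assembly)
compare_conditions(mm)
relative_copy_number(bundle$depth$cell_culture, "Chromosome")
```
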