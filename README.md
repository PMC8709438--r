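# bacmeth

Analysis of bacterial DNA methylation (6mA / 4mC / 5mC) in
multi-replicon genomes from nanopore modified-base calls, built around
the methylome of *Rhizobium leguminosarum* RCAM1026 in its two cell
states: free-living culture and the terminally differentiated,
nitrogen-fixing bacteroids formed in pea root nodules.

It is written for microbiologists comparing per-site modified-base call
tables (e.g. aggregated Megalodon output) between conditions on a
finished assembly of one chromosome plus plasmids. The package covers:

- **Degenerate motif scanning** — all occurrences of IUPAC motifs such
  as the CcrM-type `GANTC` (6mA at position 2), `GATC` (4mC at
  position 4) and the restriction–modification target `GGCGCC` (4mC at
  position 3) on both strands, including matches spanning the origin of
  circular replicons. A palindromic motif is reported once per locus
  with the modified-base coordinate on each strand.
- **Methylation summaries** — per-site percent methylated
  (`100·modified/coverage`, sites under a coverage threshold excluded),
  genome-wide and per-replicon means per base, 5-kb sliding-window
  profiles (bedGraph), per-motif means with the same-base background
  attached, and condition comparisons. Cross-site summaries are
  unweighted means of per-site percentages.
- **Promoter intersection and COG enrichment** — promoters are the
  100 bp upstream of each start codon (strand-aware, wrapping circular
  origins); genes with a motif in their promoter are tested for
  COG-category over-representation with the upper-tail hypergeometric
  probability P(X ≥ k), X ~ Hypergeom(N, K, n), and
  Benjamini–Hochberg FDR across categories.
- **Replicon copy number** — per-replicon mean read depth normalised to
  the chromosome per condition; for native-DNA libraries this ratio
  estimates relative replicon copy number.
- **Synthetic data** — a generator for genomes, COG-labelled
  annotations, Poisson coverage and binomial call tables, with packaged
  profiles (`rcam1026_profile()`) whose parameters are the published
  RCAM1026 methylome features, so the whole pipeline is testable
  without sequencing data.

## Worked example

Simulate both conditions at the package's default problem size (500-kb
chromosome plus four plasmids, 50× depth) and run the analysis:

```r
library(bacmeth)

bundle <- simulate_bundle(seed = 42)   # two packaged emulation profiles
occ <- bundle$occurrences

count_by_replicon(occ, bundle$assembly)
#>    motif Chromosome pRL10 pRL11 pRL12 pSym total
#> 1  GANTC       1720   204   227   306  101  2558
#> 2   GATC       1762   268   239   264   84  2617
#> 3 GGCGCC        412    43    45    62   12   574

mm <- lapply(bundle$tables, motif_methylation, occurrences = occ,
             assembly = bundle$assembly)
cmp <- compare_conditions(mm)
subset(cmp, replicon == "genome",
       c(motif, percent_bacteroid, percent_cell_culture,
         diff_bacteroid_minus_cell_culture))
#>     motif percent_bacteroid percent_cell_culture diff_bacteroid_minus_cell_culture
#> 6   GANTC              98.0                 55.0                            42.928
#> 12   GATC              46.7                 25.0                            21.739
#> 18 GGCGCC              98.1                 97.9                             0.162

relative_copy_number(bundle$depth$cell_culture, "Chromosome")
#>      condition   replicon mean_depth ratio
#> 1 cell_culture Chromosome         50  1.00
#> 2 cell_culture      pRL10         29  0.58
#> 3 cell_culture      pRL11         25  0.50
#> 4 cell_culture      pRL12         24  0.48
#> 5 cell_culture       pSym         30  0.60
```

The motif table counts occurrence loci per replicon. The comparison
shows the expected biology of the emulation: GANTC adenine methylation
near-complete (98%) only in bacteroids, GGCGCC effectively fully
methylated in both states (the R–M system target), and GATC
intermediate with a strong state difference. The copy-number table
recovers the planted under-representation of the symbiotic plasmid
(ratio 0.60) and the other plasmids in free-living culture.

The same analyses run from the shell via the thin CLI
(`exec/bacmeth <scan|methylation|abundance|enrich|simulate|report>
--config run.yaml`) on real FASTA / GFF3 / bedMethyl inputs.

Users holding the deposited RCAM1026 assembly (GenBank
CP084696–CP084700) can check their copy with
`verify_reference_assembly()`, which reports the chromosome length, GC
percent and GANTC site count.

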