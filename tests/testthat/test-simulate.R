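# Synthetic data generator: genomes, annotations, calls, depth.

test_that("make_genome hits the requested GC content and is reproducible", {
  asm <- make_genome(c(chr = 100000L), gc_percent = 61, seed = 1)
  expect_lt(abs(gc_content(asm)[["chr"]] - 61), 1)
  asm2 <- make_genome(c(chr = 100000L), gc_percent = 61, seed = 1)
  expect_identical(as.character(asm$replicons), as.character(asm2$replicons))
  pure <- make_genome(c(chr = 2000L), gc_percent = 100, seed = 2)
  expect_equal(gc_content(pure)[["chr"]], 100)
  roster <- make_genome(rcam1026_replicons(), seed = 3)
  expect_equal(names(roster$replicons),
               c("Chromosome", "pRL10", "pRL11", "pRL12", "pSym"))
})

test_that("make_genes places disjoint stranded genes with COG labels", {
  asm <- make_genome(c(chr = 100000L), seed = 4)
  genes <- make_genes(asm, 10, seed = 5)
  expect_equal(nrow(genes), 10L)
  ord <- genes[order(genes$start), ]
  expect_true(all(ord$start[-1] >= ord$end[-nrow(ord)]))
  expect_true(all(genes$end <= 100000L))
  # all-L frequencies label every gene L
  only_l <- make_genes(asm, 10, cog_frequencies = c(L = 1), seed = 6)
  expect_true(all(only_l$cog == "L"))
  # determinism
  again <- make_genes(asm, 10, seed = 5)
  expect_identical(as.data.frame(genes), as.data.frame(again))
  expect_error(make_genes(genome_assembly(c(chr = "ACGTACGT")), 5),
               "too small")
})

small_profile <- function(label = "x", gantc = 0.9, bgA = 0.3, bgC = 0.2,
                          depth = 40, ratio = c(chr = 1)) {
  condition_profile(label,
                    motif_meth_prob = list(GANTC = gantc),
                    background_prob = c(A = bgA, C = bgC),
                    replicon_copy_ratio = ratio, mean_depth = depth)
}

test_that("simulate_calls obeys degenerate probability settings", {
  asm <- make_genome(c(chr = 5000L), seed = 7)
  motifs <- list(iupac_motif("GANTC", 2, "6mA"))
  zero <- condition_profile("zero", list(GANTC = 0),
                            c(A = 0, C = 0), c(chr = 1), 30)
  tab0 <- simulate_calls(asm, motifs, zero, seed = 8)
  expect_true(all(tab0$modified == 0L))
  allc <- condition_profile("allc", list(GANTC = 0),
                            c(A = 0, C = 1), c(chr = 1), 30)
  tab1 <- simulate_calls(asm, motifs, allc, seed = 9)
  non_motif_c <- tab1$base == "C" & tab1$coverage > 0
  expect_true(all(tab1$modified[non_motif_c] == tab1$coverage[non_motif_c]))
  # every position of the genome yields exactly one site
  expect_equal(nrow(tab0), 5000L)
  # determinism
  expect_identical(as.data.frame(simulate_calls(asm, motifs, zero, seed = 8)),
                   as.data.frame(tab0))
})

test_that("planted motif methylation is recovered by the analysis", {
  asm <- make_genome(c(chr = 100000L), gc_percent = 61, seed = 10)
  motifs <- list(GANTC = iupac_motif("GANTC", 2, "6mA"))
  prof <- small_profile(gantc = 0.9, bgA = 0.3, depth = 50)
  occ <- scan_motifs(asm, motifs)
  tab <- simulate_calls(asm, motifs, prof, seed = 11, occurrences = occ)
  mm <- motif_methylation(tab, occ, asm)
  g <- mm[mm$replicon == "genome", ]
  expect_gt(g$n_obs, 500)
  expect_lt(abs(g$mean_percent - 90), 2)
  gb <- genome_base_methylation(tab, asm, "A")
  expect_lt(abs(gb$mean_percent[gb$replicon == "genome"] - 30), 2)
})

test_that("longer motifs win coincident modified sites", {
  # GCGC inside GGCGCC shares the 6-mer's modified C; the longer, more
  # specific pattern's probability must apply at the shared site.
  asm <- genome_assembly(c(chr = paste0(strrep("A", 30), "GGCGCC",
                                        strrep("A", 30))),
                         topology = "linear")
  motifs <- list(iupac_motif("GGCGCC", 3, "4mC"),
                 iupac_motif("GCGC", 2, "4mC"))
  prof <- condition_profile("t", list(GGCGCC = 1, GCGC = 0),
                            c(A = 0, C = 0), c(chr = 1), 200)
  tab <- simulate_calls(asm, motifs, prof, seed = 12)
  occ6 <- scan_motif(asm, motifs[[1]])
  site <- tab[tab$position == occ6$mod_site_plus & tab$strand == "+", ]
  expect_equal(site$modified, site$coverage)  # 6-mer probability applied
})

test_that("simulate_depth scales with the copy ratio", {
  asm <- make_genome(c(chr = 30000L, p1 = 30000L), seed = 13)
  prof <- small_profile(ratio = c(chr = 1, p1 = 0.5), depth = 40)
  s <- simulate_depth(asm, prof, seed = 14)
  expect_lt(abs(s$mean_depth[s$replicon == "chr"] - 40), 0.5)
  expect_lt(abs(s$mean_depth[s$replicon == "p1"] - 20), 0.5)
  expect_identical(simulate_depth(asm, prof, seed = 14)$mean_depth,
                   s$mean_depth)
  tr <- simulate_depth(asm, prof, seed = 14, track = TRUE)
  expect_equal(sum(tr$track$end - tr$track$start), 60000L)
})

test_that("packaged emulation profiles carry the published parameters", {
  bact <- rcam1026_profile("bacteroid")
  expect_equal(bact$background_prob[["A"]], 0.75)
  expect_equal(bact$background_prob[["C"]], 0.46)
  expect_equal(unlist(bact$motif_meth_prob$GANTC), c(GANTC = 0.98),
               ignore_attr = TRUE)
  expect_equal(unlist(bact$motif_meth_prob$GATC)[["Chromosome"]], 0.5)
  expect_equal(unlist(bact$motif_meth_prob$GATC)[["default"]], 0.4)
  expect_equal(bact$replicon_copy_ratio[["pSym"]], 0.59)
  cult <- rcam1026_profile("cell_culture")
  expect_equal(cult$background_prob[["C"]], 0.38)
  expect_equal(cult$replicon_copy_ratio[["pSym"]], 0.6)
  expect_equal(unlist(cult$motif_meth_prob$GGCGCC), 0.98,
               ignore_attr = TRUE)
})

test_that("bundles serialise their ground truth alongside the data", {
  roster <- data.frame(name = c("chr", "p1"), length = c(20000L, 6000L),
                       gc = c(61, 58))
  prof <- list(x = small_profile(ratio = c(chr = 1, p1 = 0.5)))
  bundle <- simulate_bundle(profiles = prof, seed = 15,
                            replicons = roster, n_genes = 30)
  dir <- tempfile()
  paths <- write_bundle(bundle, dir)
  expect_true(all(file.exists(unlist(paths))))
  gt <- jsonlite::read_json(paths$ground_truth)
  expect_equal(gt$seed, 15L)
  expect_equal(gt$profiles$x$background_prob$A, 0.3)
  # round-trip: the written FASTA/GFF reproduce the in-memory objects
  back <- read_assembly(paths$fasta, chromosome_name = "chr")
  expect_identical(as.character(back$replicons),
                   as.character(bundle$assembly$replicons))
  genes <- read_genes(paths$gff, back)
  expect_equal(genes$start, bundle$genes$start)
  expect_equal(genes$cog, bundle$genes$cog)
})
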