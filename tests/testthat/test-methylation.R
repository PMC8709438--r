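# Per-site call ingestion and methylation summaries.

test_that("read_calls parses simple_tsv and rejects impossible records", {
  asm <- genome_assembly(c(chr = random_dna(100, seed = 1)))
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chr\t10\t+\tA\t6mA\t20\t15",
               "chr\t11\t+\tA\t6mA\t20\t21",    # modified > coverage
               "plasmidX\t5\t+\tC\t4mC\t10\t5"),  # unknown replicon
             path)
  expect_message(tab <- read_calls(path, asm, "simple_tsv", "culture"),
                 "dropped 2")
  expect_equal(nrow(tab), 1L)
  expect_equal(site_fraction(tab, min_coverage = 5), 75)
  expect_equal(attr(tab, "condition"), "culture")
})

test_that("bedMethyl coverage and percent columns recover modified counts", {
  asm <- genome_assembly(c(chr = random_dna(100, seed = 2)))
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr\t10\t11\ta\t0\t+\t10\t11\t0,0,0\t10\t50",
               "chr\t20\t21\tm\t0\t-\t20\t21\t0,0,0\t7\t100"),
             path)
  tab <- read_calls(path, asm, "bedmethyl")
  expect_equal(tab$modified, c(5L, 7L))
  expect_equal(tab$base, c("A", "C"))
  expect_equal(tab$mod_type, c("6mA", "5mC"))
})

test_that("malformed lines are reported with their position", {
  asm <- genome_assembly(c(chr = random_dna(100, seed = 3)))
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chr\t10\t+\tA\t6mA\t20\t15",
               "chr\tnotanumber\t+\tA\t6mA\t20\t15"), path)
  expect_error(read_calls(path, asm), "line 2")
})

test_that("site_fraction applies the coverage threshold", {
  expect_equal(site_fraction(10, 10), 100)
  expect_true(is.na(site_fraction(0, 0)))
  expect_true(is.na(site_fraction(4, 2, min_coverage = 5)))
  expect_equal(site_fraction(5, 2, min_coverage = 5), 40)
})

test_that("genome_base_methylation is an unweighted mean over sites", {
  asm <- genome_assembly(c(chr = random_dna(2000, seed = 4)))
  tab <- make_table("chr", c(10L, 20L), "+", "A",
                    coverage = c(10L, 1000L), modified = c(0L, 1000L))
  gb <- genome_base_methylation(tab, asm, "A")
  expect_equal(gb$mean_percent[gb$replicon == "genome"], 50)
  expect_equal(gb$n_sites[gb$replicon == "genome"], 2L)
  # all sites fully methylated
  tab2 <- make_table("chr", 1:5, "+", "C", coverage = 10L, modified = 10L)
  gb2 <- genome_base_methylation(tab2, asm, "C")
  expect_equal(gb2$mean_percent[gb2$replicon == "genome"], 100)
  expect_error(genome_base_methylation(tab2, asm, "A"), "no included")
})

test_that("binomial site fractions recover their generating mean", {
  asm <- genome_assembly(c(chr = random_dna(30000, seed = 5)))
  set.seed(6)
  n <- 10000L
  tab <- make_table("chr", seq_len(n) - 1L, "+", "A", coverage = 30L,
                    modified = rbinom(n, 30L, 0.75))
  gb <- genome_base_methylation(tab, asm, "A")
  expect_lt(abs(gb$mean_percent[gb$replicon == "genome"] - 75), 1)
})

test_that("window_profile tiles replicons and matches a brute-force oracle", {
  asm <- genome_assembly(c(chr = random_dna(10000, seed = 7)))
  set.seed(8)
  n <- 800L
  pos <- sort(sample(0:9999, n))
  tab <- make_table("chr", pos, "+", "C", coverage = 20L,
                    modified = rbinom(n, 20L, 0.5))
  prof <- window_profile(tab, asm, "C", width = 5000, step = 5000)
  expect_equal(nrow(prof), 2L)
  expect_equal(prof$window_start, c(0L, 5000L))
  # sliding windows against direct re-aggregation
  prof2 <- window_profile(tab, asm, "C", width = 3000, step = 700)
  frac <- 100 * tab$modified / tab$coverage
  for (i in seq_len(nrow(prof2))) {
    sel <- pos >= prof2$window_start[i] & pos < prof2$window_end[i]
    expect_equal(prof2$n_sites[i], sum(sel))
    if (sum(sel) > 0) {
      expect_equal(prof2$percent_methylated[i], mean(frac[sel]))
    } else {
      expect_true(is.na(prof2$percent_methylated[i]))
    }
  }
  # uniform 50% sites give 50 everywhere
  tab3 <- make_table("chr", pos, "+", "C", coverage = 20L, modified = 10L)
  prof3 <- window_profile(tab3, asm, "C", width = 5000, step = 1000)
  expect_true(all(prof3$percent_methylated[prof3$n_sites > 0] == 50))
})

test_that("genome mean equals site-weighted mean of tiling windows", {
  asm <- genome_assembly(c(chr = random_dna(10000, seed = 9)))
  set.seed(10)
  n <- 600L
  pos <- sort(sample(0:9999, n))
  tab <- make_table("chr", pos, "+", "A", coverage = 25L,
                    modified = rbinom(n, 25L, 0.7))
  gb <- genome_base_methylation(tab, asm, "A")
  prof <- window_profile(tab, asm, "A", width = 1000, step = 1000)
  keep <- prof$n_sites > 0
  weighted <- sum(prof$percent_methylated[keep] * prof$n_sites[keep]) /
    sum(prof$n_sites[keep])
  expect_equal(gb$mean_percent[gb$replicon == "genome"], weighted)
})

test_that("palindromic loci contribute two strand observations", {
  asm <- genome_assembly(c(chr = "AAGATCAA"), topology = "linear")
  occ <- scan_motif(asm, iupac_motif("GATC", 4, "4mC"))
  # + strand C at 5, - strand C at 2
  tab <- make_table("chr", c(5L, 2L), c("+", "-"), "C",
                    coverage = c(10L, 10L), modified = c(10L, 0L))
  mm <- motif_methylation(tab, occ, asm)
  g <- mm[mm$replicon == "genome", ]
  expect_equal(g$mean_percent, 50)
  expect_equal(g$n_sites_used, 1)
  expect_equal(g$n_obs, 2)
  # both strand calls under the threshold exclude the locus
  low <- make_table("chr", c(5L, 2L), c("+", "-"), "C",
                    coverage = c(3L, 4L), modified = c(3L, 0L))
  mm_low <- motif_methylation(low, occ, asm)
  expect_equal(mm_low$n_sites_used[mm_low$replicon == "genome"], 0)
  # absent modification type is signalled
  tab_a <- make_table("chr", 1L, "+", "A", 10L, 5L)
  expect_error(motif_methylation(tab_a, occ, asm), "4mC")
})

test_that("motif covering all base sites reproduces the genome-wide mean", {
  # every C in the table is a GATC modified site
  asm <- genome_assembly(c(chr = "AAGATCAAGATCAA"), topology = "linear")
  occ <- scan_motif(asm, iupac_motif("GATC", 4, "4mC"))
  sites <- rbind(data.frame(position = occ$mod_site_plus, strand = "+"),
                 data.frame(position = occ$mod_site_minus, strand = "-"))
  set.seed(11)
  tab <- make_table("chr", sites$position, sites$strand, "C",
                    coverage = 20L, modified = rbinom(nrow(sites), 20L, 0.6))
  mm <- motif_methylation(tab, occ, asm)
  gb <- genome_base_methylation(tab, asm, "C")
  expect_equal(mm$mean_percent[mm$replicon == "genome"],
               gb$mean_percent[gb$replicon == "genome"])
})

test_that("equal coverages make summaries invariant to the threshold", {
  asm <- genome_assembly(c(chr = random_dna(1000, seed = 12)))
  set.seed(13)
  tab <- make_table("chr", 0:99, "+", "A", coverage = 12L,
                    modified = rbinom(100, 12L, 0.4))
  g1 <- genome_base_methylation(tab, asm, "A", min_coverage = 1)
  g2 <- genome_base_methylation(tab, asm, "A", min_coverage = 12)
  expect_equal(g1$mean_percent, g2$mean_percent)
})

test_that("compare_conditions reports zero differences for identical tables", {
  asm <- genome_assembly(c(chr = "AAGATCAAGATCAA"), topology = "linear")
  occ <- scan_motif(asm, iupac_motif("GATC", 4, "4mC"))
  set.seed(14)
  mk <- function(cond) {
    sites <- rbind(data.frame(position = occ$mod_site_plus, strand = "+"),
                   data.frame(position = occ$mod_site_minus, strand = "-"))
    make_table("chr", sites$position, sites$strand, "C", coverage = 20L,
               modified = 10L, condition = cond)
  }
  s1 <- motif_methylation(mk("a"), occ, asm)
  s2 <- motif_methylation(mk("b"), occ, asm)
  cmp <- compare_conditions(list(a = s1, b = s2))
  expect_true(all(cmp$diff_a_minus_b == 0, na.rm = TRUE))
  expect_true(all(cmp$pooled_diff_a_minus_b == 0, na.rm = TRUE))
  expect_error(compare_conditions(list(a = s1)), "at least two")
})
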