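# Degenerate motif scanning and region intersection.

test_that("IUPAC reverse complement and palindrome detection", {
  expect_equal(reverse_complement("GANTC"), "GANTC")
  expect_equal(reverse_complement("GGCGCC"), "GGCGCC")
  expect_equal(reverse_complement("GAT"), "ATC")
  expect_true(is_palindromic("GATC"))
  expect_true(is_palindromic("GANTC"))
  expect_false(is_palindromic("GAATC"))
  # agreement with an independent complement table on random patterns
  set.seed(9)
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "N")
  for (i in 1:20) {
    pat <- paste(sample(codes, sample(3:8, 1), replace = TRUE),
                 collapse = "")
    expect_equal(reverse_complement(pat), oracle_revcomp(pat))
  }
})

test_that("motif definitions validate the modified position", {
  m <- iupac_motif("GANTC", 2, "6mA")
  expect_equal(m$modified_base, "A")
  expect_error(iupac_motif("GANTC", 9, "6mA"), "outside")
  expect_error(iupac_motif("GATC", 1, "4mC"), "cannot carry")  # G is not C-compatible
  expect_error(iupac_motif("GAXTC", 2, "6mA"), "invalid")
  # N at the modified position is A-compatible
  expect_silent(iupac_motif("GANTC", 3, "6mA"))
})

test_that("scan finds degenerate matches with documented conventions", {
  asm1 <- genome_assembly(c(chr = "GAATC"), topology = "linear")
  occ <- scan_motif(asm1, iupac_motif("GANTC", 2, "6mA"))
  expect_equal(occ$start, 0L)
  expect_equal(occ$mod_site_plus, 1L)
  expect_equal(occ$mod_site_minus, 3L)

  asm2 <- genome_assembly(c(chr = "GATCGATC"), topology = "linear")
  occ2 <- scan_motif(asm2, iupac_motif("GATC", 4, "4mC"))
  expect_equal(occ2$start, c(0L, 4L))
  expect_equal(occ2$strand, c("+", "+"))  # palindromic: one row per locus

  asm3 <- genome_assembly(c(chr = "GATGATC"), topology = "linear")
  occ3 <- scan_motif(asm3, iupac_motif("GATC", 4, "4mC"))
  expect_equal(occ3$start, 3L)
})

test_that("ambiguous reference positions never match", {
  asm <- genome_assembly(c(chr = "GANTCAAA"), topology = "linear")
  occ <- scan_motif(asm, iupac_motif("GANTC", 2, "6mA"))
  expect_equal(nrow(occ), 0L)
})

test_that("origin-spanning matches are found on circular replicons only", {
  # GA | ... | TC: GATC wraps the origin
  seq <- paste0("TC", strrep("A", 20), "GA")
  circ <- genome_assembly(c(chr = seq), topology = "circular")
  lin <- genome_assembly(c(chr = seq), topology = "linear")
  m <- iupac_motif("GATC", 4, "4mC")
  occ_c <- scan_motif(circ, m)
  occ_l <- scan_motif(lin, m)
  expect_equal(nrow(occ_c), 1L)
  expect_equal(occ_c$start, 22L)
  expect_equal(occ_c$end, 26L)
  expect_equal(occ_c$mod_site_plus, 1L)   # wraps to position 1
  expect_equal(occ_c$mod_site_minus, 22L)
  expect_equal(nrow(occ_l), 0L)
})

test_that("scan counts equal the per-offset oracle on random sequences", {
  motifs <- list(iupac_motif("GANTC", 2, "6mA"),
                 iupac_motif("GATC", 4, "4mC"),
                 iupac_motif("GGCGCC", 3, "4mC"),
                 iupac_motif("GGATC", 5, "4mC"))  # non-palindromic
  set.seed(21)
  for (i in 1:5) {
    s <- random_dna(2000, gc = 0.61)
    asm <- genome_assembly(c(chr = s), topology = "linear")
    for (m in motifs) {
      occ <- scan_motif(asm, m)
      expect_identical(nrow(occ), length(oracle_match_starts(s, m$pattern)) +
                         if (is_palindromic(m)) 0L else
                           length(oracle_match_starts(s, reverse_complement(m$pattern))),
                       info = m$pattern)
    }
  }
})

test_that("strand symmetry: minus-strand count of m equals plus count of rc(m)", {
  set.seed(33)
  s <- random_dna(3000, gc = 0.5)
  asm <- genome_assembly(c(chr = s), topology = "linear")
  m <- iupac_motif("GGATC", 5, "4mC")
  rc <- iupac_motif(reverse_complement("GGATC"), 4, "4mC")  # GATCC, C at 4
  occ_m <- scan_motif(asm, m)
  occ_rc <- scan_motif(asm, rc)
  expect_equal(sum(occ_m$strand == "-"), sum(occ_rc$strand == "+"))
  expect_equal(sum(occ_m$strand == "+"), sum(occ_rc$strand == "-"))
})

test_that("replacing N with a concrete base never increases the count", {
  set.seed(34)
  s <- random_dna(3000, gc = 0.5)
  asm <- genome_assembly(c(chr = s), topology = "linear")
  n_degenerate <- nrow(scan_motif(asm, iupac_motif("GANTC", 2, "6mA")))
  for (b in c("A", "C", "G", "T")) {
    concrete <- iupac_motif(sub("N", b, "GANTC"), 2, "6mA")
    expect_lte(nrow(scan_motif(asm, concrete)), n_degenerate)
  }
})

test_that("per-replicon scan equals scan of concatenation away from junction", {
  set.seed(35)
  a <- random_dna(1500, gc = 0.5)
  b <- random_dna(1500, gc = 0.5)
  m <- iupac_motif("GATC", 4, "4mC")
  two <- genome_assembly(c(r1 = a, r2 = b), topology = "linear")
  cat_asm <- genome_assembly(c(r = paste0(a, b)), topology = "linear")
  occ_two <- scan_motif(two, m)
  occ_cat <- scan_motif(cat_asm, m)
  # drop junction-spanning matches from the concatenation
  junction <- occ_cat$start > 1500 - 4 & occ_cat$start < 1500
  expect_equal(nrow(occ_cat) - sum(junction), nrow(occ_two))
})

test_that("count_by_replicon tabulates sites with zero-filled cells", {
  asm <- toy_assembly()  # chr has GATC x2 + GANTC + GGCGCC, p1 has GATC
  occ <- scan_motifs(asm, rcam1026_motifs())
  counts <- count_by_replicon(occ, asm)
  expect_equal(counts$chr[counts$motif == "GATC"], 2L)
  expect_equal(counts$p1[counts$motif == "GATC"], 1L)
  expect_equal(counts$p1[counts$motif == "GGCGCC"], 0L)
  expect_equal(counts$total, counts$chr + counts$p1)
  # empty occurrence set keeps requested rows at zero
  none <- occ[0, ]
  z <- count_by_replicon(none, asm, motifs = "GANTC")
  expect_equal(z$total, 0L)
})

test_that("promoter intersection uses >= 1 base overlap of the full match", {
  asm <- genome_assembly(c(chr = random_dna(1000, seed = 6)),
                         topology = "linear")
  occ <- data.frame(motif = "GATC", replicon = "chr",
                    start = c(100L, 95L), end = c(105L, 100L),
                    strand = "+", palindromic = TRUE,
                    mod_site_plus = c(103L, 98L),
                    mod_site_minus = c(100L, 95L),
                    mod_type = "4mC", mod_base = "C",
                    stringsAsFactors = FALSE)
  class(occ) <- c("motif_occurrences", "data.frame")
  regions <- data.frame(gene_id = "g1", replicon = "chr", start = 100L,
                        end = 200L, strand = "+",
                        stringsAsFactors = FALSE)
  res <- intersect_with_regions(occ, regions, asm)
  expect_equal(res$counts$chr, 1L)  # [95,100) does not overlap [100,200)
  expect_true(res$gene_flags$has_motif)
  expect_equal(res$gene_flags$n_occurrences, 1L)
})

test_that("intersection counts match a quadratic all-pairs oracle", {
  set.seed(55)
  asm <- genome_assembly(c(chr = random_dna(5000, gc = 0.61)),
                         topology = "linear")
  occ <- scan_motifs(asm, rcam1026_motifs())
  starts <- sample(0:4900, 40)
  regions <- data.frame(gene_id = sprintf("g%02d", 1:40), replicon = "chr",
                        start = starts, end = starts + 100L, strand = "+",
                        stringsAsFactors = FALSE)
  res <- intersect_with_regions(occ, regions, asm)
  for (m in unique(occ$motif)) {
    om <- occ[occ$motif == m, ]
    in_any <- vapply(seq_len(nrow(om)), function(i) {
      any(om$start[i] < regions$end & om$end[i] > regions$start)
    }, logical(1))
    expect_equal(res$counts$chr[res$counts$motif == m], sum(in_any),
                 info = m)
  }
})

test_that("occurrence BED export splits origin-wrapping matches", {
  seq <- paste0("TC", strrep("A", 20), "GA")
  asm <- genome_assembly(c(chr = seq), topology = "circular")
  occ <- scan_motif(asm, iupac_motif("GATC", 4, "4mC"))
  bed <- tempfile(fileext = ".bed")
  occurrences_to_bed(occ, asm, bed)
  lines <- strsplit(readLines(bed), "\t")
  expect_length(lines, 2L)
  expect_setequal(vapply(lines, function(x) paste(x[2], x[3]), ""),
                  c("22 24", "0 2"))
})
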