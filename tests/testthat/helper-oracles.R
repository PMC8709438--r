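# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles share no code with the package implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

oracle_revcomp <- function(pattern) {
  chars <- rev(strsplit(pattern, "", fixed = TRUE)[[1]])
  paste(IUPAC_COMPLEMENT[chars], collapse = "")
}

# All 0-based forward-strand match starts of an IUPAC pattern on a linear
# sequence, checked offset by offset.
oracle_match_starts <- function(seq_chr, pattern) {
  chars <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  w <- length(pat)
  L <- length(chars)
  if (L < w) return(integer(0))
  valid <- rep(TRUE, L - w + 1L)
  for (j in seq_len(w)) {
    valid <- valid & chars[j:(L - w + j)] %in% IUPAC_SETS[[pat[j]]]
  }
  which(valid) - 1L
}

# Site-level occurrence count under the package's palindrome convention:
# palindromic motifs count forward-strand loci once; others count both
# strands.
oracle_scan_count <- function(seq_chr, pattern) {
  n_plus <- length(oracle_match_starts(seq_chr, pattern))
  rc <- oracle_revcomp(pattern)
  if (pattern == rc) return(n_plus)
  n_plus + length(oracle_match_starts(seq_chr, rc))
}

# Exhaustive urn enumeration of P(X >= k): every size-n subset of N genes
# of which the first K are marked.
oracle_hyper_upper <- function(k, n, K, N) {
  if (n == 0L) return(if (k <= 0L) 1 else 0)
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

random_dna <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Tiny two-replicon assembly used by several files.
toy_assembly <- function(chr = "GATCGANTCGATCGGCGCCAA", p1 = "GATCATTTGA",
                         topology = "linear") {
  bacmeth::genome_assembly(c(chr = chr, p1 = p1), chromosome_name = "chr",
                           topology = topology)
}

toy_genes <- function(df) {
  df$cog[is.na(df$cog)] <- ""
  structure(df, class = c("gene_features", "data.frame"))
}

# In-memory call table builder.
make_table <- function(replicon, position, strand, base, coverage,
                       modified, mod_type = NULL, condition = "test") {
  if (is.null(mod_type)) mod_type <- ifelse(base == "A", "6mA", "4mC")
  bacmeth::methylation_table(
    data.frame(replicon = replicon, position = position, strand = strand,
               base = base, mod_type = mod_type, coverage = coverage,
               modified = modified, stringsAsFactors = FALSE),
    condition = condition)
}
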