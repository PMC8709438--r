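# Degenerate IUPAC motif scanning.
#
# Motifs are the target sites of DNA methyltransferases (e.g. the
# CcrM-family GANTC site); each carries the 1-based position of the
# modified base and the modification type. Matching is IUPAC-aware on
# both strands; palindromic motifs (equal to their reverse complement,
# as all three RCAM1026 motifs are) are reported once per genomic locus
# with the modified-base coordinate on each strand.

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Define a methylation motif
#'
#' @param pattern IUPAC nucleotide string (e.g. `"GANTC"`).
#' @param modified_position 1-based index of the methylated base within
#'   the pattern.
#' @param modified_base_type One of `"6mA"`, `"4mC"`, `"5mC"`.
#' @return An `iupac_motif` object.
#' @examples
#' iupac_motif("GANTC", 2, "6mA")
#' @export
iupac_motif <- function(pattern, modified_position,
                        modified_base_type = c("6mA", "4mC", "5mC")) {
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L || !all(chars %in% names(IUPAC_EXPANSION))) {
    stop("invalid IUPAC pattern: ", pattern)
  }
  modified_base_type <- match.arg(modified_base_type)
  modified_position <- as.integer(modified_position)
  if (modified_position < 1L || modified_position > length(chars)) {
    stop("modified_position outside pattern")
  }
  target <- if (modified_base_type == "6mA") "A" else "C"
  if (!target %in% IUPAC_EXPANSION[[chars[modified_position]]]) {
    stop(sprintf("pattern position %d ('%s') cannot carry %s",
                 modified_position, chars[modified_position],
                 modified_base_type))
  }
  structure(list(pattern = pattern,
                 modified_position = modified_position,
                 modified_base_type = modified_base_type,
                 modified_base = target),
            class = "iupac_motif")
}

#' @export
print.iupac_motif <- function(x, ...) {
  cat(sprintf("iupac_motif %s (%s at position %d%s)\n", x$pattern,
              x$modified_base_type, x$modified_position,
              if (is_palindromic(x)) ", palindromic" else ""))
  invisible(x)
}

#' The three characterised RCAM1026 methylation motifs
#'
#' GANTC (CcrM-type 6mA at position 2), GATC (4mC at position 4) and
#' GGCGCC (4mC at position 3, the restriction-modification target). All
#' three are palindromic under the IUPAC complement.
#'
#' @return Named list of `iupac_motif` objects.
#' @export
rcam1026_motifs <- function() {
  list(GANTC = iupac_motif("GANTC", 2L, "6mA"),
       GATC = iupac_motif("GATC", 4L, "4mC"),
       GGCGCC = iupac_motif("GGCGCC", 3L, "4mC"))
}

#' IUPAC-aware reverse complement of a pattern
#'
#' Ambiguity codes map to their complementary sets (R<->Y, K<->M, B<->V,
#' D<->H; S, W and N are self-complementary).
#'
#' @param pattern IUPAC string.
#' @return The reverse-complement pattern as a character string.
#' @export
reverse_complement <- function(pattern) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(pattern))))
}

#' Is a motif its own reverse complement?
#' @param motif An `iupac_motif` or pattern string.
#' @return `TRUE` for palindromic patterns such as GATC or GANTC.
#' @export
is_palindromic <- function(motif) {
  pattern <- if (inherits(motif, "iupac_motif")) motif$pattern else motif
  toupper(pattern) == reverse_complement(pattern)
}

# Match starts (0-based) of an IUPAC pattern on one replicon's forward
# strand. Circular replicons are scanned with the first (w - 1) bases
# appended so origin-spanning matches are found; returned starts are in
# [0, L). Windows containing ambiguous subject bases never match.
match_starts <- function(seq, pattern, circular) {
  L <- length(seq)
  w <- nchar(pattern)
  if (L < w) return(integer(0))
  subject <- if (circular) {
    Biostrings::xscat(seq, Biostrings::subseq(seq, 1L, w - 1L))
  } else {
    seq
  }
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                   fixed = FALSE)
  starts <- Biostrings::start(hits) - 1L
  starts <- starts[starts < L]
  if (length(starts) > 0) {
    af <- Biostrings::alphabetFrequency(subject)
    if (sum(af[c("A", "C", "G", "T")]) < length(subject)) {
      chars <- strsplit(as.character(subject), "", fixed = TRUE)[[1]]
      amb <- which(!chars %in% c("A", "C", "G", "T")) - 1L
      bad <- vapply(starts, function(s) any(amb >= s & amb < s + w),
                    logical(1))
      starts <- starts[!bad]
    }
  }
  sort(starts)
}

#' Scan an assembly for motif occurrences
#'
#' Finds every (possibly overlapping) match on both strands. A
#' palindromic motif is reported once per genomic locus with strand `"+"`
#' and both strand-specific modified-base coordinates
#' (`mod_site_plus`/`mod_site_minus`); a non-palindromic motif yields
#' separate `+` and `-` occurrences. On circular replicons matches
#' spanning the origin are included (`end` then exceeds the replicon
#' length; coordinates of modified sites are reduced modulo the length).
#'
#' @param assembly A `genome_assembly`.
#' @param motif An `iupac_motif`.
#' @return A `motif_occurrences` data frame with columns `motif`,
#'   `replicon`, `start`, `end` (0-based half-open), `strand`,
#'   `palindromic`, `mod_site_plus`, `mod_site_minus`, `mod_type`,
#'   `mod_base`.
#' @export
scan_motif <- function(assembly, motif) {
  stopifnot(inherits(assembly, "genome_assembly"),
            inherits(motif, "iupac_motif"))
  w <- nchar(motif$pattern)
  p <- motif$modified_position
  pal <- is_palindromic(motif)
  rc <- reverse_complement(motif$pattern)
  rows <- lapply(names(assembly$replicons), function(nm) {
    seq <- assembly$replicons[[nm]]
    L <- length(seq)
    circ <- assembly$topology[[nm]] == "circular"
    plus <- match_starts(seq, motif$pattern, circ)
    if (pal) {
      df <- data.frame(replicon = rep(nm, length(plus)), start = plus,
                       strand = rep("+", length(plus)),
                       mod_site_plus = (plus + p - 1L) %% L,
                       mod_site_minus = (plus + w - p) %% L)
    } else {
      minus <- match_starts(seq, rc, circ)
      df <- rbind(
        data.frame(replicon = rep(nm, length(plus)), start = plus,
                   strand = rep("+", length(plus)),
                   mod_site_plus = (plus + p - 1L) %% L,
                   mod_site_minus = rep(NA_integer_, length(plus))),
        data.frame(replicon = rep(nm, length(minus)), start = minus,
                   strand = rep("-", length(minus)),
                   mod_site_plus = rep(NA_integer_, length(minus)),
                   mod_site_minus = (minus + w - p) %% L))
    }
    df
  })
  out <- do.call(rbind, rows)
  out <- data.frame(motif = rep(motif$pattern, nrow(out)), out,
                    stringsAsFactors = FALSE)
  out$end <- out$start + w
  out$palindromic <- rep(pal, nrow(out))
  out$mod_type <- rep(motif$modified_base_type, nrow(out))
  out$mod_base <- rep(motif$modified_base, nrow(out))
  out <- out[, c("motif", "replicon", "start", "end", "strand",
                 "palindromic", "mod_site_plus", "mod_site_minus",
                 "mod_type", "mod_base")]
  rownames(out) <- NULL
  class(out) <- c("motif_occurrences", "data.frame")
  out
}

#' Scan several motifs at once
#' @param assembly A `genome_assembly`.
#' @param motifs List of `iupac_motif` objects.
#' @return Row-bound `motif_occurrences` for all motifs.
#' @export
scan_motifs <- function(assembly, motifs) {
  out <- do.call(rbind, lapply(motifs, scan_motif, assembly = assembly))
  rownames(out) <- NULL
  class(out) <- c("motif_occurrences", "data.frame")
  out
}

#' Count occurrences per motif and replicon
#'
#' Site-level counts: each occurrence row (one per locus for palindromic
#' motifs, one per strand otherwise) counts once.
#'
#' @param occurrences `motif_occurrences` from [scan_motif()].
#' @param assembly The matching `genome_assembly` (fixes replicon order
#'   and reports zero counts).
#' @param motifs Motif patterns defining the table rows; defaults to the
#'   patterns present in `occurrences`. Supplying the scanned set keeps
#'   zero-count rows.
#' @return Data frame with `motif`, one column per replicon, and `total`.
#' @export
count_by_replicon <- function(occurrences, assembly,
                              motifs = unique(occurrences$motif)) {
  reps <- names(assembly$replicons)
  counts <- table(factor(occurrences$motif, levels = motifs),
                  factor(occurrences$replicon, levels = reps))
  out <- data.frame(motif = motifs, stringsAsFactors = FALSE)
  for (r in reps) out[[r]] <- as.integer(counts[, r])
  out$total <- as.integer(rowSums(counts))
  out
}

#' Intersect motif occurrences with promoter (or gene) regions
#'
#' An occurrence lies in a region when its full match interval overlaps
#' the region by at least one base (not just the modified position);
#' origin-wrapping occurrences and regions are handled segment-wise. Each
#' occurrence/region pair counts at most once; the per-replicon counts
#' tally distinct occurrences falling in at least one region.
#'
#' @param occurrences `motif_occurrences`.
#' @param regions `promoter_regions` (or any data frame with `gene_id`,
#'   `replicon`, `start`, `end`).
#' @param assembly The matching `genome_assembly`.
#' @return List with `counts` (motif x replicon table of in-region
#'   occurrence counts), `pairs` (occurrence/region hit pairs with motif
#'   and gene), and `gene_flags` (per gene and motif: number of
#'   occurrences overlapping its region and a logical `has_motif`) for
#'   the enrichment stage.
#' @export
intersect_with_regions <- function(occurrences, regions, assembly) {
  occ_seg <- region_segments(occurrences, assembly)
  reg_seg <- region_segments(regions, assembly)
  pairs <- data.frame(occ = integer(0), region = integer(0))
  if (nrow(occ_seg) > 0 && nrow(reg_seg) > 0) {
    seqinfo_levels <- names(assembly$replicons)
    q <- GenomicRanges::GRanges(
      factor(occ_seg$replicon, levels = seqinfo_levels),
      IRanges::IRanges(occ_seg$start + 1L, occ_seg$end))
    s <- GenomicRanges::GRanges(
      factor(reg_seg$replicon, levels = seqinfo_levels),
      IRanges::IRanges(reg_seg$start + 1L, reg_seg$end))
    ov <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L)
    pairs <- unique(data.frame(
      occ = occ_seg$region[S4Vectors::queryHits(ov)],
      region = reg_seg$region[S4Vectors::subjectHits(ov)]))
  }
  hit_df <- data.frame(motif = occurrences$motif[pairs$occ],
                       replicon = occurrences$replicon[pairs$occ],
                       occurrence = pairs$occ,
                       gene_id = regions$gene_id[pairs$region],
                       stringsAsFactors = FALSE)
  # distinct occurrences per motif x replicon that hit >= 1 region
  distinct <- unique(hit_df[, c("motif", "replicon", "occurrence")])
  motifs <- unique(occurrences$motif)
  counts <- count_by_replicon(distinct, assembly, motifs = motifs)
  flags <- expand.grid(gene_id = unique(regions$gene_id), motif = motifs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(hit_df$gene_id, hit_df$motif)
  tab <- table(key)
  flags$n_occurrences <- as.integer(tab[paste(flags$gene_id, flags$motif)])
  flags$n_occurrences[is.na(flags$n_occurrences)] <- 0L
  flags$has_motif <- flags$n_occurrences > 0L
  list(counts = counts, pairs = hit_df, gene_flags = flags)
}

#' Export motif occurrences as BED6
#'
#' Palindromic sites carry strand `"+"` by convention; origin-wrapping
#' matches are split into two BED lines.
#'
#' @param occurrences `motif_occurrences`.
#' @param assembly The matching `genome_assembly`.
#' @param path Output BED path.
#' @return The path, invisibly.
#' @export
occurrences_to_bed <- function(occurrences, assembly, path) {
  seg <- region_segments(occurrences, assembly)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   seg$replicon, seg$start, seg$end,
                   occurrences$motif[seg$region],
                   occurrences$strand[seg$region])
  writeLines(lines, path)
  invisible(path)
}
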