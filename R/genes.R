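# Gene features and promoter regions.
#
# Genes are stranded intervals carrying COG single-letter functional
# categories; promoters are the fixed-width windows immediately upstream
# of the start codon. Coordinates are 0-based half-open internally.

gene_features <- function(df) {
  required <- c("gene_id", "replicon", "start", "end", "strand", "cog")
  stopifnot(all(required %in% names(df)))
  df <- df[, required]
  class(df) <- c("gene_features", "data.frame")
  df
}

#' Read gene features from GFF3
#'
#' Imports `gene` features (falling back to `CDS` when no `gene` records
#' exist), converts the GFF3 1-based inclusive coordinates to the internal
#' 0-based half-open convention, and validates every feature against the
#' assembly. COG categories are read from a configurable attribute key;
#' multi-letter values (e.g. `COG=KL`) are split into one category per
#' letter.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param assembly A `genome_assembly` the features must lie on.
#' @param feature_types GFF3 `type` values to keep, in order of
#'   preference; the first type with any records wins.
#' @param cog_attribute Attribute key carrying COG letters (default
#'   `"COG"`).
#' @return A `gene_features` data frame with columns `gene_id`,
#'   `replicon`, `start`, `end` (0-based half-open), `strand`, `cog`
#'   (string of category letters, `""` when unannotated).
#' @export
read_genes <- function(gff3_path, assembly,
                       feature_types = c("gene", "CDS"),
                       cog_attribute = "COG") {
  check_file(gff3_path, "GFF3 file")
  stopifnot(inherits(assembly, "genome_assembly"))
  gr <- tryCatch(rtracklayer::import(gff3_path, format = "gff3"),
                 error = function(e) {
                   io_error(sprintf("cannot parse GFF3 '%s': %s",
                                    gff3_path, conditionMessage(e)))
                 })
  type <- as.character(gr$type)
  keep_type <- feature_types[feature_types %in% type][1]
  if (is.na(keep_type)) {
    stop("no features of type ", paste(feature_types, collapse = "/"),
         " in ", gff3_path)
  }
  gr <- gr[type == keep_type]
  lens <- replicon_lengths(assembly)
  rep_names <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(rep_names), names(lens))
  if (length(unknown) > 0) {
    stop("feature(s) on replicon(s) absent from assembly: ",
         paste(unknown, collapse = ", "))
  }
  start1 <- GenomicRanges::start(gr)   # 1-based inclusive
  end1 <- GenomicRanges::end(gr)
  if (any(end1 < start1)) stop("feature with end < start")
  if (any(start1 < 1L) || any(end1 > lens[rep_names])) {
    bad <- which(start1 < 1L | end1 > lens[rep_names])[1]
    stop(sprintf("feature outside replicon bounds on '%s': [%d, %d]",
                 rep_names[bad], start1[bad], end1[bad]))
  }
  mc <- S4Vectors::mcols(gr)
  id <- as.character(mc$ID %||% mc$locus_tag %||% mc$Name)
  if (is.null(id) || all(is.na(id))) {
    id <- sprintf("%s_%06d", keep_type, seq_along(gr))
  }
  id[is.na(id)] <- sprintf("%s_%06d", keep_type, which(is.na(id)))
  cog <- rep("", length(gr))
  if (cog_attribute %in% names(mc)) {
    raw <- mc[[cog_attribute]]
    if (methods::is(raw, "List") || is.list(raw)) {
      raw <- vapply(raw, function(v) paste(v, collapse = ""), character(1))
    }
    raw <- toupper(as.character(raw))
    raw[is.na(raw)] <- ""
    cog <- vapply(strsplit(raw, "", fixed = TRUE), function(ch) {
      paste(unique(ch[ch %in% LETTERS]), collapse = "")
    }, character(1))
  }
  gene_features(data.frame(
    gene_id = id,
    replicon = rep_names,
    start = start1 - 1L,
    end = end1,
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    cog = cog,
    stringsAsFactors = FALSE))
}

#' Derive promoter regions upstream of genes
#'
#' The promoter of a gene is the `upstream_len` bases immediately 5' of
#' its start codon: for a + strand gene `[s, e)` it is `[s - u, s)`, for a
#' - strand gene `[e, e + u)`. On circular replicons the window wraps
#' around the origin (encoded as `end > replicon length` after
#' normalising `start` into `[0, L)`); on linear replicons it is clipped
#' at the ends.
#'
#' @param genes A `gene_features` data frame.
#' @param assembly The `genome_assembly` the genes lie on.
#' @param upstream_len Promoter width in bases (default 100).
#' @return A `promoter_regions` data frame with columns `gene_id`,
#'   `replicon`, `start`, `end`, `strand`, `width`.
#' @export
extract_promoters <- function(genes, assembly, upstream_len = 100L) {
  stopifnot(inherits(assembly, "genome_assembly"), upstream_len > 0)
  lens <- replicon_lengths(assembly)
  circ <- assembly$topology[genes$replicon] == "circular"
  L <- unname(lens[genes$replicon])
  raw_start <- ifelse(genes$strand == "+", genes$start - upstream_len,
                      genes$end)
  raw_end <- raw_start + upstream_len
  start <- raw_start
  end <- raw_end
  # circular: wrap modulo replicon length, keeping width constant
  start[circ] <- ((raw_start[circ] %% L[circ]) + L[circ]) %% L[circ]
  end[circ] <- start[circ] + upstream_len
  # linear: clip at 0 and replicon length
  start[!circ] <- pmax(raw_start[!circ], 0L)
  end[!circ] <- pmin(raw_end[!circ], L[!circ])
  out <- data.frame(gene_id = genes$gene_id,
                    replicon = genes$replicon,
                    start = as.integer(start),
                    end = as.integer(end),
                    strand = genes$strand,
                    width = as.integer(end - start),
                    stringsAsFactors = FALSE)
  out <- out[out$width > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("promoter_regions", "data.frame")
  out
}

# Split regions that wrap past the replicon origin (end > L) into concrete
# forward-strand segments; returns one row per segment with the index of
# the originating region.
region_segments <- function(regions, assembly) {
  lens <- replicon_lengths(assembly)
  L <- unname(lens[regions$replicon])
  wraps <- regions$end > L
  plain <- data.frame(region = which(!wraps),
                      replicon = regions$replicon[!wraps],
                      start = regions$start[!wraps],
                      end = regions$end[!wraps])
  if (!any(wraps)) return(plain)
  w <- which(wraps)
  head_seg <- data.frame(region = w, replicon = regions$replicon[w],
                         start = regions$start[w], end = L[w])
  tail_seg <- data.frame(region = w, replicon = regions$replicon[w],
                         start = 0L, end = regions$end[w] - L[w])
  out <- rbind(plain, head_seg, tail_seg)
  out[out$end > out$start, , drop = FALSE]
}

#' Export promoter regions as BED6
#'
#' BED is 0-based half-open; the score column is 0. Promoters wrapping a
#' circular origin are written as two lines sharing the gene name.
#'
#' @param promoters A `promoter_regions` data frame.
#' @param assembly The matching `genome_assembly`.
#' @param path Output BED path.
#' @return The path, invisibly.
#' @export
promoters_to_bed <- function(promoters, assembly, path) {
  seg <- region_segments(promoters, assembly)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   seg$replicon, seg$start, seg$end,
                   promoters$gene_id[seg$region],
                   promoters$strand[seg$region])
  writeLines(lines, path)
  invisible(path)
}

#' Write gene features as GFF3
#'
#' Inverse of [read_genes()] for synthetic annotations: 1-based inclusive
#' coordinates, COG letters in the configured attribute.
#'
#' @inheritParams promoters_to_bed
#' @param genes A `gene_features` data frame.
#' @param cog_attribute Attribute key for COG letters.
#' @return The path, invisibly.
#' @export
write_genes_gff3 <- function(genes, path, cog_attribute = "COG") {
  attrs <- sprintf("ID=%s", genes$gene_id)
  has_cog <- !is.na(genes$cog) & genes$cog != ""
  attrs[has_cog] <- sprintf("%s;%s=%s", attrs[has_cog], cog_attribute,
                            genes$cog[has_cog])
  lines <- sprintf("%s\tbacmeth\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   genes$replicon, genes$start + 1L, genes$end,
                   genes$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
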