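# Replicon copy number from read coverage.
#
# Native-DNA long-read libraries make per-replicon mean depth
# proportional to replicon copy number, so the ratio of a replicon's
# mean depth to the chromosome's estimates its relative copy number in
# the cell (chromosome = 1 by construction).

#' Summarise sequencing depth per replicon
#'
#' Accepts a bedGraph depth track (path or data frame with columns
#' `replicon`/`chrom`, `start`, `end`, `depth`; 0-based half-open
#' intervals) or a precomputed per-replicon table with columns
#' `condition`, `replicon`, `mean_depth`. For tracks, the mean is taken
#' over every position of the replicon; positions absent from the track
#' count as depth 0.
#'
#' @param x Track path, track data frame, or precomputed summary.
#' @param assembly The matching `genome_assembly`.
#' @param condition Condition label for track input.
#' @param trim Fraction (0 to < 0.5) of extreme per-interval depth mass
#'   to discard from each tail before averaging; 0 (default) is the
#'   plain arithmetic mean.
#' @return A `coverage_summary` data frame: `condition`, `replicon`,
#'   `mean_depth`, `n_positions`.
#' @export
summarize_depth <- function(x, assembly, condition = "unknown", trim = 0) {
  stopifnot(inherits(assembly, "genome_assembly"), trim >= 0, trim < 0.5)
  lens <- replicon_lengths(assembly)
  if (is.character(x)) {
    check_file(x, "depth track")
    first <- readLines(x, n = 1L)
    if (grepl("mean_depth", first)) {
      # precomputed per-replicon summary TSV with header
      x <- utils::read.delim(x, comment.char = "#",
                             stringsAsFactors = FALSE)
      if (!"condition" %in% names(x)) x$condition <- condition
    } else {
      skip <- if (grepl("^track", first)) 1L else 0L
      x <- utils::read.delim(x, header = FALSE, skip = skip,
                             comment.char = "#", stringsAsFactors = FALSE)
      names(x)[1:4] <- c("replicon", "start", "end", "depth")
    }
  }
  x <- as.data.frame(x)
  if (all(c("condition", "replicon", "mean_depth") %in% names(x)) &&
      !"depth" %in% names(x)) {
    out <- data.frame(condition = x$condition, replicon = x$replicon,
                      mean_depth = as.numeric(x$mean_depth),
                      n_positions = if ("n_positions" %in% names(x)) {
                        x$n_positions
                      } else {
                        unname(lens[x$replicon])
                      },
                      stringsAsFactors = FALSE)
    class(out) <- c("coverage_summary", "data.frame")
    return(out)
  }
  if ("chrom" %in% names(x) && !"replicon" %in% names(x)) {
    names(x)[names(x) == "chrom"] <- "replicon"
  }
  stopifnot(all(c("replicon", "start", "end", "depth") %in% names(x)))
  if (any(x$depth < 0)) stop("negative depth value")
  unknown <- setdiff(unique(x$replicon), names(lens))
  if (length(unknown) > 0) {
    stop("depth on unknown replicon(s): ", paste(unknown, collapse = ", "))
  }
  if (any(x$start < 0) || any(x$end > lens[x$replicon])) {
    stop("depth interval outside replicon bounds")
  }
  widths <- x$end - x$start
  out <- do.call(rbind, lapply(names(lens), function(nm) {
    sel <- x$replicon == nm
    L <- lens[[nm]]
    if (L == 0L) stop("replicon of zero length: ", nm)
    md <- if (trim > 0) {
      # expand interval depths position-wise for the trimmed mean
      # (uncovered positions included as zeros)
      vals <- c(rep(x$depth[sel], widths[sel]),
                rep(0, L - sum(widths[sel])))
      mean(vals, trim = trim)
    } else {
      sum(x$depth[sel] * widths[sel]) / L
    }
    data.frame(condition = condition, replicon = nm, mean_depth = md,
               n_positions = L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("coverage_summary", "data.frame")
  out
}

#' Relative replicon copy number
#'
#' Each replicon's mean depth divided by the chromosome's mean depth,
#' per condition; the chromosome's ratio is exactly 1.
#'
#' @param summaries A `coverage_summary` data frame (may hold several
#'   conditions).
#' @param chromosome_name Replicon used as the normalisation reference.
#' @return Data frame `condition`, `replicon`, `mean_depth`, `ratio`.
#' @export
relative_copy_number <- function(summaries, chromosome_name) {
  stopifnot(all(c("condition", "replicon", "mean_depth") %in%
                  names(summaries)))
  out <- do.call(rbind, lapply(split(as.data.frame(summaries),
                                     summaries$condition), function(s) {
    chrom <- s$mean_depth[s$replicon == chromosome_name]
    if (length(chrom) != 1L) {
      stop("chromosome '", chromosome_name, "' missing from condition '",
           s$condition[1], "'")
    }
    if (chrom <= 0) {
      stop("chromosome mean depth is zero in condition '",
           s$condition[1], "'")
    }
    s$ratio <- s$mean_depth / chrom
    s$ratio[s$replicon == chromosome_name] <- 1
    s[, c("condition", "replicon", "mean_depth", "ratio")]
  }))
  rownames(out) <- NULL
  out
}
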