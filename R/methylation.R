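# Per-site modified-base call tables and their summaries.
#
# A site is one (replicon, position, strand) with the number of reads
# covering it and the number called modified; the analysis works on the
# per-site percent-modified values, so cross-site summaries are
# unweighted means of per-site percentages (each site one vote), never
# read-weighted.

MOD_TYPES <- c("6mA", "4mC", "5mC", "any")

# Map bedMethyl name-column codes to modification types.
BEDMETHYL_CODES <- c(a = "6mA", m = "5mC", h = "5mC",
                     `6mA` = "6mA", `4mC` = "4mC", `5mC` = "5mC")

#' Construct a methylation call table
#'
#' @param df Data frame with columns `replicon`, `position` (0-based
#'   forward-strand coordinate), `strand`, `base` (`A`/`C`), `mod_type`,
#'   `coverage`, `modified`.
#' @param condition Condition label (e.g. `"bacteroid"`).
#' @return A `methylation_table` data frame with a `condition` attribute.
#' @export
methylation_table <- function(df, condition = "unknown") {
  required <- c("replicon", "position", "strand", "base", "mod_type",
                "coverage", "modified")
  stopifnot(all(required %in% names(df)))
  df <- as.data.frame(df)[, required]
  stopifnot(all(df$strand %in% c("+", "-")),
            all(df$base %in% c("A", "C")),
            all(df$mod_type %in% MOD_TYPES),
            all(df$coverage >= 0), all(df$modified >= 0),
            all(df$modified <= df$coverage))
  key <- paste(df$replicon, df$position, df$strand, df$mod_type)
  if (anyDuplicated(key)) stop("duplicate (replicon, position, strand, mod_type) records")
  attr(df, "condition") <- condition
  class(df) <- c("methylation_table", "data.frame")
  df
}

#' @export
print.methylation_table <- function(x, ...) {
  cat(sprintf("methylation_table: condition '%s', %d sites on %d replicon(s)\n",
              attr(x, "condition"), nrow(x), length(unique(x$replicon))))
  print(utils::head(as.data.frame(x)), row.names = FALSE)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read per-site modified-base calls
#'
#' Two dialects are supported. `simple_tsv` has columns `replicon`,
#' `position` (0-based), `strand`, `base`, `mod_type`, `coverage`,
#' `modified` (header optional). `bedmethyl` is BED9+2: columns 1-3 give
#' the site interval, column 4 the modification code (`a`/`m` or a
#' literal type), column 6 the strand, columns 10-11 coverage and percent
#' modified; the modified-read count is recovered by rounding
#' `coverage * percent / 100`.
#'
#' Records on replicons absent from the assembly, or with
#' `modified > coverage`, are dropped with a message giving the count;
#' structurally malformed lines are an error naming the line.
#'
#' @param path Input file path.
#' @param assembly A `genome_assembly` used for validation.
#' @param dialect `"simple_tsv"` or `"bedmethyl"`.
#' @param condition Condition label attached to the table.
#' @return A `methylation_table`.
#' @export
read_calls <- function(path, assembly,
                       dialect = c("simple_tsv", "bedmethyl"),
                       condition = "unknown") {
  check_file(path, "call table")
  dialect <- match.arg(dialect)
  stopifnot(inherits(assembly, "genome_assembly"))
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) io_error(sprintf("empty call table: %s", path))
  if (dialect == "simple_tsv") {
    if (identical(as.character(raw[1, 1]), "replicon")) {
      raw <- raw[-1, , drop = FALSE]
    }
    if (ncol(raw) < 7L) stop("simple_tsv requires 7 columns")
    df <- data.frame(replicon = as.character(raw[[1]]),
                     position = suppressWarnings(as.integer(raw[[2]])),
                     strand = as.character(raw[[3]]),
                     base = toupper(as.character(raw[[4]])),
                     mod_type = as.character(raw[[5]]),
                     coverage = suppressWarnings(as.integer(raw[[6]])),
                     modified = suppressWarnings(as.integer(raw[[7]])),
                     stringsAsFactors = FALSE)
  } else {
    if (ncol(raw) < 11L) stop("bedMethyl requires 11 columns (BED9+2)")
    cov <- suppressWarnings(as.integer(raw[[10]]))
    pct <- suppressWarnings(as.numeric(raw[[11]]))
    code <- as.character(raw[[4]])
    mod_type <- unname(BEDMETHYL_CODES[code])
    mod_type[is.na(mod_type)] <- "any"
    df <- data.frame(replicon = as.character(raw[[1]]),
                     position = suppressWarnings(as.integer(raw[[2]])),
                     strand = as.character(raw[[6]]),
                     base = ifelse(mod_type == "6mA", "A", "C"),
                     mod_type = mod_type,
                     coverage = cov,
                     modified = as.integer(round(cov * pct / 100)),
                     stringsAsFactors = FALSE)
  }
  malformed <- which(is.na(df$position) | is.na(df$coverage) |
                       is.na(df$modified) | !df$strand %in% c("+", "-") |
                       !df$base %in% c("A", "C"))
  if (length(malformed) > 0) {
    stop(sprintf("malformed call record at line %d of %s",
                 malformed[1], path))
  }
  lens <- replicon_lengths(assembly)
  drop_rep <- !df$replicon %in% names(lens)
  drop_cov <- !drop_rep & df$modified > df$coverage
  drop_pos <- !drop_rep & !drop_cov &
    (df$position < 0L | df$position >= lens[df$replicon])
  n_drop <- sum(drop_rep | drop_cov | drop_pos)
  if (n_drop > 0) {
    message(sprintf(
      "read_calls: dropped %d record(s) (%d unknown replicon, %d modified > coverage, %d out of bounds)",
      n_drop, sum(drop_rep), sum(drop_cov), sum(drop_pos)))
    df <- df[!(drop_rep | drop_cov | drop_pos), , drop = FALSE]
  }
  rownames(df) <- NULL
  methylation_table(df, condition = condition)
}

#' Write a call table in the simple_tsv dialect
#' @param table A `methylation_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_calls <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-site percent methylated
#'
#' `100 * modified / coverage` for sites meeting the coverage threshold;
#' `NA` (site excluded from all summaries) below it.
#'
#' @param coverage,modified Read counts (vectorised), or `coverage` may
#'   be a `methylation_table` in which case `modified` is ignored.
#' @param min_coverage Minimum reads for a site to be included
#'   (default 5).
#' @return Numeric vector of percentages with `NA` for excluded sites.
#' @export
site_fraction <- function(coverage, modified = NULL, min_coverage = 5L) {
  if (inherits(coverage, "methylation_table")) {
    modified <- coverage$modified
    coverage <- coverage$coverage
  }
  ifelse(coverage >= min_coverage, 100 * modified / coverage, NA_real_)
}

# Rows of `table` for one base, with their percent values; excluded
# (low-coverage) sites carry NA.
base_site_percents <- function(table, base, min_coverage) {
  idx <- which(table$base == base)
  list(idx = idx,
       percent = site_fraction(table$coverage[idx], table$modified[idx],
                               min_coverage))
}

#' Genome-wide and per-replicon base methylation
#'
#' Unweighted mean of per-site percent methylated over all included
#' sites of one base, per replicon and genome-wide (`replicon ==
#' "genome"`).
#'
#' @param table A `methylation_table`.
#' @param assembly The matching `genome_assembly`.
#' @param base `"A"` or `"C"`.
#' @param min_coverage Site inclusion threshold (reads).
#' @return Data frame `condition`, `replicon`, `base`, `mean_percent`,
#'   `n_sites`. Replicons with no included site carry `NA`; no included
#'   site anywhere is an error.
#' @export
genome_base_methylation <- function(table, assembly, base = c("A", "C"),
                                    min_coverage = 5L) {
  base <- match.arg(base)
  bs <- base_site_percents(table, base, min_coverage)
  pct <- bs$percent
  ok <- !is.na(pct)
  if (!any(ok)) stop("no included sites for base ", base)
  reps <- names(assembly$replicons)
  rep_f <- factor(table$replicon[bs$idx], levels = reps)
  means <- tapply(pct[ok], rep_f[ok], mean)
  n <- tapply(rep(1L, sum(ok)), rep_f[ok], sum)
  out <- data.frame(condition = attr(table, "condition"),
                    replicon = c(reps, "genome"),
                    base = base,
                    mean_percent = c(as.numeric(means[reps]),
                                     mean(pct[ok])),
                    n_sites = c(ifelse(is.na(n[reps]), 0L,
                                       as.integer(n[reps])),
                                sum(ok)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sliding-window methylation profile
#'
#' Windows of `width` bases every `step` bases along each replicon
#' (clipped at the replicon end); per window, the unweighted mean of
#' included per-site percentages for one base. Windows without included
#' sites are emitted with `n_sites = 0` and `NA` percent.
#'
#' @inheritParams genome_base_methylation
#' @param width Window width in bases (default 5000, as used for
#'   genome-wide methylation plots).
#' @param step Step between window starts (default 1000; set equal to
#'   `width` for non-overlapping tiles).
#' @return Data frame `condition`, `replicon`, `window_start`,
#'   `window_end` (0-based half-open), `base`, `percent_methylated`,
#'   `n_sites`.
#' @export
window_profile <- function(table, assembly, base = c("A", "C"),
                           width = 5000L, step = 1000L, min_coverage = 5L) {
  base <- match.arg(base)
  stopifnot(width > 0, step > 0)
  bs <- base_site_percents(table, base, min_coverage)
  pos <- table$position[bs$idx]
  pct <- bs$percent
  ok <- !is.na(pct)
  lens <- replicon_lengths(assembly)
  out <- lapply(names(lens), function(nm) {
    L <- lens[[nm]]
    starts <- seq.int(0L, max(0L, L - 1L), by = step)
    ends <- pmin(starts + width, L)
    sel <- ok & table$replicon[bs$idx] == nm
    p <- sort.int(pos[sel], index.return = TRUE)
    sp <- p$x
    sv <- pct[sel][p$ix]
    cs <- c(0, cumsum(sv))
    lo <- findInterval(starts - 0.5, sp) + 1L
    hi <- findInterval(ends - 0.5, sp)
    n <- hi - lo + 1L
    mean_pct <- ifelse(n > 0, (cs[hi + 1L] - cs[lo]) / n, NA_real_)
    data.frame(condition = attr(table, "condition"), replicon = nm,
               window_start = starts, window_end = ends, base = base,
               percent_methylated = mean_pct,
               n_sites = pmax(n, 0L), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-motif methylation summaries
#'
#' For each occurrence the call at the strand-specific modified-base
#' coordinate is looked up; a palindromic site contributes its two
#' strand calls as two separate observations. Means are unweighted over
#' included observations, per replicon and overall (`replicon ==
#' "genome"`), with the same-base genome-wide average attached as
#' `background_percent` for context.
#'
#' @param table A `methylation_table`.
#' @param occurrences `motif_occurrences` from [scan_motif()] /
#'   [scan_motifs()] on the same assembly.
#' @param assembly The matching `genome_assembly`.
#' @param min_coverage Site inclusion threshold (reads).
#' @param match_mod_type When `TRUE` (default) a call matches an
#'   occurrence only if its `mod_type` equals the motif's type or is
#'   `"any"`; set `FALSE` to pool all call types at the position.
#' @return Data frame `motif`, `condition`, `replicon`, `mean_percent`,
#'   `n_sites_used` (occurrences with at least one included
#'   observation), `n_obs` (included strand observations),
#'   `pooled_modified`, `pooled_coverage` (read-count sums over included
#'   observations), `background_percent`. A motif whose modification type
#'   is absent from the table is an error.
#' @export
motif_methylation <- function(table, occurrences, assembly,
                              min_coverage = 5L, match_mod_type = TRUE) {
  stopifnot(inherits(table, "methylation_table"))
  cond <- attr(table, "condition")
  reps <- names(assembly$replicons)
  key <- paste(table$replicon, table$position, table$strand)
  out <- lapply(unique(occurrences$motif), function(m) {
    occ <- occurrences[occurrences$motif == m, , drop = FALSE]
    mod_type <- occ$mod_type[1]
    if (match_mod_type && !any(table$mod_type %in% c(mod_type, "any"))) {
      stop(sprintf("no '%s' calls in table for motif %s", mod_type, m))
    }
    obs <- rbind(
      data.frame(occ_id = seq_len(nrow(occ)), replicon = occ$replicon,
                 position = occ$mod_site_plus, strand = "+"),
      data.frame(occ_id = seq_len(nrow(occ)), replicon = occ$replicon,
                 position = occ$mod_site_minus, strand = "-"))
    obs <- obs[!is.na(obs$position), , drop = FALSE]
    hit <- match(paste(obs$replicon, obs$position, obs$strand), key)
    found <- !is.na(hit)
    if (match_mod_type) {
      found[found] <- table$mod_type[hit[found]] %in% c(mod_type, "any")
    }
    obs <- obs[found, , drop = FALSE]
    hit <- hit[found]
    pct <- site_fraction(table$coverage[hit], table$modified[hit],
                         min_coverage)
    ok <- !is.na(pct)
    rep_f <- factor(obs$replicon, levels = reps)
    summarize <- function(sel) {
      if (!any(sel)) {
        return(c(mean_percent = NA_real_, n_sites_used = 0, n_obs = 0,
                 pooled_modified = 0, pooled_coverage = 0))
      }
      c(mean_percent = mean(pct[sel]),
        n_sites_used = length(unique(obs$occ_id[sel])),
        n_obs = sum(sel),
        pooled_modified = sum(table$modified[hit[sel]]),
        pooled_coverage = sum(table$coverage[hit[sel]]))
    }
    per_rep <- t(vapply(reps, function(r) summarize(ok & rep_f == r),
                        numeric(5)))
    overall <- summarize(ok)
    stats_mat <- rbind(per_rep, genome = overall)
    data.frame(motif = m, condition = cond,
               replicon = c(reps, "genome"),
               as.data.frame(stats_mat),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  # attach same-base genome-wide background for context
  out$background_percent <- NA_real_
  for (b in c("A", "C")) {
    motifs_b <- unique(occurrences$motif[occurrences$mod_base == b])
    if (length(motifs_b) == 0 || !any(table$base == b)) next
    bg <- tryCatch(genome_base_methylation(table, assembly, b, min_coverage),
                   error = function(e) NULL)
    if (is.null(bg)) next
    out$background_percent[out$motif %in% motifs_b] <-
      bg$mean_percent[match(out$replicon[out$motif %in% motifs_b],
                            bg$replicon)]
  }
  out
}

#' Compare motif methylation between conditions
#'
#' Side-by-side per-motif means for two or more conditions with pairwise
#' differences, plus a pooled read-count two-proportion effect size
#' (difference of pooled modified/total proportions; no p-value is
#' attached, following the descriptive design of the analysis).
#'
#' @param summaries Named list (one element per condition) of
#'   [motif_methylation()] outputs sharing motif and replicon sets.
#' @return Data frame keyed by `motif` and `replicon` with
#'   `percent_<condition>` columns, `diff_<a>_minus_<b>` for each
#'   condition pair, and `pooled_diff_<a>_minus_<b>` on the pooled read
#'   proportions (in percentage points).
#' @export
compare_conditions <- function(summaries) {
  if (length(summaries) < 2L) {
    stop("compare_conditions needs at least two conditions")
  }
  conds <- names(summaries) %||%
    vapply(summaries, function(s) s$condition[1], character(1))
  names(summaries) <- conds
  keys <- lapply(summaries, function(s) paste(s$motif, s$replicon))
  common <- Reduce(intersect, keys)
  if (length(common) == 0L) {
    stop("conditions share no (motif, replicon) combinations")
  }
  first <- summaries[[1]]
  base_key <- paste(first$motif, first$replicon)
  keep <- base_key %in% common
  out <- data.frame(motif = first$motif[keep],
                    replicon = first$replicon[keep],
                    stringsAsFactors = FALSE)
  prop <- list()
  for (cn in conds) {
    s <- summaries[[cn]]
    i <- match(paste(out$motif, out$replicon), paste(s$motif, s$replicon))
    out[[paste0("percent_", cn)]] <- s$mean_percent[i]
    prop[[cn]] <- 100 * s$pooled_modified[i] /
      ifelse(s$pooled_coverage[i] > 0, s$pooled_coverage[i], NA_real_)
  }
  for (a in seq_along(conds)) {
    for (b in seq_along(conds)) {
      if (a >= b) next
      ca <- conds[a]; cb <- conds[b]
      out[[sprintf("diff_%s_minus_%s", ca, cb)]] <-
        out[[paste0("percent_", ca)]] - out[[paste0("percent_", cb)]]
      out[[sprintf("pooled_diff_%s_minus_%s", ca, cb)]] <-
        prop[[ca]] - prop[[cb]]
    }
  }
  out
}

#' Write a window profile as bedGraph
#'
#' One track line per window with an included site; the value is the
#' window's percent methylated (0-based half-open intervals).
#'
#' @param profile Output of [window_profile()].
#' @param path Output bedGraph path.
#' @param name Track name.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(profile, path, name = "methylation") {
  keep <- !is.na(profile$percent_methylated)
  lines <- sprintf("%s\t%d\t%d\t%.4f",
                   profile$replicon[keep], profile$window_start[keep],
                   profile$window_end[keep],
                   profile$percent_methylated[keep])
  writeLines(c(sprintf("track type=bedGraph name=\"%s\"", name), lines),
             path)
  invisible(path)
}
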