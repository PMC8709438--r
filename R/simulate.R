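# Synthetic data generator.
#
# Emulates the statistical structure the analysis assumes: i.i.d. random
# genomes at a set GC content, non-overlapping COG-labelled genes,
# per-position Poisson read coverage scaled by replicon copy ratio, and
# binomial modified-read counts with per-motif methylation probabilities
# layered over base-specific background rates. Everything is
# bit-reproducible given (seed, parameters).

#' Define a simulation condition profile
#'
#' @param label Condition name (e.g. `"bacteroid"`).
#' @param motif_meth_prob Named list/vector, motif pattern -> probability
#'   that a read at one of the motif's modified sites is called
#'   modified. An entry may itself be a named list of per-replicon
#'   probabilities with a `"default"` fallback (used for motifs whose
#'   methylation differs between chromosome and plasmids).
#' @param background_prob Named vector/list with elements `A` and `C`:
#'   modified-call probability at non-motif sites of each base.
#' @param replicon_copy_ratio Named vector/list, replicon -> copy number
#'   relative to the chromosome (chromosome must be 1).
#' @param mean_depth Mean read depth at copy ratio 1.
#' @param position_effect Optional function `(replicon, position, p) ->
#'   p` applied to the per-site probability vector, a hook for
#'   position-dependent effects (e.g. Ori->Ter methylation gradients);
#'   `NULL` (default) keeps probabilities position-independent.
#' @return A `condition_profile` object.
#' @export
condition_profile <- function(label, motif_meth_prob, background_prob,
                              replicon_copy_ratio, mean_depth,
                              position_effect = NULL) {
  bg <- unlist(background_prob)
  stopifnot(all(c("A", "C") %in% names(bg)),
            all(bg >= 0 & bg <= 1), mean_depth > 0)
  flat <- unlist(motif_meth_prob)
  stopifnot(all(flat >= 0 & flat <= 1))
  ratio <- unlist(replicon_copy_ratio)
  stopifnot(all(ratio > 0))
  if (!is.null(position_effect)) stopifnot(is.function(position_effect))
  structure(list(label = label,
                 motif_meth_prob = as.list(motif_meth_prob),
                 background_prob = bg[c("A", "C")],
                 replicon_copy_ratio = ratio,
                 mean_depth = mean_depth,
                 position_effect = position_effect),
            class = "condition_profile")
}

#' @export
print.condition_profile <- function(x, ...) {
  cat(sprintf("condition_profile '%s': depth %gx, background A=%.2f C=%.2f\n",
              x$label, x$mean_depth, x$background_prob[["A"]],
              x$background_prob[["C"]]))
  for (m in names(x$motif_meth_prob)) {
    v <- x$motif_meth_prob[[m]]
    cat(sprintf("  %s: %s\n", m,
                paste(sprintf("%s=%g", names(unlist(v)) %||% "p",
                              unlist(v)), collapse = " ")))
  }
  invisible(x)
}

#' Packaged RCAM1026 emulation profiles
#'
#' Condition profiles whose parameters are the published methylome
#' features of R. leguminosarum RCAM1026: near-complete (98%) GGCGCC
#' methylation in both states; bacteroid backgrounds of 75% (adenine)
#' and 46% (cytosine) versus a 38% cytosine background in culture;
#' bacteroid GANTC at 98% and GATC at 50% on the chromosome / 40% on
#' plasmids; and Table-1 replicon copy ratios including the
#' under-represented symbiotic plasmid (0.6) in culture. Culture values
#' the study reports only qualitatively (GANTC baseline, adenine
#' background, GATC level) are package choices documented in the methods
#' vignette. The profiles are stored as JSON under
#' `system.file("extdata/profiles", package = "bacmeth")`.
#'
#' @param condition `"bacteroid"` or `"cell_culture"`.
#' @return A `condition_profile`.
#' @export
rcam1026_profile <- function(condition = c("bacteroid", "cell_culture")) {
  condition <- match.arg(condition)
  path <- system.file("extdata", "profiles", paste0(condition, ".json"),
                      package = "bacmeth", mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  condition_profile(label = cfg$label,
                    motif_meth_prob = cfg$motif_meth_prob,
                    background_prob = unlist(cfg$background_prob),
                    replicon_copy_ratio = unlist(cfg$replicon_copy_ratio),
                    mean_depth = cfg$mean_depth)
}

#' Scaled RCAM1026-like replicon roster
#'
#' One chromosome and four plasmids with the published GC contents and
#' length proportions at roughly one tenth of genome scale (500 kb
#' chromosome), the problem size used throughout the package's
#' simulation studies.
#'
#' @return Data frame `name`, `length`, `gc`.
#' @export
rcam1026_replicons <- function() {
  data.frame(name = c("Chromosome", "pRL10", "pRL11", "pRL12", "pSym"),
             length = c(500000L, 63000L, 66000L, 84000L, 27000L),
             gc = c(61.09, 60.61, 60.89, 60.40, 58.12),
             stringsAsFactors = FALSE)
}

#' Generate a random multi-replicon genome
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc/200` and
#' `P(A) = P(T) = (100 - gc)/200`.
#'
#' @param lengths Named vector of replicon lengths in bases (names become
#'   replicon names), or a roster data frame as from
#'   [rcam1026_replicons()].
#' @param gc_percent GC content per replicon (recycled; ignored when a
#'   roster data frame supplies `gc`).
#' @param seed Integer seed; identical seeds give identical genomes.
#' @param chromosome_name Normalisation reference; defaults to the first
#'   replicon.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return A `genome_assembly`.
#' @export
make_genome <- function(lengths, gc_percent = 61, seed = 1L,
                        chromosome_name = NULL, topology = "circular") {
  if (is.data.frame(lengths)) {
    gc_percent <- lengths$gc %||% gc_percent
    lengths <- stats::setNames(lengths$length, lengths$name)
  }
  stopifnot(all(lengths > 0), all(gc_percent > 0 & gc_percent <= 100))
  nm <- names(lengths) %||% sprintf("replicon_%02d", seq_along(lengths))
  gc <- rep_len(gc_percent, length(lengths))
  seqs <- with_seed(seed, {
    vapply(seq_along(lengths), function(i) {
      pg <- gc[i] / 200
      paste(sample(c("A", "C", "G", "T"), lengths[i], replace = TRUE,
                   prob = c((100 - gc[i]) / 200, pg, pg,
                            (100 - gc[i]) / 200)),
            collapse = "")
    }, character(1))
  })
  genome_assembly(stats::setNames(seqs, nm),
                  chromosome_name = chromosome_name, topology = topology)
}

# Default COG letter frequencies for synthetic annotations, loosely
# shaped like a typical bacterial genome; "none" leaves a gene
# unannotated.
DEFAULT_COG_FREQ <- c(C = 0.05, E = 0.09, G = 0.07, H = 0.04, I = 0.03,
                      J = 0.05, K = 0.09, L = 0.05, M = 0.06, N = 0.02,
                      O = 0.04, P = 0.06, Q = 0.03, R = 0.08, S = 0.07,
                      T = 0.05, U = 0.02, V = 0.02, none = 0.13)

#' Generate non-overlapping stranded genes with COG labels
#'
#' Genes are allocated to replicons in proportion to length and placed
#' in disjoint slots (one gene per slot), so they never overlap. Each
#' gene draws one COG category (or none) from `cog_frequencies`.
#'
#' @param assembly A `genome_assembly`.
#' @param n_genes Total genes to place.
#' @param mean_len Mean gene length in bases.
#' @param cog_frequencies Named weights over COG letters; the reserved
#'   name `"none"` yields an unannotated gene. Normalised internally.
#' @param seed Integer seed.
#' @return A `gene_features` data frame.
#' @export
make_genes <- function(assembly, n_genes, mean_len = 900,
                       cog_frequencies = DEFAULT_COG_FREQ, seed = 1L) {
  stopifnot(n_genes >= 1)
  lens <- replicon_lengths(assembly)
  alloc <- pmax(round(n_genes * lens / sum(lens)), 1L)
  # largest-remainder style fixup to hit n_genes exactly
  while (sum(alloc) > n_genes) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_genes) alloc[which.max(lens / alloc)] <- alloc[which.max(lens / alloc)] + 1L
  with_seed(seed, {
    rows <- lapply(names(lens), function(nm) {
      n <- alloc[[nm]]
      if (n == 0L) return(NULL)
      slot <- lens[[nm]] %/% n
      if (slot < 60L) {
        stop("replicon '", nm, "' too small for ", n, " genes")
      }
      gene_len <- pmin(pmax(60L, round(stats::rgamma(n, shape = 4,
                                                     scale = mean_len / 4))),
                       slot - 10L)
      offset <- vapply(slot - gene_len, function(room) {
        sample.int(room, 1L) - 1L
      }, integer(1))
      start <- (seq_len(n) - 1L) * slot + offset
      data.frame(replicon = nm, start = as.integer(start),
                 end = as.integer(start + gene_len),
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    freq <- cog_frequencies / sum(cog_frequencies)
    cat_draw <- sample(names(freq), nrow(df), replace = TRUE, prob = freq)
    df$cog <- ifelse(cat_draw == "none", "", cat_draw)
    df$gene_id <- sprintf("gene_%05d", seq_len(nrow(df)))
    gene_features(df)
  })
}

# Resolve a motif's methylation probability for one replicon from a
# profile entry that is either a scalar or a per-replicon list with a
# "default" fallback.
resolve_motif_prob <- function(entry, replicon) {
  if (length(entry) == 1L && is.null(names(entry))) return(as.numeric(entry))
  entry <- unlist(entry)
  if (replicon %in% names(entry)) return(as.numeric(entry[[replicon]]))
  if ("default" %in% names(entry)) return(as.numeric(entry[["default"]]))
  if (length(entry) == 1L) return(as.numeric(entry))
  stop("no probability for replicon '", replicon, "' and no default")
}

resolve_copy_ratio <- function(profile, replicon) {
  r <- profile$replicon_copy_ratio
  if (replicon %in% names(r)) return(as.numeric(r[[replicon]]))
  1
}

#' Simulate a per-site modified-base call table
#'
#' Every unambiguous position carries exactly one call site: an A site
#' on the strand where the base reads A, or a C site on the strand where
#' it reads C. Per site, coverage is Poisson(`mean_depth` x copy ratio
#' of the replicon) and the modified-read count is Binomial(coverage,
#' p), where p is the motif probability when the site is the modified
#' position of a scanned motif occurrence (the motif rule wins over the
#' background; where sites of two motifs coincide the longer, more
#' specific pattern wins) and the base-specific background otherwise.
#'
#' @param assembly A `genome_assembly`.
#' @param motifs List of `iupac_motif` objects defining modified sites.
#' @param profile A `condition_profile`.
#' @param seed Integer seed.
#' @param occurrences Optional precomputed [scan_motifs()] result for
#'   `motifs` on `assembly` (scanned internally when `NULL`).
#' @return A `methylation_table` labelled with the profile's condition.
#' @export
simulate_calls <- function(assembly, motifs, profile, seed = 1L,
                           occurrences = NULL) {
  stopifnot(inherits(profile, "condition_profile"))
  if (is.null(occurrences)) occurrences <- scan_motifs(assembly, motifs)
  # longer pattern assigned last so it wins coincident sites
  pattern_order <- unique(occurrences$motif)
  pattern_order <- pattern_order[order(nchar(pattern_order))]
  with_seed(seed, {
    tabs <- lapply(names(assembly$replicons), function(nm) {
      chars <- strsplit(as.character(assembly$replicons[[nm]]), "",
                        fixed = TRUE)[[1]]
      keep <- chars %in% c("A", "C", "G", "T")
      L <- length(chars)
      strand <- ifelse(chars %in% c("A", "C"), "+", "-")
      site_base <- ifelse(chars %in% c("A", "T"), "A", "C")
      p <- unname(profile$background_prob[site_base])
      occ_rep <- occurrences[occurrences$replicon == nm, , drop = FALSE]
      for (m in pattern_order) {
        entry <- profile$motif_meth_prob[[m]]
        if (is.null(entry)) next  # motif not in profile: background applies
        prob <- resolve_motif_prob(entry, nm)
        rows <- occ_rep[occ_rep$motif == m, , drop = FALSE]
        sites <- c(rows$mod_site_plus, rows$mod_site_minus)
        sites <- sites[!is.na(sites)]
        p[sites + 1L] <- prob
      }
      if (!is.null(profile$position_effect)) {
        p <- profile$position_effect(nm, seq_len(L) - 1L, p)
      }
      lambda <- profile$mean_depth * resolve_copy_ratio(profile, nm)
      coverage <- stats::rpois(L, lambda)
      modified <- stats::rbinom(L, coverage, p)
      data.frame(replicon = nm, position = seq_len(L) - 1L,
                 strand = strand, base = site_base,
                 mod_type = ifelse(site_base == "A", "6mA", "4mC"),
                 coverage = coverage, modified = modified,
                 stringsAsFactors = FALSE)[keep, , drop = FALSE]
    })
    df <- do.call(rbind, tabs)
    rownames(df) <- NULL
    methylation_table(df, condition = profile$label)
  })
}

#' Simulate per-replicon sequencing depth
#'
#' Per position, depth ~ Poisson(`mean_depth` x copy ratio); the summary
#' is the arithmetic mean over all positions of the replicon.
#'
#' @inheritParams simulate_calls
#' @param track When `TRUE` also return the per-position depth track
#'   (run-length encoded bedGraph-style intervals).
#' @return A `coverage_summary` data frame, or (with `track = TRUE`) a
#'   list with elements `summary` and `track`.
#' @export
simulate_depth <- function(assembly, profile, seed = 1L, track = FALSE) {
  stopifnot(inherits(profile, "condition_profile"))
  lens <- replicon_lengths(assembly)
  with_seed(seed, {
    res <- lapply(names(lens), function(nm) {
      L <- lens[[nm]]
      depth <- stats::rpois(L, profile$mean_depth *
                              resolve_copy_ratio(profile, nm))
      summ <- data.frame(condition = profile$label, replicon = nm,
                         mean_depth = mean(depth), n_positions = L,
                         stringsAsFactors = FALSE)
      tr <- NULL
      if (track) {
        r <- rle(depth)
        end <- cumsum(r$lengths)
        tr <- data.frame(replicon = nm, start = end - r$lengths,
                         end = end, depth = r$values,
                         stringsAsFactors = FALSE)
      }
      list(summary = summ, track = tr)
    })
    summary <- do.call(rbind, lapply(res, `[[`, "summary"))
    rownames(summary) <- NULL
    class(summary) <- c("coverage_summary", "data.frame")
    if (!track) return(summary)
    list(summary = summary, track = do.call(rbind, lapply(res, `[[`, "track")))
  })
}

#' Simulate a complete analysis bundle
#'
#' Generates one genome and annotation shared by all conditions, then a
#' call table and a depth summary per condition, keeping the generating
#' profiles as ground truth for recovery tests. Derived seeds are
#' deterministic offsets of `seed`.
#'
#' @param profiles Named list of `condition_profile`s (default: the two
#'   packaged RCAM1026 emulation profiles).
#' @param seed Integer master seed.
#' @param replicons Roster data frame (`name`, `length`, `gc`); default
#'   [rcam1026_replicons()].
#' @param n_genes Genes to annotate (default 600).
#' @param motifs Motif set (default [rcam1026_motifs()]).
#' @return A `simulation_bundle`: list with `assembly`, `genes`,
#'   `motifs`, `occurrences`, `tables` (per condition), `depth` (per
#'   condition), `ground_truth` (the profiles and seed).
#' @export
simulate_bundle <- function(profiles = list(bacteroid = rcam1026_profile("bacteroid"),
                                            cell_culture = rcam1026_profile("cell_culture")),
                            seed = 1L, replicons = rcam1026_replicons(),
                            n_genes = 600L, motifs = rcam1026_motifs()) {
  seed <- as.integer(seed)
  names(profiles) <- names(profiles) %||%
    vapply(profiles, `[[`, character(1), "label")
  assembly <- make_genome(replicons, seed = seed)
  genes <- make_genes(assembly, n_genes, seed = seed + 1L)
  occurrences <- scan_motifs(assembly, motifs)
  tables <- list()
  depth <- list()
  for (i in seq_along(profiles)) {
    cn <- names(profiles)[i]
    tables[[cn]] <- simulate_calls(assembly, motifs, profiles[[i]],
                                   seed = seed + 10L + i,
                                   occurrences = occurrences)
    depth[[cn]] <- simulate_depth(assembly, profiles[[i]],
                                  seed = seed + 100L + i)
  }
  structure(list(assembly = assembly, genes = genes, motifs = motifs,
                 occurrences = occurrences, tables = tables,
                 depth = depth,
                 ground_truth = list(seed = seed, profiles = profiles)),
            class = "simulation_bundle")
}

#' Write a simulation bundle to disk
#'
#' Emits FASTA, GFF3, one simple_tsv call table and one coverage summary
#' TSV per condition, and a ground-truth JSON with the generating
#' parameters.
#'
#' @param bundle A `simulation_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(dir, "genome.fasta"),
                gff = file.path(dir, "genes.gff3"),
                ground_truth = file.path(dir, "ground_truth.json"))
  write_assembly(bundle$assembly, paths$fasta)
  write_genes_gff3(bundle$genes, paths$gff)
  for (cn in names(bundle$tables)) {
    paths[[paste0("calls_", cn)]] <- file.path(dir,
                                               sprintf("calls_%s.tsv", cn))
    write_calls(bundle$tables[[cn]], paths[[paste0("calls_", cn)]])
    paths[[paste0("depth_", cn)]] <- file.path(dir,
                                               sprintf("depth_%s.tsv", cn))
    utils::write.table(as.data.frame(bundle$depth[[cn]]),
                       paths[[paste0("depth_", cn)]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  gt <- list(seed = bundle$ground_truth$seed,
             profiles = lapply(bundle$ground_truth$profiles, function(p) {
               list(label = p$label,
                    motif_meth_prob = p$motif_meth_prob,
                    background_prob = as.list(p$background_prob),
                    replicon_copy_ratio = as.list(p$replicon_copy_ratio),
                    mean_depth = p$mean_depth)
             }))
  jsonlite::write_json(gt, paths$ground_truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
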