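# Pipeline entry points: thin compositions of the module operations that
# read a run configuration, write report tables, and record the run's
# conventions. Each has a matching subcommand in the exec/bacmeth CLI.

#' Build a run configuration
#'
#' @param fasta Path to the assembly FASTA.
#' @param gff Path to the GFF3 annotation (optional for
#'   methylation/abundance runs).
#' @param calls Named character vector/list of call-table paths, one per
#'   condition.
#' @param depth Named character vector/list of depth inputs (bedGraph
#'   track or per-replicon TSV), one per condition.
#' @param outdir Output directory.
#' @param motifs Motif set (default [rcam1026_motifs()]).
#' @param chromosome Chromosome (normalisation reference) name; default
#'   the first FASTA record.
#' @param upstream_len Promoter width in bases (default 100).
#' @param window_width,window_step Sliding-window parameters in bases
#'   (defaults 5000 and 1000).
#' @param min_coverage Site inclusion threshold in reads (default 5).
#' @param dialect Call-table dialect (`"simple_tsv"` or `"bedmethyl"`).
#' @param cog_attribute GFF3 attribute key carrying COG letters.
#' @param seed Seed for [run_simulate()].
#' @return A `run_config` list.
#' @export
run_config <- function(fasta = NULL, gff = NULL, calls = NULL,
                       depth = NULL, outdir = "bacmeth_out",
                       motifs = rcam1026_motifs(), chromosome = NULL,
                       upstream_len = 100L, window_width = 5000L,
                       window_step = 1000L, min_coverage = 5L,
                       dialect = "simple_tsv", cog_attribute = "COG",
                       seed = 1L) {
  stopifnot(upstream_len > 0, window_width > 0, window_step > 0,
            min_coverage >= 0)
  structure(list(fasta = fasta, gff = gff, calls = as.list(calls),
                 depth = as.list(depth), outdir = outdir, motifs = motifs,
                 chromosome = chromosome, upstream_len = upstream_len,
                 window_width = window_width, window_step = window_step,
                 min_coverage = min_coverage, dialect = dialect,
                 cog_attribute = cog_attribute, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Recognised keys mirror the arguments of [run_config()]; `motifs` is a
#' list of `{pattern, modified_position, modified_base_type}` entries.
#'
#' @param path Configuration file (`.yaml`/`.yml` or `.json`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  check_file(path, "config file")
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  motifs <- if (is.null(cfg$motifs)) {
    rcam1026_motifs()
  } else {
    lapply(cfg$motifs, function(m) {
      iupac_motif(m$pattern, m$modified_position, m$modified_base_type)
    })
  }
  run_config(fasta = cfg$fasta, gff = cfg$gff,
             calls = lapply(cfg$calls, as.character),
             depth = lapply(cfg$depth, as.character),
             outdir = cfg$outdir %||% "bacmeth_out", motifs = motifs,
             chromosome = cfg$chromosome,
             upstream_len = cfg$upstream_len %||% 100L,
             window_width = cfg$window_width %||% 5000L,
             window_step = cfg$window_step %||% 1000L,
             min_coverage = cfg$min_coverage %||% 5L,
             dialect = cfg$dialect %||% "simple_tsv",
             cog_attribute = cfg$cog_attribute %||% "COG",
             seed = cfg$seed %||% 1L)
}

config_params <- function(config) {
  list(upstream_len = config$upstream_len,
       window_width = config$window_width,
       window_step = config$window_step,
       min_coverage = config$min_coverage,
       palindrome_convention = "one occurrence per locus, two strand observations")
}

load_config_assembly <- function(config) {
  if (is.null(config$fasta)) io_error("config lacks 'fasta'")
  read_assembly(config$fasta, chromosome_name = config$chromosome)
}

#' Scan motifs and intersect with promoters
#'
#' Writes `motif_counts.tsv` (total and in-promoter counts per motif and
#' replicon, the layout of a motif-by-replicon distribution table),
#' `motif_occurrences.bed` and `promoter_gene_flags.tsv` (per-gene
#' motif-in-promoter indicators consumed by [run_enrich()]).
#'
#' @param config A `run_config` with `fasta`, `gff` and `outdir`.
#' @return List with `counts`, `promoter_counts`, `gene_flags`,
#'   invisibly.
#' @export
run_scan <- function(config) {
  assembly <- load_config_assembly(config)
  if (is.null(config$gff)) io_error("config lacks 'gff'")
  genes <- read_genes(config$gff, assembly,
                      cog_attribute = config$cog_attribute)
  promoters <- extract_promoters(genes, assembly,
                                 upstream_len = config$upstream_len)
  occ <- scan_motifs(assembly, config$motifs)
  totals <- count_by_replicon(occ, assembly)
  inter <- intersect_with_regions(occ, promoters, assembly)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  reps <- names(assembly$replicons)
  wide <- totals
  for (r in reps) {
    wide[[paste0(r, "_promoter")]] <-
      inter$counts[[r]][match(wide$motif, inter$counts$motif)]
  }
  write_tsv_report(wide, file.path(config$outdir, "motif_counts.tsv"),
                   config_params(config))
  occurrences_to_bed(occ, assembly,
                     file.path(config$outdir, "motif_occurrences.bed"))
  write_tsv_report(inter$gene_flags,
                   file.path(config$outdir, "promoter_gene_flags.tsv"),
                   config_params(config))
  invisible(list(counts = totals, promoter_counts = inter$counts,
                 gene_flags = inter$gene_flags))
}

#' Methylation summaries across conditions
#'
#' Reads every configured call table and writes genome/base-level means
#' (`base_methylation.tsv`), per-motif summaries
#' (`motif_methylation.tsv`), sliding-window bedGraph tracks per
#' condition and base, and (with two or more conditions) the
#' condition-comparison table (`condition_comparison.tsv`).
#'
#' @param config A `run_config` with `fasta`, `calls` and `outdir`.
#' @return List with `base_methylation`, `motif_methylation`,
#'   `comparison` (NULL for one condition), invisibly.
#' @export
run_methylation <- function(config) {
  assembly <- load_config_assembly(config)
  if (length(config$calls) == 0L) io_error("config lacks 'calls'")
  occ <- scan_motifs(assembly, config$motifs)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  base_rows <- list()
  motif_rows <- list()
  summaries <- list()
  for (cn in names(config$calls)) {
    tab <- read_calls(config$calls[[cn]], assembly,
                      dialect = config$dialect, condition = cn)
    for (b in c("A", "C")) {
      if (!any(tab$base == b)) next
      base_rows[[paste(cn, b)]] <-
        genome_base_methylation(tab, assembly, b, config$min_coverage)
      prof <- window_profile(tab, assembly, b,
                             width = config$window_width,
                             step = config$window_step,
                             min_coverage = config$min_coverage)
      write_bedgraph(prof,
                     file.path(config$outdir,
                               sprintf("windows_%s_%s.bedgraph", cn, b)),
                     name = sprintf("%s %s methylation", cn, b))
    }
    summaries[[cn]] <- motif_methylation(tab, occ, assembly,
                                         min_coverage = config$min_coverage)
    motif_rows[[cn]] <- summaries[[cn]]
  }
  base_df <- do.call(rbind, base_rows)
  rownames(base_df) <- NULL
  motif_df <- do.call(rbind, motif_rows)
  rownames(motif_df) <- NULL
  write_tsv_report(base_df, file.path(config$outdir, "base_methylation.tsv"),
                   config_params(config))
  write_tsv_report(motif_df,
                   file.path(config$outdir, "motif_methylation.tsv"),
                   config_params(config))
  comparison <- NULL
  if (length(summaries) >= 2L) {
    comparison <- compare_conditions(summaries)
    write_tsv_report(comparison,
                     file.path(config$outdir, "condition_comparison.tsv"),
                     config_params(config))
  }
  invisible(list(base_methylation = base_df, motif_methylation = motif_df,
                 comparison = comparison))
}

#' Replicon copy-number estimation
#'
#' Summarises each configured depth input and writes
#' `replicon_abundance.tsv` with per-condition ratios to the chromosome
#' (rounded to two decimals in the report; full precision is returned).
#'
#' @param config A `run_config` with `fasta`, `depth` and `outdir`.
#' @return The abundance data frame, invisibly.
#' @export
run_abundance <- function(config) {
  assembly <- load_config_assembly(config)
  if (length(config$depth) == 0L) io_error("config lacks 'depth'")
  summaries <- do.call(rbind, lapply(names(config$depth), function(cn) {
    x <- config$depth[[cn]]
    if (is.character(x) && length(x) == 1L) {
      summarize_depth(x, assembly, condition = cn)
    } else {
      summarize_depth(as.data.frame(x), assembly, condition = cn)
    }
  }))
  abundance <- relative_copy_number(summaries, assembly$chromosome)
  report <- abundance
  report$ratio <- round(report$ratio, 2)
  report$mean_depth <- round(report$mean_depth, 2)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_report(report,
                   file.path(config$outdir, "replicon_abundance.tsv"),
                   list(chromosome = assembly$chromosome))
  invisible(abundance)
}

#' COG enrichment of genes with a motif in their promoter
#'
#' Recomputes the promoter intersection from the configured assembly and
#' annotation and writes one enrichment table per motif
#' (`enrichment_<motif>.tsv`).
#'
#' @param config A `run_config` with `fasta`, `gff` and `outdir`.
#' @return Named list of enrichment data frames per motif, invisibly.
#' @export
run_enrich <- function(config) {
  assembly <- load_config_assembly(config)
  if (is.null(config$gff)) io_error("config lacks 'gff'")
  genes <- read_genes(config$gff, assembly,
                      cog_attribute = config$cog_attribute)
  promoters <- extract_promoters(genes, assembly,
                                 upstream_len = config$upstream_len)
  occ <- scan_motifs(assembly, config$motifs)
  inter <- intersect_with_regions(occ, promoters, assembly)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (m in unique(inter$gene_flags$motif)) {
    flags <- inter$gene_flags[inter$gene_flags$motif == m, , drop = FALSE]
    fg <- flags$gene_id[flags$has_motif]
    fg <- fg[fg %in% genes$gene_id[genes$cog != ""]]
    if (length(fg) == 0L) next
    res <- cog_enrichment(fg, genes)
    out[[m]] <- res
    write_tsv_report(res,
                     file.path(config$outdir,
                               sprintf("enrichment_%s.tsv", m)),
                     config_params(config))
  }
  invisible(out)
}

#' Simulate a bundle from packaged or supplied profiles
#'
#' Writes the bundle files under `<outdir>/sim` and returns a config
#' pointing at them, so downstream commands can run unchanged on the
#' synthetic data.
#'
#' @param config A `run_config`; its `seed`, `motifs` and `outdir` are
#'   used.
#' @param profiles Named list of `condition_profile`s (default the two
#'   packaged RCAM1026 emulation profiles).
#' @param ... Passed to [simulate_bundle()].
#' @return List with `bundle`, `paths` and a derived `config`,
#'   invisibly.
#' @export
run_simulate <- function(config,
                         profiles = list(bacteroid = rcam1026_profile("bacteroid"),
                                         cell_culture = rcam1026_profile("cell_culture")),
                         ...) {
  bundle <- simulate_bundle(profiles = profiles, seed = config$seed,
                            motifs = config$motifs, ...)
  dir <- file.path(config$outdir, "sim")
  paths <- write_bundle(bundle, dir)
  calls <- paths[grep("^calls_", names(paths))]
  names(calls) <- sub("^calls_", "", names(calls))
  depth <- paths[grep("^depth_", names(paths))]
  names(depth) <- sub("^depth_", "", names(depth))
  derived <- run_config(fasta = paths$fasta, gff = paths$gff,
                        calls = calls, depth = depth,
                        outdir = config$outdir, motifs = config$motifs,
                        chromosome = names(bundle$assembly$replicons)[1],
                        upstream_len = config$upstream_len,
                        window_width = config$window_width,
                        window_step = config$window_step,
                        min_coverage = config$min_coverage,
                        dialect = "simple_tsv", seed = config$seed)
  invisible(list(bundle = bundle, paths = paths, config = derived))
}

#' Assemble a combined report directory
#'
#' Collects the tables previously written by the scan, methylation,
#' abundance and enrichment commands into `<outdir>/report`, together
#' with a `metadata.json` recording the tool version, parameters and
#' analysis conventions. Never recomputes; a missing upstream artifact
#' is an error naming it.
#'
#' @param config The `run_config` used for the upstream commands.
#' @param require Artifact file names that must exist (defaults to the
#'   scan, methylation and abundance tables).
#' @return Path of the report directory, invisibly.
#' @export
run_report <- function(config,
                       require = c("motif_counts.tsv",
                                   "base_methylation.tsv",
                                   "motif_methylation.tsv",
                                   "replicon_abundance.tsv")) {
  missing <- require[!file.exists(file.path(config$outdir, require))]
  if (length(missing) > 0) {
    io_error(paste0("missing upstream artifact(s): ",
                    paste(missing, collapse = ", "),
                    " - run the corresponding command first"))
  }
  report_dir <- file.path(config$outdir, "report")
  dir.create(report_dir, showWarnings = FALSE, recursive = TRUE)
  tsvs <- list.files(config$outdir, pattern = "\\.tsv$", full.names = TRUE)
  file.copy(tsvs, report_dir, overwrite = TRUE)
  meta <- list(tool = "bacmeth", version = pkg_version(),
               parameters = config_params(config),
               chromosome = config$chromosome,
               conventions = list(
                 coordinates = "0-based half-open internal, 1-based inclusive in GFF3",
                 palindromic_sites = "one occurrence per locus; strand calls are separate observations",
                 site_summaries = "unweighted mean of per-site percentages"),
               inputs = list(fasta = config$fasta, gff = config$gff,
                             calls = config$calls, depth = config$depth))
  jsonlite::write_json(meta, file.path(report_dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report_dir)
}
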