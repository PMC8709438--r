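# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

pkg_version <- function() as.character(utils::packageVersion("bacmeth"))

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so library functions do not
#' perturb user-level reproducibility.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Parameter digest for the header comment carried by every report table.
param_digest <- function(params) {
  if (is.null(params) || length(params) == 0L) return("")
  paste(sprintf("%s=%s", names(params),
                vapply(params, function(p) paste(format(p), collapse = ","),
                       character(1))),
        collapse = " ")
}

#' Write a report table as TSV with a version/parameter header comment
#' @noRd
write_tsv_report <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bacmeth %s | %s", pkg_version(), param_digest(params)),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Condition raised for I/O and configuration problems (CLI exit code 2).
io_error <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("bacmeth_io_error", "error", "condition"),
                 list(message = msg, call = call)))
}

check_file <- function(path, what = "file") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    io_error(sprintf("%s not found: %s", what, paste(path, collapse = ", ")))
  }
  invisible(path)
}
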