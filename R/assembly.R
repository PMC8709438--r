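# Genome assembly container: named replicon sequences plus the replicon
# designated as the normalisation reference (the chromosome).

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Construct a genome assembly from replicon sequences
#'
#' A bacterial genome is represented as an ordered set of named replicons
#' (one chromosome plus any plasmids), each a nucleotide sequence with a
#' topology. Internal coordinates throughout the package are 0-based
#' half-open on the forward strand; report output is 1-based inclusive.
#'
#' @param replicons A named [Biostrings::DNAStringSet] or named character
#'   vector of sequences (uppercased on input).
#' @param chromosome_name Name of the replicon used as the normalisation
#'   reference for copy-number ratios. Defaults to the first replicon.
#' @param topology `"circular"` (default) or `"linear"`; recycled across
#'   replicons.
#' @return An object of class `genome_assembly`: a list with elements
#'   `replicons` (DNAStringSet), `chromosome` and `topology` (named
#'   character vector).
#' @export
genome_assembly <- function(replicons, chromosome_name = NULL,
                            topology = "circular") {
  if (is.character(replicons)) {
    replicons <- Biostrings::DNAStringSet(toupper(replicons))
  }
  if (!methods::is(replicons, "DNAStringSet")) {
    stop("replicons must be a DNAStringSet or named character vector")
  }
  nm <- names(replicons)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    stop("every replicon must be named")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate replicon names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (any(Biostrings::width(replicons) == 0L)) stop("empty replicon sequence")
  chromosome_name <- chromosome_name %||% nm[1]
  if (!chromosome_name %in% nm) {
    stop("chromosome_name '", chromosome_name, "' is not a replicon name")
  }
  topology <- match.arg(topology, c("circular", "linear"), several.ok = TRUE)
  topology <- stats::setNames(rep_len(topology, length(nm)), nm)
  structure(list(replicons = replicons, chromosome = chromosome_name,
                 topology = topology),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("genome_assembly: %d replicon(s), chromosome = '%s'\n",
              length(x$replicons), x$chromosome))
  info <- data.frame(replicon = names(x$replicons),
                     length = Biostrings::width(x$replicons),
                     topology = unname(x$topology[names(x$replicons)]),
                     gc_percent = round(gc_content(x), 2))
  print(info, row.names = FALSE)
  invisible(x)
}

#' Replicon lengths of an assembly
#' @param assembly A `genome_assembly`.
#' @return Named integer vector of replicon lengths in bases.
#' @export
replicon_lengths <- function(assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  stats::setNames(Biostrings::width(assembly$replicons),
                  names(assembly$replicons))
}

#' Read a multi-record FASTA assembly
#'
#' One replicon per FASTA record; record identifiers (first whitespace
#' token of the header) must be unique. Sequences are uppercased; IUPAC
#' ambiguity codes are accepted, any other character is rejected with its
#' position.
#'
#' @param fasta_path Path to a FASTA file.
#' @inheritParams genome_assembly
#' @return A `genome_assembly`.
#' @export
read_assembly <- function(fasta_path, chromosome_name = NULL,
                          topology = "circular") {
  check_file(fasta_path, "FASTA file")
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta_path),
                   error = function(e) {
                     io_error(sprintf("cannot parse FASTA '%s': %s",
                                      fasta_path, conditionMessage(e)))
                   })
  if (length(seqs) == 0L) io_error(sprintf("empty FASTA file: %s", fasta_path))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  bad <- Biostrings::alphabetFrequency(seqs)
  allowed <- colnames(bad) %in% IUPAC_LETTERS
  offending <- rowSums(bad[, !allowed, drop = FALSE])
  if (any(offending > 0)) {
    i <- which(offending > 0)[1]
    chars <- strsplit(as.character(seqs[[i]]), "", fixed = TRUE)[[1]]
    pos <- which(!chars %in% IUPAC_LETTERS)[1]
    stop(sprintf("non-IUPAC character '%s' in record '%s' at position %d",
                 chars[pos], names(seqs)[i], pos))
  }
  genome_assembly(seqs, chromosome_name = chromosome_name,
                  topology = topology)
}

#' Write an assembly to FASTA
#' @param assembly A `genome_assembly`.
#' @param path Output FASTA path.
#' @param width Line width for wrapping sequences.
#' @return The path, invisibly.
#' @export
write_assembly <- function(assembly, path, width = 70L) {
  stopifnot(inherits(assembly, "genome_assembly"))
  Biostrings::writeXStringSet(assembly$replicons, path, width = width)
  invisible(path)
}

#' GC content in percent
#'
#' 100 * (#G + #C) / (#A + #C + #G + #T); ambiguous bases are excluded
#' from numerator and denominator.
#'
#' @param x A `genome_assembly` (returns a named vector, one value per
#'   replicon), a [Biostrings::DNAString], or a character sequence.
#' @return Percent GC. A sequence with no unambiguous base is an error.
#' @export
gc_content <- function(x) {
  if (inherits(x, "genome_assembly")) {
    freq <- Biostrings::alphabetFrequency(x$replicons)
    gc <- freq[, "G"] + freq[, "C"]
    acgt <- gc + freq[, "A"] + freq[, "T"]
    if (any(acgt == 0)) {
      stop("replicon with no unambiguous bases: ",
           paste(names(x$replicons)[acgt == 0], collapse = ", "))
    }
    return(stats::setNames(100 * gc / acgt, names(x$replicons)))
  }
  if (is.character(x)) x <- Biostrings::DNAString(toupper(x))
  freq <- Biostrings::alphabetFrequency(x)
  gc <- freq[["G"]] + freq[["C"]]
  acgt <- gc + freq[["A"]] + freq[["T"]]
  if (acgt == 0) stop("sequence contains no unambiguous bases")
  100 * gc / acgt
}

#' Summary checks against the deposited RCAM1026 assembly
#'
#' Convenience for users holding the deposited genome (GenBank
#' CP084696-CP084700): reports chromosome length, chromosome GC percent
#' and the site-level GANTC count on the chromosome, the quantities most
#' useful for verifying a local copy of the reference.
#'
#' @param fasta_path Path to the deposited multi-record FASTA.
#' @param chromosome_name Record name of the chromosome (defaults to the
#'   longest record).
#' @return A list with `chromosome_length`, `chromosome_gc` and
#'   `gantc_chromosome_sites`.
#' @export
verify_reference_assembly <- function(fasta_path, chromosome_name = NULL) {
  asm <- read_assembly(fasta_path)
  if (is.null(chromosome_name)) {
    chromosome_name <- names(asm$replicons)[which.max(replicon_lengths(asm))]
  }
  asm$chromosome <- chromosome_name
  occ <- scan_motif(asm, iupac_motif("GANTC", 2L, "6mA"))
  list(chromosome_length = unname(replicon_lengths(asm)[chromosome_name]),
       chromosome_gc = unname(gc_content(asm)[chromosome_name]),
       gantc_chromosome_sites = sum(occ$replicon == chromosome_name))
}
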