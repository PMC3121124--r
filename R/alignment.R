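#' Construct a domain alignment
#'
#' A `domain_alignment` holds one domain family's multiple sequence
#' alignment together with the organism each row comes from.  Organism tags
#' are what allows rows of two different domain alignments to be paired
#' when computing inter-domain mutual information.
#'
#' @param domain_id Identifier of the domain family.
#' @param seqs Named character vector of aligned sequences (names are
#'   sequence identifiers); all sequences must have equal length.
#' @param organisms Optional character vector of organism identifiers, one
#'   per sequence.  If `NULL` they are parsed from the sequence names with
#'   [organism_from_id()].
#' @param organism_regex Optional regex with one capture group used to
#'   extract the organism from each sequence name; see [organism_from_id()].
#' @return An object of class `domain_alignment` with elements
#'   `domain_id`, `seq_ids`, `organisms`, `seqs`, `mat` (integer-encoded
#'   residues, rows x columns), `n_rows`, `n_cols`.
#' @seealso [read_alignment()], [pair_rows()], [compute_domain_mi()]
#' @export
domain_alignment <- function(domain_id, seqs, organisms = NULL,
                             organism_regex = NULL) {
  stopifnot(is.character(domain_id), length(domain_id) == 1L, nzchar(domain_id))
  if (length(seqs) == 0L) stop("alignment '", domain_id, "' has no rows")
  seq_ids <- names(seqs)
  if (is.null(seq_ids)) seq_ids <- paste0("seq", seq_along(seqs))
  if (is.null(organisms)) organisms <- organism_from_id(seq_ids, organism_regex)
  stopifnot(length(organisms) == length(seqs))
  mat <- encode_residues(unname(seqs))
  structure(
    list(domain_id = domain_id,
         seq_ids = seq_ids,
         organisms = as.character(organisms),
         seqs = stats::setNames(unname(seqs), seq_ids),
         mat = mat,
         n_rows = nrow(mat),
         n_cols = ncol(mat)),
    class = "domain_alignment")
}

#' @export
print.domain_alignment <- function(x, ...) {
  cat("domain_alignment '", x$domain_id, "': ", x$n_rows, " rows x ",
      x$n_cols, " columns, ", length(unique(x$organisms)),
      " organism(s)\n", sep = "")
  invisible(x)
}

#' Parse organism identifiers out of sequence names
#'
#' By default the token after the last underscore is taken as the organism
#' mnemonic, matching UniProt-style names such as `RL12_HUMAN` (a trailing
#' `/start-end` Pfam coordinate suffix is stripped first).  A custom regex
#' with exactly one capture group can be supplied instead.
#'
#' @param ids Character vector of sequence names.
#' @param regex Optional regex whose first capture group is the organism.
#' @return Character vector of organism identifiers.
#' @export
#' @examples
#' organism_from_id(c("RL12_HUMAN/1-120", "RL12_YEAST"))
organism_from_id <- function(ids, regex = NULL) {
  stripped <- sub("/\\d+-\\d+$", "", ids)
  if (is.null(regex)) return(sub(".*_", "", stripped))
  m <- regmatches(stripped, regexec(regex, stripped))
  vapply(m, function(g) {
    if (length(g) < 2L) stop("organism regex did not match: ", g[1L])
    g[2L]
  }, character(1L))
}

#' Read a domain alignment from Stockholm or aligned-FASTA
#'
#' File parsing is delegated to [Biostrings::readAAMultipleAlignment()];
#' the format is auto-detected from the `# STOCKHOLM` magic line unless
#' given explicitly.
#'
#' @param path Path to the alignment file.
#' @param domain_id Domain identifier; defaults to the file name without
#'   extension.
#' @param format `"auto"`, `"stockholm"` or `"fasta"`.
#' @param organism_regex Passed to [organism_from_id()].
#' @return A [domain_alignment()].
#' @export
read_alignment <- function(path, domain_id = NULL,
                           format = c("auto", "stockholm", "fasta"),
                           organism_regex = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(Biostrings::unmasked(aln))
  if (is.null(domain_id))
    domain_id <- sub("\\.[^.]*$", "", basename(path))
  domain_alignment(domain_id, seqs, organism_regex = organism_regex)
}

#' Read every alignment in a directory
#'
#' @param dir Directory containing `.sto`/`.stk`/`.stockholm`/`.fa`/
#'   `.fasta`/`.afa` files, one domain per file.
#' @param organism_regex Passed to [organism_from_id()].
#' @return Named list of [domain_alignment()] objects keyed by domain id.
#' @export
read_alignment_dir <- function(dir, organism_regex = NULL) {
  files <- list.files(dir, pattern = "\\.(sto|stk|stockholm|fa|fasta|afa)$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no alignment files found in ", dir)
  alns <- lapply(files, read_alignment, organism_regex = organism_regex)
  stats::setNames(alns, vapply(alns, `[[`, character(1L), "domain_id"))
}

#' Write a domain alignment in Stockholm format
#'
#' @param al A [domain_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(al, path) {
  stopifnot(inherits(al, "domain_alignment"))
  width <- max(nchar(al$seq_ids)) + 2L
  lines <- c("# STOCKHOLM 1.0",
             paste0("#=GF ID ", al$domain_id),
             sprintf("%-*s%s", width, al$seq_ids, al$seqs),
             "//")
  writeLines(lines, path)
  invisible(path)
}
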