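# Protein records, FASTA IO, composition tables, packaged manifests.

#' Create a protein record
#'
#' @param id unique identifier (first whitespace-delimited token of a FASTA
#'   header).
#' @param sequence amino-acid sequence over the 20 canonical one-letter codes
#'   plus the tolerated ambiguity codes B, Z, X, U. Lower case is normalized
#'   to upper case.
#' @param description free-text description (rest of the FASTA header).
#' @return An object of class `protein_record` with elements `id`,
#'   `description`, `sequence`.
#' @examples
#' protein_record("p1", "SSSG")
#' @export
protein_record <- function(id, sequence, description = "") {
  if (!nzchar(id)) stop("record id must be non-empty")
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("sequence of record '", id, "' is empty")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  allowed <- c(AA_ALPHABET, AMBIGUITY_CODES)
  bad <- which(!chars %in% allowed)
  if (length(bad))
    stop("illegal character '", chars[bad[1]], "' in record '", id,
         "' at position ", bad[1])
  amb <- chars[chars %in% AMBIGUITY_CODES]
  if (length(amb))
    for (code in unique(amb))
      warning("record '", id, "': ambiguity code '", code, "' (",
              sum(amb == code), "x)", call. = FALSE)
  structure(list(id = id, description = description, sequence = sequence),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  n <- nchar(x$sequence)
  head <- substr(x$sequence, 1, 40)
  cat("<protein_record>", x$id, paste0("(", n, " aa)"), "\n")
  cat(" ", if (n > 40) paste0(head, "...") else head, "\n")
  invisible(x)
}

#' Read a protein FASTA file
#'
#' Sequences are normalized to upper case; one warning is recorded per
#' ambiguity code encountered; an illegal character is an error naming the
#' record and position.
#'
#' @param path path to a FASTA file.
#' @return A named list of [protein_record()]s, order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  desc <- sub("^\\S+\\s*", "", headers)
  recs <- mapply(protein_record, ids, as.character(set), desc,
                 SIMPLIFY = FALSE)
  stats::setNames(recs, ids)
}

#' Write protein records to FASTA
#'
#' @param records a [protein_record()] or list of them.
#' @param path output path.
#' @param width line width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "protein_record")) records <- list(records)
  lines <- unlist(lapply(records, function(r) {
    header <- if (nzchar(r$description))
      paste0(">", r$id, " ", r$description) else paste0(">", r$id)
    n <- nchar(r$sequence)
    starts <- seq(1L, n, by = width)
    c(header, substring(r$sequence, starts, pmin(starts + width - 1L, n)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a measured composition table
#'
#' Reads a two-column TSV (`channel<TAB>fraction`) as produced by an
#' amino-acid analyzer export, validates the channel names against the active
#' scheme, and renormalizes the fractions to sum to 1 (the analyzer reports
#' relative content; raw chromatograms need not be normalized). The original
#' column sum is kept as the `raw_sum` field. Channels of the scheme absent
#' from the table are set to 0.
#'
#' @param path path to the TSV file.
#' @param scheme the [hydrolysis_scheme()] the measurement was made under.
#' @return A [composition_vector()] with `n_residues = NA` (measured, not
#'   counted).
#' @export
read_composition_table <- function(path, scheme) {
  stopifnot(inherits(scheme, "hydrolysis_scheme"))
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("channel", "fraction") %in% names(tab)))
    stop("composition table must have header 'channel<TAB>fraction'")
  if (anyDuplicated(tab$channel))
    stop("duplicate channel in table: ",
         paste(unique(tab$channel[duplicated(tab$channel)]), collapse = ", "))
  unknown <- setdiff(tab$channel, scheme$channels)
  if (length(unknown))
    stop("unknown channel(s) for scheme '", scheme$name, "': ",
         paste(unknown, collapse = ", "), "; allowed: ",
         paste(scheme$channels, collapse = ", "))
  if (any(tab$fraction < 0))
    stop("negative fraction for channel ",
         tab$channel[which(tab$fraction < 0)[1]])
  raw <- stats::setNames(rep(0, length(scheme$channels)), scheme$channels)
  raw[tab$channel] <- tab$fraction
  composition_vector(raw, scheme, n_residues = NA_real_, raw_sum = sum(raw))
}

#' Write a composition vector as a TSV table
#'
#' @param x a [composition_vector()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(x, path) {
  stopifnot(inherits(x, "composition_vector"))
  utils::write.table(
    data.frame(channel = names(x$fractions), fraction = unname(x$fractions)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Candidate manifest of deposit-specific proteins
#'
#' Loads the packaged manifest of the 19 proteins specifically identified in
#' the intranuclear inclusions of the index patient brain (description and
#' UniProt accession per row). Sequences are not bundled; see
#' `scripts/fetch_table1.R` in the source repository for the documented
#' one-time fetch used by the accession-dependent checks.
#'
#' @return A data.frame with columns `description` and `accession`, class
#'   `candidate_manifest`.
#' @examples
#' m <- load_table1_manifest()
#' nrow(m)  # 19
#' @export
load_table1_manifest <- function() {
  path <- system.file("extdata", "table1_manifest.tsv",
                      package = "depositcomp", mustWork = TRUE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab$accession))
    stop("manifest accessions are not unique")
  class(tab) <- c("candidate_manifest", "data.frame")
  tab
}

#' Packaged candidate sequences, when fetched
#'
#' Returns the records of the manifest proteins if the optional sequence
#' fixture (created by `scripts/fetch_table1.R`) is present in the installed
#' package, otherwise `NULL`.
#'
#' @return Named list of [protein_record()]s, or `NULL` if the fixture has
#'   not been fetched.
#' @export
load_table1_sequences <- function() {
  path <- system.file("extdata", "table1_sequences.fasta",
                      package = "depositcomp")
  if (!nzchar(path) || !file.exists(path)) return(NULL)
  read_fasta(path)
}
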