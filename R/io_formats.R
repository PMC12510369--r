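# Readers and writers for all external tables and sequence files.
# Coordinates in annotation tables are 1-based inclusive; delimiter is tab;
# encoding is UTF-8. Every reader validates and reports rejected rows via the
# "parse_summary" attribute rather than dropping them silently.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Read a protein FASTA file
#'
#' Parses a protein FASTA file into a tibble of protein entries. The accession
#' is the header token before the first whitespace (PROKKA-style ids such as
#' `MMBJNONL_14124`); the remainder of the header becomes the description.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with columns `accession`, `description`, `sequence` and
#'   `length`. Sequences are uppercase strings over the 20 canonical residues
#'   plus `X`.
#' @details Duplicate accessions are a hard error (downstream joins assume
#'   accessions are unique keys). An empty file yields an empty tibble with a
#'   warning.
#' @export
read_protein_fasta <- function(path) {
  stopifnot(file.exists(path))
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) {
    warning("FASTA file '", path, "' contains no records")
    return(tibble::tibble(accession = character(), description = character(),
                          sequence = character(), length = integer()))
  }
  headers <- names(aas)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  dup <- accession[duplicated(accession)]
  if (length(dup) > 0L) {
    stop("duplicate accession(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "))
  }
  sequence <- unname(toupper(as.character(aas)))
  bad <- !grepl(sprintf("^[%s]*$", paste(AA_ALPHABET, collapse = "")), sequence)
  if (any(bad)) {
    stop("non-canonical residues in sequence(s): ",
         paste(accession[bad], collapse = ", "))
  }
  tibble::tibble(accession = accession, description = description,
                 sequence = sequence, length = nchar(sequence))
}

#' Write protein entries to FASTA
#'
#' @param proteins Tibble as returned by [read_protein_fasta()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_protein_fasta <- function(proteins, path) {
  stopifnot(all(c("accession", "sequence") %in% names(proteins)))
  aas <- Biostrings::AAStringSet(proteins$sequence)
  desc <- proteins$description %||% rep("", nrow(proteins))
  names(aas) <- ifelse(is.na(desc) | desc == "", proteins$accession,
                       paste(proteins$accession, desc))
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

parse_summary_attr <- function(x, n_read, n_rejected, messages = character()) {
  attr(x, "parse_summary") <- list(n_read = n_read, n_kept = nrow(x),
                                   n_rejected = n_rejected,
                                   messages = messages)
  x
}

#' Parse summary of a reader result
#'
#' Readers in this package never drop rows silently: each returns its result
#' with an attached summary of how many input rows were read, kept and
#' rejected.
#'
#' @param x A tibble returned by one of the table readers.
#' @return A list with elements `n_read`, `n_kept`, `n_rejected`, `messages`.
#' @export
parse_summary <- function(x) {
  attr(x, "parse_summary") %||%
    list(n_read = nrow(x), n_kept = nrow(x), n_rejected = 0L,
         messages = character())
}

#' Read an InterProScan-style annotation TSV
#'
#' Reads the tab-separated output dialect of InterProScan (11-15 columns, no
#' header): protein accession, sequence MD5, sequence length, analysis,
#' signature accession, signature description, start, end, score, status,
#' date, and optionally the integrated InterPro entry accession and
#' description. Coordinates are 1-based inclusive.
#'
#' @param path Path to the TSV file. Lines starting with `#` are ignored.
#' @return A tibble of annotation rows with columns `protein_accession`,
#'   `source_db`, `signature_id`, `signature_desc`, `start`, `end`,
#'   `entry_id`, `entry_desc`, `evalue`. Missing integrated entries are `NA`
#'   (never empty strings), so the "unannotated" predicate is unambiguous.
#'   A [parse_summary()] attribute reports rejected rows.
#' @details Rows with `start > end` are rejected with a warning. A malformed
#'   InterPro id (anything not `IPR` + 6 digits) keeps the row but drops the
#'   entry id, with a warning.
#' @export
read_annotation_tsv <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0L) {
    out <- tibble::tibble(protein_accession = character(),
                          source_db = character(), signature_id = character(),
                          signature_desc = character(), start = integer(),
                          end = integer(), entry_id = character(),
                          entry_desc = character(), evalue = double())
    return(parse_summary_attr(out, 0L, 0L))
  }
  if (ncol(raw) < 11L) {
    stop("annotation TSV '", path, "' has ", ncol(raw),
         " columns; at least 11 expected")
  }
  col <- function(i) if (i <= ncol(raw)) raw[[i]] else rep(NA_character_, nrow(raw))
  blank_na <- function(x) ifelse(is.na(x) | x == "" | x == "-", NA_character_, x)
  out <- tibble::tibble(
    protein_accession = col(1L),
    source_db = col(4L),
    signature_id = col(5L),
    signature_desc = blank_na(col(6L)),
    start = suppressWarnings(as.integer(col(7L))),
    end = suppressWarnings(as.integer(col(8L))),
    entry_id = blank_na(col(12L)),
    entry_desc = blank_na(col(13L)),
    evalue = suppressWarnings(as.numeric(blank_na(col(9L))))
  )
  msgs <- character()
  bad_coord <- is.na(out$start) | is.na(out$end) | out$start > out$end |
    out$start < 1L
  if (any(bad_coord)) {
    msgs <- c(msgs, sprintf("%d row(s) rejected: invalid coordinates (start > end or non-numeric)",
                            sum(bad_coord)))
    warning(msgs[length(msgs)])
  }
  out <- out[!bad_coord, , drop = FALSE]
  bad_ipr <- !is.na(out$entry_id) & !grepl("^IPR[0-9]{6}$", out$entry_id)
  if (any(bad_ipr)) {
    msg <- sprintf("%d row(s) with malformed InterPro id kept with entry_id set to NA",
                   sum(bad_ipr))
    msgs <- c(msgs, msg)
    warning(msg)
    out$entry_id[bad_ipr] <- NA_character_
  }
  parse_summary_attr(out, nrow(raw), sum(bad_coord), msgs)
}

#' Write annotation rows as an InterProScan-style TSV
#'
#' @param annotations Tibble as returned by [read_annotation_tsv()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_tsv <- function(annotations, path) {
  a <- annotations
  dash <- function(x) ifelse(is.na(x), "-", as.character(x))
  lines <- paste(a$protein_accession, "-", "-", a$source_db, a$signature_id,
                 dash(a$signature_desc), a$start, a$end, dash(a$evalue),
                 "T", "-", dash(a$entry_id), dash(a$entry_desc),
                 sep = "\t")
  writeLines(c("# InterProScan-style TSV; coordinates 1-based inclusive",
               lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read a DIAMOND-style tabular alignment file
#'
#' Reads the 12-column blast tabular format (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore) with one appended
#' column holding a semicolon-delimited subject lineage
#' (superkingdom;...;species, possibly truncated or empty).
#'
#' @param path Path to the tab-separated alignment file (no header; `#`
#'   comment lines ignored).
#' @return A tibble with columns `query_accession`, `subject_accession`,
#'   `pct_identity`, `align_length`, `evalue`, `bitscore`, `subject_lineage`,
#'   with a [parse_summary()] attribute.
#' @details Rows with non-positive bitscore are rejected with a warning;
#'   lineage strings are kept verbatim (parsing into ranks happens in the
#'   taxonomy functions).
#' @export
read_alignment_tsv <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0L) {
    out <- tibble::tibble(query_accession = character(),
                          subject_accession = character(),
                          pct_identity = double(), align_length = integer(),
                          evalue = double(), bitscore = double(),
                          subject_lineage = character())
    return(parse_summary_attr(out, 0L, 0L))
  }
  if (ncol(raw) < 12L) {
    stop("alignment table '", path, "' has ", ncol(raw),
         " columns; at least 12 expected")
  }
  lineage <- if (ncol(raw) >= 13L) raw[[13L]] else rep(NA_character_, nrow(raw))
  out <- tibble::tibble(
    query_accession = raw[[1L]],
    subject_accession = raw[[2L]],
    pct_identity = suppressWarnings(as.numeric(raw[[3L]])),
    align_length = suppressWarnings(as.integer(raw[[4L]])),
    evalue = suppressWarnings(as.numeric(raw[[11L]])),
    bitscore = suppressWarnings(as.numeric(raw[[12L]])),
    subject_lineage = ifelse(is.na(lineage), "", lineage)
  )
  bad <- is.na(out$bitscore) | out$bitscore <= 0
  msgs <- character()
  if (any(bad)) {
    msgs <- sprintf("%d row(s) rejected: missing or non-positive bitscore", sum(bad))
    warning(msgs)
  }
  out <- out[!bad, , drop = FALSE]
  parse_summary_attr(out, nrow(raw), sum(bad), msgs)
}

#' Write alignments as DIAMOND-style tabular
#'
#' Emits the 12 standard blast tabular columns plus the appended lineage
#' column. Fields this package does not model (mismatch, gapopen, coordinate
#' columns) are written as zeros.
#'
#' @param alignments Tibble as returned by [read_alignment_tsv()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment_tsv <- function(alignments, path) {
  a <- alignments
  lines <- paste(a$query_accession, a$subject_accession, a$pct_identity,
                 a$align_length, 0L, 0L, 1L, a$align_length, 1L,
                 a$align_length, a$evalue, a$bitscore,
                 ifelse(is.na(a$subject_lineage), "", a$subject_lineage),
                 sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a fractionated protein-identification table
#'
#' Reads a delimited table (tab or comma, detected from the header line) with
#' header columns `accession`, `fraction`, `sample_id`, `spectral_count`,
#' `unique_peptides`. One row is one protein observation in one fraction of
#' one sample.
#'
#' @param path Path to the identification table.
#' @return A tibble with columns `protein_accession`, `fraction` (factor with
#'   levels `pellet`, `supernatant`), `sample_id`, `spectral_count`,
#'   `unique_peptides`.
#' @details Unknown fraction labels and negative counts are hard errors, as is
#'   `spectral_count < unique_peptides` (a spectral count tallies all
#'   peptide-spectrum matches, so it can never undercut the unique-peptide
#'   count).
#' @export
read_identifications <- function(path) {
  stopifnot(file.exists(path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  needed <- c("accession", "fraction", "sample_id", "spectral_count",
              "unique_peptides")
  if (!all(needed %in% names(raw))) {
    stop("identification table '", path, "' must have header columns: ",
         paste(needed, collapse = ", "))
  }
  out <- tibble::tibble(
    protein_accession = raw$accession,
    fraction = raw$fraction,
    sample_id = raw$sample_id,
    spectral_count = suppressWarnings(as.integer(raw$spectral_count)),
    unique_peptides = suppressWarnings(as.integer(raw$unique_peptides))
  )
  validate_identifications(out)
  out$fraction <- factor(out$fraction, levels = FRACTION_LEVELS)
  parse_summary_attr(out, nrow(raw), 0L)
}

validate_identifications <- function(ids) {
  bad_frac <- !as.character(ids$fraction) %in% FRACTION_LEVELS
  if (any(bad_frac)) {
    stop("unknown fraction label(s): ",
         paste(unique(as.character(ids$fraction)[bad_frac]), collapse = ", "),
         " (allowed: ", paste(FRACTION_LEVELS, collapse = ", "), ")")
  }
  if (anyNA(ids$spectral_count) || anyNA(ids$unique_peptides) ||
      any(ids$spectral_count < 0L) || any(ids$unique_peptides < 0L)) {
    stop("spectral_count and unique_peptides must be non-negative integers")
  }
  if (any(ids$spectral_count < ids$unique_peptides)) {
    stop("spectral_count < unique_peptides in ",
         sum(ids$spectral_count < ids$unique_peptides), " row(s)")
  }
  invisible(ids)
}

#' Write a protein-identification table
#'
#' @param ids Tibble as returned by [read_identifications()].
#' @param path Output path.
#' @param delim Field delimiter, `"\t"` (default) or `","`.
#' @return Invisibly, `path`.
#' @export
write_identifications <- function(ids, path, delim = "\t") {
  out <- tibble::tibble(accession = ids$protein_accession,
                        fraction = as.character(ids$fraction),
                        sample_id = ids$sample_id,
                        spectral_count = ids$spectral_count,
                        unique_peptides = ids$unique_peptides)
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

REPORT_COLUMNS <- c("accession", "MW", "entry_ids", "entry_descs",
                    "matched_keywords", "localization", "sup_spectral_count",
                    "pellet_spectral_count", "rank")

#' Write a candidate report
#'
#' Writes ranked candidate records (see [rank_candidates()]) in a fixed,
#' deterministic column order: accession, MW, entry_ids, entry_descs,
#' matched_keywords, localization, sup_spectral_count, pellet_spectral_count,
#' rank. List-valued fields are `;`-joined in TSV; JSON is an array of flat
#' objects.
#'
#' @param records Candidate-record tibble from [rank_candidates()].
#' @param path Output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_candidate_report <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  join <- function(x) vapply(x, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) "" else paste(v, collapse = ";")
  }, character(1))
  flat <- tibble::tibble(
    accession = as.character(records$protein_accession %||% character()),
    MW = if (nrow(records)) round(records$molecular_weight) else numeric(),
    entry_ids = if (nrow(records)) join(records$entry_ids) else character(),
    entry_descs = if (nrow(records)) join(records$entry_descs) else character(),
    matched_keywords = if (nrow(records)) join(records$matched_keywords) else character(),
    localization = as.character(records$localization %||% character()),
    sup_spectral_count = records$sup_count %||% integer(),
    pellet_spectral_count = records$pellet_count %||% integer(),
    rank = records$rank %||% integer()
  )
  names(flat) <- REPORT_COLUMNS
  if (format == "tsv") {
    body <- strsplit(readr::format_tsv(flat), "\n", fixed = TRUE)[[1]]
    writeLines(c("# ghmine candidate report; coordinates 1-based inclusive",
                 body), path, useBytes = TRUE)
  } else {
    jsonlite::write_json(flat, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a candidate report written by [write_candidate_report()]
#'
#' @param path Path to the TSV or JSON report.
#' @param format `"tsv"` or `"json"`; guessed from the file extension by
#'   default.
#' @return A flat tibble with the report columns.
#' @export
read_candidate_report <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path)) "json" else "tsv"
  if (format == "json") {
    out <- tibble::as_tibble(jsonlite::fromJSON(path))
    if (nrow(out) == 0L) {
      out <- tibble::as_tibble(setNames(
        rep(list(character()), length(REPORT_COLUMNS)), REPORT_COLUMNS))
    }
    return(out)
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE,
                  col_types = readr::cols(
                    accession = readr::col_character(),
                    MW = readr::col_double(),
                    entry_ids = readr::col_character(),
                    entry_descs = readr::col_character(),
                    matched_keywords = readr::col_character(),
                    localization = readr::col_character(),
                    sup_spectral_count = readr::col_integer(),
                    pellet_spectral_count = readr::col_integer(),
                    rank = readr::col_integer()))
}
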