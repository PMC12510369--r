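# Keyword screen over functional annotations: flag glycoside-hydrolase
# candidate genes, retaining unannotated genes as candidates for novelty.

#' Default glycoside-hydrolase keyword set
#'
#' The eight search strings used to mine annotations for pullulan-degrading
#' enzyme candidates: amylase-superfamily (GH13) and GH57 family labels plus
#' generic hydrolase and substrate terms.
#'
#' @return Character vector of keywords.
#' @export
default_keywords <- function() {
  c("family 13", "GH13", "family 57", "GH57",
    "amylase", "glycosidase", "glycoside hydrolase", "pullulan")
}

#' Build a keyword set
#'
#' @param keywords Character vector of search strings; defaults to
#'   [default_keywords()].
#' @return The validated keyword vector (non-empty, no duplicates after case
#'   folding), Unicode NFC-normalized.
#' @export
keyword_set <- function(keywords = default_keywords()) {
  stopifnot(is.character(keywords), length(keywords) > 0L)
  keywords <- stringi::stri_trans_nfc(keywords)
  if (anyDuplicated(tolower(keywords))) {
    stop("duplicate keywords after case folding: ",
         paste(keywords[duplicated(tolower(keywords))], collapse = ", "))
  }
  keywords
}

#' Screen proteins for glycoside-hydrolase candidates by keyword search
#'
#' Performs a case-insensitive plain substring match of each keyword against
#' the signature description, integrated-entry description, signature id and
#' integrated-entry id of every annotation row of a protein (no word
#' boundaries, so `"GH13"` hits subfamily labels like `GH13_39`). Text is
#' Unicode NFC-normalized before matching. Proteins with no annotation rows
#' at all are retained as candidates with `is_unannotated = TRUE`, so
#' completely novel sequences are not lost.
#'
#' @param annotations Annotation tibble (see [read_annotation_tsv()]). Rows
#'   referencing accessions absent from `proteins` are ignored with a
#'   warning.
#' @param proteins Protein tibble (see [read_protein_fasta()]); defines the
#'   universe of accessions, each of which appears exactly once in the
#'   output.
#' @param keywords Keyword vector, validated through [keyword_set()].
#' @param strict_unannotated If `TRUE`, "unannotated" additionally includes
#'   proteins whose annotation rows all lack an integrated entry; default
#'   `FALSE` (unannotated means zero annotation rows).
#' @return A tibble with one row per protein: `protein_accession`,
#'   `matched_keywords` and `matched_signatures` (list columns),
#'   `is_unannotated`, and `is_candidate` (`TRUE` iff any keyword matched or
#'   the protein is unannotated).
#' @export
screen <- function(annotations, proteins, keywords = default_keywords(),
                   strict_unannotated = FALSE) {
  keywords <- keyword_set(keywords)
  if (nrow(proteins) == 0L) {
    return(tibble::tibble(protein_accession = character(),
                          matched_keywords = list(),
                          matched_signatures = list(),
                          is_unannotated = logical(),
                          is_candidate = logical()))
  }
  orphan <- !annotations$protein_accession %in% proteins$accession
  if (any(orphan)) {
    warning(sum(orphan), " annotation row(s) reference accessions absent ",
            "from the protein collection; ignored")
    annotations <- annotations[!orphan, , drop = FALSE]
  }

  # Long table of the four searchable fields; NFC-normalize and case-fold
  # once, then scan each keyword with a fixed-string match.
  long <- tibble::tibble(
    protein_accession = rep(annotations$protein_accession, 4L),
    signature_id = rep(annotations$signature_id, 4L),
    entry_id = rep(annotations$entry_id, 4L),
    text = c(annotations$signature_desc, annotations$entry_desc,
             annotations$signature_id, annotations$entry_id))
  long <- long[!is.na(long$text), , drop = FALSE]
  text_lc <- tolower(stringi::stri_trans_nfc(long$text))

  hits <- lapply(keywords, function(kw) {
    idx <- which(stringr::str_detect(text_lc, stringr::fixed(tolower(kw))))
    if (length(idx) == 0L) return(NULL)
    tibble::tibble(protein_accession = long$protein_accession[idx],
                   keyword = kw,
                   signature = ifelse(is.na(long$entry_id[idx]),
                                      long$signature_id[idx],
                                      long$entry_id[idx]))
  })
  hits <- dplyr::bind_rows(hits)

  acc <- proteins$accession
  mk <- setNames(vector("list", length(acc)), acc)
  ms <- mk
  for (a in acc) { mk[[a]] <- character(); ms[[a]] <- character() }
  if (!is.null(hits) && nrow(hits) > 0L) {
    by_acc <- split(hits, hits$protein_accession)
    for (a in names(by_acc)) {
      # keep keyword order as supplied, signatures sorted and unique
      mk[[a]] <- keywords[keywords %in% unique(by_acc[[a]]$keyword)]
      ms[[a]] <- sort(unique(by_acc[[a]]$signature))
    }
  }
  n_rows <- table(factor(annotations$protein_accession, levels = acc))
  unann <- as.integer(n_rows) == 0L
  if (strict_unannotated) {
    has_entry <- tapply(!is.na(annotations$entry_id),
                        factor(annotations$protein_accession, levels = acc),
                        any)
    unann <- unann | !ifelse(is.na(has_entry), FALSE, has_entry)
  }
  matched <- lengths(mk) > 0L
  # an unannotated protein by definition matched nothing
  unann <- unann & !matched
  tibble::tibble(protein_accession = acc,
                 matched_keywords = unname(mk),
                 matched_signatures = unname(ms),
                 is_unannotated = unname(unann),
                 is_candidate = matched | unann)
}

#' Restrict candidate flags to a specific enzyme family
#'
#' Keeps only flags whose matched keywords intersect the family keywords
#' (e.g. `c("family 13", "GH13")`); unannotated proteins are excluded since
#' family membership requires an annotation.
#'
#' @param flags Candidate-flag tibble from [screen()].
#' @param family_keywords Character vector of family-defining keywords.
#' @return The filtered flag tibble.
#' @export
restrict_to_family <- function(flags, family_keywords) {
  if (length(family_keywords) == 0L) return(flags[0, , drop = FALSE])
  keep <- vapply(flags$matched_keywords, function(k) {
    any(tolower(k) %in% tolower(family_keywords))
  }, logical(1))
  flags[keep & !flags$is_unannotated, , drop = FALSE]
}

#' Write candidate flags as TSV
#'
#' Columns: accession, matched_keywords (`;`-joined), matched_signatures
#' (`;`-joined), is_unannotated.
#'
#' @param flags Candidate-flag tibble from [screen()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_candidate_flags <- function(flags, path) {
  join <- function(x) vapply(x, paste, character(1), collapse = ";")
  out <- tibble::tibble(accession = flags$protein_accession,
                        matched_keywords = join(flags$matched_keywords),
                        matched_signatures = join(flags$matched_signatures),
                        is_unannotated = flags$is_unannotated)
  readr::write_tsv(out, path)
  invisible(path)
}
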