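# Consensus taxonomic classification of ORFs from alignment hits, and
# spectral-count-weighted community composition.

#' Consensus parameters for lineage voting
#'
#' Controls the bitscore-weighted consensus vote used by
#' [consensus_lineage()] and [classify_all()].
#'
#' @param top_n Number of best alignments retained per query (default 25).
#' @param min_support Exclusive support threshold a name must exceed to be
#'   assigned at a rank (default 0.5, i.e. strict majority of the retained
#'   bitscore mass).
#' @param weight_by_bitscore If `TRUE` (default) hits vote with their
#'   bitscore; if `FALSE` each retained hit counts 1 (uniform weights, useful
#'   for sensitivity checks).
#' @return A list of class `consensus_params`.
#' @export
consensus_params <- function(top_n = 25L, min_support = 0.5,
                             weight_by_bitscore = TRUE) {
  stopifnot(top_n >= 1L, min_support >= 0.5, min_support <= 1)
  structure(list(top_n = as.integer(top_n), min_support = min_support,
                 weight_by_bitscore = isTRUE(weight_by_bitscore)),
            class = "consensus_params")
}

#' Split a semicolon-delimited lineage string into the seven ranks
#'
#' @param x Character vector of lineage strings
#'   (`superkingdom;phylum;...;species`, possibly truncated or empty).
#' @return A character matrix with one row per input and one column per rank
#'   in [LINEAGE_RANKS]; unassigned ranks are `NA`. An empty token truncates
#'   the lineage from that rank downward (prefix property).
#' @export
parse_lineage <- function(x) {
  parts <- stringr::str_split(ifelse(is.na(x), "", x), ";")
  m <- matrix(NA_character_, nrow = length(x), ncol = 7L,
              dimnames = list(NULL, LINEAGE_RANKS))
  for (i in seq_along(parts)) {
    p <- stringr::str_trim(parts[[i]])
    p <- p[seq_len(min(length(p), 7L))]
    blank <- which(p == "" | is.na(p))
    if (length(blank) > 0L) p <- p[seq_len(min(blank) - 1L)]
    if (length(p) > 0L) m[i, seq_along(p)] <- p
  }
  m
}

#' Format rank vectors back into semicolon-delimited lineage strings
#'
#' @param m Character matrix as produced by [parse_lineage()], or a single
#'   named rank vector.
#' @return Character vector of `;`-joined lineage strings with trailing
#'   unassigned ranks removed.
#' @export
format_lineage <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  apply(m, 1L, function(r) {
    keep <- which(!is.na(r))
    if (length(keep) == 0L) "" else paste(r[seq_len(max(keep))], collapse = ";")
  })
}

consensus_from_matrix <- function(lin, weights, min_support) {
  out <- setNames(rep(NA_character_, 7L), LINEAGE_RANKS)
  total <- sum(weights)
  if (total <= 0) return(out)
  for (r in seq_len(7L)) {
    names_r <- lin[, r]
    ok <- !is.na(names_r)
    if (!any(ok)) break
    support <- tapply(weights[ok], names_r[ok], sum)
    best <- which.max(support)
    if (support[[best]] / total > min_support) {
      out[r] <- names(support)[best]
    } else {
      break
    }
  }
  out
}

#' Consensus lineage for one query from its alignment hits
#'
#' Implements a rank-wise bitscore-weighted vote: hits are sorted by
#' descending bitscore (ties broken by ascending subject accession) and
#' truncated to the `top_n` best. At each rank from superkingdom downward a
#' name's support is the summed weight of the retained hits carrying that
#' name divided by the summed weight of *all* retained hits (so hits with
#' missing or truncated lineages count against every candidate —
#' a conservative, LCA-like behaviour). The name is assigned iff its support
#' strictly exceeds `min_support`; the first failing rank and all deeper
#' ranks stay unassigned.
#'
#' @param hits Tibble of alignment rows for a single query (columns
#'   `subject_accession`, `bitscore`, `subject_lineage`; see
#'   [read_alignment_tsv()]).
#' @param params A [consensus_params()] object.
#' @return A named character vector over [LINEAGE_RANKS]; unassigned ranks
#'   are `NA`. An empty hit set returns a fully unassigned lineage.
#' @export
consensus_lineage <- function(hits, params = consensus_params()) {
  empty <- setNames(rep(NA_character_, 7L), LINEAGE_RANKS)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  if ("query_accession" %in% names(hits) &&
      length(unique(hits$query_accession)) > 1L) {
    stop("consensus_lineage() expects hits for a single query; got ",
         length(unique(hits$query_accession)))
  }
  ord <- order(-hits$bitscore, hits$subject_accession)
  hits <- hits[ord, , drop = FALSE]
  hits <- head(hits, params$top_n)
  w <- if (params$weight_by_bitscore) hits$bitscore else rep(1, nrow(hits))
  lin <- parse_lineage(hits$subject_lineage)
  consensus_from_matrix(lin, w, params$min_support)
}

#' Classify every query in an alignment table
#'
#' Applies [consensus_lineage()] to the hits of each distinct query
#' accession. Queries with no alignment rows do not appear in the output.
#'
#' @param alignments Tibble of alignment rows (see [read_alignment_tsv()]).
#' @param params A [consensus_params()] object.
#' @return A tibble with column `accession`, one column per rank in
#'   [LINEAGE_RANKS], and a `lineage` column holding the `;`-joined string.
#'   Sorted by accession, so output is independent of input row order.
#' @export
classify_all <- function(alignments, params = consensus_params()) {
  if (nrow(alignments) == 0L) {
    out <- tibble::as_tibble(setNames(
      rep(list(character()), 9L), c("accession", LINEAGE_RANKS, "lineage")))
    return(out)
  }
  groups <- split(seq_len(nrow(alignments)), alignments$query_accession)
  res <- vapply(groups, function(idx) {
    consensus_lineage(alignments[idx, , drop = FALSE], params)
  }, character(7))
  m <- t(res)
  out <- tibble::tibble(accession = rownames(m))
  for (r in LINEAGE_RANKS) out[[r]] <- unname(m[, r])
  out$lineage <- format_lineage(m)
  dplyr::arrange(out, .data$accession)
}

#' Genus-level community composition from spectral counts
#'
#' Sums spectral counts per genus over the retained identification rows and
#' normalizes to 100%. Proteins whose lineage has no genus assignment (or no
#' lineage at all) are pooled into an explicit `"unclassified"` bucket, which
#' participates in the normalization; display-level filtering of small genera
#' is left to the caller.
#'
#' @param ids Identification tibble (see [read_identifications()]).
#' @param lineages Classification tibble from [classify_all()].
#' @param fraction_filter Optional fraction label (`"pellet"` or
#'   `"supernatant"`); if given, only rows from that fraction are counted.
#' @return A tibble with columns `genus` and `percent`, sorted by descending
#'   percent; percentages sum to 100.
#' @export
genus_composition <- function(ids, lineages, fraction_filter = NULL) {
  if (!is.null(fraction_filter)) {
    fraction_filter <- match.arg(fraction_filter, FRACTION_LEVELS)
    ids <- ids[as.character(ids$fraction) == fraction_filter, , drop = FALSE]
  }
  total <- sum(ids$spectral_count)
  if (nrow(ids) == 0L || total == 0) {
    stop("no spectral counts to compose (zero total)")
  }
  genus_of <- setNames(lineages$genus, lineages$accession)
  g <- unname(genus_of[ids$protein_accession])
  g[is.na(g)] <- "unclassified"
  comp <- tibble::tibble(genus = g, count = ids$spectral_count) |>
    dplyr::summarise(percent = 100 * sum(.data$count) / total,
                     .by = "genus") |>
    dplyr::arrange(dplyr::desc(.data$percent), .data$genus)
  comp
}

#' Write a two-column lineage TSV (accession, semicolon lineage)
#'
#' @param lineages Tibble from [classify_all()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lineage_tsv <- function(lineages, path) {
  readr::write_tsv(lineages[, c("accession", "lineage")], path)
  invisible(path)
}

#' Write a composition TSV (genus, percent)
#'
#' @param composition Tibble from [genus_composition()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_composition_tsv <- function(composition, path) {
  readr::write_tsv(composition, path)
  invisible(path)
}
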