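# Intersect candidate flags with expression evidence: identification
# criteria, fraction-based localization, lysis quality control and
# spectral-count ranking.

#' Default glycolytic marker proteins for the lysis quality control
#'
#' Abundant cytoplasmic glycolysis enzymes whose appearance in the secretome
#' indicates cell lysis rather than secretion.
#'
#' @return Character vector of marker protein names.
#' @export
default_lysis_markers <- function() {
  c("glyceraldehyde-3-phosphate dehydrogenase",
    "phosphoglycerate mutase",
    "glucose-6-phosphate isomerase")
}

#' Apply protein-identification criteria
#'
#' Retains identification rows with at least `min_unique_peptides` unique
#' peptides (the FDR filter is the search engine's job upstream and is not
#' recomputed here).
#'
#' @param ids Identification tibble (see [read_identifications()]).
#' @param min_unique_peptides Minimum unique peptides per observation
#'   (default 2; 0 is the identity filter).
#' @return The filtered tibble.
#' @export
apply_id_criteria <- function(ids, min_unique_peptides = 2L) {
  ids[ids$unique_peptides >= min_unique_peptides, , drop = FALSE]
}

#' Per-protein, per-fraction spectral-count totals
#'
#' Sums spectral counts across samples within each fraction.
#'
#' @param ids Filtered identification tibble.
#' @return A tibble with columns `protein_accession`, `sup_count`,
#'   `pellet_count` (zero where the protein was not observed in a fraction).
#' @export
fraction_totals <- function(ids) {
  if (nrow(ids) == 0L) {
    return(tibble::tibble(protein_accession = character(),
                          sup_count = integer(), pellet_count = integer()))
  }
  ids |>
    dplyr::summarise(count = sum(.data$spectral_count),
                     .by = c("protein_accession", "fraction")) |>
    dplyr::mutate(fraction = as.character(.data$fraction)) |>
    tidyr::pivot_wider(names_from = "fraction", values_from = "count",
                       values_fill = 0L) |>
    (\(d) {
      if (!"supernatant" %in% names(d)) d$supernatant <- 0L
      if (!"pellet" %in% names(d)) d$pellet <- 0L
      tibble::tibble(protein_accession = d$protein_accession,
                     sup_count = as.integer(d$supernatant),
                     pellet_count = as.integer(d$pellet))
    })() |>
    dplyr::arrange(.data$protein_accession)
}

#' Classify protein localization from fraction evidence
#'
#' A protein identified in at least one supernatant sample is called
#' `secreted` (secreted enzymes are commonly also cell-associated, so pellet
#' co-detection does not revoke the call); a protein identified only in the
#' pellet is `intracellular`. The two calls partition the identified
#' proteins. A `detail` column preserves the `"both"` sub-label for QC.
#'
#' @param ids Identification tibble that already passed
#'   [apply_id_criteria()].
#' @return A tibble with columns `protein_accession`, `call` (`secreted` or
#'   `intracellular`), `detail` (`supernatant_only`, `both`, `pellet_only`),
#'   `sup_count`, `pellet_count`.
#' @export
classify_localization <- function(ids) {
  totals <- fraction_totals(ids)
  in_sup <- totals$sup_count > 0L
  in_pel <- totals$pellet_count > 0L
  tibble::tibble(
    protein_accession = totals$protein_accession,
    call = ifelse(in_sup, "secreted", "intracellular"),
    detail = dplyr::case_when(in_sup & in_pel ~ "both",
                              in_sup ~ "supernatant_only",
                              TRUE ~ "pellet_only"),
    sup_count = totals$sup_count,
    pellet_count = totals$pellet_count)
}

#' Cell-lysis quality control
#'
#' Checks whether the secretome is contaminated by cytoplasm from lysed
#' cells, in two ways: (1) how many of the `top_k` most abundant pellet
#' proteins (by summed pellet spectral count, ties broken by ascending
#' accession) were never identified in any supernatant sample — a high count
#' argues against significant lysis; (2) whether named glycolytic marker
#' proteins appear in the secretome at all, matched case-insensitively as
#' substrings of the protein descriptions.
#'
#' @param ids Identification tibble that already passed
#'   [apply_id_criteria()]; must contain at least one pellet protein.
#' @param proteins Protein tibble supplying `description` for marker
#'   matching (optional; markers are reported absent when missing).
#' @param top_k Number of most-abundant pellet proteins compared (default
#'   50). If larger than the pellet, the full pellet is used with a warning.
#' @param markers Marker name vector; defaults to [default_lysis_markers()].
#' @return A list of class `lysis_qc_report`: `top_k` (effective), `top_pellet`
#'   (accession vector), `absent_from_secretome` (count), `marker_hits`
#'   (tibble: marker, present_in_secretome, sup_count).
#' @export
lysis_qc <- function(ids, proteins = NULL, top_k = 50L,
                     markers = default_lysis_markers()) {
  if (top_k <= 0L) stop("top_k must be positive")
  totals <- fraction_totals(ids)
  pellet <- totals[totals$pellet_count > 0L, , drop = FALSE]
  if (nrow(pellet) == 0L) stop("lysis_qc() requires at least one pellet protein")
  if (top_k > nrow(pellet)) {
    warning("top_k (", top_k, ") exceeds pellet size (", nrow(pellet),
            "); using the full pellet")
    top_k <- nrow(pellet)
  }
  pellet <- pellet[order(-pellet$pellet_count, pellet$protein_accession), ]
  top <- head(pellet, top_k)
  absent <- sum(top$sup_count == 0L)

  marker_hits <- tibble::tibble(marker = markers,
                                present_in_secretome = FALSE,
                                sup_count = 0L)
  if (!is.null(proteins) && nrow(proteins) > 0L) {
    sup <- totals[totals$sup_count > 0L, , drop = FALSE]
    desc <- setNames(tolower(proteins$description), proteins$accession)
    sup_desc <- desc[sup$protein_accession]
    for (i in seq_along(markers)) {
      hit <- !is.na(sup_desc) &
        stringr::str_detect(sup_desc, stringr::fixed(tolower(markers[i])))
      marker_hits$present_in_secretome[i] <- any(hit)
      marker_hits$sup_count[i] <- sum(sup$sup_count[hit])
    }
  }
  structure(list(top_k = as.integer(top_k),
                 top_pellet = top$protein_accession,
                 absent_from_secretome = absent,
                 marker_hits = marker_hits),
            class = "lysis_qc_report")
}

#' @export
print.lysis_qc_report <- function(x, ...) {
  cat("Lysis QC: ", x$absent_from_secretome, " of the top ", x$top_k,
      " pellet proteins absent from the secretome\n", sep = "")
  n_mark <- sum(x$marker_hits$present_in_secretome)
  cat("Glycolytic markers in secretome: ", n_mark, "/",
      nrow(x$marker_hits), "\n", sep = "")
  invisible(x)
}

# Average (isotope-abundance-weighted) residue masses in Da; a peptide chain
# of these residues plus one water gives the protein molecular weight.
AA_AVERAGE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
  X = 110.0000)
WATER_AVERAGE_MASS <- 18.0153

#' Average-isotopic molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water. `X` counts as a generic
#' residue of 110 Da.
#'
#' @param sequence Character vector of amino-acid sequences (20 canonical
#'   residues plus `X`; case-insensitive).
#' @return Numeric vector of molecular weights in Da. The empty chain
#'   returns the mass of water.
#' @export
compute_molecular_weight <- function(sequence) {
  vapply(toupper(sequence), function(s) {
    if (is.na(s)) return(NA_real_)
    res <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- !res %in% names(AA_AVERAGE_MASS)
    if (any(bad)) {
      stop("invalid residue(s): ", paste(unique(res[bad]), collapse = ", "))
    }
    sum(AA_AVERAGE_MASS[res]) + WATER_AVERAGE_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' Rank enzyme candidates within a localization class
#'
#' Keeps proteins that are candidates by the keyword screen *and* localized
#' to the requested class, sorts them by descending spectral count in the
#' class-defining fraction (supernatant for secreted, pellet for
#' intracellular; ties broken by ascending accession) and assigns ranks
#' 1..n.
#'
#' @param flags Candidate-flag tibble from [screen()].
#' @param calls Localization tibble from [classify_localization()].
#' @param fraction Defining fraction: `"supernatant"` (secreted class,
#'   default) or `"pellet"` (intracellular class).
#' @param proteins Optional protein tibble; used for molecular weight,
#'   either from an `mw` column if present or computed from sequences.
#' @param annotations Optional annotation tibble; supplies the integrated
#'   entry ids/descriptions reported per candidate.
#' @return A candidate-record tibble: `protein_accession`,
#'   `molecular_weight`, `entry_ids`, `entry_descs`, `matched_keywords`
#'   (list columns), `localization`, `sup_count`, `pellet_count`, `rank`.
#' @export
rank_candidates <- function(flags, calls, fraction = "supernatant",
                            proteins = NULL, annotations = NULL) {
  if (!fraction %in% FRACTION_LEVELS) {
    stop("unknown fraction label '", fraction, "'")
  }
  class_call <- if (fraction == "supernatant") "secreted" else "intracellular"
  cand <- flags[flags$is_candidate, , drop = FALSE]
  keep_calls <- calls[calls$call == class_call, , drop = FALSE]
  rec <- dplyr::inner_join(cand, keep_calls, by = "protein_accession")
  if (nrow(rec) == 0L) {
    return(tibble::tibble(protein_accession = character(),
                          molecular_weight = double(), entry_ids = list(),
                          entry_descs = list(), matched_keywords = list(),
                          localization = character(), sup_count = integer(),
                          pellet_count = integer(), rank = integer()))
  }
  key_count <- if (fraction == "supernatant") rec$sup_count else rec$pellet_count
  ord <- order(-key_count, rec$protein_accession)
  rec <- rec[ord, , drop = FALSE]

  mw <- rep(NA_real_, nrow(rec))
  if (!is.null(proteins)) {
    idx <- match(rec$protein_accession, proteins$accession)
    if ("mw" %in% names(proteins)) {
      mw <- proteins$mw[idx]
    } else if ("sequence" %in% names(proteins)) {
      seqs <- proteins$sequence[idx]
      ok <- !is.na(seqs)
      mw[ok] <- compute_molecular_weight(seqs[ok])
    }
  }
  entry_ids <- entry_descs <- rep(list(character()), nrow(rec))
  if (!is.null(annotations)) {
    ann <- annotations[!is.na(annotations$entry_id), , drop = FALSE]
    by_acc <- split(ann, ann$protein_accession)
    for (i in seq_len(nrow(rec))) {
      a <- by_acc[[rec$protein_accession[i]]]
      if (!is.null(a)) {
        u <- !duplicated(a$entry_id)
        entry_ids[[i]] <- a$entry_id[u]
        entry_descs[[i]] <- ifelse(is.na(a$entry_desc[u]), "", a$entry_desc[u])
      }
    }
  }
  tibble::tibble(protein_accession = rec$protein_accession,
                 molecular_weight = mw,
                 entry_ids = entry_ids,
                 entry_descs = entry_descs,
                 matched_keywords = rec$matched_keywords,
                 localization = rec$call,
                 sup_count = rec$sup_count,
                 pellet_count = rec$pellet_count,
                 rank = seq_len(nrow(rec)))
}
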