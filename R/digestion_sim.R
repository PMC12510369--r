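# Bond-context model of pullulan depolymerization. A glycan chain is a run
# of glucose units joined by alpha-1,4 or alpha-1,6 bonds; an enzyme is a
# pure predicate on a bond's local context (its own type, the types of its
# neighbouring bonds, and the chain-end flags). Unit 1 is the non-reducing
# end; bond i joins unit i to unit i+1.

BOND_TYPES <- c(a14 = "alpha-1,4", a16 = "alpha-1,6")

#' Build a glycan chain
#'
#' @param bonds Character vector of bond types, each `"alpha-1,4"` or
#'   `"alpha-1,6"` (the short forms `"a14"`/`"a16"` are accepted). A chain
#'   of n glucose units has n - 1 bonds; `character(0)` gives a single
#'   glucose.
#' @return A list of class `glycan_chain` with fields `n_units` and `bonds`
#'   (canonical long names).
#' @export
glycan_chain <- function(bonds) {
  bonds <- as.character(bonds)
  short <- names(BOND_TYPES)[match(bonds, BOND_TYPES)]
  short[is.na(short)] <- bonds[is.na(short)]
  if (!all(short %in% names(BOND_TYPES))) {
    stop("bond types must be alpha-1,4 or alpha-1,6")
  }
  structure(list(n_units = length(bonds) + 1L,
                 bonds = unname(BOND_TYPES[short])),
            class = "glycan_chain")
}

#' Build a pullulan chain
#'
#' Pullulan is a linear polymer of maltotriose units (three glucoses joined
#' by two alpha-1,4 bonds) connected by alpha-1,6 bonds: `n_repeats` repeats
#' give `3 * n_repeats` glucose units with bond pattern
#' (alpha-1,4, alpha-1,4, alpha-1,6) repeating, the final alpha-1,6 absent.
#'
#' @param n_repeats Number of maltotriose repeats (>= 1).
#' @return A `glycan_chain`.
#' @export
build_pullulan <- function(n_repeats) {
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  bonds <- rep(c("a14", "a14", "a16"), n_repeats)
  glycan_chain(bonds[-length(bonds)])
}

#' @export
print.glycan_chain <- function(x, ...) {
  cat("glycan chain: ", x$n_units, " glucose units, ",
      sum(x$bonds == BOND_TYPES["a16"]), " alpha-1,6 and ",
      sum(x$bonds == BOND_TYPES["a14"]), " alpha-1,4 bonds\n", sep = "")
  invisible(x)
}

#' Enzyme cleavage rules
#'
#' Builds an enzyme rule, either from a named preset or from a custom
#' predicate. The predicate sees only a bond's local context: its own type,
#' the predecessor and successor bond types (`NA` at chain ends), and
#' whether it is the first/last bond of the chain.
#'
#' Presets (products named for a pullulan substrate):
#' \describe{
#'   \item{`pullulanase-I`}{cleaves every alpha-1,6 bond; converts pullulan
#'     entirely into maltotriose.}
#'   \item{`pullulanase-II`}{cleaves both bond types (amylopullulanase
#'     activity modelled at the bond level); exhaustive use gives glucose.}
#'   \item{`neopullulanase`}{cleaves the alpha-1,4 bond whose successor bond
#'     is alpha-1,6 or the chain end; interior products are panose
#'     (alpha-1,6 then alpha-1,4).}
#'   \item{`isopullulanase`}{cleaves the alpha-1,4 bond whose predecessor
#'     bond is alpha-1,6 or the chain start; interior products are isopanose
#'     (alpha-1,4 then alpha-1,6).}
#'   \item{`pullulan-hydrolase-III`}{cleaves both bond types; typically used
#'     in stochastic mode to produce the panose/maltotriose/maltose/glucose
#'     mixture of a partial digest.}
#' }
#'
#' @param preset Preset name (see above), ignored when `cleaves` is given.
#' @param cleaves Optional custom predicate
#'   `function(type, prev, succ, at_start, at_end) -> logical(1)`.
#' @param mode `"exhaustive"` (cut every satisfying bond) or `"stochastic"`
#'   (cut each satisfying bond independently with probability `p`).
#' @param p Per-bond cut probability for stochastic mode.
#' @param seed Integer seed for stochastic mode.
#' @param name Rule name for reporting; defaults to the preset.
#' @return A list of class `enzyme_rule`.
#' @export
enzyme_rule <- function(preset = c("pullulanase-I", "pullulanase-II",
                                   "neopullulanase", "isopullulanase",
                                   "pullulan-hydrolase-III"),
                        cleaves = NULL, mode = c("exhaustive", "stochastic"),
                        p = 1, seed = 1L, name = NULL) {
  mode <- match.arg(mode)
  stopifnot(p >= 0, p <= 1)
  a14 <- BOND_TYPES[["a14"]]; a16 <- BOND_TYPES[["a16"]]
  if (is.null(cleaves)) {
    preset <- match.arg(preset)
    cleaves <- switch(preset,
      "pullulanase-I" = function(type, prev, succ, at_start, at_end)
        type == a16,
      "pullulanase-II" = ,
      "pullulan-hydrolase-III" = function(type, prev, succ, at_start, at_end)
        TRUE,
      "neopullulanase" = function(type, prev, succ, at_start, at_end)
        type == a14 && (at_end || identical(succ, a16)),
      "isopullulanase" = function(type, prev, succ, at_start, at_end)
        type == a14 && (at_start || identical(prev, a16)))
    name <- name %||% preset
  } else {
    name <- name %||% "custom"
  }
  structure(list(name = name, cleaves = cleaves, mode = mode, p = p,
                 seed = as.integer(seed)), class = "enzyme_rule")
}

classify_fragment <- function(pattern) {
  key <- paste(pattern, collapse = ";")
  a14 <- BOND_TYPES[["a14"]]; a16 <- BOND_TYPES[["a16"]]
  known <- c("glucose", "maltose", "isomaltose", "maltotriose", "panose",
             "isopanose")
  names(known) <- c("", a14, a16, paste(a14, a14, sep = ";"),
                    paste(a16, a14, sep = ";"), paste(a14, a16, sep = ";"))
  idx <- match(key, names(known))
  if (!is.na(idx)) unname(known[idx])
  else sprintf("Hex%d-other", length(pattern) + 1L)
}

#' Digest a glycan chain with an enzyme rule
#'
#' Evaluates the rule's predicate on every bond; in exhaustive mode every
#' satisfying bond is cut, in stochastic mode each satisfying bond is cut
#' independently with probability `p` under the rule's seed. The resulting
#' fragments are classified by their bond pattern into a product spectrum.
#'
#' @param chain A `glycan_chain`.
#' @param enzyme An `enzyme_rule`.
#' @param seed Optional seed overriding the rule's (stochastic mode only).
#' @return A tibble of class `product_spectrum` with columns `species`,
#'   `bond_pattern` (`;`-joined), `length` (glucose units), `count` and
#'   `fraction` (of product molecules); attribute `n_units` carries the
#'   substrate size. Hexose is conserved:
#'   `sum(length * count) == chain$n_units`.
#' @export
digest <- function(chain, enzyme, seed = NULL) {
  stopifnot(inherits(chain, "glycan_chain"), inherits(enzyme, "enzyme_rule"))
  nb <- length(chain$bonds)
  satisf <- logical(nb)
  for (i in seq_len(nb)) {
    satisf[i] <- isTRUE(enzyme$cleaves(
      chain$bonds[i],
      if (i > 1L) chain$bonds[i - 1L] else NA_character_,
      if (i < nb) chain$bonds[i + 1L] else NA_character_,
      i == 1L, i == nb))
  }
  cut <- satisf
  if (enzyme$mode == "stochastic" && any(satisf)) {
    old <- .Random.seed_save()
    set.seed(seed %||% enzyme$seed)
    cut[satisf] <- runif(sum(satisf)) < enzyme$p
    .Random.seed_restore(old)
  }
  # fragment unit ranges: cuts after bond i split units (..i | i+1..)
  ends <- c(which(cut), chain$n_units)
  starts <- c(1L, head(ends, -1L) + 1L)
  frags <- lapply(seq_along(starts), function(k) {
    if (starts[k] == ends[k]) character(0)
    else chain$bonds[seq(starts[k], ends[k] - 1L)]
  })
  pattern <- vapply(frags, paste, character(1), collapse = ";")
  len <- lengths(frags) + 1L
  species <- vapply(frags, classify_fragment, character(1))
  spec <- tibble::tibble(species = species, bond_pattern = pattern,
                         length = len) |>
    dplyr::summarise(count = dplyr::n(),
                     .by = c("species", "bond_pattern", "length")) |>
    dplyr::arrange(.data$length, .data$bond_pattern)
  spec$fraction <- spec$count / sum(spec$count)
  attr(spec, "n_units") <- chain$n_units
  attr(spec, "enzyme") <- enzyme$name
  class(spec) <- c("product_spectrum", class(spec))
  spec
}

# Save/restore the global RNG state so stochastic digests are reproducible
# without disturbing the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Hexose-length histogram of a product spectrum
#'
#' Aggregates a product spectrum by product length (Hex1, Hex2, ...),
#' reporting the fraction of product molecules at each length and the
#' dominant length (ties broken toward the smallest).
#'
#' @param spectrum A `product_spectrum` from [digest()].
#' @return A list with `histogram` (tibble: length, fraction) and
#'   `dominant_length`.
#' @export
hexose_histogram <- function(spectrum) {
  if (nrow(spectrum) == 0L) stop("empty product spectrum")
  h <- spectrum |>
    dplyr::summarise(count = sum(.data$count), .by = "length") |>
    dplyr::arrange(.data$length)
  h$fraction <- h$count / sum(h$count)
  dominant <- h$length[which.max(h$fraction)]
  list(histogram = h[, c("length", "fraction")],
       dominant_length = as.integer(dominant))
}

#' Write a product spectrum TSV
#'
#' Columns: species, bond_pattern, length, count, fraction. A header comment
#' records the orientation convention (unit 1 = non-reducing end; bond i
#' joins units i and i+1).
#'
#' @param spectrum A `product_spectrum`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  body <- strsplit(readr::format_tsv(tibble::as_tibble(spectrum)), "\n",
                   fixed = TRUE)[[1]]
  writeLines(c(paste0("# product spectrum; enzyme=",
                      attr(spectrum, "enzyme") %||% "NA",
                      "; unit 1 is the non-reducing end, bond i joins units i,i+1"),
               body), path, useBytes = TRUE)
  invisible(path)
}
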