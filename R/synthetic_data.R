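# Ground-truth-labelled synthetic inputs emulating the two community
# scenarios of the study design: a highly diverse inoculum in which most ORFs
# cannot be classified, and an enriched community dominated by one genus that
# carries the planted secreted glycoside hydrolase. Every emitted table
# parses cleanly through the io_formats readers.

#' Community specification for the metagenome generator
#'
#' @param genus_weights Named numeric vector of genus proportions (must sum
#'   to 1 within 1e-9).
#' @param n_orfs Number of ORFs to generate (desk scale default 2000; the
#'   study-scale value would be ~14000).
#' @param unclassifiable_fraction Fraction of ORFs whose alignments carry no
#'   informative lineage, so consensus classification must fail for them.
#' @param seed Integer seed.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(genus_weights, n_orfs = 2000L,
                           unclassifiable_fraction = 0, seed = 1L) {
  stopifnot(is.numeric(genus_weights), !is.null(names(genus_weights)),
            all(genus_weights >= 0),
            unclassifiable_fraction >= 0, unclassifiable_fraction <= 1,
            n_orfs >= 1L)
  if (abs(sum(genus_weights) - 1) > 1e-9) {
    stop("genus weights must sum to 1 (got ", sum(genus_weights), ")")
  }
  structure(list(genus_weights = genus_weights, n_orfs = as.integer(n_orfs),
                 unclassifiable_fraction = unclassifiable_fraction,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' High-diversity inoculum community preset
#'
#' Many genera with long-tailed weights and a high unclassifiable fraction,
#' emulating an environmental inoculum in which most genes cannot be
#' assigned a genus.
#'
#' @param n_genera Number of genera (default 120).
#' @param n_orfs Number of ORFs.
#' @param unclassifiable_fraction Default 0.8.
#' @param seed Integer seed (also shapes the weight tail).
#' @return A `community_spec`.
#' @export
inoculum_community <- function(n_genera = 120L, n_orfs = 2000L,
                               unclassifiable_fraction = 0.8, seed = 1L) {
  w <- exp(-seq_len(n_genera) / 25)
  w <- w / sum(w)
  names(w) <- c("Geofilum", "Capillibacterium", "Methanoculleus",
                "Methanosarcina",
                sprintf("Genus%03d", seq_len(n_genera - 4L)))[seq_len(n_genera)]
  community_spec(w, n_orfs = n_orfs,
                 unclassifiable_fraction = unclassifiable_fraction,
                 seed = seed)
}

#' Enriched community preset dominated by one genus
#'
#' One dominant genus holding `dominant_weight` of the ORFs (default 0.70,
#' the enrichment outcome the pipeline is designed to resolve), the rest
#' spread over a small tail of coexisting genera.
#'
#' @param dominant_genus Name of the dominant genus.
#' @param dominant_weight Its ORF proportion (default 0.70).
#' @param n_other Number of minor genera (default 25).
#' @param n_orfs Number of ORFs.
#' @param unclassifiable_fraction Default 0 (the enriched community is well
#'   represented in reference databases).
#' @param seed Integer seed.
#' @return A `community_spec`.
#' @export
enrichment_community <- function(dominant_genus = "Alicyclobacillus",
                                 dominant_weight = 0.70, n_other = 25L,
                                 n_orfs = 2000L,
                                 unclassifiable_fraction = 0, seed = 1L) {
  stopifnot(dominant_weight > 0, dominant_weight < 1)
  tail_w <- exp(-seq_len(n_other) / 8)
  tail_w <- (1 - dominant_weight) * tail_w / sum(tail_w)
  w <- c(setNames(dominant_weight, dominant_genus),
         setNames(tail_w, sprintf("Genus%03d", seq_len(n_other))))
  community_spec(w, n_orfs = n_orfs,
                 unclassifiable_fraction = unclassifiable_fraction,
                 seed = seed)
}

# Deterministic synthetic lineage for a genus; the dominant enrichment genus
# gets its real higher taxonomy so composition tables read naturally.
genus_lineage <- function(genus) {
  vapply(genus, function(g) {
    if (g == "Alicyclobacillus") {
      return(paste("Bacteria", "Bacillota", "Bacilli", "Bacillales",
                   "Alicyclobacillaceae", "Alicyclobacillus",
                   "Alicyclobacillus acidocaldarius", sep = ";"))
    }
    h <- sum(utf8ToInt(g)) %% 97L
    paste("Bacteria", sprintf("Phylum%02d", h %% 12L),
          sprintf("Class%02d", h %% 23L), sprintf("Order%02d", h %% 41L),
          sprintf("Family%02d", h %% 67L), g, paste(g, "sp."), sep = ";")
  }, character(1), USE.NAMES = FALSE)
}

GH_ENTRY_VOCAB <- tibble::tibble(
  entry_id = c("IPR006047", "IPR004185", "IPR017853", "IPR015020",
               "IPR015955"),
  entry_desc = c("Glycoside hydrolase, family 13, catalytic domain",
                 "Glycoside hydrolase, family 13, N-terminal Ig-like domain",
                 "Glycoside hydrolase superfamily",
                 "Rv2525c-like, glycoside hydrolase-like domain",
                 "Lactate dehydrogenase/glycoside hydrolase, family 4, C-terminal"),
  signature_id = c("PF00128", "PF02903", "SSF51445", "PF08940", "SSF56327"),
  signature_desc = c("Alpha-amylase", "Alpha-amylase N-terminal domain",
                     "(Trans)glycosidases", "Glycoside hydrolase-like domain",
                     "LDH C-terminal domain-like"))

HOUSEKEEPING_DESCS <- c("50S ribosomal protein L2",
                        "ATP synthase subunit beta",
                        "elongation factor Tu",
                        "DNA gyrase subunit A",
                        "chaperonin GroEL",
                        "DNA-directed RNA polymerase subunit beta")

ROLE_LEVELS <- c("secreted-GH", "intracellular-GH", "glycolytic-marker",
                 "transporter", "housekeeping")

#' Generate a synthetic metagenome with ground truth
#'
#' Emits the protein, annotation and alignment tables of a simulated
#' enrichment metagenome plus the per-ORF ground truth. Each ORF is assigned
#' a genus from the community weights and a functional role; glycoside
#' hydrolase ORFs receive GH13-flavoured annotation rows (drawn from the
#' amylase-superfamily entry vocabulary) unless suppressed by
#' `annotation_missing_rate`; every ORF gets up to `max_hits` alignment rows
#' with descending bitscores whose lineages equal the true lineage apart
#' from a configurable contamination rate; unclassifiable ORFs get
#' lineage-free hits. One secreted-GH ORF in the dominant genus is planted
#' as an extracellular amylopullulanase, the expected top secreted
#' candidate.
#'
#' @param community A [community_spec()].
#' @param gh_fraction Fraction of ORFs carrying a glycoside hydrolase role
#'   (default 0.06, split ~15/85 between secreted and intracellular).
#' @param annotation_missing_rate Probability that a GH ORF carries no
#'   annotation rows at all (default 0.35), exercising the retention of
#'   unannotated genes.
#' @param lineage_noise Per-hit probability that an alignment carries a
#'   wrong-genus lineage (default 0.02).
#' @param annotation_coverage Probability that a non-GH ORF is annotated
#'   (default 0.7).
#' @param max_hits Maximum alignments per ORF (default 25).
#' @param with_alignments Set `FALSE` to skip the alignment table (the
#'   screening/ranking stages do not consume it).
#' @return A list of class `ghmine_dataset` with elements `proteins`,
#'   `annotations`, `alignments`, `truth` and `community`. `truth` has one
#'   row per ORF: `accession`, `genus`, `lineage`, `role`,
#'   `true_localization`, `annotated`, `classifiable`, `planted`.
#' @export
generate_metagenome <- function(community, gh_fraction = 0.06,
                                annotation_missing_rate = 0.35,
                                lineage_noise = 0.02,
                                annotation_coverage = 0.7,
                                max_hits = 25L, with_alignments = TRUE) {
  stopifnot(inherits(community, "community_spec"),
            gh_fraction >= 0, gh_fraction <= 1)
  set.seed(community$seed)
  n <- community$n_orfs
  acc <- sprintf("ORF_%05d", seq_len(n))
  genera <- names(community$genus_weights)
  genus <- sample(genera, n, replace = TRUE,
                  prob = community$genus_weights)
  classifiable <- runif(n) >= community$unclassifiable_fraction

  # roles: GH split secreted/intracellular, a few markers and transporters
  role <- rep("housekeeping", n)
  p_role <- c(`secreted-GH` = 0.15 * gh_fraction,
              `intracellular-GH` = 0.85 * gh_fraction,
              `glycolytic-marker` = 0.005, transporter = 0.01)
  u <- runif(n)
  cum <- cumsum(p_role)
  role[u < cum[1]] <- "secreted-GH"
  role[u >= cum[1] & u < cum[2]] <- "intracellular-GH"
  role[u >= cum[2] & u < cum[3]] <- "glycolytic-marker"
  role[u >= cum[3] & u < cum[4]] <- "transporter"

  dominant <- genera[which.max(community$genus_weights)]
  planted <- rep(FALSE, n)
  planted_idx <- which(genus == dominant)[1]
  if (is.na(planted_idx)) planted_idx <- 1L
  planted[planted_idx] <- TRUE
  role[planted_idx] <- "secreted-GH"
  genus[planted_idx] <- dominant

  marker_names <- default_lysis_markers()
  idx <- seq_len(n)
  description <- HOUSEKEEPING_DESCS[(idx %% length(HOUSEKEEPING_DESCS)) + 1L]
  description[role == "secreted-GH"] <- "alpha-amylase family protein"
  description[role == "intracellular-GH"] <- "cyclomaltodextrinase"
  description[role == "glycolytic-marker"] <-
    marker_names[(idx[role == "glycolytic-marker"] %% length(marker_names)) + 1L]
  description[role == "transporter"] <-
    "maltose/maltodextrin ABC transporter permease MalG"
  description[planted_idx] <- "extracellular amylopullulanase"

  len <- pmax(50L, round(exp(rnorm(n, log(300), 0.3))))
  len[planted_idx] <- 1250L   # large multi-domain secreted enzyme
  sequence <- stringi::stri_rand_strings(
    n, len, pattern = "[ACDEFGHIKLMNPQRSTVWY]")
  proteins <- tibble::tibble(accession = acc, description = description,
                             sequence = sequence, length = len)

  # annotations ------------------------------------------------------------
  is_gh <- role %in% c("secreted-GH", "intracellular-GH")
  annotated <- ifelse(is_gh, runif(n) >= annotation_missing_rate,
                      runif(n) < annotation_coverage)
  # GH ORFs draw 1..k rows from the amylase-superfamily vocabulary
  # (secreted: up to catalytic + N-terminal + superfamily; intracellular:
  # up to catalytic + superfamily); other annotated ORFs get one generic row
  gh_idx <- which(annotated & is_gh)
  sec_gh <- role[gh_idx] == "secreted-GH"
  k_max <- ifelse(sec_gh, 3L, 2L)
  n_rows <- vapply(k_max, function(k) sample.int(k, 1L), integer(1))
  rep_i <- rep(gh_idx, n_rows)
  within <- sequence_int(n_rows)
  sec_rep <- rep(sec_gh, n_rows)
  vocab_row <- integer(length(within))
  vocab_row[sec_rep] <- within[sec_rep]
  vocab_row[!sec_rep] <- c(1L, 3L)[within[!sec_rep]]
  v <- GH_ENTRY_VOCAB[vocab_row, , drop = FALSE]
  st <- sample(5:60, length(rep_i), replace = TRUE)
  gh_ann <- tibble::tibble(
    protein_accession = acc[rep_i], source_db = "Pfam",
    signature_id = v$signature_id, signature_desc = v$signature_desc,
    start = st,
    end = pmin(st + sample(150:400, length(rep_i), TRUE), len[rep_i]),
    entry_id = v$entry_id, entry_desc = v$entry_desc,
    evalue = 10^-runif(length(rep_i), 20, 80))
  other_idx <- which(annotated & !is_gh)
  st2 <- sample(5:40, length(other_idx), replace = TRUE)
  other_ann <- tibble::tibble(
    protein_accession = acc[other_idx], source_db = "Pfam",
    signature_id = sprintf("PF%05d", 2000L + (other_idx %% 500L)),
    signature_desc = description[other_idx],
    start = st2,
    end = pmin(st2 + sample(100:250, length(other_idx), TRUE), len[other_idx]),
    entry_id = sprintf("IPR%06d", 100000L + (other_idx %% 900L)),
    entry_desc = description[other_idx],
    evalue = 10^-runif(length(other_idx), 10, 60))
  annotations <- dplyr::bind_rows(gh_ann, other_ann)
  annotations <- annotations[order(annotations$protein_accession), ]
  # ensure start <= end even for short proteins
  annotations$end <- pmax(annotations$end, annotations$start)

  lineage <- genus_lineage(genus)
  truth <- tibble::tibble(
    accession = acc, genus = genus, lineage = lineage, role = role,
    true_localization = ifelse(role == "secreted-GH", "secreted",
                               "intracellular"),
    annotated = annotated, classifiable = classifiable, planted = planted)

  alignments <- NULL
  if (with_alignments) {
    n_hits <- pmin(max_hits, 5L + rpois(n, 10))
    qidx <- rep(seq_len(n), n_hits)
    N <- length(qidx)
    hit_no <- sequence_int(n_hits)
    top <- runif(n, 150, 900)[qidx]
    dec <- stats::ave(c(rexp(N, 1 / 15)), qidx, FUN = cumsum)
    bitscore <- round(pmax(top - dec + 15, 30), 1)
    lin <- lineage[qidx]
    contaminated <- runif(N) < lineage_noise
    if (any(contaminated)) {
      lin[contaminated] <- genus_lineage(
        sample(genera, sum(contaminated), replace = TRUE))
    }
    lin[!classifiable[qidx]] <- ""
    alignments <- tibble::tibble(
      query_accession = acc[qidx],
      subject_accession = sprintf("REF_%05d_%02d", qidx, hit_no),
      pct_identity = round(runif(N, 40, 95), 1),
      align_length = sample(80:400, N, replace = TRUE),
      evalue = 10^(-bitscore / 15),
      bitscore = bitscore,
      subject_lineage = lin)
  }

  structure(list(proteins = proteins, annotations = annotations,
                 alignments = alignments, truth = truth,
                 community = community),
            class = "ghmine_dataset")
}

# base::sequence() for integer run lengths (1:k per group)
sequence_int <- function(nvec) {
  unlist(lapply(nvec, seq_len), use.names = FALSE)
}

#' Expression specification for the identification generator
#'
#' Mean spectral counts per role and fraction, overdispersion, the lysis
#' leak, and detectability. Supernatant means of intracellular roles are
#' `lysis_rate` times their pellet means — the leak of cytoplasm from lysed
#' cells that the lysis QC is designed to detect.
#'
#' @param lysis_rate Fraction of each intracellular protein's pellet
#'   abundance leaking into the supernatant (default 0.05).
#' @param dispersion Negative-binomial size parameter (default 2; smaller is
#'   more overdispersed).
#' @param min_count Minimum detectable spectral count; rows below it are
#'   omitted (default 2).
#' @param depth Optional target expected total spectral count over all rows;
#'   when given, all means are rescaled to hit it.
#' @param n_samples Samples per fraction (default 1).
#' @param pellet_means Named vector of pellet mean counts per role.
#' @param sup_mean_secreted Supernatant mean for secreted-GH ORFs.
#' @param planted_sup_mean Supernatant mean of the planted amylopullulanase
#'   (the dominant band of the secretome).
#' @param planted_dispersion Negative-binomial size for the planted protein
#'   only; a large value reflects the relatively lower count noise of a
#'   strongly expressed protein (default 20).
#' @param detect_rate Named per-role probability that an ORF is expressed
#'   at detectable levels at all.
#' @param seed Integer seed.
#' @return A list of class `expression_spec`.
#' @export
expression_spec <- function(lysis_rate = 0.05, dispersion = 2,
                            min_count = 2L, depth = NULL, n_samples = 1L,
                            pellet_means = c(`secreted-GH` = 12,
                                             `intracellular-GH` = 25,
                                             `glycolytic-marker` = 40,
                                             transporter = 12,
                                             housekeeping = 6),
                            sup_mean_secreted = 45,
                            planted_sup_mean = 400,
                            planted_dispersion = 20,
                            detect_rate = c(`secreted-GH` = 1,
                                            `intracellular-GH` = 0.9,
                                            `glycolytic-marker` = 1,
                                            transporter = 0.6,
                                            housekeeping = 0.25),
                            seed = 1L) {
  stopifnot(lysis_rate >= 0, lysis_rate <= 1, dispersion > 0,
            all(pellet_means >= 0), all(ROLE_LEVELS %in% names(pellet_means)),
            all(ROLE_LEVELS %in% names(detect_rate)))
  structure(list(lysis_rate = lysis_rate, dispersion = dispersion,
                 min_count = as.integer(min_count), depth = depth,
                 n_samples = as.integer(n_samples),
                 pellet_means = pellet_means,
                 sup_mean_secreted = sup_mean_secreted,
                 planted_sup_mean = planted_sup_mean,
                 planted_dispersion = planted_dispersion,
                 detect_rate = detect_rate, seed = as.integer(seed)),
            class = "expression_spec")
}

#' Generate fractionated identification tables from metagenome ground truth
#'
#' Draws per-protein, per-fraction spectral counts from a negative binomial
#' with role- and fraction-specific means: secreted-GH ORFs have high
#' supernatant means (the planted amylopullulanase the highest), while
#' intracellular roles reach the supernatant only through the lysis leak
#' (`sup mean = lysis_rate * pellet mean`). Rows below the minimum
#' detectable count are omitted; unique peptide counts are drawn consistent
#' with the spectral counts (never exceeding them).
#'
#' @param truth Ground-truth tibble from [generate_metagenome()] (or a full
#'   `ghmine_dataset`, whose `$truth` is used).
#' @param expr An [expression_spec()].
#' @return An identification tibble in the [read_identifications()] schema.
#' @export
generate_identifications <- function(truth, expr = expression_spec()) {
  if (inherits(truth, "ghmine_dataset")) truth <- truth$truth
  stopifnot(inherits(expr, "expression_spec"))
  # scramble the seed so the identification stream is decorrelated from the
  # metagenome generator even when both are handed the same user seed
  set.seed((expr$seed * 7919L + 13L) %% .Machine$integer.max)
  n <- nrow(truth)
  role <- truth$role
  mu_pellet <- unname(expr$pellet_means[role])
  mu_sup <- expr$lysis_rate * mu_pellet
  sec <- role == "secreted-GH"
  mu_sup[sec] <- expr$sup_mean_secreted
  mu_sup[truth$planted] <- expr$planted_sup_mean
  det <- runif(n) < unname(expr$detect_rate[role])

  if (!is.null(expr$depth)) {
    expected <- sum((mu_pellet + mu_sup)[det]) * expr$n_samples
    if (expected > 0) {
      scale <- expr$depth / expected
      mu_pellet <- mu_pellet * scale
      mu_sup <- mu_sup * scale
    }
  }

  rows <- list()
  for (s in seq_len(expr$n_samples)) {
    for (fr in FRACTION_LEVELS) {
      mu <- if (fr == "pellet") mu_pellet else mu_sup
      size <- ifelse(truth$planted, expr$planted_dispersion %||% 20,
                     expr$dispersion)
      cnt <- rnbinom(n, size = size, mu = mu)
      cnt[!det] <- 0L
      keep <- cnt >= expr$min_count
      if (!any(keep)) next
      cnt <- cnt[keep]
      up <- pmin(cnt, 2L + rpois(length(cnt), cnt / 10))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        protein_accession = truth$accession[keep],
        fraction = fr,
        sample_id = paste0(if (fr == "pellet") "P" else "SN", s),
        spectral_count = as.integer(cnt),
        unique_peptides = as.integer(up))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || nrow(out) == 0L) {
    out <- tibble::tibble(protein_accession = character(),
                          fraction = character(), sample_id = character(),
                          spectral_count = integer(),
                          unique_peptides = integer())
  }
  validate_identifications(out)
  out$fraction <- factor(out$fraction, levels = FRACTION_LEVELS)
  out
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the formats the io_formats readers consume
#' (`proteins.faa`, `annotations.tsv`, `alignments.tsv`,
#' `identifications.tsv`, `truth.tsv`) plus a `manifest.json` recording the
#' generator parameters and seed.
#'
#' @param dataset A `ghmine_dataset` from [generate_metagenome()].
#' @param dir Output directory (created if needed).
#' @param ids Optional identification tibble from
#'   [generate_identifications()].
#' @return Invisibly, a named list of the written paths.
#' @export
write_dataset <- function(dataset, dir, ids = NULL) {
  stopifnot(inherits(dataset, "ghmine_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(proteins = file.path(dir, "proteins.faa"),
                annotations = file.path(dir, "annotations.tsv"),
                alignments = file.path(dir, "alignments.tsv"),
                identifications = file.path(dir, "identifications.tsv"),
                truth = file.path(dir, "truth.tsv"),
                manifest = file.path(dir, "manifest.json"))
  write_protein_fasta(dataset$proteins, paths$proteins)
  write_annotation_tsv(dataset$annotations, paths$annotations)
  if (!is.null(dataset$alignments)) {
    write_alignment_tsv(dataset$alignments, paths$alignments)
  } else {
    paths$alignments <- NULL
  }
  if (!is.null(ids)) {
    write_identifications(ids, paths$identifications)
  } else {
    paths$identifications <- NULL
  }
  readr::write_tsv(dataset$truth, paths$truth)
  manifest <- list(
    n_orfs = dataset$community$n_orfs,
    seed = dataset$community$seed,
    unclassifiable_fraction = dataset$community$unclassifiable_fraction,
    genus_weights = as.list(dataset$community$genus_weights),
    files = lapply(paths[!vapply(paths, is.null, logical(1))], basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Packaged replica of the secretome candidate table
#'
#' A 17-protein replica of the published secretome candidate table: the
#' printed accessions, molecular weights and integrated InterPro entry
#' ids/descriptions, with each protein marked present in the supernatant.
#' Spectral counts are **not authoritative** (the original reports abundance
#' only as bar graphics), so they are arbitrary positive placeholders and
#' abundance-dependent conclusions should not be drawn from them; the
#' member-database signature accessions inside the annotation rows are
#' likewise synthesized. Six proteins carry integrated entries, eleven carry
#' no annotation at all.
#'
#' @return A list with tibbles `proteins` (with an `mw` column in Da),
#'   `annotations` and `identifications`.
#' @export
table1_fixture <- function() {
  acc <- c("MMBJNONL_14124", "MMBJNONL_07072", "MMBJNONL_03000",
           "MMBJNONL_05960", "MMBJNONL_09916", "MMBJNONL_07048",
           "MMBJNONL_05225", "MMBJNONL_03006", "MMBJNONL_05223",
           "MMBJNONL_09075", "MMBJNONL_01486", "MMBJNONL_05876",
           "MMBJNONL_03029", "MMBJNONL_02580", "MMBJNONL_02999",
           "MMBJNONL_07823", "MMBJNONL_01632")
  mw <- c(140550, 91271, 75891, 58192, 33232, 33418,
          21160, 18307, 27924, 32173, 47258, 18086,
          18064, 15965, 13289, 21122, 28355)
  group <- c(rep("Glycoside hydrolase domain", 2L),
             rep("Glycoside hydrolase superfamily", 2L),
             rep("Lactate dehydrogenase/glycoside hydrolase superfamily", 2L),
             rep("Protein without functional annotation", 11L))
  entries <- list(c("IPR006047", "IPR004185", "IPR017853"),
                  c("IPR006047", "IPR004185", "IPR017853"),
                  c("IPR015020", "IPR017853"),
                  "IPR017853", "IPR015955", "IPR015955")
  proteins <- tibble::tibble(accession = acc, description = group,
                             sequence = NA_character_, length = NA_integer_,
                             mw = mw)
  ann_rows <- lapply(seq_along(entries), function(i) {
    v <- GH_ENTRY_VOCAB[match(entries[[i]], GH_ENTRY_VOCAB$entry_id), ]
    tibble::tibble(protein_accession = acc[i], source_db = "Pfam",
                   signature_id = v$signature_id,
                   signature_desc = v$signature_desc,
                   start = 30L + 120L * (seq_len(nrow(v)) - 1L),
                   end = 140L + 120L * (seq_len(nrow(v)) - 1L),
                   entry_id = v$entry_id, entry_desc = v$entry_desc,
                   evalue = 1e-30)
  })
  annotations <- dplyr::bind_rows(ann_rows)
  # placeholder counts: descending with table order, all passing the
  # 2-unique-peptide identification criterion
  counts <- c(58L, 41L, 33L, 27L, 22L, 18L, 16L, 15L, 14L, 13L, 12L, 11L,
              10L, 9L, 8L, 7L, 6L)
  identifications <- tibble::tibble(
    protein_accession = acc,
    fraction = factor("supernatant", levels = FRACTION_LEVELS),
    sample_id = "SN1",
    spectral_count = counts,
    unique_peptides = pmin(counts, 4L))
  list(proteins = proteins, annotations = annotations,
       identifications = identifications)
}
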