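# End-to-end orchestration of the discovery funnel:
# all genes -> keyword-flagged -> expressed -> localized -> ranked.

#' Load a pipeline configuration
#'
#' Reads a YAML configuration and fills defaults. Recognized keys: input
#' paths (`proteins`, `annotations`, `alignments`, `identifications`),
#' `keywords`, `consensus` (`top_n`, `min_support`, `weight_by_bitscore`),
#' `min_unique_peptides`, `top_k`, `markers`, `strict_unannotated`,
#' `chunk_size` (batching hint for external annotators, default 1000; kept
#' for interoperability, the pipeline itself never invokes them),
#' `out_dir`, `seed`.
#'
#' @param path Path to a YAML file, or a named list to be completed with
#'   defaults.
#' @return A config list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  stopifnot(is.list(cfg))
  defaults <- list(keywords = default_keywords(),
                   consensus = list(top_n = 25L, min_support = 0.5,
                                    weight_by_bitscore = TRUE),
                   min_unique_peptides = 2L, top_k = 50L,
                   markers = default_lysis_markers(),
                   strict_unannotated = FALSE, chunk_size = 1000L,
                   seed = 1L)
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  if (cfg$chunk_size < 1L) stop("chunk_size must be >= 1")
  structure(cfg, class = c("pipeline_config", "list"))
}

resolve_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("input file does not exist: ", x)
    return(reader(x))
  }
  x
}

#' Run the full discovery pipeline
#'
#' Executes io -> taxonomy -> keyword screen -> proteomics integration and
#' (optionally) writes every artifact under `config$out_dir`: the secreted
#' and intracellular candidate reports, the lysis QC JSON, the genus
#' composition table, the lineage table and a funnel/manifest JSON. Stage
#' progress and the stage-by-stage funnel are logged via [message()].
#'
#' @param config A `pipeline_config` (or list / YAML path accepted by
#'   [load_config()]). Inputs may be file paths or in-memory tibbles.
#' @return A list of class `discovery_result`: `funnel` (named counts),
#'   `secreted` and `intracellular` candidate-record tibbles, `flags`,
#'   `calls`, `qc` (lysis QC report or `NULL`), `composition` (or `NULL`),
#'   `lineages` (or `NULL`).
#' @export
run_discovery <- function(config) {
  cfg <- load_config(config)
  stage <- function(s, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", s, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  proteins <- stage("io", resolve_input(cfg$proteins, read_protein_fasta))
  annotations <- stage("io", resolve_input(cfg$annotations, read_annotation_tsv))
  alignments <- stage("io", resolve_input(cfg$alignments, read_alignment_tsv))
  ids <- stage("io", resolve_input(cfg$identifications, read_identifications))
  if (is.null(proteins) || is.null(annotations) || is.null(ids)) {
    stop("config must provide proteins, annotations and identifications")
  }
  message("io: ", nrow(proteins), " proteins, ", nrow(annotations),
          " annotation rows, ", nrow(ids), " identification rows")

  lineages <- NULL
  composition <- NULL
  if (!is.null(alignments)) {
    params <- consensus_params(cfg$consensus$top_n, cfg$consensus$min_support,
                               cfg$consensus$weight_by_bitscore)
    lineages <- stage("taxonomy", classify_all(alignments, params))
    message("taxonomy: ", nrow(lineages), " ORFs classified (",
            sum(!is.na(lineages$genus)), " to genus level)")
  }

  flags <- stage("annotation_screen",
                 screen(annotations, proteins, cfg$keywords,
                        cfg$strict_unannotated))
  n_flagged <- sum(flags$is_candidate)
  message("annotation_screen: ", n_flagged, " candidate(s) (",
          sum(lengths(flags$matched_keywords) > 0), " by keyword, ",
          sum(flags$is_unannotated), " unannotated)")

  filtered <- stage("proteomics_integration",
                    apply_id_criteria(ids, cfg$min_unique_peptides))
  calls <- stage("proteomics_integration", classify_localization(filtered))
  secreted <- stage("proteomics_integration",
                    rank_candidates(flags, calls, "supernatant",
                                    proteins, annotations))
  intracellular <- stage("proteomics_integration",
                         rank_candidates(flags, calls, "pellet",
                                         proteins, annotations))

  qc <- NULL
  if (any(as.character(filtered$fraction) == "pellet")) {
    qc <- stage("proteomics_integration",
                suppressWarnings(lysis_qc(filtered, proteins, cfg$top_k,
                                          cfg$markers)))
  } else {
    message("lysis QC skipped: no pellet identifications")
  }
  if (!is.null(lineages) && nrow(filtered) > 0L &&
      sum(filtered$spectral_count) > 0) {
    composition <- stage("taxonomy",
                         genus_composition(filtered, lineages))
  } else if (!is.null(lineages)) {
    message("composition skipped: no spectral counts")
  }

  funnel <- c(total_genes = nrow(proteins),
              keyword_flagged = n_flagged,
              expressed = length(unique(filtered$protein_accession)),
              intracellular_candidates = nrow(intracellular),
              extracellular_candidates = nrow(secreted))
  message("funnel: ", paste(names(funnel), funnel, sep = "=",
                            collapse = ", "))

  result <- structure(list(funnel = funnel, secreted = secreted,
                           intracellular = intracellular, flags = flags,
                           calls = calls, qc = qc,
                           composition = composition, lineages = lineages),
                      class = "discovery_result")
  if (!is.null(cfg$out_dir)) write_discovery_artifacts(result, cfg)
  result
}

write_discovery_artifacts <- function(result, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  write_candidate_report(result$secreted, out("candidates_secreted.tsv"))
  write_candidate_report(result$intracellular,
                         out("candidates_intracellular.tsv"))
  write_candidate_flags(result$flags, out("candidate_flags.tsv"))
  if (!is.null(result$lineages)) {
    write_lineage_tsv(result$lineages, out("lineages.tsv"))
  }
  if (!is.null(result$composition)) {
    write_composition_tsv(result$composition, out("composition.tsv"))
  }
  if (!is.null(result$qc)) {
    jsonlite::write_json(
      list(top_k = result$qc$top_k,
           absent_from_secretome = result$qc$absent_from_secretome,
           marker_hits = result$qc$marker_hits),
      out("lysis_qc.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(list(funnel = as.list(result$funnel),
                            seed = cfg$seed,
                            keywords = cfg$keywords),
                       out("funnel.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(cfg$out_dir)
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("Discovery funnel:\n")
  for (k in names(x$funnel)) cat("  ", k, ": ", x$funnel[[k]], "\n", sep = "")
  invisible(x)
}
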