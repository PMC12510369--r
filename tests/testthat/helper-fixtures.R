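# Shared in-code fixtures for the test suite.

# A small alignment-hit tibble for one query.
make_hits <- function(bitscores, lineages,
                      subjects = sprintf("S%02d", seq_along(bitscores)),
                      query = "Q1") {
  tibble::tibble(query_accession = query,
                 subject_accession = subjects,
                 pct_identity = 80, align_length = 100L,
                 evalue = 1e-30, bitscore = bitscores,
                 subject_lineage = lineages)
}

# Random but internally consistent lineages: a tiny 2-phylum taxonomy tree so
# that deeper ranks always nest inside shallower ones.
random_tree_lineage <- function(n) {
  genus <- sample(c("GenA", "GenB", "GenC", "GenD"), n, replace = TRUE)
  fam <- ifelse(genus %in% c("GenA", "GenB"), "Fam1", "Fam2")
  phy <- ifelse(fam == "Fam1", "Phy1", "Phy2")
  paste("Bacteria", phy, paste0("Cls_", phy), paste0("Ord_", fam), fam,
        genus, paste0(genus, " sp."), sep = ";")
}

# Independent brute-force consensus voter: explicit loops, no sorting tricks.
# Used as the oracle for consensus_lineage() on small hit sets.
brute_force_vote <- function(hits, top_n = 25L, min_support = 0.5,
                             weight_by_bitscore = TRUE) {
  ranks <- c("superkingdom", "phylum", "class", "order", "family", "genus",
             "species")
  out <- stats::setNames(rep(NA_character_, 7L), ranks)
  if (nrow(hits) == 0L) return(out)
  ord <- order(-hits$bitscore, hits$subject_accession)
  hits <- hits[ord, , drop = FALSE][seq_len(min(top_n, nrow(hits))), ,
                                    drop = FALSE]
  w <- if (weight_by_bitscore) hits$bitscore else rep(1, nrow(hits))
  total <- sum(w)
  split_lin <- lapply(hits$subject_lineage, function(s) {
    p <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    p[p == ""] <- NA_character_
    # truncate at first missing token
    if (anyNA(p)) p <- p[seq_len(which(is.na(p))[1] - 1L)]
    p
  })
  for (r in seq_len(7L)) {
    votes <- list()
    for (i in seq_len(nrow(hits))) {
      nm <- if (length(split_lin[[i]]) >= r) split_lin[[i]][r] else NA
      if (!is.na(nm)) votes[[nm]] <- (votes[[nm]] %||% 0) + w[i]
    }
    assigned <- NA_character_
    for (nm in names(votes)) {
      if (votes[[nm]] / total > min_support) assigned <- nm
    }
    if (is.na(assigned)) break
    out[r] <- assigned
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small screened universe: 4 proteins, one GH13, one GH4-like, one
# ribosomal, one unannotated.
tiny_screen_fixture <- function() {
  proteins <- tibble::tibble(
    accession = c("P1", "P2", "P3", "P4"),
    description = c("amylase-like", "LDH-like", "ribosomal", "novel"),
    sequence = c("MKL", "MKL", "MKL", "MKL"), length = 3L)
  annotations <- tibble::tibble(
    protein_accession = c("P1", "P2", "P3"),
    source_db = "Pfam",
    signature_id = c("PF00128", "SSF56327", "PF00181"),
    signature_desc = c("Alpha-amylase", "LDH C-terminal domain-like",
                       "Ribosomal protein L2"),
    start = 1L, end = 3L,
    entry_id = c("IPR006047", "IPR015955", "IPR022666"),
    entry_desc = c("Glycoside hydrolase, family 13, catalytic domain",
                   "Lactate dehydrogenase/glycoside hydrolase, family 4, C-terminal",
                   "Ribosomal protein L2"),
    evalue = 1e-10)
  list(proteins = proteins, annotations = annotations)
}

make_ids <- function(acc, fraction, sample_id, count, up = pmin(count, 3L)) {
  tibble::tibble(protein_accession = acc,
                 fraction = factor(fraction,
                                   levels = c("pellet", "supernatant")),
                 sample_id = sample_id,
                 spectral_count = as.integer(count),
                 unique_peptides = as.integer(up))
}
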