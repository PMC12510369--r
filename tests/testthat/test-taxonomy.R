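test_that("unanimous hits assign the full lineage and no hits assign nothing", {
  lin <- "Bacteria;Bacillota;Bacilli;Bacillales;Alicyclobacillaceae;Alicyclobacillus;Alicyclobacillus acidocaldarius"
  hits <- make_hits(seq(300, 60, length.out = 25), rep(lin, 25))
  res <- consensus_lineage(hits)
  expect_equal(unname(res["genus"]), "Alicyclobacillus")
  expect_equal(unname(res["species"]), "Alicyclobacillus acidocaldarius")

  empty <- consensus_lineage(make_hits(numeric(), character()))
  expect_true(all(is.na(empty)))
})

test_that("support below the strict majority leaves the rank and deeper ranks unassigned", {
  # bitscores 100/60/50, genera A/B/B sharing family F: the top hit's genus A
  # has support 100/210 < 0.5, but B carries 110/210 > 0.5 and wins the
  # genus vote; family F is unanimous (values frozen from the brute-force
  # voter).
  hits <- make_hits(c(100, 60, 50),
                    c("Bacteria;P;C;O;F;A;A sp.",
                      "Bacteria;P;C;O;F;B;B sp.",
                      "Bacteria;P;C;O;F;B;B sp."))
  res <- consensus_lineage(hits)
  expect_equal(unname(res["family"]), "F")
  expect_equal(unname(res["genus"]), "B")
  expect_equal(res, brute_force_vote(hits))

  # a genuine split: 100 vs 100, no name exceeds 0.5 -> genus and deeper
  # unassigned while family holds
  split_hits <- make_hits(c(100, 100),
                          c("Bacteria;P;C;O;F;A;A sp.",
                            "Bacteria;P;C;O;F;B;B sp."))
  res2 <- consensus_lineage(split_hits)
  expect_equal(unname(res2["family"]), "F")
  expect_true(is.na(res2["genus"]))
  expect_true(is.na(res2["species"]))
  expect_equal(res2, brute_force_vote(split_hits))
})

test_that("consensus equals an exhaustive brute-force voter on all hit sets of size <= 6", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(0:6, 1)
    lineages <- random_tree_lineage(n)
    # occasionally truncate or blank lineages
    cut <- runif(n) < 0.2
    lineages[cut] <- vapply(lineages[cut], function(s) {
      p <- strsplit(s, ";")[[1]]
      paste(p[seq_len(sample(0:6, 1))], collapse = ";")
    }, character(1))
    hits <- make_hits(round(runif(n, 30, 500), 1), lineages)
    # duplicate bitscores sometimes, to exercise the tie-break
    if (n >= 2 && runif(1) < 0.3) hits$bitscore[2] <- hits$bitscore[1]
    for (wb in c(TRUE, FALSE)) {
      got <- consensus_lineage(hits, consensus_params(top_n = 6,
                                                      weight_by_bitscore = wb))
      want <- brute_force_vote(hits, top_n = 6, weight_by_bitscore = wb)
      expect_equal(got, want)
    }
  }
})

test_that("consensus support is monotone down the ranks and honors the prefix property", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(1:25, 1)
    hits <- make_hits(round(runif(n, 30, 900), 1), random_tree_lineage(n))
    res <- consensus_lineage(hits)
    assigned <- !is.na(res)
    # prefix property: once unassigned, all deeper ranks unassigned
    if (any(!assigned)) {
      expect_true(all(!assigned[seq(which(!assigned)[1], 7L)]))
    }
  }
})

test_that("classify_all covers each query once and is input-order invariant", {
  hits1 <- make_hits(c(200, 100), rep("Bacteria;P;C;O;F;G1;G1 s.", 2),
                     query = "Q1")
  hits2 <- make_hits(c(300, 50), rep("Bacteria;P;C;O;F;G2;G2 s.", 2),
                     subjects = c("T1", "T2"), query = "Q2")
  aln <- dplyr::bind_rows(hits1, hits2)
  res <- classify_all(aln)
  expect_equal(nrow(res), 2L)
  expect_equal(res$genus, c("G1", "G2"))

  shuffled <- aln[sample(nrow(aln)), ]
  expect_equal(classify_all(shuffled), res)
})

test_that("noise-free synthetic alignments recover every source genus", {
  com <- enrichment_community(n_orfs = 50L, seed = 11L)
  ds <- generate_metagenome(com, lineage_noise = 0)
  lin <- classify_all(ds$alignments)
  truth <- ds$truth[match(lin$accession, ds$truth$accession), ]
  expect_equal(lin$genus, truth$genus)
})

test_that("genus composition normalizes to 100, handles unclassified, and is permutation-invariant", {
  lineages <- tibble::tibble(accession = c("P1", "P2", "P3"),
                             genus = c("X", "X", NA_character_))
  ids <- make_ids(c("P1", "P2"), "pellet", "P1s", c(10L, 5L))
  comp <- genus_composition(ids, lineages)
  expect_equal(comp$genus, "X")
  expect_equal(comp$percent, 100)

  ids2 <- make_ids(c("P1", "P3", "P4"), "pellet", "P1s", c(70L, 20L, 10L))
  comp2 <- genus_composition(ids2, lineages)
  expect_equal(sum(comp2$percent), 100)
  expect_equal(comp2$percent[comp2$genus == "X"], 70)
  expect_equal(comp2$percent[comp2$genus == "unclassified"], 30)

  perm <- genus_composition(ids2[c(3, 1, 2), ], lineages)
  expect_equal(dplyr::arrange(perm, genus), dplyr::arrange(comp2, genus))

  none <- make_ids("P1", "pellet", "P1s", 0L, 0L)
  expect_error(genus_composition(none, lineages), "zero total")
})

test_that("a planted 70% dominant genus is recovered within 5 points at depth 5000", {
  com <- enrichment_community(dominant_weight = 0.7, seed = 1L)
  ds <- generate_metagenome(com)
  ids <- generate_identifications(ds, expression_spec(seed = 1L, depth = 5000))
  lin <- classify_all(ds$alignments)
  comp <- genus_composition(ids, lin)
  est <- comp$percent[comp$genus == "Alicyclobacillus"]
  expect_lt(abs(est - 70), 5)
})
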