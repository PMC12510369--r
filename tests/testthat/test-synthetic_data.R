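test_that("community specs validate weights and presets emulate the two scenarios", {
  expect_error(community_spec(c(A = 0.6, B = 0.5)), "sum to 1")
  inoc <- inoculum_community(n_genera = 120L)
  expect_equal(sum(inoc$genus_weights), 1, tolerance = 1e-12)
  expect_gte(length(inoc$genus_weights), 100L)
  enr <- enrichment_community()
  expect_equal(unname(enr$genus_weights["Alicyclobacillus"]), 0.70)
})

test_that("noise-free generation recovers every genus; gh_fraction 0 leaves only unannotated candidates", {
  ds <- generate_metagenome(enrichment_community(n_orfs = 60L, seed = 2L),
                            lineage_noise = 0)
  lin <- classify_all(ds$alignments)
  expect_equal(lin$genus,
               ds$truth$genus[match(lin$accession, ds$truth$accession)])

  ds0 <- generate_metagenome(enrichment_community(n_orfs = 60L, seed = 2L),
                             gh_fraction = 0, with_alignments = FALSE)
  # the planted amylopullulanase is the single forced GH
  expect_equal(sum(ds0$truth$role %in% c("secreted-GH", "intracellular-GH")),
               1L)
  flags <- screen(ds0$annotations[
    !ds0$annotations$protein_accession %in%
      ds0$truth$accession[ds0$truth$planted], ], ds0$proteins)
  non_planted <- flags[flags$protein_accession !=
                         ds0$truth$accession[ds0$truth$planted], ]
  expect_true(all(non_planted$is_unannotated[non_planted$is_candidate]))
})

test_that("a high unclassifiable fraction leaves about that share of ORFs genus-unassigned", {
  ds <- generate_metagenome(inoculum_community(seed = 3L))
  lin <- classify_all(ds$alignments)
  # binomial expectation 0.8 at n = 2000; allow 3 sd
  expect_lt(abs(mean(is.na(lin$genus)) - 0.8), 0.03)
})

test_that("identification tables respect detection, lysis and identification invariants", {
  ds <- generate_metagenome(enrichment_community(seed = 4L),
                            with_alignments = FALSE)
  ids <- generate_identifications(ds, expression_spec(lysis_rate = 0,
                                                      seed = 4L))
  expect_true(all(ids$spectral_count >= ids$unique_peptides))
  expect_true(all(ids$unique_peptides >= 0))
  sup_roles <- ds$truth$role[match(
    unique(ids$protein_accession[as.character(ids$fraction) == "supernatant"]),
    ds$truth$accession)]
  expect_true(all(sup_roles == "secreted-GH"))
})

test_that("identical seeds give byte-identical dataset files", {
  gen <- function(dir) {
    ds <- generate_metagenome(enrichment_community(n_orfs = 150L, seed = 9L))
    ids <- generate_identifications(ds, expression_spec(seed = 9L))
    write_dataset(ds, dir, ids = ids)
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- gen(d1); p2 <- gen(d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
})

test_that("every emitted file parses through the io readers with zero rejected rows", {
  ds <- generate_metagenome(enrichment_community(n_orfs = 200L, seed = 5L))
  ids <- generate_identifications(ds, expression_spec(seed = 5L))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir, ids = ids)
  prot <- read_protein_fasta(paths$proteins)
  expect_equal(nrow(prot), 200L)
  ann <- read_annotation_tsv(paths$annotations)
  expect_equal(parse_summary(ann)$n_rejected, 0L)
  expect_equal(nrow(ann), nrow(ds$annotations))
  aln <- read_alignment_tsv(paths$alignments)
  expect_equal(parse_summary(aln)$n_rejected, 0L)
  expect_equal(nrow(aln), nrow(ds$alignments))
  back_ids <- read_identifications(paths$identifications)
  expect_equal(nrow(back_ids), nrow(ids))
})

test_that("dominant-genus spectral fraction converges toward the community weight with depth", {
  est <- vapply(c(1500, 15000), function(depth) {
    ds <- generate_metagenome(enrichment_community(seed = 6L))
    ids <- generate_identifications(ds, expression_spec(seed = 6L,
                                                        depth = depth))
    j <- ds$truth$genus[match(ids$protein_accession, ds$truth$accession)]
    sum(ids$spectral_count[j == "Alicyclobacillus"]) / sum(ids$spectral_count)
  }, numeric(1))
  expect_lt(abs(est[2] - 0.7), abs(est[1] - 0.7) + 0.03)
  expect_lt(abs(est[2] - 0.7), 0.05)
})

test_that("the packaged secretome fixture reproduces the printed table structure", {
  fx <- table1_fixture()
  expect_equal(nrow(fx$proteins), 17L)
  r1 <- fx$proteins[fx$proteins$accession == "MMBJNONL_14124", ]
  expect_equal(r1$mw, 140550)
  e1 <- fx$annotations$entry_id[fx$annotations$protein_accession ==
                                  "MMBJNONL_14124"]
  expect_setequal(e1, c("IPR006047", "IPR004185", "IPR017853"))
  # exactly six proteins carry integrated entries
  expect_equal(length(unique(fx$annotations$protein_accession)), 6L)
  # unannotated example row
  expect_equal(fx$proteins$mw[fx$proteins$accession == "MMBJNONL_02999"],
               13289)
  expect_false("MMBJNONL_02999" %in% fx$annotations$protein_accession)
  # all present in the supernatant and passing the identification criteria
  expect_true(all(as.character(fx$identifications$fraction) == "supernatant"))
  expect_true(all(fx$identifications$unique_peptides >= 2L))
})
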