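a14 <- "alpha-1,4"
a16 <- "alpha-1,6"

test_that("pullulan chains have the triad bond pattern", {
  p1 <- build_pullulan(1)
  expect_equal(p1$n_units, 3L)
  expect_equal(p1$bonds, c(a14, a14))
  p2 <- build_pullulan(2)
  expect_equal(p2$n_units, 6L)
  expect_equal(p2$bonds, c(a14, a14, a16, a14, a14))
  p100 <- build_pullulan(100)
  expect_equal(p100$n_units, 300L)
  expect_equal(sum(p100$bonds == a16), 99L)
  expect_error(build_pullulan(0), "n_repeats")
})

test_that("pullulanase-I converts pullulan entirely into maltotriose", {
  spec <- digest(build_pullulan(5), enzyme_rule("pullulanase-I"))
  expect_equal(nrow(spec), 1L)
  expect_equal(spec$species, "maltotriose")
  expect_equal(spec$count, 5L)
  h <- hexose_histogram(spec)
  expect_equal(h$histogram$fraction[h$histogram$length == 3], 1.0)
  expect_equal(h$dominant_length, 3L)
})

test_that("neopullulanase and isopullulanase give panose and isopanose interior products", {
  # enumerated on the 9-unit chain: neopullulanase cuts bonds 2, 5, 8 ->
  # maltose + panose + panose + glucose
  neo <- digest(build_pullulan(3), enzyme_rule("neopullulanase"))
  expect_equal(sum(neo$count[neo$species == "panose"]), 2L)
  expect_equal(sum(neo$count[neo$species == "maltose"]), 1L)
  expect_equal(sum(neo$count[neo$species == "glucose"]), 1L)
  # every 3-unit product has pattern (a16, a14)
  expect_equal(neo$bond_pattern[neo$length == 3],
               paste(a16, a14, sep = ";"))

  iso <- digest(build_pullulan(3), enzyme_rule("isopullulanase"))
  expect_equal(sum(iso$count[iso$species == "isopanose"]), 2L)
  expect_equal(iso$bond_pattern[iso$length == 3],
               paste(a14, a16, sep = ";"))
})

test_that("exhaustive both-bond digestion fully hydrolyzes to glucose; p=0 is the identity", {
  ch <- build_pullulan(4)
  full <- digest(ch, enzyme_rule("pullulanase-II"))
  expect_equal(full$species, "glucose")
  expect_equal(full$count, ch$n_units)

  none <- digest(ch, enzyme_rule("pullulan-hydrolase-III",
                                 mode = "stochastic", p = 0))
  expect_equal(nrow(none), 1L)
  expect_equal(none$length, ch$n_units)
  expect_equal(none$count, 1L)
})

test_that("hexose counts are conserved for random chains and enzymes", {
  set.seed(99)
  presets <- c("pullulanase-I", "pullulanase-II", "neopullulanase",
               "isopullulanase", "pullulan-hydrolase-III")
  for (rep in 1:40) {
    bonds <- sample(c(a14, a16), sample(1:40, 1), replace = TRUE)
    ch <- glycan_chain(bonds)
    enz <- enzyme_rule(sample(presets, 1),
                       mode = sample(c("exhaustive", "stochastic"), 1),
                       p = runif(1), seed = rep)
    spec <- digest(ch, enz)
    expect_equal(sum(spec$length * spec$count), ch$n_units)
  }
})

test_that("stochastic digestion is seed-deterministic", {
  ch <- build_pullulan(20)
  enz <- enzyme_rule("pullulan-hydrolase-III", mode = "stochastic", p = 0.5,
                     seed = 123L)
  expect_equal(digest(ch, enz), digest(ch, enz))
  alt <- digest(ch, enz, seed = 124L)
  expect_false(identical(alt$count, digest(ch, enz)$count) &&
                 identical(alt$bond_pattern, digest(ch, enz)$bond_pattern))
})

test_that("near-complete stochastic both-bond digestion is glucose-dominated, matching the geometric fragment-length law", {
  spec <- digest(build_pullulan(50),
                 enzyme_rule("pullulan-hydrolase-III", mode = "stochastic",
                             p = 0.9, seed = 7L))
  h <- hexose_histogram(spec)
  expect_equal(h$dominant_length, 1L)
  # i.i.d. cuts at rate p give fragment lengths ~ Geometric(p): the Hex1
  # fraction estimates p
  frac1 <- h$histogram$fraction[h$histogram$length == 1]
  expect_lt(abs(frac1 - 0.9), 0.1)
})

test_that("partial both-bond digestion of pullulan yields the expected short-product species set", {
  # 1-3 unit products of an i.i.d. both-bond cutter: the four named type-III
  # products (glucose, maltose, maltotriose, panose) plus isopanose, plus the
  # occasional isolated alpha-1,6 fragment (isomaltose) the independence
  # assumption admits
  allowed <- c("glucose", "maltose", "isomaltose", "maltotriose", "panose",
               "isopanose")
  seen <- character()
  for (s in 1:10) {
    spec <- digest(build_pullulan(30),
                   enzyme_rule("pullulan-hydrolase-III", mode = "stochastic",
                               p = 0.5, seed = s))
    short <- spec$species[spec$length <= 3]
    expect_true(all(short %in% allowed))
    expect_true(all(grepl("^Hex[0-9]+-other$", spec$species[spec$length > 3])))
    seen <- union(seen, short)
  }
  expect_true(all(c("glucose", "maltose", "maltotriose", "panose") %in% seen))
})

test_that("spectrum TSV round-trips through readr", {
  spec <- digest(build_pullulan(3), enzyme_rule("neopullulanase"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_tsv(spec, path)
  back <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  expect_equal(back$species, spec$species)
  expect_equal(back$count, spec$count)
})
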