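---
title: "Methods: mining glycoside hydrolase candidates from enrichment metaproteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining glycoside hydrolase candidates from enrichment metaproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghmine)
```

## The problem ghmine addresses

Enrichment cultures grown on a single polymeric carbon source select for
organisms that can hydrolyse that polymer. Sequencing the enriched community
yields thousands of open reading frames (ORFs); fractionated metaproteomics
(cell pellet versus culture supernatant) tells us which of those genes are
actually expressed and where the proteins end up. `ghmine` implements the
downstream informatics of such an experiment for glycoside hydrolase (GH)
discovery on pullulan, a linear polysaccharide of maltotriose units
(Glc-α1,4-Glc-α1,4-Glc) joined by α-1,6 bonds:

1. strict readers/writers for the tables such experiments produce,
2. consensus taxonomic classification of ORFs from alignment hits,
3. a keyword screen of functional annotations that retains unannotated genes,
4. integration with fractionated spectral counts (localization, ranking,
   lysis quality control),
5. two self-contained computations: the growth-stoichiometry balance behind
   culture acidification, and a bond-context simulator of pullulan
   depolymerization,
6. a ground-truth synthetic-data generator so every stage is testable
   without access to raw data.

The package never runs external annotators or aligners (InterProScan,
DIAMOND, search engines); it consumes their tabular outputs. FDR control of
peptide-spectrum matches is search-engine territory and is not recomputed;
the unique-peptide identification filter is.

## Consensus taxonomy

Each ORF's alignment hits are sorted by descending bitscore (ties broken by
ascending subject accession, so results are deterministic), truncated to the
top `top_n` (default 25). At each rank from superkingdom down to species a
candidate name's support is the summed bitscore of the retained hits
carrying that name divided by the summed bitscore of *all* retained hits.
The name is assigned iff its support strictly exceeds `min_support`
(default 0.5, a strict majority); the first failing rank and everything
deeper stay unassigned, which guarantees the prefix property of lineages.

Design choices made here, where the design was genuinely open:

* Whether the original bitscore-consensus procedure uses a strict majority,
  a plurality, or some fixed support threshold is not something this package
  can settle; `min_support` is therefore an explicit parameter with a strict
  majority as the default, which degrades gracefully (LCA-like) when hits
  conflict.
* Hits with missing or truncated lineages count toward the denominator but
  support no name. This is the conservative reading: uninformative hits are
  evidence *against* confident assignment, not missing data to be dropped.
* `weight_by_bitscore = FALSE` switches to uniform weights for sensitivity
  analysis.

Genus composition tables are spectral-count weighted: per-genus counts over
the grand total, with an explicit `unclassified` bucket that participates in
the normalization. Display filtering of small genera (e.g. "genera with more
than 10 counts") is deliberately left to report time so that percentages
always refer to the full community.

## Keyword screen

Matching is case-insensitive plain substring over four fields of every
annotation row (signature description, integrated-entry description,
signature id, integrated-entry id), after Unicode NFC normalization. No word
boundaries are imposed: `"GH13"` must hit subfamily labels like `GH13_39`.
The default keyword set is frozen to eight strings: `family 13`, `GH13`,
`family 57`, `GH57`, `amylase`, `glycosidase`, `glycoside hydrolase`,
`pullulan`.

"Unannotated" by default means *zero annotation rows at all*, and
unannotated proteins are retained as candidates — this is what lets the
funnel surface completely novel sequences. A stricter mode
(`strict_unannotated = TRUE`) additionally counts proteins whose rows all
lack an integrated entry. Whether the original screen searched only
integrated-entry descriptions or all columns is unknowable from the outside;
all-columns is the default here and the choice is visible in the function
contract.

The screen is provably monotone: enlarging the keyword set never removes a
keyword-matched candidate. The test suite asserts this on randomized
fixtures.

## Localization, ranking and the lysis QC

Identification rows need at least 2 unique peptides (configurable). Spectral
counts are summed per protein per fraction across samples. A protein seen in
*any* supernatant sample is called `secreted` — secreted enzymes are
commonly also cell-associated, so pellet co-detection does not revoke the
call; a `both` sub-label is kept for QC. Pellet-only proteins are
`intracellular`. The two calls partition the identified proteins; whether a
study's "intracellular" class excluded supernatant-positive proteins is one
consistent reading of fraction-based localization, recorded here as a
decision, not a fact.

Candidates are ranked within each class by descending spectral count in the
class-defining fraction (supernatant for secreted, pellet for
intracellular), ties broken by ascending accession. Abundance is the plain
summed spectral count; no length normalization (NSAF-style) is applied by
default because the ranking only needs to be order-faithful within one
experiment.

The lysis QC asks two questions: how many of the `top_k` (default 50) most
abundant pellet proteins were *never* identified in the supernatant (a high
number argues against cytoplasmic contamination of the secretome), and
whether named glycolytic markers — glyceraldehyde-3-phosphate dehydrogenase,
phosphoglycerate mutase, glucose-6-phosphate isomerase — appear in the
secretome at all. Marker matching is by description substring because the
synthetic data labels roles explicitly; with real data one would supply
accession lists instead.

Molecular weights are average-isotopic: the sum of standard average residue
masses plus one water, with `X` counted as a generic 110 Da residue.
Reports round to whole daltons; internal values keep full precision.

## Growth stoichiometry

For aerobic growth on a CHON substrate with ammonium as the nitrogen
source,

$$ 1\,S + a\,\mathrm{NH_4^+} + b\,\mathrm{O_2} \rightarrow
   c\,X + d\,\mathrm{CO_2} + e\,\mathrm{H_2O} + f\,\mathrm{H^+} $$

the system is closed-form once the biomass yield (C-mol X per mol substrate)
is given: the N balance fixes $a$, the C balance $d$, the charge balance
$f = a$ (each ammonium taken up leaves one proton behind — this is why an
unbuffered culture acidifies), the H balance $e$ and the O balance $b$. The
degree-of-reduction balance with $\gamma = 4C + H - 2O - 3N$ (the
ammonium-as-N-source convention, which gives a standard biomass
$\gamma_X = 4.2$ for CH$_{1.8}$N$_{0.2}$O$_{0.5}$) is redundant and is
verified as a residual, as are all five elemental/charge balances
(closure $< 10^{-9}$, property-tested over random feasible formulas).

```{r stoich}
st <- solve_growth_stoichiometry("C6H12O6", "CH1.8N0.2O0.5",
                                 biomass_yield_c = 3.28)
st
protons_per_substrate(st)
```

The yield is always an explicit input — the solver never infers it. Note
that with an ammonium coefficient of 0.656 the charge balance forces the
proton coefficient to be 0.656 as well; a report that prints the proton
term as 0.6 alongside 0.656 ammonium is rounding inconsistently, and this
solver always returns the balance-consistent value. Coefficients are
rounded (3 decimals for NH$_4^+$, 2 for O$_2$/CO$_2$/H$_2$O) only at the
report layer.

## Pullulan digestion model

A glycan chain is a run of glucose units with an ordered bond vector over
{α-1,4, α-1,6}; pullulan from $r$ repeats has $3r$ units and the pattern
(α1,4, α1,4, α1,6) repeating with the final α1,6 absent. Unit 1 is the
non-reducing end and bond $i$ joins units $i$ and $i+1$ (this orientation is
recorded in every emitted spectrum header).

An enzyme is a pure predicate on a bond's local context (its type, its
neighbours' types, chain-end flags):

* **pullulanase-I** cleaves every α-1,6 bond → pure maltotriose from
  pullulan;
* **neopullulanase** cleaves the α-1,4 bond whose *successor* is α-1,6 or
  the chain end → interior products are panose (pattern α1,6–α1,4);
* **isopullulanase** cleaves the α-1,4 bond whose *predecessor* is α-1,6 or
  the chain start → interior products are isopanose (α1,4–α1,6);
* **pullulanase-II** and **pullulan-hydrolase-III** cleave both bond types.
  Exhaustive use gives glucose; stochastic use (each satisfying bond cut
  independently with probability `p` under a fixed seed) models partial
  digestion.

The two α-1,4-specific rules are distinguishable purely by product bond
pattern, which the tests assert. Chain-terminal fragments that are not full
triads (maltose, glucose at the ends of a neopullulanase digest, say) are
reported as their own species, never merged.

Two modelling caveats are worth stating plainly. Modelling the
both-bond enzymes at the bond level is a simplification — no subsite
binding, no kinetics — and under independent per-bond cuts an isolated
α-1,6 fragment (isomaltose) is occasionally produced (cut both flanking
α-1,4 bonds, leave the α-1,6), a species a real type III hydrolase is not
reported to release. The tests therefore assert the realizable species set
(the four reported products glucose, maltose, maltotriose, panose, plus
isopanose and occasional isomaltose) rather than pretending the
independence assumption is exact. Hexose conservation,
$\sum_k k \cdot n_k = n_\text{units}$, holds for every enzyme and mode and
is property-tested on 1000 random chains.

```{r digest}
tibble::as_tibble(digest(build_pullulan(5), enzyme_rule("pullulanase-I")))
hexose_histogram(digest(build_pullulan(50),
                        enzyme_rule("pullulan-hydrolase-III",
                                    mode = "stochastic", p = 0.9,
                                    seed = 7)))$dominant_length
```

## What the synthetic data emulates — and what it does not

The generator produces two community scenarios as package defaults, chosen
once as the study conditions:

* **inoculum**: 120 genera with a long-tailed weight distribution and an
  unclassifiable fraction of 0.8 (most environmental genes cannot be
  assigned a genus);
* **enrichment**: one dominant genus (*Alicyclobacillus*) holding 70% of
  the ORFs with a 25-genus tail and no unclassifiable ORFs.

Desk scale is 2000 ORFs (a study-scale run would be ~14 000; `n_orfs` is a
plain parameter). Per ORF the generator assigns a genus, a functional role
(secreted GH ~0.9%, intracellular GH ~5.1%, glycolytic markers 0.5%,
transporters 1%, the rest housekeeping — roughly the 17/96
secreted/intracellular candidate proportions at desk scale), a random
sequence of length ~log-normal(300) residues so MW computation is exercised
end-to-end, GH13-flavoured annotation rows unless suppressed by
`annotation_missing_rate` (default 0.35, exercising unannotated retention),
and up to 25 alignment rows with descending bitscores carrying the true
lineage apart from a 2% contamination rate.

Spectral counts are negative-binomial (size 2 by default) with role- and
fraction-specific means; one sample per fraction by default (the replicate
structure of real studies varies; it is a parameter). Intracellular roles
reach the supernatant only through `lysis_rate` (default 0.05) times their
pellet mean, so `lysis_rate = 0` provably yields a marker-free secretome.
One secreted-GH ORF in the dominant genus is planted as an "extracellular
amylopullulanase" with supernatant mean 400 and size 20 — the clearly
dominant band a growth-essential secreted hydrolase forms in a secretome
gel. The tighter dispersion for this one protein is a deliberate design
choice: the generator's contract is that the planted gene *is* the most
abundant supernatant protein, and a size-2 dispersion at mean 400 would
contradict that contract in a substantial fraction of runs.

Two RNG details matter for reproducibility. Identical seeds give
byte-identical output files (tested). And the identification generator
scrambles its seed relative to the metagenome generator: both consume one
uniform per ORF in their first drawing step, so seeding both streams
identically would correlate detection with genus assignment — a subtle
artifact we hit and test against.

What passing tests on this data do **not** show: real spectral counts are
not negative binomial with known means; real annotation coverage is not
uniform across roles; real lineage errors are not i.i.d. contamination; and
real secretomes contain membrane shedding, moonlighting proteins and signal
peptide-less secretion that no role label captures. The synthetic data
establishes that the *pipeline logic* is correct under known truth, not that
the statistical model is faithful to any instrument.

The packaged 17-protein secretome fixture carries the published accessions,
molecular weights and integrated-entry annotations of the worked example;
its spectral counts are arbitrary positive placeholders (the source reports
abundance only as bar graphics) and its member-database signature ids are
synthesized, so tests against the fixture use only presence/absence and
annotation content, never its count values.

## Numerical and degenerate-input policy

* Annotation coordinates are 1-based inclusive; emitted files say so in a
  header comment.
* Missing integrated entries are represented as `NA`, never the empty
  string, so "unannotated" is unambiguous.
* Readers reject invalid rows (start > end, non-positive bitscore) with
  warnings and report counts via `parse_summary()`; they never drop rows
  silently. Unknown fraction labels and negative counts are hard errors.
* Empty hit sets classify as fully unassigned (not an error); zero total
  spectral counts make composition an error (no composition is definable).
* Ties: bitscore ties break by subject accession; ranking ties by protein
  accession; hexose-histogram dominance ties toward the smaller length. All
  orderings are total, so every report is permutation-invariant and
  byte-reproducible under a fixed seed.
* `top_k` larger than the pellet uses the full pellet with a warning;
  `top_k <= 0` is an error.

## Problem sizes used by the test suite

The suite runs the generator at 150–2000 ORFs, the composition recovery at
depth 5000, the rank-1 recovery at 100 seeds × 2000 ORFs (skipping the
alignment table inside that loop, which ranking does not consume), and
hexose conservation on 1000 random chains of up to 30 bonds. These sizes
were chosen to give stable statistics at interactive runtimes.

## Known limitations

* The consensus voter takes lineage strings as given; there is no taxonomy
  database integration, no taxid resolution, and no correction of
  internally inconsistent reference lineages.
* Localization is purely fraction-based; signal-peptide or localization
  predictions can be joined as extra columns but are never computed.
* The digestion model is combinatorial, not kinetic: no rates, no Km, no
  subsite preferences, no branched substrates.
* The growth solver handles CHON substrates and biomass with ammonium as
  the sole N source; other electron acceptors or N sources would need
  additional balance terms.
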