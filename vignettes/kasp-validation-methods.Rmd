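---
title: "Methods: KASP assay validation and cross-fidelity QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KASP assay validation and cross-fidelity QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaspqc)
```

## What the package models

KASP (Kompetitive allele-specific PCR) is a fluorescence-based bi-allelic
genotyping system: each assay interrogates one SNP and returns one of three
clusters, recorded as a two-letter *SNP code* (`AA`, `AG`, `GG`). The codes
are unphased and carry no allele dosage, which matters in polyploids: a
tetraploid heterozygote of any dosage is just "AG". `kaspqc`
operationalizes the analysis chain around such assays for a polyploid
outcrossing grass — prairie cordgrass (*Spartina pectinata*), with
tetraploid (4X), hexaploid (6X) and octoploid (8X) cytotypes — but nothing
in the code is species-specific.

The chain has five stages, each its own module:

1. **Candidate filtering** — nominate assay-suitable SNPs from
   transcriptome variant calls.
2. **Assay validation** — classify each designed assay as failed,
   monomorphic or polymorphic across a germplasm collection, and summarize
   within-population polymorphism by cytotype.
3. **Fingerprinting and phylogeny** — concatenate SNP codes into a
   DNA-like sequence per sample and infer a bootstrapped
   maximum-parsimony tree.
4. **Cross fidelity** — verify F1 hybrids and F2 selfs of controlled
   tetraploid crosses with informative-marker rules and chi-square
   segregation tests.
5. **Simulation** — generate bi-allelic call data under disomic
   inheritance with controlled contamination and noise, so every detector
   can be tested against known truth.

## Candidate filtering

A variant is nominated for assay design iff it is a bi-allelic
single-nucleotide substitution with pooled read depth at least
`min_coverage` (default 100x), alternate-allele frequency inside
`[af_low, af_high]` (default [0.20, 0.80], inclusive — the usual "20–80%"
guideline reads naturally as a closed interval), and no other variant of
any type within `window_width / 2` bp on either side. The window default
is 80 bp total, the conservative end of the customary 80–100 bp
assay-design range, read as a symmetric exclusion zone centered on the
site: flanking primers fail over nearby polymorphisms, and indels are as
disruptive as SNPs, so indels disqualify neighbors even though they are
never candidates themselves. Rejected records are annotated with the
*first* failing rule in the fixed order bi-allelic, coverage, frequency,
window, which makes rejection logs stable under re-ordering of the input.

In the allele-frequency rule, depth and frequency come from `INFO/DP` and
`INFO/AF` when a VCF provides them, falling back to the first sample's
`AD` field otherwise; whether the 100x threshold should apply per
library or to pooled depth is rarely documented in practice, and pooled depth is
assumed here.

Accepted candidates are emitted in the assay-order format
`LEFT15[X/Y]RIGHT14` — 15 bp of upstream flank, the allele pair with the
reference-matching allele first, 14 bp of downstream flank — with an
explicit error when a contig cannot provide the full flanks.

## Assay validation

"Failed" is a wet-lab outcome (no scorable clusters, typically paralogous
amplification) that cannot be inferred from a genotype table, so the
classifier takes the design-failure list as explicit input; a marker with
zero interpretable calls is also failed. Among the rest, a marker is
monomorphic when all non-missing calls are identical, polymorphic
otherwise — a *validated allelic variant*. The three statuses partition
the panel by construction.

Within-population polymorphism treats missing codes the way the original
genotyping protocol did — codes that could not be accurately called are
removed: a marker enters a population's comparison only when every plant
of that population was called at it, and counts as polymorphic when those
calls disagree. A consequence worth knowing: masking a call can hide a
difference but can never create one. Populations with fewer than two
samples (single parents, outgroup accessions) are excluded with a
warning. Cytotype strata are taken from the sample metadata verbatim;
nothing is inferred from the genotypes.

## Fingerprints and maximum parsimony

Each sample's fingerprint is the concatenation of its canonical two-letter
codes in panel order — two independent characters per marker, so 59
markers give 118 characters, and a heterozygote sits one character change
from either homozygote. No IUPAC ambiguity coding is used; a missing
genotype contributes `--`. Columns with less than 95% site coverage
(non-gap fraction) are removed before tree inference, mirroring the usual
alignment-hygiene rule.

The tree machinery is written in the package rather than delegated,
because its exact semantics are part of what is being reproduced:

* **Fitch counting** scores a fixed unrooted binary topology as the sum
  over columns of minimum state changes. Gaps are treated as missing data
  (full ambiguity), so a gapped taxon never forces a change. Duplicate
  column patterns are collapsed with weights before scoring.
* **Search** follows the classic recipe: for each of `n_random_additions`
  random taxon orders, build a greedy stepwise-addition tree, then
  hill-climb with subtree-pruning-regrafting (SPR) moves, taking the
  first improving rearrangement until none shortens the tree. The
  reference analyses in this field typically run in MEGA with SPR
  rearrangements at search level one from random-addition starts; MEGA's
  internal semantics are not published at implementable precision, so first-improvement hill-climbing from stepwise starts with
  ties broken by first find under the seeded order is this package's
  explicit interpretation. Given a seed, the result is deterministic.
* **Bootstrap** resamples columns with replacement, re-searches each
  replicate (with a reduced addition count, as is customary), and reports
  for each internal edge of the reference tree the percentage of
  replicates containing the same bipartition.

The test suite checks the search against exhaustive topology enumeration
(105 trees at 6 taxa) on 100 random alignments, and checks Fitch scores
against an independent implementation (phangorn). Because the full
76-plant call table was never published, the collection-level results —
the exact published topology, the 52.6%/66.7%/43.5% polymorphism splits
and the 3.8 missing codes per population — are not reproducible from
shipped data; the tree driver operates on the published 17-sample excerpt,
and correctness is established by the property tests instead.

## Cross fidelity

For two parental codes, marker informativeness falls into a five-way
classification (`hom_opposite`, `het_x_hom`, `het_x_het`,
`uninformative`, `unknown`), and under disomic inheritance each
informative class fixes the expected progeny distribution: all
heterozygous (fixed-het), 1:1 between the heterozygote and the
shared-allele homozygote, or 1:2:1. The goodness-of-fit statistic is the
textbook `sum((O - E)^2 / E)` over classes with positive expectation,
with expected counts at full precision (`n/2`, `n/4` — never the
1-decimal rounding used for display; the published statistics only
reproduce with unrounded expectations). The number called `n` varies per
marker because missing calls are removed marker by marker.

Two deliberate reporting conventions:

* The verdict uses df = 2 with critical value 5.991 for *both* test
  types, as the procedure this package reproduces reported, even though a two-class 1:1
  test conventionally has df = 1. `conventional_df = TRUE` switches to
  `classes - 1` degrees of freedom; both behaviors are first-class
  because it is genuinely unclear whether the published df was intentional.
* Off-type progeny (classes with zero expectation, e.g. an unexpected
  homozygote under fixed-het) are excluded from the statistic and
  reported separately via `n_offtype`.

**F1 self detection.** Diagnostic markers are the hom-opposite ones. A
progeny is a self iff every non-missing diagnostic call is homozygous and
equal to the female (seed) parent's code, with at least `min_diagnostic`
(default 2) such observations; any heterozygous diagnostic call
contradicts selfing. Progeny homozygous for the *male* allele are
off-type, not selfs — selfing can only reproduce the seed parent.
Progeny with too few observed diagnostics are `unresolved` rather than
guessed. The procedure this reproduces described the rule only as consistency
across multiple diagnostic assays, without a numeric threshold, so the
threshold is explicit and configurable here.

**F2 outcross detection.** For a selfed parent the diagnostic set is the
markers where it is homozygous; a true self can only be the parental
homozygote there. An individual off-type (heterozygous or
opposite-homozygote) at `min_offtype` (default 2) or more diagnostics is
an outcross.

## The simulator

The generator emulates the study design rather than a general coalescent:
populations draw two independent alleles per genotype from per-population
frequencies (Hardy–Weinberg within population); crosses draw one
uniformly chosen allele from each parent per marker (disomic Mendelian
gametes), with a progeny-level selfing probability `s` replacing the male
gamete by a second female gamete; selfed families analogously substitute a
pollen-pool gamete with probability `o`. Noise is applied per call:
a miscall with probability `e` replaces the code by a uniformly chosen
*different* valid code for that marker's allele pair (KASP errors are
cluster-level, not allele-level), then the call is masked with
probability `m`. Truth labels (origin per progeny, error and missing
flags per call) are returned alongside the matrix, so detector
sensitivity and specificity can be asserted exactly at zero noise.

Octoploids are simulated with the same bi-allelic code model (optionally
with higher heterozygosity via the frequency matrix); no dosage model is
attempted because the assay provides none, and true octoploid inheritance
in this species is unresolved. Partially readable calls are not modeled:
anything not a clean two-letter code is missing.

Default study conditions mirror the emulated design: 38 populations x 2
plants, 59 markers, F1 families of about 80, selfing contamination near
5% and outcrossing near 10% in the respective checks — the rates the
detectors are calibrated against.

## Numerical and design choices

* Heterozygote codes are stored lexicographically sorted ("GA" ≡ "AG");
  writers emit the canonical form, and `-` is the missing token on
  output (en dashes and `NA` are accepted on input).
* Allele-frequency bounds are inclusive; the exclusion window uses
  distance ≤ `window_width / 2`.
* Chi-square expectations are exact fractions of `n`; display rounding
  happens only in reports.
* Tree searches and the bootstrap take explicit seeds; the RNG state is
  restored afterwards. Ties in stepwise addition and SPR are resolved by
  first find in a fixed enumeration order, so a seed fully determines the
  output.
* Test problem sizes are desk-scale by design: exhaustive tree oracles at
  4–6 taxa, 500-variant filter fixtures, 2000-progeny recovery checks
  pooled over 20 simulated families, and 4000 replicates for the type-I
  error of the segregation verdict. The simulation drivers in `analysis/`
  state their own sizes in-line.

## Known limitations

* The classifier cannot discover wet-lab design failures; they are input.
* Dosage-aware genotypes (e.g. `AAAG`) are out of scope end to end.
* The MP search is a heuristic; optimality is only guaranteed where the
  exhaustive oracle can check it, and the MEGA interpretation above is
  one defensible reading, not a reimplementation.
* Population-level summaries on the shipped data cover the published
  17-sample excerpt, not the full collection, and say nothing about
  quantities that require the unpublished 59 x 76 table.
* The simulator draws unlinked markers; linkage, recombination maps and
  population history are deliberately absent.
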