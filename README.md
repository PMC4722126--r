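# kaspqc

Validation and cross-fidelity analysis of KASP SNP genotyping assays in
polyploid plants.

KASP (Kompetitive allele-specific PCR) assays genotype one bi-allelic SNP
at a time, returning an unphased two-letter *SNP code* (`AA`, `AG`, `GG`)
per sample. Breeding programs that adopt the technology face the same
chain of questions every time: which transcriptome variants are worth
designing assays for; which designed assays actually work and are truly
polymorphic in the germplasm; what the validated markers say about
population structure; and — for a self-compatible outcrossing species —
whether a nominal F1 hybrid is really a hybrid and a nominal F2 self is
really a self. `kaspqc` implements that chain for bi-allelic codes under
disomic inheritance, with prairie cordgrass (*Spartina pectinata*, 4X/8X
cytotypes) as the motivating system.

## What it computes

* **Candidate filtering** (`filter_candidates`, `kasp_candidates`):
  bi-allelic SNVs with coverage ≥ 100x, allele frequency in 20–80%, and an
  80 bp window free of other variants; survivors are emitted as
  `LEFT15[X/Y]RIGHT14` assay context sequences.
* **Assay validation** (`classify_assays`, `population_polymorphism`):
  failed / monomorphic / polymorphic accounting over a panel, and
  within-population polymorphism by cytotype.
* **Fingerprints and trees** (`build_fingerprints`, `filter_sites`,
  `fitch_length`, `search_mp`, `bootstrap_support`): concatenated
  SNP-code sequences (two characters per marker), 95% site-coverage
  filtering, and a seeded maximum-parsimony search (stepwise addition +
  SPR hill-climbing) with bootstrap supports.
* **Cross fidelity** (`classify_marker`, `expected_segregation`,
  `chi_square_segregation`, `detect_f1_selfs`, `detect_f2_outcrosses`):
  disomic Mendelian expectations (fixed-het, 1:1, 1:2:1), the χ²
  goodness-of-fit statistic Σ(O−E)²/E with exact expected counts, and
  diagnostic-marker rules for self/outcross detection.
* **Simulation** (`simulate_populations`, `simulate_cross`,
  `simulate_self`): disomic call data with configurable selfing,
  outcrossing, miscall and missing rates, plus truth labels.

Reference genotype tables for the motivating system ship as plain-CSV
fixtures (`kaspqc_example()` lists them), so the whole pipeline runs
without downloads.

## Worked example

Segregation QC of a tetraploid cross (seed parent PC20_102 x pollen
parent PC17_109), using the bundled F1 table:

```r
library(kaspqc)

f1 <- read_genotype_table(kaspqc_example("f1_cross.csv"))
female <- f1$calls["PC20_102", ]
male   <- f1$calls["PC17_109", ]

# expected segregation at a het x hom marker
expected_segregation(female[["pcg_00011"]], male[["pcg_00011"]])
#> 1:1 segregation:
#>  GG  AG
#> 0.5 0.5

# chi-square test from the study's observed class counts (44 GG, 35 AG)
e <- expected_segregation("GG", "GA")
chi_square_segregation(c(GG = 44, AG = 35), e, marker_id = "pcg_00011")
#> pcg_00011 [1:1]: chi2 = 1.025 (df 2, crit 5.991) -> fit, n = 79
```

The statistic 1.025 is below the 5.991 critical value: the marker
segregates 1:1 as disomic inheritance predicts. Self detection on the
eight printed F1 individuals:

```r
progeny <- f1[setdiff(rownames(f1$calls), c("PC17_109", "PC20_102")), ]
rep <- detect_f1_selfs(progeny, female, male)
rep$diagnostic_markers
#> [1] "pcg_00050" "pcg_00058" "pcg_00059" "pcg_00106" "pcg_1186"  "pcg_14142"
subset(rep$verdicts, verdict == "self")$sample_id
#> [1] "13_F1001" "13_F1007"
```

Both flagged individuals match the seed parent at all six hom-opposite
diagnostic markers — they are selfs, not hybrids.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full chain
on the bundled data and write tables under `results/`:

| script | what it does |
|---|---|
| `01_filter_variants.R` | VCF -> candidate SNPs + assay contexts |
| `02_validate_assays.R` | panel accounting, population polymorphism |
| `03_fingerprint_tree.R` | fingerprints, MP tree with bootstrap |
| `04_cross_fidelity.R` | F1 χ² table, F1 self / F2 outcross reports |
| `05_simulation_study.R` | detector calibration on simulated data |

Run them from the repository root, e.g.
`Rscript analysis/04_cross_fidelity.R`.

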