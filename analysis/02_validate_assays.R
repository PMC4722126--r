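#!/usr/bin/env Rscript
# Assay-outcome accounting over the 121-assay panel and within-population
# polymorphism of the core-collection sampling.

suppressPackageStartupMessages({
  library(kaspqc)
  library(jsonlite)
})
dir.create("results", showWarnings = FALSE)

## panel accounting: failed / monomorphic / polymorphic of 121 assays
mk <- read_marker_panel(kaspqc_example("marker_panel.csv"))
panel <- read_genotype_table(kaspqc_example("panel_calls_synthetic.csv"),
                             markers = mk)
fails <- readLines(kaspqc_example("panel_design_failures_synthetic.txt"))
cls <- classify_assays(panel, fails)
print(cls$counts)
cat(sprintf("assay design success: %.1f%%\n", cls$pct_success))
write.table(cls$outcomes, "results/assay_outcomes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

## within-population polymorphism of the published collection sampling
core <- read_genotype_table(kaspqc_example("core_collection.csv"))
pp <- suppressWarnings(population_polymorphism(core))
cat("\nper-population polymorphism (2-plant populations only):\n")
print(pp$per_population)
cat("\nsummary by cytotype stratum:\n")
print(pp$summary)
write.table(pp$per_population, "results/population_polymorphism.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

ms <- missingness_summary(core)
cat(sprintf("\nmissing calls: %d total, %.1f per population on average\n",
            ms$total, ms$mean_per_population))

write_json(list(panel = as.list(cls$counts),
                pct_success = cls$pct_success,
                frac_populations_polymorphic =
                  pp$summary$frac_polymorphic[pp$summary$stratum == "all"],
                mean_missing_per_population = ms$mean_per_population),
           "results/validation_summary.json", auto_unbox = TRUE,
           digits = NA, pretty = TRUE)
cat("wrote results/assay_outcomes.tsv, results/population_polymorphism.tsv,",
    "results/validation_summary.json\n")
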