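#!/usr/bin/env Rscript
# Candidate SNP nomination for KASP assay design.
#
# Walks the demo transcriptome variant set through the four candidate
# rules (bi-allelic SNV, >=100x coverage, allele frequency 20-80%, an
# 80 bp window free of other variants) and emits assay-ready context
# sequences for the survivors.

suppressPackageStartupMessages(library(kaspqc))
dir.create("results", showWarnings = FALSE)

variants <- read_variant_records(kaspqc_example("demo_variants.vcf"))
contigs <- read_contigs(kaspqc_example("demo_contigs.fa"))
cat(nrow(variants), "variant records on", length(contigs), "contigs\n")

res <- kasp_candidates(variants, contigs, filter_params())

cat(nrow(res$accepted), "candidate(s) pass all rules;",
    nrow(res$rejected), "rejected\n")
print(table(res$rejected$reason))
cat("\nassay context(s):\n")
print(res$accepted[, c("contig", "pos", "context")])

write.table(res$accepted, "results/kasp_candidates.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(res$rejected, "results/kasp_rejections.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nwrote results/kasp_candidates.tsv and results/kasp_rejections.tsv\n")
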