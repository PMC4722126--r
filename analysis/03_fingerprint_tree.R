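#!/usr/bin/env Rscript
# SNP-code fingerprints and the bootstrapped maximum-parsimony tree of the
# core-collection sampling (12 cordgrass samples + 5 outgroup Spartina).
#
# The published analysis used 1000 bootstrap replicates on the full
# 76-plant collection; this driver works on the printed 17-sample subset
# and uses 100 replicates, which resolves the same structure at desk scale.

suppressPackageStartupMessages(library(kaspqc))
dir.create("results", showWarnings = FALSE)

core <- read_genotype_table(kaspqc_example("core_collection.csv"))
aln <- build_fingerprints(core)
cat("fingerprints:", length(aln$sample_ids), "samples x",
    nchar(aln$seqs[1]), "characters\n")

filtered <- filter_sites(aln, min_site_coverage = 0.95)
cat("after the 95% site-coverage filter:", nchar(filtered$seqs[1]),
    "characters retained\n")
write_fingerprints_fasta(filtered, "results/fingerprints.fasta")

mp <- search_mp(filtered, n_random_additions = 10, seed = 20160122)
cat("best tree: parsimony length", mp$length, "\n")

bs <- bootstrap_support(filtered, replicates = 100, seed = 20160122,
                        n_random_additions = 2, tree = mp)
cat("bootstrap supports (%):\n")
print(round(sort(bs$supports, decreasing = TRUE)))

ape::write.tree(bs$phylo, "results/mp_tree.nwk")
cat("wrote results/fingerprints.fasta and results/mp_tree.nwk\n")
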