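# Shared fixture loaders and independent oracles for the test suite.

fx <- function(file) kaspqc_example(file)

load_f1 <- function() read_genotype_table(fx("f1_cross.csv"))

f1_parents <- function() {
  gm <- load_f1()
  # the printed F1 family comes from the reciprocal cross with PC20_102
  # as the seed (female) parent
  list(female = gm$calls["PC20_102", ], male = gm$calls["PC17_109", ])
}

f1_progeny <- function() {
  gm <- load_f1()
  gm[setdiff(rownames(gm$calls), c("PC17_109", "PC20_102")), ]
}

load_core <- function() read_genotype_table(fx("core_collection.csv"))

load_seg_observed <- function() {
  utils::read.csv(fx("f1_segregation_observed.csv"),
                  colClasses = c(primer_id = "character",
                                 test = "character",
                                 allele_x = "character",
                                 allele_y = "character"))
}

# observed counts of one segregation fixture row, named by genotype code
seg_observed_counts <- function(row) {
  stats::setNames(
    c(row$obs_x_hom, row$obs_y_hom, row$obs_het),
    c(paste0(row$allele_x, row$allele_x),
      paste0(row$allele_y, row$allele_y),
      parse_snp_code(paste0(row$allele_x, row$allele_y))))
}

f2_family <- function(family) {
  gm <- read_genotype_table(fx("f2_families.csv"))
  gm[gm$samples$population_id == family, ]
}

# build a fingerprint_alignment directly from a character matrix
aln_from_matrix <- function(m) {
  structure(list(sample_ids = rownames(m),
                 seqs = unname(apply(m, 1, paste, collapse = "")),
                 site_map = data.frame(
                   marker_id = paste0("site", seq_len(ncol(m))),
                   slot = 1L)),
            class = "fingerprint_alignment")
}

random_alignment <- function(n_taxa, n_sites, gap_prob = 0.05) {
  m <- matrix(sample(c("A", "C", "G", "T", "-"), n_taxa * n_sites,
                     replace = TRUE,
                     prob = c(rep((1 - gap_prob) / 4, 4), gap_prob)),
              n_taxa, n_sites,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  aln_from_matrix(m)
}

# --- independent oracles -------------------------------------------------

# brute-force re-check of the four candidate rules, written as plain
# nested loops with no shared code with filter_candidates()
oracle_filter <- function(v, params) {
  half <- params$window_width / 2
  ok <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    snv <- grepl("^[ACGT]$", v$ref[i]) && grepl("^[ACGT]$", v$alt[i])
    crowded <- FALSE
    for (j in seq_len(nrow(v))) {
      if (i != j && v$contig[j] == v$contig[i] &&
            abs(v$pos[j] - v$pos[i]) <= half) {
        crowded <- TRUE
      }
    }
    ok[i] <- snv &&
      v$coverage[i] >= params$min_coverage &&
      v$af[i] >= params$af_low && v$af[i] <= params$af_high &&
      !crowded
  }
  v[ok, c("contig", "pos")]
}

# exhaustive-enumeration minimum parsimony length for small alignments
oracle_mp_minimum <- function(aln) {
  enc <- kaspqc:::encode_alignment(aln)
  trees <- kaspqc:::enumerate_topologies(length(aln$sample_ids))
  min(vapply(trees, kaspqc:::fitch_score_utree, numeric(1), enc = enc))
}

random_variants <- function(n, n_contigs = 8) {
  ref <- sample(c("A", "C", "G", "T", "AT", "GCC"), n, replace = TRUE,
                prob = c(.22, .22, .22, .22, .06, .06))
  alt <- vapply(ref, function(r) {
    if (nchar(r) > 1) "A" else sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, "")
  data.frame(contig = paste0("c", sample.int(n_contigs, n, replace = TRUE)),
             pos = sample.int(2000, n, replace = TRUE),
             ref = ref, alt = unname(alt),
             coverage = sample(20:300, n, replace = TRUE),
             af = round(stats::runif(n), 3),
             stringsAsFactors = FALSE)
}
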