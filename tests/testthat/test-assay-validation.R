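toy_matrix <- function(calls) {
  n <- nrow(calls)
  genotype_matrix(calls,
                  data.frame(sample_id = rownames(calls),
                             population_id = sub("_[0-9]+$", "",
                                                 rownames(calls)),
                             ploidy = "4X"))
}

test_that("assay statuses partition the panel", {
  calls <- matrix(c("GG", "GG", "GG",    # monomorphic
                    "AG", "GG", "AA",    # polymorphic
                    NA, NA, NA,          # zero calls -> failed
                    "CC", "CC", "CT"),   # polymorphic but design-failed
                  nrow = 3,
                  dimnames = list(paste0("s_", 1:3),
                                  c("m1", "m2", "m3", "m4")))
  res <- classify_assays(toy_matrix(calls), design_failures = "m4")
  expect_equal(res$outcomes$status,
               c("monomorphic", "polymorphic", "failed", "failed"))
  expect_equal(sum(res$counts[c("failed", "monomorphic", "polymorphic")]),
               unname(res$counts["panel_size"]))
  expect_error(classify_assays(toy_matrix(calls), "nope"),
               "not in panel")
})

test_that("panel accounting reproduces the published 121-assay totals", {
  mk <- read_marker_panel(fx("marker_panel.csv"))
  gm <- read_genotype_table(fx("panel_calls_synthetic.csv"), markers = mk)
  fails <- readLines(fx("panel_design_failures_synthetic.txt"))
  res <- classify_assays(gm, fails)
  expect_equal(unname(res$counts["failed"]), 26L)
  expect_equal(unname(res$counts["monomorphic"]), 11L)
  expect_equal(unname(res$counts["polymorphic"]), 84L)
  expect_equal(res$pct_success, 100 * 95 / 121, tolerance = 1e-10)
})

test_that("population polymorphism counts differing co-called columns", {
  core <- load_core()
  pp <- suppressWarnings(population_polymorphism(core))
  per <- pp$per_population
  # the two PC19_103 plants print identical rows at every co-called marker
  expect_equal(per$n_polymorphic_markers[per$population_id == "PC19_103"], 0L)
  expect_false(per$polymorphic[per$population_id == "PC19_103"])
  # independent column-wise diff oracle for PC38_101
  rows <- core$calls[core$samples$population_id == "PC38_101", ]
  manual <- 0L
  for (j in seq_len(ncol(rows))) {
    col <- rows[, j]
    if (!anyNA(col) && length(unique(col)) > 1L) manual <- manual + 1L
  }
  expect_equal(per$n_polymorphic_markers[per$population_id == "PC38_101"],
               manual)
  # singleton populations (the parents, the outgroup species) are excluded
  expect_warning(population_polymorphism(core), "<2 samples")
  expect_false("PC17_109" %in% per$population_id)
})

test_that("a missing call can hide but never create polymorphism", {
  calls <- matrix(c("AA", "AA", "AG", "AG", "CC", "CT"), nrow = 2,
                  dimnames = list(c("p_1", "p_2"), c("m1", "m2", "m3")))
  before <- population_polymorphism(toy_matrix(calls))
  expect_equal(before$per_population$n_polymorphic_markers, 1L)
  calls[1, "m3"] <- NA      # mask one side of the one difference
  after <- population_polymorphism(toy_matrix(calls))
  expect_equal(after$per_population$n_polymorphic_markers, 0L)
  calls[1, "m1"] <- NA      # masking an identical column changes nothing
  again <- population_polymorphism(toy_matrix(calls))
  expect_equal(again$per_population$n_polymorphic_markers, 0L)
})

test_that("simulated within-population variance drives the summary", {
  cfg0 <- sim_config(n_markers = 20, n_populations = 6,
                     samples_per_population = 2,
                     allele_freq = matrix(rep(c(0, 1), 60), 6, 20),
                     seed = 11)
  none <- simulate_populations(cfg0)
  expect_equal(population_polymorphism(none)$summary$frac_polymorphic[1], 0)
  cfg1 <- sim_config(n_markers = 40, n_populations = 6,
                     samples_per_population = 6, allele_freq = 0.5,
                     seed = 12)
  lots <- simulate_populations(cfg1)
  expect_equal(population_polymorphism(lots)$summary$frac_polymorphic[1], 1)
})
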