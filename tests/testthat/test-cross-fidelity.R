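test_that("marker informativeness follows the parental genotype table", {
  expect_equal(classify_marker("TT", "CC")$class, "hom_opposite")
  expect_equal(classify_marker("GA", "GG")$class, "het_x_hom")
  expect_equal(classify_marker("TG", "TG")$class, "het_x_het")
  expect_equal(classify_marker("GG", "GG")$class, "uninformative")
  expect_equal(classify_marker("-", "GG")$class, "unknown")
})

test_that("expected disomic segregation derives from the parental pair", {
  e11 <- expected_segregation("GA", "GG")
  expect_equal(e11$ratio, "1:1")
  expect_equal(e11$classes, c(GG = 0.5, AG = 0.5))
  e121 <- expected_segregation("TG", "TG")
  expect_equal(e121$ratio, "1:2:1")
  expect_equal(e121$classes, c(GG = 0.25, GT = 0.5, TT = 0.25))
  efix <- expected_segregation("TT", "CC")
  expect_equal(efix$ratio, "fixed-het")
  expect_equal(efix$classes, c(CT = 1))
  expect_error(expected_segregation("GG", "GG"), "uninformative")
  expect_error(expected_segregation("-", "GG"), "unknown")
})

test_that("chi-square statistics reproduce every published F1 test row", {
  seg <- load_seg_observed()
  p <- f1_parents()
  want <- c(pcg_00011 = 1.025, pcg_00012 = 0.821, pcg_00024 = 0.821,
            pcg_00050 = 0, pcg_00058 = 0, pcg_00059 = 0, pcg_00106 = 0,
            pcg_1186 = 0, pcg_14142 = 0,
            pcg_00061 = 3.962, pcg_00062 = 3.962, pcg_7965 = 0.544)
  for (i in seq_len(nrow(seg))) {
    mk <- seg$primer_id[i]
    e <- expected_segregation(p$female[[mk]], p$male[[mk]])
    res <- chi_square_segregation(seg_observed_counts(seg[i, ]), e,
                                  marker_id = mk)
    expect_equal(round(res$chi_square, 3), unname(want[mk]), info = mk)
    expect_false(res$reject)
    expect_equal(sum(res$expected_counts), res$n_called)
    # independent implementation of the same goodness-of-fit test
    keep <- res$expected_counts > 0
    if (sum(keep) > 1) {
      ref <- suppressWarnings(
        stats::chisq.test(res$observed[keep],
                          p = e$classes[keep] / sum(e$classes[keep])))
      expect_equal(res$chi_square, unname(ref$statistic), tolerance = 1e-12)
    }
  }
})

test_that("the statistic is zero exactly when observed equals expected", {
  e <- expected_segregation("GA", "GG")
  expect_equal(chi_square_segregation(c(GG = 40, AG = 40), e)$chi_square, 0)
  expect_gt(chi_square_segregation(c(GG = 41, AG = 39), e)$chi_square, 0)
  expect_error(chi_square_segregation(c(GG = 0, AG = 0), e),
               "no interpretable calls")
})

test_that("the conventional-df switch tightens the 1:1 verdict", {
  e <- expected_segregation("GA", "GG")
  fixed <- chi_square_segregation(c(GG = 50, AG = 29), e)
  conv <- chi_square_segregation(c(GG = 50, AG = 29), e,
                                 conventional_df = TRUE)
  expect_equal(fixed$df, 2)
  expect_equal(fixed$critical_value, 5.991)
  expect_equal(conv$df, 1)
  expect_equal(conv$critical_value, stats::qchisq(0.95, 1))
  expect_equal(fixed$chi_square, conv$chi_square)
  # 5.59 falls between the two critical values
  expect_false(fixed$reject)
  expect_true(conv$reject)
})

test_that("the F1 segregation scan reports the published layout", {
  p <- f1_parents()
  scan <- segregation_scan(f1_progeny(), p$female, p$male)
  expect_true(all(c("pcg_00050", "pcg_00061") %in% scan$marker_id))
  expect_false(any(scan$reject))
  fixedhet <- scan[scan$ratio == "fixed-het", ]
  expect_true(all(fixedhet$chi_square == 0))
})

test_that("F1 self detection flags exactly the two published selfs", {
  p <- f1_parents()
  rep <- detect_f1_selfs(f1_progeny(), p$female, p$male)
  expect_setequal(rep$diagnostic_markers,
                  c("pcg_00050", "pcg_00058", "pcg_00059", "pcg_00106",
                    "pcg_1186", "pcg_14142"))
  selfs <- rep$verdicts$sample_id[rep$verdicts$verdict == "self"]
  expect_setequal(selfs, c("13_F1001", "13_F1007"))
  expect_true(all(rep$verdicts$verdict[!rep$verdicts$sample_id %in% selfs]
                  == "true_hybrid"))
})

test_that("self verdicts demand evidence and tolerate missingness rules", {
  female <- c(m1 = "AA", m2 = "CC", m3 = "GG")
  male <- c(m1 = "GG", m2 = "TT", m3 = "AA")
  calls <- rbind(hyb = c("AG", "CT", "AG"),
                 self = c("AA", "CC", "GG"),
                 thin = c("AA", NA, NA),      # one diagnostic seen
                 off = c("GG", "TT", "AG"))   # matches the male
  colnames(calls) <- names(female)
  gm <- genotype_matrix(calls, data.frame(
    sample_id = rownames(calls), population_id = "f1", ploidy = "4X"))
  rep <- detect_f1_selfs(gm, female, male)
  v <- stats::setNames(rep$verdicts$verdict, rep$verdicts$sample_id)
  expect_equal(unname(v["hyb"]), "true_hybrid")
  expect_equal(unname(v["self"]), "self")
  expect_equal(unname(v["thin"]), "unresolved")
  expect_equal(unname(v["off"]), "true_hybrid")
  expect_equal(rep$verdicts$n_offtype[rep$verdicts$sample_id == "off"], 2L)
  expect_error(detect_f1_selfs(gm, c(m1 = "AG", m2 = "CT", m3 = "AG"),
                               female), "no hom-opposite")
})

test_that("parent-homozygous marker sets match the published asterisks", {
  f2p <- read_genotype_table(fx("f2_parents.csv"))
  expect_setequal(parent_homozygous_markers(f2p$calls["13-F1011", ]),
                  c("pcg_00011", "pcg_00012", "pcg_00024", "pcg_00061",
                    "pcg_00062"))
  expect_setequal(parent_homozygous_markers(f2p$calls["14-F1008", ]),
                  c("pcg_00061", "pcg_00062"))
  allhet <- c(m1 = "AG", m2 = "CT")
  expect_length(parent_homozygous_markers(allhet), 0)
})

test_that("F2 outcross detection flags exactly the two published cases", {
  fam <- f2_family("13_F1008")
  parent <- fam$calls["13-F1008", ]
  prog <- fam[setdiff(rownames(fam$calls), "13-F1008"), ]
  rep <- detect_f2_outcrosses(prog, parent)
  expect_setequal(rep$diagnostic_markers,
                  c("pcg_00011", "pcg_00012", "pcg_00024", "pcg_7965"))
  out <- rep$verdicts$sample_id[rep$verdicts$verdict == "outcross"]
  expect_setequal(out, c("F2:2012_13_F1_008_5", "F2:2012_13_F1_008_6"))
  # the second family has no consistent off-types
  fam2 <- f2_family("13_F1011")
  rep2 <- detect_f2_outcrosses(fam2[setdiff(rownames(fam2$calls),
                                            "13-F1011"), ],
                               fam2$calls["13-F1011", ])
  expect_true(all(rep2$verdicts$verdict == "true_self"))
  expect_error(detect_f2_outcrosses(prog, c(pcg_00011 = "GA")),
               "diagnostic")
})

test_that("purity verdicts recover simulator truth without noise", {
  markers <- paste0("m", 1:8)
  female <- stats::setNames(c(rep("AA", 6), "AG", "CT"), markers)
  male <- stats::setNames(c(rep("GG", 6), "AG", "CT"), markers)
  sim <- simulate_cross(female, male, 400, selfing_rate = 0.06, seed = 71)
  rep <- detect_f1_selfs(sim$matrix, female, male)
  got <- rep$verdicts$verdict == "self"
  truth <- sim$truth$origin$origin == "self"
  expect_identical(got, truth)     # sensitivity and specificity 1

  parent <- stats::setNames(c("AA", "GG", "TT", "CC", "AG"), paste0("k", 1:5))
  pool <- stats::setNames(c("GG", "AA", "CC", "TT", "AG"), paste0("k", 1:5))
  sim2 <- simulate_self(parent, 400, outcross_rate = 0.1,
                        pollen_pool_row = pool, seed = 72)
  rep2 <- detect_f2_outcrosses(sim2$matrix, parent)
  expect_identical(rep2$verdicts$verdict == "outcross",
                   sim2$truth$origin$origin == "outcross")
})
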