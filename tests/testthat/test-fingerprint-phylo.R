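test_that("fingerprints concatenate two characters per marker", {
  core <- load_core()
  aln <- build_fingerprints(core)
  expect_equal(unique(nchar(aln$seqs)), 118L)   # 59 markers x 2
  expect_equal(nrow(aln$site_map), 118L)

  one <- genotype_matrix(
    matrix(c("AG", NA), 2, 1, dimnames = list(c("a", "b"), "m1")),
    data.frame(sample_id = c("a", "b"), population_id = "p", ploidy = "4X"))
  a <- build_fingerprints(one)
  expect_equal(a$seqs, c("AG", "--"))
})

test_that("site filtering keeps exactly the well-covered columns", {
  m <- matrix("A", 20, 5, dimnames = list(paste0("t", 1:20), NULL))
  aln <- aln_from_matrix(m)
  expect_equal(filter_sites(aln)$seqs, aln$seqs)     # gap-free: unchanged
  m[1:2, 3] <- "-"                                   # coverage 0.90 < 0.95
  filt <- filter_sites(aln_from_matrix(m))
  expect_equal(nchar(filt$seqs[1]), 4L)
  expect_equal(filt$site_map$marker_id, paste0("site", c(1, 2, 4, 5)))
  # brute-force per-column oracle on random gappy alignments
  set.seed(5)
  for (rep in 1:5) {
    aln <- random_alignment(12, 30, gap_prob = 0.2)
    mm <- do.call(rbind, strsplit(aln$seqs, ""))
    keep <- vapply(seq_len(ncol(mm)),
                   function(j) mean(mm[, j] != "-") >= 0.95, logical(1))
    expect_equal(nchar(filter_sites(aln)$seqs[1]), sum(keep))
  }
})

test_that("Fitch length matches hand-countable cases", {
  ident <- aln_from_matrix(matrix("G", 5, 8,
                                  dimnames = list(paste0("t", 1:5), NULL)))
  any_tree <- ape::rtree(5, tip.label = paste0("t", 1:5))
  expect_equal(fitch_length(any_tree, ident), 0)

  # one site with states A,A,T,T over the three quartet topologies
  quartet <- aln_from_matrix(matrix(c("A", "A", "T", "T"), 4, 1,
                                    dimnames = list(paste0("t", 1:4), NULL)))
  expect_equal(fitch_length(ape::read.tree(text = "((t1,t2),(t3,t4));"),
                            quartet), 1)
  expect_equal(fitch_length(ape::read.tree(text = "((t1,t3),(t2,t4));"),
                            quartet), 2)
  expect_equal(fitch_length(ape::read.tree(text = "((t1,t4),(t2,t3));"),
                            quartet), 2)
  other <- ape::rtree(4, tip.label = paste0("x", 1:4))
  expect_error(fitch_length(other, quartet), "do not match")
})

test_that("Fitch agrees with phangorn on random trees and alignments", {
  skip_if_not_installed("phangorn")
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    aln <- random_alignment(n, 25)
    tr <- ape::rtree(n, tip.label = sample(paste0("t", 1:n)))
    pd <- phangorn::phyDat(stats::setNames(strsplit(aln$seqs, ""),
                                           aln$sample_ids), type = "DNA")
    expect_equal(fitch_length(tr, aln),
                 phangorn::parsimony(ape::unroot(tr), pd))
  }
})

test_that("heuristic search finds the exhaustive minimum on small cases", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    aln <- random_alignment(n, 20)
    res <- search_mp(aln, n_random_additions = 10, seed = rep)
    expect_equal(res$length, oracle_mp_minimum(aln))
    # and never beats its own score claim
    expect_equal(fitch_length(res$tree, aln), res$length)
  }
})

test_that("search is deterministic given a seed and never loses to a
           user-supplied topology", {
  set.seed(33)
  aln <- random_alignment(7, 30)
  a <- search_mp(aln, n_random_additions = 5, seed = 99)
  b <- search_mp(aln, n_random_additions = 5, seed = 99)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$length, b$length)
  for (i in 1:5) {
    user <- ape::rtree(7, tip.label = sample(aln$sample_ids))
    expect_lte(a$length, fitch_length(user, aln))
  }
  expect_error(search_mp(random_alignment(3, 10)), ">= 4 samples")
})

test_that("parsimony length respects the informative-site lower bound", {
  set.seed(55)
  aln <- random_alignment(8, 40)
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  lb <- 0L
  for (j in seq_len(ncol(m))) {
    tab <- table(m[m[, j] != "-", j])
    lb <- lb + max(0L, sum(tab >= 2) - 1L)   # informative-state bound
  }
  res <- search_mp(aln, n_random_additions = 5, seed = 1)
  expect_gte(res$length, lb)
})

test_that("bootstrap support saturates for a clean bipartition", {
  # two 3-taxon groups separated by many consistent columns
  block <- c("A", "A", "A", "T", "T", "T")
  m <- matrix(rep(block, 30), 6, 30,
              dimnames = list(paste0("t", 1:6), NULL))
  m <- cbind(m, matrix(sample(c("A", "C", "G", "T"), 6 * 5, TRUE), 6, 5))
  aln <- aln_from_matrix(m)
  bs <- bootstrap_support(aln, replicates = 50, seed = 3)
  central <- "t4|t5|t6"
  expect_true(central %in% names(bs$supports))
  expect_equal(unname(bs$supports[central]), 100)
  # node labels on the exported tree carry the percentages
  expect_true(any(grepl("100", ape::write.tree(bs$phylo))))
})

test_that("an invariant alignment has parsimony length zero everywhere", {
  m <- matrix(rep(c("A", "A", "C", "C", "G", "G"), 10), 6, 10,
              dimnames = list(paste0("t", 1:6), NULL))
  m[] <- "A"
  aln <- aln_from_matrix(m)
  res <- search_mp(aln, n_random_additions = 3, seed = 2)
  expect_equal(res$length, 0)
  bs <- bootstrap_support(aln, replicates = 10, seed = 4, tree = res)
  expect_true(all(bs$supports >= 0 & bs$supports <= 100))
})
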