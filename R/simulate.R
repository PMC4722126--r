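# Disomic-inheritance simulators for bi-allelic KASP calls. The tetraploid
# populations this package targets pair as bivalents, so each locus
# segregates like a diploid: genotypes are two independently drawn alleles
# and crosses follow 1:1 / 1:2:1 monohybrid ratios. Octoploids are emulated
# with the same two-letter code model (KASP codes carry no dosage).

#' Simulation configuration
#'
#' @param n_markers number of bi-allelic markers.
#' @param n_populations number of populations.
#' @param samples_per_population samples drawn per population (the core
#'   collection this emulates sampled 2 plants from each of 38
#'   populations).
#' @param allele_freq frequency of each marker's first allele: a scalar, a
#'   length-`n_markers` vector, or an `n_populations x n_markers` matrix.
#' @param ploidy ploidy label per population (recycled).
#' @param selfing_rate,outcross_rate contamination rates used by the cross
#'   and self generators.
#' @param error_rate per-call probability of a cluster miscall (the code is
#'   replaced by a uniformly chosen different valid code).
#' @param missing_rate per-call probability of a failed call (`NA`).
#' @param seed integer seed making every draw reproducible.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_markers = 59, n_populations = 38,
                       samples_per_population = 2, allele_freq = 0.5,
                       ploidy = "4X", selfing_rate = 0, outcross_rate = 0,
                       error_rate = 0, missing_rate = 0, seed = 20160122) {
  freq <- allele_freq
  if (is.matrix(freq)) {
    stopifnot(nrow(freq) == n_populations, ncol(freq) == n_markers)
  } else {
    freq <- matrix(freq, n_populations, n_markers, byrow = TRUE)
  }
  if (any(freq < 0 | freq > 1)) stop("allele frequencies must be in [0,1]")
  rates <- c(selfing_rate, outcross_rate, error_rate, missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0,1]")
  structure(list(n_markers = n_markers, n_populations = n_populations,
                 samples_per_population = samples_per_population,
                 allele_freq = freq,
                 ploidy = rep_len(ploidy, n_populations),
                 selfing_rate = selfing_rate, outcross_rate = outcross_rate,
                 error_rate = error_rate, missing_rate = missing_rate,
                 seed = seed),
            class = "sim_config")
}

sim_marker_ids <- function(n) sprintf("sim_%05d", seq_len(n))

# allele pair per marker: cycle over transition/transversion pairs
sim_marker_alleles <- function(n) {
  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"),
                  ncol = 2, byrow = TRUE)
  pairs[rep_len(seq_len(nrow(pairs)), n), , drop = FALSE]
}

#' Simulate a multi-population genotype collection
#'
#' Draws each sample's genotype at each marker as two independent alleles
#' from its population's allele frequency (Hardy-Weinberg within
#' population), then masks calls at the configured missing rate. Ploidy
#' labels are attached as metadata without changing the call model.
#'
#' @param cfg a [sim_config()].
#' @return a `genotype_matrix` with samples named `P<i>_<j>`.
#' @export
simulate_populations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  restore <- restore_rng(cfg$seed)
  on.exit(restore())
  alleles <- sim_marker_alleles(cfg$n_markers)
  n_samp <- cfg$n_populations * cfg$samples_per_population
  pop_of <- rep(seq_len(cfg$n_populations), each = cfg$samples_per_population)
  calls <- matrix(NA_character_, n_samp, cfg$n_markers)
  for (j in seq_len(cfg$n_markers)) {
    p <- cfg$allele_freq[pop_of, j]
    a1 <- ifelse(stats::runif(n_samp) < p, alleles[j, 1], alleles[j, 2])
    a2 <- ifelse(stats::runif(n_samp) < p, alleles[j, 1], alleles[j, 2])
    calls[, j] <- code_from_alleles(pmin(a1, a2), pmax(a1, a2))
  }
  if (cfg$missing_rate > 0) {
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_character_
  }
  colnames(calls) <- sim_marker_ids(cfg$n_markers)
  samples <- data.frame(
    sample_id = paste0("P", pop_of, "_",
                       sequence(rep(cfg$samples_per_population,
                                    cfg$n_populations))),
    population_id = paste0("P", pop_of),
    ploidy = cfg$ploidy[pop_of],
    stringsAsFactors = FALSE)
  rownames(calls) <- samples$sample_id
  genotype_matrix(calls, samples)
}

# one gamete (one allele per marker) from a parent's codes
draw_gametes <- function(codes, n) {
  a1 <- substr(codes, 1, 1)
  a2 <- substr(codes, 2, 2)
  k <- length(codes)
  pick <- matrix(stats::runif(n * k) < 0.5, n, k)
  out <- matrix(rep(a1, each = n), n, k)
  alt <- matrix(rep(a2, each = n), n, k)
  out[pick] <- alt[pick]
  out
}

# code-level miscall + missing noise; returns calls plus flag matrices
apply_call_noise <- function(calls, allele_pairs, error_rate, missing_rate) {
  n <- nrow(calls); k <- ncol(calls)
  err <- matrix(FALSE, n, k); mis <- matrix(FALSE, n, k)
  if (error_rate > 0) {
    err <- matrix(stats::runif(n * k) < error_rate, n, k)
    for (j in seq_len(k)) {
      ab <- allele_pairs[j, ]
      valid <- unique(c(paste0(ab[1], ab[1]),
                        code_from_alleles(ab[1], ab[2]),
                        paste0(ab[2], ab[2])))
      if (length(valid) < 2L) { err[, j] <- FALSE; next }
      idx <- which(err[, j])
      for (i in idx) {
        alt <- setdiff(valid, calls[i, j])
        calls[i, j] <- alt[sample.int(length(alt), 1L)]
      }
    }
  }
  if (missing_rate > 0) {
    mis <- matrix(stats::runif(n * k) < missing_rate, n, k)
    calls[mis] <- NA_character_
  }
  list(calls = calls, error_flag = err, missing_flag = mis)
}

parent_codes <- function(row) {
  codes <- parse_snp_code(unlist(row))
  if (anyNA(codes)) stop("parent genotypes must be fully specified")
  stats::setNames(codes, names(row))
}

# union of the alleles two parents carry, per marker
pair_alleles <- function(f_codes, m_codes) {
  t(vapply(seq_along(f_codes), function(j) {
    a <- sort(unique(c(substr(f_codes[j], 1, 1), substr(f_codes[j], 2, 2),
                       substr(m_codes[j], 1, 1), substr(m_codes[j], 2, 2))))
    c(a[1], a[min(2, length(a))])
  }, character(2)))
}

#' Simulate an F1 cross with selfing contamination
#'
#' With probability `1 - selfing_rate` a progeny receives one uniformly
#' chosen allele from each parent at every marker (disomic Mendelian
#' gametes); with probability `selfing_rate` both gametes come from the
#' female. Each emitted call is then miscalled with probability
#' `error_rate` (replaced by a uniformly chosen different valid code for
#' that marker's allele pair) and set missing with probability
#' `missing_rate`.
#'
#' @param female_row,male_row named character vectors of fully specified
#'   parental codes (names = marker ids).
#' @param n_progeny number of progeny.
#' @param selfing_rate,error_rate,missing_rate probabilities in `[0, 1]`.
#' @param seed optional integer seed.
#' @return list with `matrix` (a `genotype_matrix`) and `truth` (list:
#'   `origin` data frame with the true `hybrid`/`self` label per progeny,
#'   `error_flag` and `missing_flag` matrices).
#' @export
simulate_cross <- function(female_row, male_row, n_progeny,
                           selfing_rate = 0, error_rate = 0,
                           missing_rate = 0, seed = NULL) {
  restore <- restore_rng(seed)
  if (!is.null(seed)) on.exit(restore())
  f <- parent_codes(female_row)
  m <- parent_codes(male_row)
  stopifnot(identical(names(f), names(m)), n_progeny >= 1)
  is_self <- stats::runif(n_progeny) < selfing_rate
  g_f <- draw_gametes(f, n_progeny)
  g_m <- draw_gametes(m, n_progeny)
  g_f2 <- draw_gametes(f, n_progeny)     # second female gamete for selfs
  g_m[is_self, ] <- g_f2[is_self, , drop = FALSE]
  calls <- matrix(code_from_alleles(pmin(g_f, g_m), pmax(g_f, g_m)),
                  n_progeny, length(f))
  noisy <- apply_call_noise(calls, pair_alleles(f, m),
                            error_rate, missing_rate)
  colnames(noisy$calls) <- names(f)
  ids <- sprintf("F1_%04d", seq_len(n_progeny))
  rownames(noisy$calls) <- ids
  samples <- data.frame(sample_id = ids, population_id = "simulated_F1",
                        ploidy = "4X", stringsAsFactors = FALSE)
  list(matrix = genotype_matrix(noisy$calls, samples),
       truth = list(origin = data.frame(
                      sample_id = ids,
                      origin = ifelse(is_self, "self", "hybrid"),
                      stringsAsFactors = FALSE),
                    error_flag = noisy$error_flag,
                    missing_flag = noisy$missing_flag))
}

#' Simulate selfed (F2) progeny with outcross contamination
#'
#' With probability `1 - outcross_rate` both gametes are drawn from the
#' selfed parent; with probability `outcross_rate` the male gamete is
#' drawn from `pollen_pool_row` (stray pollen). Call noise as in
#' [simulate_cross()].
#'
#' @param parent_row named character vector of the selfed parent's codes.
#' @param n_progeny number of progeny.
#' @param outcross_rate probability a progeny is pollinated from the pool.
#' @param pollen_pool_row named character vector of contaminating pollen
#'   genotypes; required when `outcross_rate > 0`.
#' @param error_rate,missing_rate per-call noise probabilities.
#' @param seed optional integer seed.
#' @return list with `matrix` and `truth` (`origin` labels
#'   `self`/`outcross`, plus flag matrices), as in [simulate_cross()].
#' @export
simulate_self <- function(parent_row, n_progeny, outcross_rate = 0,
                          pollen_pool_row = NULL, error_rate = 0,
                          missing_rate = 0, seed = NULL) {
  restore <- restore_rng(seed)
  if (!is.null(seed)) on.exit(restore())
  p <- parent_codes(parent_row)
  if (outcross_rate > 0 && is.null(pollen_pool_row)) {
    stop("pollen_pool_row is required when outcross_rate > 0")
  }
  is_out <- stats::runif(n_progeny) < outcross_rate
  g_f <- draw_gametes(p, n_progeny)
  g_m <- draw_gametes(p, n_progeny)
  pool <- if (is.null(pollen_pool_row)) p else parent_codes(pollen_pool_row)
  stopifnot(identical(names(pool), names(p)))
  g_pool <- draw_gametes(pool, n_progeny)
  g_m[is_out, ] <- g_pool[is_out, , drop = FALSE]
  calls <- matrix(code_from_alleles(pmin(g_f, g_m), pmax(g_f, g_m)),
                  n_progeny, length(p))
  noisy <- apply_call_noise(calls, pair_alleles(p, pool),
                            error_rate, missing_rate)
  colnames(noisy$calls) <- names(p)
  ids <- sprintf("F2_%04d", seq_len(n_progeny))
  rownames(noisy$calls) <- ids
  samples <- data.frame(sample_id = ids, population_id = "simulated_F2",
                        ploidy = "4X", stringsAsFactors = FALSE)
  list(matrix = genotype_matrix(noisy$calls, samples),
       truth = list(origin = data.frame(
                      sample_id = ids,
                      origin = ifelse(is_out, "outcross", "self"),
                      stringsAsFactors = FALSE),
                    error_flag = noisy$error_flag,
                    missing_flag = noisy$missing_flag))
}
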