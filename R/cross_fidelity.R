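# F1/F2 cross-fidelity machinery: informative-marker classification,
# expected disomic segregation, chi-square goodness of fit, self and
# outcross detection.

#' Classify a marker's informativeness from the parental genotypes
#'
#' Under disomic (bivalent-pairing) inheritance a bi-allelic marker's
#' usefulness for cross verification is fixed by the two parental codes:
#' \describe{
#'   \item{hom_opposite}{both parents homozygous for different alleles —
#'     every true hybrid is heterozygous, the diagnostic class;}
#'   \item{het_x_hom}{exactly one parent heterozygous (1:1 segregation);}
#'   \item{het_x_het}{both parents heterozygous (1:2:1 segregation);}
#'   \item{uninformative}{both parents homozygous for the same allele;}
#'   \item{unknown}{either parental call missing.}
#' }
#'
#' @param female,male parental SNP codes (any accepted token form).
#' @param marker_id optional id carried through to the result.
#' @return list with `marker_id`, `class`, `female_code`, `male_code`.
#' @export
classify_marker <- function(female, male, marker_id = NA_character_) {
  f <- parse_snp_code(female)
  m <- parse_snp_code(male)
  cls <- if (is.na(f) || is.na(m)) {
    "unknown"
  } else {
    fh <- is_homozygous(f); mh <- is_homozygous(m)
    if (fh && mh) {
      if (f == m) "uninformative" else "hom_opposite"
    } else if (fh || mh) "het_x_hom" else "het_x_het"
  }
  list(marker_id = marker_id, class = cls, female_code = f, male_code = m)
}

#' Expected disomic segregation of a cross
#'
#' Derives the progeny genotype classes and their Mendelian weights from
#' the parental codes of an informative marker:
#' hom-opposite parents give a fixed heterozygote (all progeny XY);
#' heterozygote x homozygote gives 1:1 between the heterozygote and the
#' homozygote for the shared allele; heterozygote x heterozygote gives
#' 1:2:1 (X-homozygote : heterozygote : Y-homozygote).
#'
#' @param female,male parental SNP codes.
#' @return list of class `expected_segregation` with `classes` (named
#'   numeric vector of genotype-code weights summing to 1) and `ratio`
#'   (`"fixed-het"`, `"1:1"` or `"1:2:1"`).
#' @export
expected_segregation <- function(female, male) {
  info <- classify_marker(female, male)
  if (info$class %in% c("uninformative", "unknown")) {
    stop("no segregation expectation for an ", info$class, " marker (",
         format_snp_code(female), " x ", format_snp_code(male), ")")
  }
  f <- snp_code_alleles(info$female_code)[[1]]
  m <- snp_code_alleles(info$male_code)[[1]]
  classes <- switch(
    info$class,
    hom_opposite = stats::setNames(1, code_from_alleles(f[1], m[1])),
    het_x_hom = {
      het <- if (is_homozygous(info$female_code)) info$male_code else
        info$female_code
      hom <- if (is_homozygous(info$female_code)) info$female_code else
        info$male_code
      shared <- substr(hom, 1, 1)
      other <- setdiff(snp_code_alleles(het)[[1]], shared)
      stats::setNames(c(0.5, 0.5),
                      c(hom, code_from_alleles(shared, other)))
    },
    het_x_het = {
      a <- sort(f)
      stats::setNames(c(0.25, 0.5, 0.25),
                      c(paste0(a[1], a[1]),
                        code_from_alleles(a[1], a[2]),
                        paste0(a[2], a[2])))
    })
  ratio <- switch(info$class, hom_opposite = "fixed-het",
                  het_x_hom = "1:1", het_x_het = "1:2:1")
  structure(list(classes = classes, ratio = ratio),
            class = "expected_segregation")
}

#' @export
print.expected_segregation <- function(x, ...) {
  cat(x$ratio, "segregation:\n")
  print(x$classes)
  invisible(x)
}

#' Chi-square goodness-of-fit test of a segregation ratio
#'
#' Computes the textbook statistic `sum((obs - exp)^2 / exp)` over the
#' genotype classes with positive expected weight, with expected counts
#' taken at full precision (`n/2`, `n/4`, never rounded). By default the
#' verdict uses df = 2 and critical value 5.991 for every ratio — the
#' reporting convention of the KASP cross-fidelity procedure this package
#' reproduces — regardless of the conventional `classes - 1` degrees of
#' freedom; set `conventional_df = TRUE` for the latter.
#'
#' @param observed named integer vector of observed counts per genotype
#'   code (codes are normalized; classes absent from `expected` are
#'   ignored for the statistic but reported as off-type).
#' @param expected an [expected_segregation()] result.
#' @param df degrees of freedom used for the verdict (default 2).
#' @param critical_value rejection threshold for the statistic
#'   (default 5.991 = the 0.05 quantile complement at df 2).
#' @param conventional_df if `TRUE`, use `df = length(classes) - 1` and
#'   the matching 5 percent critical value instead of the fixed pair.
#' @param marker_id optional id carried through.
#' @return list of class `segregation_result`: `marker_id`, `observed`,
#'   `expected_counts`, `n_called`, `n_offtype`, `chi_square`, `df`,
#'   `critical_value`, `reject`, `ratio`.
#' @export
chi_square_segregation <- function(observed, expected, df = 2,
                                   critical_value = 5.991,
                                   conventional_df = FALSE,
                                   marker_id = NA_character_) {
  stopifnot(inherits(expected, "expected_segregation"))
  names(observed) <- parse_snp_code(names(observed))
  cls <- names(expected$classes)
  obs <- stats::setNames(numeric(length(cls)), cls)
  hit <- names(observed) %in% cls
  obs[names(observed)[hit]] <- observed[hit]
  n_offtype <- sum(observed[!hit])
  n_called <- sum(obs)
  if (n_called == 0) stop("no interpretable calls to test")
  exp_counts <- expected$classes * n_called
  chi2 <- sum((obs - exp_counts)^2 / exp_counts)
  if (conventional_df) {
    df <- length(cls) - 1L
    critical_value <- if (df > 0) stats::qchisq(0.95, df) else 0
  }
  structure(list(marker_id = marker_id, observed = obs,
                 expected_counts = exp_counts,
                 n_called = n_called, n_offtype = n_offtype,
                 chi_square = chi2, df = df,
                 critical_value = critical_value,
                 reject = chi2 > critical_value,
                 ratio = expected$ratio),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("%s [%s]: chi2 = %.3f (df %s, crit %.3f) -> %s, n = %d\n",
              x$marker_id, x$ratio, x$chi_square, x$df, x$critical_value,
              if (x$reject) "reject" else "fit", x$n_called))
  invisible(x)
}

#' Chi-square segregation scan over a progeny matrix
#'
#' Convenience wrapper: for each marker, derives the expectation from the
#' parental codes (skipping uninformative/unknown markers), tallies the
#' progeny calls per genotype class (missing calls removed per marker, so
#' the called total varies across markers), and runs
#' [chi_square_segregation()].
#'
#' @param progeny a `genotype_matrix` of progeny only.
#' @param female,male named character vectors of parental codes (names =
#'   marker ids), covering the progeny markers.
#' @param ... passed on to [chi_square_segregation()].
#' @return data frame with one row per informative marker: ratio,
#'   per-class observed and expected counts, chi-square, verdict.
#' @export
segregation_scan <- function(progeny, female, male, ...) {
  stopifnot(inherits(progeny, "genotype_matrix"))
  out <- list()
  for (mk in colnames(progeny$calls)) {
    info <- classify_marker(female[[mk]], male[[mk]], marker_id = mk)
    if (info$class %in% c("uninformative", "unknown")) next
    exp <- expected_segregation(female[[mk]], male[[mk]])
    calls <- progeny$calls[, mk]
    calls <- calls[!is.na(calls)]
    if (!length(calls)) next
    obs <- table(calls)
    res <- chi_square_segregation(stats::setNames(as.numeric(obs),
                                                  names(obs)),
                                  exp, marker_id = mk, ...)
    cls <- names(res$expected_counts)
    out[[mk]] <- data.frame(
      marker_id = mk, class = info$class, ratio = res$ratio,
      classes = paste(cls, collapse = "/"),
      observed = paste(res$observed, collapse = "/"),
      expected = paste(format(res$expected_counts, trim = TRUE),
                       collapse = "/"),
      n_called = res$n_called, n_offtype = res$n_offtype,
      chi_square = res$chi_square, df = res$df,
      critical_value = res$critical_value, reject = res$reject,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Detect selfed individuals among F1 progeny
#'
#' The diagnostic markers are those where the parents are homozygous for
#' opposite alleles, so every true hybrid must be heterozygous. A progeny
#' is called a self when, at every non-missing diagnostic marker, its code
#' is homozygous and equal to the female parent's code, with at least
#' `min_diagnostic` such markers observed (no heterozygous diagnostic call
#' may contradict the pattern). Progeny homozygous for the male allele at
#' diagnostic markers are off-type — reported, but not selfs. Progeny with
#' fewer than `min_diagnostic` observed diagnostic calls are unresolved.
#'
#' @param f1 a `genotype_matrix` of F1 progeny.
#' @param female,male named character vectors of parental codes (names =
#'   marker ids).
#' @param min_diagnostic minimum observed diagnostic markers for a verdict.
#' @return list of class `purity_report` with `verdicts` (data frame:
#'   `sample_id`, `verdict` in `self`/`true_hybrid`/`unresolved`,
#'   `n_diagnostic`, `n_observed`, `n_female_match`, `n_offtype`,
#'   `n_het`), `diagnostic_markers`, and `rates` (fraction per verdict).
#' @export
detect_f1_selfs <- function(f1, female, male, min_diagnostic = 2) {
  stopifnot(inherits(f1, "genotype_matrix"))
  mk <- colnames(f1$calls)
  cls <- vapply(mk, function(m) classify_marker(female[[m]],
                                                male[[m]])$class, "")
  diag <- mk[cls == "hom_opposite"]
  if (!length(diag)) {
    stop("no hom-opposite diagnostic markers between these parents")
  }
  fem <- parse_snp_code(unlist(female[diag]))
  rows <- lapply(seq_len(nrow(f1$calls)), function(i) {
    calls <- f1$calls[i, diag]
    seen <- !is.na(calls)
    hom <- !is.na(calls) & is_homozygous(calls)
    match_f <- hom & calls == fem
    offtype <- hom & calls != fem
    het <- seen & !hom
    verdict <- if (sum(seen) < min_diagnostic) {
      "unresolved"
    } else if (all(match_f[seen]) && sum(match_f) >= min_diagnostic) {
      "self"
    } else {
      "true_hybrid"
    }
    data.frame(sample_id = rownames(f1$calls)[i], verdict = verdict,
               n_diagnostic = length(diag), n_observed = sum(seen),
               n_female_match = sum(match_f), n_offtype = sum(offtype),
               n_het = sum(het), stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, rows)
  structure(list(verdicts = verdicts, diagnostic_markers = diag,
                 rates = prop.table(table(factor(
                   verdicts$verdict,
                   levels = c("true_hybrid", "self", "unresolved"))))),
            class = "purity_report")
}

#' Markers at which a parent is homozygous
#'
#' These are the markers that can expose pollen contamination among its
#' selfed progeny: a true self of a homozygous parent can only reproduce
#' the parental homozygote.
#'
#' @param parent_row named character vector of the parent's SNP codes.
#' @return character vector of marker ids.
#' @export
parent_homozygous_markers <- function(parent_row) {
  codes <- parse_snp_code(unlist(parent_row))
  names(parent_row)[!is.na(codes) & is_homozygous(codes)]
}

#' Detect outcrossed individuals among selfed (F2) progeny
#'
#' The diagnostic set is the markers at which the selfed parent is
#' homozygous. An individual is called an outcross when it is off-type —
#' heterozygous, or homozygous for the absent allele — at at least
#' `min_offtype` non-missing diagnostic markers; otherwise it is a true
#' self.
#'
#' @param f2 a `genotype_matrix` of progeny from one selfed parent.
#' @param parent_row named character vector of the parent's SNP codes.
#' @param min_offtype minimum off-type diagnostic calls for an outcross
#'   verdict.
#' @return list of class `purity_report` with `verdicts` (`sample_id`,
#'   `verdict` in `outcross`/`true_self`, `n_diagnostic`, `n_observed`,
#'   `n_offtype`), `diagnostic_markers`, and `rates`.
#' @export
detect_f2_outcrosses <- function(f2, parent_row, min_offtype = 2) {
  stopifnot(inherits(f2, "genotype_matrix"))
  diag <- intersect(parent_homozygous_markers(parent_row),
                    colnames(f2$calls))
  if (length(diag) < min_offtype) {
    stop("parent provides only ", length(diag),
         " homozygous diagnostic marker(s); need at least ", min_offtype)
  }
  par <- parse_snp_code(unlist(parent_row[diag]))
  rows <- lapply(seq_len(nrow(f2$calls)), function(i) {
    calls <- f2$calls[i, diag]
    seen <- !is.na(calls)
    offtype <- seen & calls != par
    verdict <- if (sum(offtype) >= min_offtype) "outcross" else "true_self"
    data.frame(sample_id = rownames(f2$calls)[i], verdict = verdict,
               n_diagnostic = length(diag), n_observed = sum(seen),
               n_offtype = sum(offtype), stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, rows)
  structure(list(verdicts = verdicts, diagnostic_markers = diag,
                 rates = prop.table(table(factor(
                   verdicts$verdict, levels = c("true_self", "outcross"))))),
            class = "purity_report")
}

#' @export
print.purity_report <- function(x, ...) {
  cat("purity_report:", nrow(x$verdicts), "progeny,",
      length(x$diagnostic_markers), "diagnostic markers\n")
  print(table(x$verdicts$verdict))
  invisible(x)
}
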