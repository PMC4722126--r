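#' Classify assay outcomes across a collection
#'
#' Each marker of a genotyping panel gets exactly one status:
#' \describe{
#'   \item{failed}{the assay is on the supplied design-failure list (a
#'     wet-lab outcome that cannot be inferred from genotype tables), or
#'     produced zero interpretable calls;}
#'   \item{monomorphic}{at least one call and all non-missing calls
#'     identical;}
#'   \item{polymorphic}{at least two distinct non-missing codes — a
#'     validated allelic variant.}
#' }
#'
#' @param x a `genotype_matrix` whose columns are the full assay panel.
#' @param design_failures character vector of marker ids that failed assay
#'   design; must be a subset of the panel.
#' @return list with `outcomes` (data frame: `marker_id`, `status`,
#'   `n_called`, `n_distinct`) and `counts` (named integer vector over the
#'   three statuses, plus `panel_size` and `pct_success`, the percentage of
#'   the panel that survived assay design).
#' @export
classify_assays <- function(x, design_failures = character(0)) {
  stopifnot(inherits(x, "genotype_matrix"))
  panel <- colnames(x$calls)
  extra <- setdiff(design_failures, panel)
  if (length(extra)) {
    stop("design_failures not in panel: ", paste(extra, collapse = ", "))
  }
  n_called <- colSums(!is.na(x$calls))
  n_distinct <- apply(x$calls, 2, function(cc) length(unique(cc[!is.na(cc)])))
  status <- ifelse(panel %in% design_failures | n_called == 0L, "failed",
                   ifelse(n_distinct <= 1L, "monomorphic", "polymorphic"))
  outcomes <- data.frame(marker_id = panel, status = status,
                         n_called = as.integer(n_called),
                         n_distinct = as.integer(n_distinct),
                         stringsAsFactors = FALSE)
  counts <- c(failed = sum(status == "failed"),
              monomorphic = sum(status == "monomorphic"),
              polymorphic = sum(status == "polymorphic"))
  list(outcomes = outcomes,
       counts = c(counts, panel_size = length(panel)),
       pct_success = 100 * (length(panel) - counts[["failed"]]) /
         length(panel))
}

#' Within-population polymorphism summary
#'
#' For every population with at least two samples, counts the markers at
#' which its samples disagree. Following the convention of removing codes
#' that could not be accurately called, a marker enters a population's
#' comparison only when every sample of that population has a non-missing
#' call at it; it is polymorphic within the population when those calls are
#' not all identical.
#'
#' @param x a `genotype_matrix`.
#' @return list with `per_population` (data frame: `population_id`,
#'   `ploidy`, `n_samples`, `n_markers_compared`, `n_polymorphic_markers`,
#'   `polymorphic` flag) and `summary` (data frame by stratum — `all` plus
#'   each ploidy — with the fraction of populations polymorphic and the
#'   mean polymorphic-marker count).
#' @export
population_polymorphism <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  pops <- split(seq_len(nrow(x$calls)), x$samples$population_id)
  small <- names(pops)[vapply(pops, length, 0L) < 2L]
  if (length(small)) {
    warning("excluding population(s) with <2 samples: ",
            paste(small, collapse = ", "))
    pops <- pops[!names(pops) %in% small]
  }
  if (!length(pops)) stop("no population has >=2 samples")
  rows <- lapply(names(pops), function(p) {
    idx <- pops[[p]]
    sub <- x$calls[idx, , drop = FALSE]
    complete <- colSums(is.na(sub)) == 0L
    npoly <- sum(apply(sub[, complete, drop = FALSE], 2,
                       function(cc) length(unique(cc)) > 1L))
    data.frame(population_id = p,
               ploidy = x$samples$ploidy[idx[1]],
               n_samples = length(idx),
               n_markers_compared = sum(complete),
               n_polymorphic_markers = npoly,
               polymorphic = npoly > 0L,
               stringsAsFactors = FALSE)
  })
  per_pop <- do.call(rbind, rows)
  strata <- c(list(all = per_pop),
              split(per_pop, per_pop$ploidy))
  summary <- do.call(rbind, lapply(names(strata), function(s) {
    d <- strata[[s]]
    data.frame(stratum = s, n_populations = nrow(d),
               frac_polymorphic = mean(d$polymorphic),
               mean_polymorphic_markers = mean(d$n_polymorphic_markers),
               stringsAsFactors = FALSE)
  }))
  list(per_population = per_pop, summary = summary)
}
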