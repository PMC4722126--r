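#' Default candidate-filter parameters
#'
#' Thresholds for nominating KASP-suitable SNPs from transcriptome variant
#' calls: minimum pooled read depth of 100x, an 80 bp exclusion window that
#' must be free of any other variant, and an alternate-allele frequency
#' between 20 and 80 percent (inclusive). The window is symmetric about the
#' candidate site: another variant within `window_width / 2` bp on either
#' side disqualifies it.
#'
#' @param min_coverage minimum read depth (reads).
#' @param window_width total width (bp) of the variant-free window centered
#'   on the site; 80-100 is the usual assay-design range.
#' @param af_low,af_high inclusive alternate-allele frequency bounds.
#' @param require_biallelic keep only single-nucleotide bi-allelic
#'   substitutions as candidates (indels and multi-allelic records are
#'   never candidates, but always count as disqualifying neighbors).
#' @return a list of class `filter_params`.
#' @export
filter_params <- function(min_coverage = 100, window_width = 80,
                          af_low = 0.20, af_high = 0.80,
                          require_biallelic = TRUE) {
  stopifnot(min_coverage >= 0, window_width > 0,
            af_low >= 0, af_high <= 1, af_low < af_high)
  structure(list(min_coverage = min_coverage, window_width = window_width,
                 af_low = af_low, af_high = af_high,
                 require_biallelic = require_biallelic),
            class = "filter_params")
}

is_snv <- function(ref, alt) {
  grepl("^[ACGT]$", ref) & grepl("^[ACGT]$", alt)
}

#' Filter putative SNPs for assay design
#'
#' Applies the four candidate rules to a table of variant records: (1) the
#' record is a bi-allelic single-nucleotide substitution; (2) read coverage
#' is at least `min_coverage`; (3) alternate-allele frequency lies in
#' `[af_low, af_high]`; (4) no other variant of any type on the same contig
#' lies within `window_width / 2` bp. Each rejected record is annotated
#' with the first rule it fails, in that order.
#'
#' @param variants data frame with columns `contig`, `pos` (1-based),
#'   `ref`, `alt`, `coverage`, `af`.
#' @param params a [filter_params()] list.
#' @param sort if `TRUE` (default) records are sorted by (contig, pos)
#'   first; if `FALSE`, unsorted input is an error.
#' @return list with `accepted` (data frame of passing records) and
#'   `rejected` (data frame with a `reason` column: one of
#'   `"not_biallelic_snv"`, `"coverage"`, `"allele_frequency"`,
#'   `"window"`).
#' @export
filter_candidates <- function(variants, params = filter_params(),
                              sort = TRUE) {
  need <- c("contig", "pos", "ref", "alt", "coverage", "af")
  stopifnot(all(need %in% names(variants)))
  v <- as.data.frame(variants)[, need]
  v$pos <- as.numeric(v$pos)
  stopifnot(all(v$pos >= 1), all(v$coverage >= 0),
            all(v$af >= 0 & v$af <= 1))
  ord <- order(v$contig, v$pos)
  if (!identical(ord, seq_len(nrow(v)))) {
    if (!sort) stop("variants are not sorted by (contig, pos)")
    v <- v[ord, , drop = FALSE]
  }
  rownames(v) <- NULL

  half <- params$window_width / 2
  n <- nrow(v)
  reason <- rep(NA_character_, n)

  snv <- is_snv(v$ref, v$alt)
  if (params$require_biallelic) reason[!snv] <- "not_biallelic_snv"
  fail_cov <- is.na(reason) & v$coverage < params$min_coverage
  reason[fail_cov] <- "coverage"
  fail_af <- is.na(reason) & (v$af < params$af_low | v$af > params$af_high)
  reason[fail_af] <- "allele_frequency"

  # any other variant (any type, any status) within half-window distance
  crowded <- logical(n)
  for (ct in unique(v$contig)) {
    idx <- which(v$contig == ct)
    if (length(idx) < 2L) next
    p <- v$pos[idx]
    d_prev <- c(Inf, diff(p))
    d_next <- c(diff(p), Inf)
    crowded[idx] <- pmin(d_prev, d_next) <= half
  }
  reason[is.na(reason) & crowded] <- "window"

  acc <- v[is.na(reason), , drop = FALSE]
  rej <- v[!is.na(reason), , drop = FALSE]
  rej$reason <- reason[!is.na(reason)]
  rownames(acc) <- rownames(rej) <- NULL
  list(accepted = acc, rejected = rej)
}

#' Format a KASP context sequence
#'
#' Builds the assay-design string `LEFT15[X/Y]RIGHT14` from a contig
#' sequence and a variant site: 15 bases of upstream flank, the allele pair
#' in brackets with the reference-matching allele first, then 14 bases of
#' downstream flank.
#'
#' @param contig_sequence character scalar of A/C/G/T (the full contig).
#' @param position 1-based variant position on the contig.
#' @param allele_x,allele_y the two alleles; one of them must equal the
#'   contig base at `position` and is placed first.
#' @param contig_id optional id used in error messages.
#' @return the context string.
#' @export
format_kasp_context <- function(contig_sequence, position, allele_x,
                                allele_y, contig_id = "contig") {
  seq <- toupper(as.character(contig_sequence))
  stopifnot(length(seq) == 1L, grepl("^[ACGT]+$", seq))
  n <- nchar(seq)
  position <- as.integer(position)
  if (position - 15L < 1L || position + 14L > n) {
    stop("insufficient flank for ", contig_id, ":", position,
         " (need 15 bp upstream and 14 bp downstream, contig is ",
         n, " bp)")
  }
  ref_base <- substr(seq, position, position)
  if (allele_x == ref_base) {
    x <- allele_x; y <- allele_y
  } else if (allele_y == ref_base) {
    x <- allele_y; y <- allele_x
  } else {
    stop("neither allele matches the contig base ", ref_base, " at ",
         contig_id, ":", position)
  }
  paste0(substr(seq, position - 15L, position - 1L),
         "[", x, "/", y, "]",
         substr(seq, position + 1L, position + 14L))
}

#' Parse a KASP context sequence
#'
#' Inverse of [format_kasp_context()].
#'
#' @param context string of the form `LEFT15[X/Y]RIGHT14`.
#' @return list with `left_flank`, `right_flank`, `allele_x`, `allele_y`.
#' @export
parse_kasp_context <- function(context) {
  m <- regexec("^([ACGT]{15})\\[([ACGT])/([ACGT])\\]([ACGT]{14})$", context)
  parts <- regmatches(context, m)[[1]]
  if (length(parts) != 5L) stop("malformed context sequence: ", context)
  list(left_flank = parts[2], allele_x = parts[3], allele_y = parts[4],
       right_flank = parts[5])
}

#' Read variant records from a VCF file
#'
#' Extracts the fields the candidate filter needs. Coverage is taken from
#' `INFO/DP` when present, otherwise summed from the first sample's `AD`;
#' allele frequency from `INFO/AF` when present, otherwise the alternate
#' `AD` fraction. Multi-allelic records keep their comma-joined `ALT` and
#' are therefore treated as non-bi-allelic by the filter (but still occupy
#' their position as disqualifying neighbors).
#'
#' @param path path to a VCF file.
#' @return data frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `coverage`, `af`.
#' @export
read_variant_records <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "DP")))
  af <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "AF")))
  need_ad <- any(is.na(dp)) || any(is.na(af))
  if (need_ad && nrow(vcf@gt) > 0 && "AD" %in%
        unlist(strsplit(vcf@gt[1, "FORMAT"], ":"))) {
    ad <- vcfR::extract.gt(vcf, "AD")[, 1]
    ad2 <- t(vapply(strsplit(ad, ","),
                    function(z) as.numeric(z)[1:2], numeric(2)))
    dp_ad <- rowSums(ad2)
    dp <- ifelse(is.na(dp), dp_ad, dp)
    af <- ifelse(is.na(af), ad2[, 2] / dp_ad, af)
  }
  data.frame(contig = fix$CHROM, pos = as.numeric(fix$POS),
             ref = fix$REF, alt = fix$ALT,
             coverage = dp, af = af, stringsAsFactors = FALSE)
}

#' Build a candidate table with context sequences
#'
#' Runs [filter_candidates()] and attaches a KASP context string to every
#' accepted variant whose contig provides enough flank; accepted variants
#' with insufficient flank are moved to the rejection log with reason
#' `"flank"`.
#'
#' @param variants variant data frame (see [filter_candidates()]).
#' @param contigs named character vector of contig sequences (names =
#'   contig ids), e.g. from [read_contigs()].
#' @param params a [filter_params()] list.
#' @return list with `accepted` (including a `context` column) and
#'   `rejected`.
#' @export
kasp_candidates <- function(variants, contigs, params = filter_params()) {
  res <- filter_candidates(variants, params)
  acc <- res$accepted
  if (nrow(acc)) {
    ctx <- character(nrow(acc))
    ok <- logical(nrow(acc))
    for (i in seq_len(nrow(acc))) {
      seq <- contigs[[acc$contig[i]]]
      if (is.null(seq)) stop("no contig sequence for ", acc$contig[i])
      ctx[i] <- tryCatch(
        format_kasp_context(seq, acc$pos[i], acc$ref[i], acc$alt[i],
                            contig_id = acc$contig[i]),
        error = function(e) NA_character_)
      ok[i] <- !is.na(ctx[i])
    }
    flanked <- acc[!ok, , drop = FALSE]
    if (nrow(flanked)) {
      flanked$reason <- "flank"
      res$rejected <- rbind(res$rejected, flanked)
    }
    acc <- acc[ok, , drop = FALSE]
    acc$context <- ctx[ok]
  } else {
    acc$context <- character(0)
  }
  res$accepted <- acc
  res
}

#' Read contig sequences from a FASTA file
#'
#' @param path FASTA file of contigs.
#' @return named character vector of uppercase sequences.
#' @export
read_contigs <- function(path) {
  dna <- ape::read.FASTA(path)
  out <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
  names(out) <- sub("\\s.*$", "", names(dna))
  out
}
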