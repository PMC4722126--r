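#' Build SNP-code fingerprints
#'
#' Concatenates every sample's canonical two-letter SNP codes, in marker
#' order, into one DNA-like character sequence: two characters per marker,
#' so a 59-marker panel yields 118-character fingerprints. A missing
#' genotype contributes `"--"`.
#'
#' @param x a `genotype_matrix`.
#' @return an object of class `fingerprint_alignment`: list with
#'   `sample_ids`, `seqs` (equal-length strings over `A,C,G,T,-`), and
#'   `site_map` (data frame mapping each column to its marker and allele
#'   slot 1 or 2).
#' @export
build_fingerprints <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  calls <- x$calls
  calls[is.na(calls)] <- "--"
  seqs <- apply(calls, 1, paste, collapse = "")
  site_map <- data.frame(
    marker_id = rep(colnames(x$calls), each = 2L),
    slot = rep(1:2, ncol(x$calls)),
    stringsAsFactors = FALSE)
  structure(list(sample_ids = rownames(x$calls),
                 seqs = unname(seqs),
                 site_map = site_map),
            class = "fingerprint_alignment")
}

#' @export
print.fingerprint_alignment <- function(x, ...) {
  cat("fingerprint_alignment:", length(x$sample_ids), "samples x",
      nchar(x$seqs[1]), "characters\n")
  invisible(x)
}

# character matrix view (samples x sites)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$sample_ids
  m
}

#' Drop low-coverage alignment columns
#'
#' Retains exactly the columns whose non-gap fraction is at least
#' `min_site_coverage` (default 0.95, the usual "eliminate positions with
#' <95% site coverage" rule); the site map is updated accordingly.
#'
#' @param aln a `fingerprint_alignment`.
#' @param min_site_coverage minimum fraction of samples with a non-gap
#'   character at a column.
#' @return a filtered `fingerprint_alignment`.
#' @export
filter_sites <- function(aln, min_site_coverage = 0.95) {
  stopifnot(inherits(aln, "fingerprint_alignment"),
            min_site_coverage >= 0, min_site_coverage <= 1)
  m <- aln_matrix(aln)
  keep <- colMeans(m != "-") >= min_site_coverage
  structure(list(sample_ids = aln$sample_ids,
                 seqs = unname(apply(m[, keep, drop = FALSE], 1, paste,
                                     collapse = "")),
                 site_map = aln$site_map[keep, , drop = FALSE]),
            class = "fingerprint_alignment")
}

#' Export fingerprints as FASTA
#'
#' @param aln a `fingerprint_alignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fingerprints_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$sample_ids)) {
    writeLines(c(paste0(">", aln$sample_ids[i]), aln$seqs[i]), con)
  }
  invisible(path)
}
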