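#' Parse two-letter SNP codes
#'
#' KASP genotyping assays report one genotype per marker as a two-letter
#' "SNP code" (e.g. `AA`, `AG`, `GG`). Calls are unphased, so the letter
#' order carries no information: codes are normalized by sorting the two
#' alleles lexicographically, and `"GA"` parses to the same code as `"AG"`.
#'
#' Missing-call tokens (`""`, `"-"`, `"--"`, `"NA"`, and the en dash
#' the literature tends to print) map to `NA`.
#'
#' @param x character vector of raw code tokens.
#' @return character vector of normalized two-letter codes, `NA` for missing.
#' @examples
#' parse_snp_code(c("GA", "AG", "GG", "-"))
#' @export
parse_snp_code <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  missing_tok <- is.na(x) | x %in% c("", "-", "--", "NA", "–", "—")
  todo <- which(!missing_tok)
  if (length(todo)) {
    tok <- toupper(x[todo])
    bad <- nchar(tok) != 2L | !grepl("^[ACGT][ACGT]$", tok)
    if (any(bad)) {
      stop("malformed SNP code token(s): ",
           paste(sQuote(unique(x[todo][bad])), collapse = ", "))
    }
    a1 <- substr(tok, 1L, 1L)
    a2 <- substr(tok, 2L, 2L)
    out[todo] <- ifelse(a1 <= a2, paste0(a1, a2), paste0(a2, a1))
  }
  out
}

#' Format SNP codes for output
#'
#' Emits the canonical two-letter form; missing calls are written as `"-"`.
#'
#' @param x character vector of normalized codes (or raw tokens; they are
#'   re-normalized first).
#' @return character vector.
#' @export
format_snp_code <- function(x) {
  x <- parse_snp_code(x)
  ifelse(is.na(x), "-", x)
}

#' Zygosity of a SNP code
#'
#' @param x character vector of codes.
#' @return logical vector; `TRUE` for homozygous calls, `NA` for missing.
#' @export
is_homozygous <- function(x) {
  x <- parse_snp_code(x)
  substr(x, 1L, 1L) == substr(x, 2L, 2L)
}

#' Alleles of SNP codes
#'
#' @param x character vector of codes.
#' @return list of character vectors (length 2 each; `NULL` entries for
#'   missing calls).
#' @export
snp_code_alleles <- function(x) {
  x <- parse_snp_code(x)
  lapply(x, function(cc) {
    if (is.na(cc)) NULL else c(substr(cc, 1L, 1L), substr(cc, 2L, 2L))
  })
}

# canonical code from two allele letters (vectorized)
code_from_alleles <- function(a1, a2) {
  ifelse(a1 <= a2, paste0(a1, a2), paste0(a2, a1))
}
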