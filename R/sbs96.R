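#' The 96 single-base-substitution classes
#'
#' Substitution classes in the pyrimidine-strand convention, ordered first by
#' substitution type (C>A, C>G, C>T, T>A, T>C, T>G) and then alphabetically by
#' the 5' and 3' flanking bases, e.g. `A[C>A]A`, `A[C>A]C`, ... This is the
#' row ordering used by the standard reference signature tables, so reference
#' matrices load without permutation.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs96_classes())
sbs96_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs)
    for (p5 in bases)
      for (p3 in bases)
        out <- c(out, paste0(p5, "[", s, "]", p3))
  out
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Cosine similarity between two non-negative spectra
#'
#' Scale-invariant similarity `a.b / (|a||b|)`; lies in \[0, 1\] for
#' non-negative inputs such as mutation catalogues and signatures.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A single number.
#' @export
#' @examples
#' cosine_similarity(c(1, 2, 2), c(2, 1, 2))
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stopf("vectors differ in length (%d vs %d)", length(a), length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stopf("cosine similarity is undefined for a zero vector")
  sum(a * b) / (na * nb)
}
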