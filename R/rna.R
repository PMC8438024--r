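#' Normalise a nucleotide sequence to the internal RNA alphabet
#'
#' Sequences are handled internally as RNA (U, never T), upper case.
#' `T` is unified to `U` so DNA- and RNA-spelled inputs scan identically.
#'
#' @param x character vector of sequences over `{A,C,G,U,T,N}`, any case.
#' @param what label used in error messages (e.g. a record id).
#' @return character vector of upper-case RNA sequences.
#' @export
normalize_rna <- function(x, what = "sequence") {
  x <- chartr("acgutn", "ACGUTN", x)
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    stop("illegal character in ", what, ": ",
         paste(utils::head(which(bad), 3L), collapse = ", "),
         " (allowed: A, C, G, U/T, N)")
  }
  x
}

#' Reverse complement of an RNA sequence
#'
#' @param x character vector of RNA sequences (A/C/G/U/N).
#' @return reverse complements, 5'->3'.
#' @export
rc_rna <- function(x) {
  stringi::stri_reverse(chartr("ACGUN", "UGCAN", x))
}
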