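#' @importFrom Biostrings GENETIC_CODE readBStringSet writeXStringSet BStringSet
NULL

# Standard genetic code (table 1), codon -> one-letter amino acid, "*" = stop.
.code <- function() Biostrings::GENETIC_CODE

.STOPS <- c("TAA", "TAG", "TGA")

# 61 sense codons of the standard code, fixed order.
sense_codons <- function() {
  cods <- names(Biostrings::GENETIC_CODE)
  cods[!cods %in% .STOPS]
}

#' Translate a vector of codons under the standard genetic code
#'
#' Codons containing characters outside A/C/G/T (gaps, N) translate to
#' `NA`; stop codons translate to `"*"`.
#'
#' @param codons character vector of 3-letter codons.
#' @return character vector of one-letter amino acids.
#' @export
translate_codons <- function(codons) {
  aa <- unname(.code()[toupper(codons)])
  aa
}

# TRUE for codons made only of A/C/G/T
.is_clean_codon <- function(codons) {
  !is.na(.code()[toupper(codons)])
}

#' Reverse complement of a nucleotide string
#'
#' @param seq nucleotide string over A/C/G/T/N (case-insensitive).
#' @return reverse-complemented upper-case string.
#' @export
reverse_complement <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")
  chars <- strsplit(toupper(seq), "")[[1]]
  out <- map[chars]
  if (anyNA(out)) stop("reverse_complement: unexpected character in sequence")
  paste(rev(out), collapse = "")
}

#' Split a nucleotide string into in-frame codons
#'
#' Frame is anchored at the first position; the length must be divisible
#' by 3.
#'
#' @param seq nucleotide string.
#' @return character vector of 3-letter codons.
#' @export
split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# transition (A<->G, C<->T) test for two single nucleotides
.is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}
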