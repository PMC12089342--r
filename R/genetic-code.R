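#' The 61 sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons (uppercase DNA triplets),
#'   in alphabetical order.
#' @export
#' @examples
#' length(sense_codons())
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc != "*"])
}

#' Stop codons of the standard genetic code
#' @return Character vector `c("TAA", "TAG", "TGA")`.
#' @export
stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc == "*"])
}

#' Translate codons to one-letter amino acids
#'
#' Standard nuclear genetic code; stop codons map to `"*"`, triplets with
#' non-ACGT characters to `NA`.
#'
#' @param codons Character vector of uppercase DNA triplets.
#' @return Character vector of one-letter amino-acid codes.
#' @export
#' @examples
#' codon_to_aa(c("GCA", "TGG", "TAA"))
codon_to_aa <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Amino acids decoded by the sense codons
#' @return Character vector of the 20 one-letter amino-acid codes.
#' @export
amino_acids <- function() {
  sort(unique(codon_to_aa(sense_codons())))
}

## split a nucleotide string into consecutive triplets (frame 0)
codon_split <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}
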