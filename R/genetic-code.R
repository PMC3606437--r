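#' Vertebrate mitochondrial genetic code
#'
#' Codon-to-amino-acid table for the vertebrate mitochondrial code
#' (NCBI translation table 2), in which ATA codes for Met, TGA for Trp, and
#' AGA/AGG are stop codons. Stops are reported as `"*"`.
#'
#' @return Named character vector of length 64 mapping codons to one-letter
#'   amino-acid codes.
#' @export
#' @examples
#' mito_genetic_code()[c("ATA", "TGA", "AGA", "AGG")]
mito_genetic_code <- function() {
  if (is.null(.purisel_env$code)) {
    code <- Biostrings::getGeneticCode("2")
    .purisel_env$code <- setNames(as.character(code), names(code))
  }
  .purisel_env$code
}

.purisel_env <- new.env(parent = emptyenv())

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of A/C/G/T strings.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

translate_codon <- function(codon, code = mito_genetic_code()) {
  aa <- code[codon]
  if (anyNA(aa)) stop("cannot translate codon(s): ",
                      paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

#' Classify a base change as transition or transversion
#'
#' @param ref,alt single bases in A/C/G/T (vectorised).
#' @return character vector, `"transition"` or `"transversion"`.
#' @export
mutation_type <- function(ref, alt) {
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ifelse(purine[ref] == purine[alt], "transition", "transversion")
}
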