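# Fixed codon class sets: the 24 ADAT-sensitive codons (U/C/A-ended codons
# of the eight I34-decoded boxes) and the 37 sense codons encoding TAPSLIVR.

# standard genetic code, DNA alphabet, from Biostrings
.genetic_code <- function() Biostrings::GENETIC_CODE

#' The eight TAPSLIVR amino acids
#'
#' Thr, Ala, Pro, Ser, Leu, Ile, Val, Arg: the amino acids whose codon
#' boxes are read by I34-tRNAs in eukaryotes.
#'
#' @return Character vector of eight one-letter amino-acid codes.
#' @export
#' @examples
#' tapslivr_aa()
tapslivr_aa <- function() c("T", "A", "P", "S", "L", "I", "V", "R")

#' The 24 ADAT-sensitive codons
#'
#' The U-, C- and A-ended codons of the eight codon boxes decoded by
#' I34-tRNAs (anticodons IGU, IGC, IGG, IGA, IAG, IAU, IAC, ICG for
#' Thr, Ala, Pro, Ser, Leu, Ile, Val and Arg respectively).  DNA
#' alphabet.
#'
#' @return Character vector of 24 codons.
#' @export
#' @examples
#' adat_codons()
adat_codons <- function() {
  boxes <- c("AC", "GC", "CC", "TC", "CT", "AT", "GT", "CG")
  paste0(rep(boxes, each = 3L), c("T", "C", "A"))
}

#' The 37 sense codons encoding TAPSLIVR amino acids
#'
#' @return Character vector of 37 codons (DNA alphabet).
#' @export
tapslivr_codons <- function() {
  gc <- .genetic_code()
  sort(names(gc)[gc %in% tapslivr_aa()])
}

#' Normalise codon or nucleotide strings to the DNA alphabet
#'
#' Uppercases and maps U to T, so codons quoted in RNA notation are
#' accepted everywhere.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector in uppercase DNA alphabet.
#' @export
normalize_nt <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' Classify codons by their relationship to I34-tRNA decoding
#'
#' Each sense codon is ADAT-sensitive (decoded by an I34-tRNA),
#' TAPSLIVR-encoding but not I34-decoded, or unrelated to the TAPSLIVR
#' amino acids; stop codons form a fourth class.
#'
#' @param codon Character vector of 3-mers over A/C/G/T (U accepted).
#' @return Character vector with values `"ADAT"`, `"TAPSLIVR_NON_ADAT"`,
#'   `"OTHER"` or `"STOP"`.
#' @export
#' @examples
#' codon_class(c("ACC", "AGC", "ATG", "TAA"))
codon_class <- function(codon) {
  codon <- normalize_nt(codon)
  bad <- nchar(codon) != 3L | grepl("[^ACGT]", codon)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "))
  }
  gc <- .genetic_code()
  aa <- unname(gc[codon])
  out <- rep("OTHER", length(codon))
  out[aa == "*"] <- "STOP"
  out[aa %in% tapslivr_aa()] <- "TAPSLIVR_NON_ADAT"
  out[codon %in% adat_codons()] <- "ADAT"
  out
}

# split a CDS string into codons; assumes length divisible by 3
codon_split <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
}
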