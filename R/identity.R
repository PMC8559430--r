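# Pairwise nucleotide identity over globally aligned V-REGIONs. The
# denominator is the number of alignment columns, so gaps count as
# mismatches and length differences are penalized.

#' Percent nucleotide identity between two sequences
#'
#' Global (end-gap penalized) alignment; identity = matching columns /
#' total alignment columns x 100.
#'
#' @param a,b nucleotide strings (or `DNAString`s).
#' @return numeric percent identity in `[0, 100]`.
#' @examples
#' pairwiseIdentity("ACGT", "ACGT")  # 100
#' pairwiseIdentity("ACGT", "ACG")   # 75: 3 matches over 4 columns
#' @export
pairwiseIdentity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(nzchar(a), nzchar(b))
  aln <- .globalDNA(a, b)
  100 * Biostrings::nmatch(aln) / .alignmentColumns(aln)
}

## alignment length including end gaps (pattern()/nchar() clip terminal
## indels; the aligned views do not)
.alignmentColumns <- function(aln) {
  nchar(as.character(Biostrings::alignedPattern(aln)))
}

.globalDNA <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    pattern, subject, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 2, gapExtension = 1)
}

#' Symmetric percent-identity matrix over a set of sequences
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @return numeric matrix with 100 on the diagonal.
#' @export
identityMatrix <- function(seqs) {
  seqs <- asNamedCharacter(seqs)
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(m)
  for (j in seq(2L, n)) {
    ## one vectorized call per subject: all earlier sequences as patterns
    aln <- .globalDNA(Biostrings::DNAStringSet(seqs[seq_len(j - 1L)]),
                      Biostrings::DNAString(seqs[[j]]))
    v <- 100 * Biostrings::nmatch(aln) / .alignmentColumns(aln)
    m[seq_len(j - 1L), j] <- v
    m[j, seq_len(j - 1L)] <- v
  }
  m
}
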