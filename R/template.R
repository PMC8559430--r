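# V-domain numbering template. The packaged template is a synthetic
# IMGT-gapped reference: 104 numbered framework/CDR positions (1st-CYS at 23,
# conserved Trp at 41, hydrophobic 89, 2nd-CYS at 104) followed by three
# germline CDR3 anchor residues. Region windows follow the IMGT unique
# numbering delimitations: FR1 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65,
# FR3 66-104, germline CDR3 from 105.

IMGT_REGIONS <- data.frame(
  region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3"),
  from   = c(1L, 27L, 39L, 56L, 66L, 105L),
  to     = c(26L, 38L, 55L, 65L, 104L, 130L))

imgtRegionOf <- function(pos) {
  r <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(IMGT_REGIONS)))
    r[pos >= IMGT_REGIONS$from[i] & pos <= IMGT_REGIONS$to[i]] <-
      IMGT_REGIONS$region[i]
  r
}

#' Load a gapped V-domain numbering template
#'
#' Reads an IMGT-gapped amino-acid template (dots mark unoccupied numbered
#' positions) and returns the ungapped sequence together with the numbered
#' position and region of every residue. The packaged synthetic template is
#' used by default.
#'
#' @param file path to a gapped single-record FASTA; default: the packaged
#'   template.
#' @return a list with `gapped` (character), `aa` (ungapped character),
#'   `pos` (integer vector, numbered position of each ungapped residue) and
#'   `region` (character vector of region labels).
#' @examples
#' tpl <- loadVTemplate()
#' substr(tpl$aa, 1, 10)
#' @export
loadVTemplate <- function(file = system.file("extdata",
                                             "v_domain_template.fasta",
                                             package = "tralocus")) {
  aa <- as.character(Biostrings::readAAStringSet(file)[[1L]])
  chars <- strsplit(aa, "")[[1L]]
  keep <- chars != "."
  list(gapped = aa,
       aa = paste0(chars[keep], collapse = ""),
       pos = which(keep),
       region = imgtRegionOf(which(keep)))
}

## Deterministic back-translation table used to seed synthetic coding
## sequences (one codon per residue; Cys -> TGC, Trp -> TGG).
BACKTRANSLATE <- c(
  A = "GCT", C = "TGC", D = "GAT", E = "GAA", F = "TTT", G = "GGA",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
  P = "CCA", Q = "CAA", R = "CGT", S = "TCT", T = "ACA", V = "GTG",
  W = "TGG", Y = "TAT")

backTranslate <- function(aa) {
  paste0(BACKTRANSLATE[strsplit(aa, "")[[1L]]], collapse = "")
}
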