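# IMGT-style functionality classification.
#
# Deterministic mapping from the observed defect list:
#   stop codon or frameshift            -> P  (pseudogene)
#   splice/RS defect, missing FGXG (J)  -> ORF
#   otherwise                           -> F
# Substitutions of the conserved V residues (23/41/104) are recorded but by
# default do not alone demote F to ORF: functional genes with a replaced
# 1st-CYS exist (TRAV1-type Tyr23), so the "incorrect folding" judgement is
# not mechanically derivable. `strictConserved = TRUE` enables demotion.
# Under the TRDJ policy a missing FGXG motif (the salmonid FGKA variant
# replaces the hallmark motif) does not demote TRDJ functionality.

P_DEFECTS <- c("stop_codon", "frameshift")
ORF_DEFECTS <- c("rs_defect", "splice_defect", "missing_FGXG")

#' Classify gene functionality from its defect list
#'
#' @param defects character vector of defect codes (possibly empty): any of
#'   `stop_codon`, `frameshift`, `rs_defect`, `splice_defect`,
#'   `missing_FGXG`, `missing_conserved_residue`.
#' @param geneType one of `"V"`, `"D"`, `"J"`, `"C"`.
#' @param chain `"TRA"` or `"TRD"`; TRDJ genes are exempt from the FGXG
#'   requirement.
#' @param strictConserved when TRUE, a conserved-residue substitution alone
#'   demotes F to ORF.
#' @return one of `"F"`, `"ORF"`, `"P"`.
#' @examples
#' classifyFunctionality(character(), "V", "TRA")          # "F"
#' classifyFunctionality("rs_defect", "V", "TRA")          # "ORF"
#' classifyFunctionality(c("frameshift"), "V", "TRA")      # "P"
#' classifyFunctionality("missing_FGXG", "J", "TRD")       # "F" (FGKA)
#' @export
classifyFunctionality <- function(defects, geneType = "V", chain = "TRA",
                                  strictConserved = FALSE) {
  defects <- defects[nzchar(defects)]
  if (any(defects %in% P_DEFECTS)) return("P")
  orf <- ORF_DEFECTS
  if (geneType == "J" && chain == "TRD")
    orf <- setdiff(orf, "missing_FGXG")
  if (strictConserved) orf <- c(orf, "missing_conserved_residue")
  if (any(defects %in% orf)) return("ORF")
  "F"
}

splitDefects <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";")[[1L]]
}
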