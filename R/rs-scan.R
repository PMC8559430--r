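# Recombination-signal (RS) motif scanning.
#
# The canonical RS is heptamer CACAGTG + spacer + nonamer ACAAAAACC; V and
# 3'D RS carry ~23 bp spacers, J and 5'D RS ~12 bp spacers. In gene
# orientation the heptamer always abuts the coding segment: V/D3 RS read
# hept->nonamer downstream of the segment, J/D5 RS read nonamer->hept
# upstream of it. Scanning for the hept+spacer+nonamer pattern on both
# genome strands therefore covers all four kinds; the gene strand equals
# the pattern strand for V/D3 and the opposite strand for J/D5.

RS_SPACER_RANGES <- list(V = 22:23, J = 11:13, D5 = 11:13, D3 = 22:23)

#' Scan a sequence for recombination-signal motifs
#'
#' Finds heptamer/spacer/nonamer matches of the requested RS kind on both
#' strands. Default tolerances: at most `maxHeptMismatch` heptamer
#' mismatches with the first three bases (CAC) exact, at most
#' `maxNonaMismatch` nonamer mismatches. Hits are sorted by composite score
#' (fewest total mismatches, then spacer-length deviation from the canonical
#' 23/12 architecture, then position).
#'
#' @param genome a [Biostrings::DNAString], `DNAStringSet` (first sequence
#'   used) or character string.
#' @param kind one of `"V"`, `"J"`, `"D5"`, `"D3"`.
#' @param window optional `c(start, end)` (1-based, inclusive) restricting
#'   the scan.
#' @param maxHeptMismatch,maxNonaMismatch mismatch tolerances.
#' @param heptCACExact require the CAC core of the heptamer to be exact.
#' @param spacerRange integer vector of allowed spacer lengths; defaults to
#'   the kind's canonical range (V/D3: 22-23, J/D5: 11-13).
#' @return a data.frame with one row per hit: `start`/`end` (full RS span,
#'   1-based genomic), `strand` (gene strand), `heptamerStart`,
#'   `nonamerStart`, `spacer`, `heptMismatch`, `nonaMismatch`, `score`.
#' @examples
#' seq <- paste0(strrep("T", 50), "CACAGTG", strrep("A", 22), "ACAAAAACC",
#'               strrep("T", 50))
#' scanRS(seq, "V")
#' @export
scanRS <- function(genome, kind = c("V", "J", "D5", "D3"), window = NULL,
                   maxHeptMismatch = 1L, maxNonaMismatch = 3L,
                   heptCACExact = TRUE, spacerRange = NULL) {
  kind <- match.arg(kind)
  seqchar <- toupper(asSingleSequence(genome))
  n <- nchar(seqchar)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1L] >= 1L, window[2L] <= n)
  } else window <- c(1L, n)
  spacers <- spacerRange %||% RS_SPACER_RANGES[[kind]]
  canon <- if (kind %in% c("V", "D3")) 23L else 12L

  sub <- substr(seqchar, window[1L], window[2L])
  withStrand <- function(df, s) {
    df$patStrand <- rep(s, nrow(df))
    df
  }
  hits <- rbind(
    withStrand(.scanPattern(sub, spacers, maxHeptMismatch, maxNonaMismatch,
                            heptCACExact), "+"),
    withStrand(.scanPattern(revComp(sub), spacers, maxHeptMismatch,
                            maxNonaMismatch, heptCACExact), "-"))
  if (!nrow(hits)) return(emptyRSHits())

  m <- nchar(sub)
  ## convert minus-pattern coordinates back to the forward strand
  flip <- hits$patStrand == "-"
  len <- 16L + hits$spacer
  startF <- ifelse(flip, m - (hits$start + len - 1L) + 1L, hits$start)
  hits$start <- startF + window[1L] - 1L
  hits$end <- hits$start + len - 1L
  hits$heptamerStart <- ifelse(flip, hits$end - 6L, hits$start)
  hits$nonamerStart <- ifelse(flip, hits$start, hits$end - 8L)
  geneFlip <- kind %in% c("J", "D5")
  hits$strand <- ifelse(xor(flip, geneFlip), "-", "+")
  hits$score <- hits$heptMismatch + hits$nonaMismatch +
    0.25 * abs(hits$spacer - canon)
  hits <- hits[order(hits$score, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("start", "end", "strand", "heptamerStart", "nonamerStart",
           "spacer", "heptMismatch", "nonaMismatch", "score")]
}

emptyRSHits <- function() {
  data.frame(start = integer(), end = integer(), strand = character(),
             heptamerStart = integer(), nonamerStart = integer(),
             spacer = integer(), heptMismatch = integer(),
             nonaMismatch = integer(), score = numeric())
}

## Scan the pattern orientation (hept + spacer + nonamer, left to right) of
## a single strand given as a character string.
.scanPattern <- function(seqchar, spacers, maxHept, maxNona, cacExact) {
  subject <- Biostrings::DNAString(seqchar)
  heptHits <- Biostrings::start(Biostrings::matchPattern(
    RS_HEPTAMER, subject, max.mismatch = maxHept))
  ## mismatch-tolerant matching can report motifs hanging off the ends
  heptHits <- heptHits[heptHits >= 1L & heptHits + 6L <= nchar(seqchar)]
  if (cacExact && length(heptHits)) {
    keep <- substr(rep(seqchar, length(heptHits)), heptHits,
                   heptHits + 2L) == "CAC"
    heptHits <- heptHits[keep]
  }
  out <- list()
  n <- nchar(seqchar)
  for (h in heptHits) {
    hseq <- substr(seqchar, h, h + 6L)
    hmm <- strMismatch(hseq, RS_HEPTAMER)
    for (s in spacers) {
      ns <- h + 7L + s
      if (ns + 8L > n) next
      nseq <- substr(seqchar, ns, ns + 8L)
      if (grepl("[^ACGT]", nseq)) next
      nmm <- strMismatch(nseq, RS_NONAMER)
      if (nmm <= maxNona)
        out[[length(out) + 1L]] <- data.frame(
          start = h, spacer = s, heptMismatch = hmm, nonaMismatch = nmm)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), spacer = integer(),
                      heptMismatch = integer(), nonaMismatch = integer()))
  do.call(rbind, out)
}

asSingleSequence <- function(genome) {
  if (is.character(genome)) return(genome[[1L]])
  if (methods::is(genome, "DNAStringSet"))
    return(as.character(genome[[1L]]))
  as.character(genome)
}
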