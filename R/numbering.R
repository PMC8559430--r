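# IMGT-style unique numbering of V domains by alignment to a gapped template.

## Local alignment of a (possibly partial or garbled) V-domain translation to
## the ungapped template; stops are treated as X. Returns the per-residue
## query -> template residue map plus summary statistics.
alignToTemplate <- function(aa, tpl, type = "local") {
  aa <- gsub("*", "X", aa, fixed = TRUE)
  if (nchar(aa) < 10L)
    return(list(score = -Inf, ncols = 0L, identity = 0, coverage = 0,
                map = integer(0), qstart = 0L, qend = 0L))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa), Biostrings::AAString(tpl$aa),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
    type = type)
  pat <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1L]]
  sub <- strsplit(as.character(Biostrings::subject(aln)), "")[[1L]]
  qpos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  tpos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  map <- rep(NA_integer_, nchar(aa))  # query residue -> template residue
  matches <- 0L; ncols <- length(pat)
  for (k in seq_along(pat)) {
    qgap <- pat[k] == "-"; tgap <- sub[k] == "-"
    if (!qgap) qpos <- qpos + 1L
    if (!tgap) tpos <- tpos + 1L
    if (!qgap && !tgap) {
      map[qpos] <- tpos
      if (pat[k] == sub[k]) matches <- matches + 1L
    } else if (!qgap && tgap) {
      map[qpos] <- -tpos  # insertion after template residue tpos
    }
  }
  aligned <- map[!is.na(map) & map > 0L]
  list(score = Biostrings::score(aln), ncols = ncols,
       identity = if (ncols) matches / ncols else 0,
       coverage = length(unique(aligned)) /
         sum(tpl$pos <= 104L),
       map = map,
       qstart = Biostrings::start(Biostrings::pattern(aln)),
       qend = Biostrings::end(Biostrings::pattern(aln)),
       tstart = Biostrings::start(Biostrings::subject(aln)),
       tend = Biostrings::end(Biostrings::subject(aln)))
}

## Minimal evidence that a translated candidate really is a V domain; used to
## validate de novo V candidates (tolerates truncation by frameshift).
templateEvidence <- function(aa, tpl, minCols = 35L, minScore = 60) {
  a <- alignToTemplate(aa, tpl)
  a$ok <- a$ncols >= minCols && is.finite(a$score) && a$score >= minScore
  a
}

#' Number a V-domain amino-acid sequence against a gapped template
#'
#' Aligns a V-REGION translation to an IMGT-gapped reference template and
#' assigns standardized positions: the conserved 1st-CYS is expected at
#' position 23, the conserved tryptophan at 41, the hydrophobic position at
#' 89 and the 2nd-CYS at 104. CDR lengths are counted inside the standard
#' windows (CDR1 27-38, CDR2 56-65; a CDR2 of length 0 is legitimate), the
#' germline CDR3 length counts residues beyond position 104.
#'
#' @param vAA amino-acid string (stops tolerated, treated as X).
#' @param template a template as returned by [loadVTemplate()].
#' @return an object of class `NumberedVDomain`: a list with `residues`
#'   (named character at positions 23/41/89/104), `cdrLengths` (integer
#'   `c(cdr1, cdr2, cdr3)`), `frLengths`, `positions` (per-residue table),
#'   `coverage`, `identity`, `score` and logical `success`.
#' @examples
#' tpl <- loadVTemplate()
#' num <- imgtNumberV(tpl$aa, tpl)
#' num$residues        # C at 23, W at 41, C at 104
#' num$cdrLengths      # template CDR lengths
#' @export
imgtNumberV <- function(vAA, template = loadVTemplate()) {
  a <- alignToTemplate(vAA, template)
  n <- nchar(vAA)
  qres <- strsplit(gsub("*", "X", vAA, fixed = TRUE), "")[[1L]]
  imgt <- rep(NA_integer_, n)
  region <- rep(NA_character_, n)
  ok <- !is.na(a$map) & a$map > 0L
  imgt[ok] <- template$pos[a$map[ok]]
  region[ok] <- template$region[a$map[ok]]
  ins <- !is.na(a$map) & a$map < 0L
  if (any(ins)) {
    prev <- -a$map[ins]
    nxt <- pmin(prev + 1L, length(template$pos))
    rprev <- template$region[prev]; rnext <- template$region[nxt]
    region[ins] <- ifelse(grepl("^CDR", rnext), rnext, rprev)
    imgt[ins] <- NA_integer_
  }
  ## the germline CDR3 is by definition everything 3' of the 2nd-CYS: all
  ## residues after the one assigned position 104, whether or not the
  ## local alignment extended through them
  i104 <- which(imgt == 104L)
  if (length(i104) && i104[1L] < n)
    region[(i104[1L] + 1L):n] <- "CDR3"
  resAt <- function(p) {
    i <- which(imgt == p)
    if (length(i)) qres[i[1L]] else NA_character_
  }
  residues <- c(`23` = resAt(23L), `41` = resAt(41L),
                `89` = resAt(89L), `104` = resAt(104L))
  cdr <- c(cdr1 = sum(region == "CDR1", na.rm = TRUE),
           cdr2 = sum(region == "CDR2", na.rm = TRUE),
           cdr3 = sum(region == "CDR3", na.rm = TRUE))
  fr <- c(fr1 = sum(region == "FR1", na.rm = TRUE),
          fr2 = sum(region == "FR2", na.rm = TRUE),
          fr3 = sum(region == "FR3", na.rm = TRUE))
  out <- list(residues = residues, cdrLengths = cdr, frLengths = fr,
              positions = data.frame(index = seq_len(n), residue = qres,
                                     imgt = imgt, region = region),
              coverage = a$coverage, identity = a$identity, score = a$score,
              success = a$coverage >= 0.8 && !is.na(residues[["104"]]) &&
                !is.na(residues[["23"]]))
  class(out) <- "NumberedVDomain"
  out
}

#' @export
print.NumberedVDomain <- function(x, ...) {
  cat("NumberedVDomain: residues 23/41/89/104 =",
      paste(x$residues, collapse = "/"),
      sprintf("; CDR lengths [%d.%d.%d]; coverage %.2f\n",
              x$cdrLengths[1L], x$cdrLengths[2L], x$cdrLengths[3L],
              x$coverage))
  invisible(x)
}

#' Format the CDR length triplet used in subgroup census tables
#' @param num a `NumberedVDomain`.
#' @return a string like `"[7.6.3]"`.
#' @export
cdrTriplet <- function(num) {
  sprintf("[%d.%d.%d]", num$cdrLengths[1L], num$cdrLengths[2L],
          num$cdrLengths[3L])
}
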