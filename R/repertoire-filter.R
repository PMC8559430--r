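# Per-read filtering, best-hit deduplication and productivity calling.

#' Filter segment hits and assign one V/J/C per read
#'
#' Applies the per-read validity criteria: a C-region hit longer than 30
#' bp, a J hit with identity strictly greater than 99.9%, and a V hit with
#' identity strictly greater than 99.9% and aligned length of at least 50
#' bp. Among multiple hits of a class the lowest expectancy wins (ties:
#' higher identity, then lexicographic gene name). Reads failing any
#' criterion are dropped with a single first-failure reason code
#' (`no_C`/`C_too_short`, `no_J`/`J_identity`, `no_V`/`V_identity`/
#' `V_too_short`).
#'
#' @param hits `data.table` from [assignSegments()].
#' @param minCLength minimum C aligned length, exclusive bound (default 30).
#' @param minSegIdentity identity bound for V and J, exclusive (default
#'   99.9).
#' @param minVLength minimum V aligned length, inclusive (default 50).
#' @return list with `assignments` (data.frame: readId, sample, v, j,
#'   cGene plus per-class hit coordinates) and `dropped` (data.frame:
#'   readId, reason).
#' @export
filterAndDedupe <- function(hits, minCLength = 30L, minSegIdentity = 99.9,
                            minVLength = 50L) {
  hits <- data.table::as.data.table(hits)
  readIds <- unique(hits$readId)
  pickBest <- function(h) {
    h[order(evalue, -identity, gene)][1L]
  }
  rows <- list(); drops <- list()
  for (id in readIds) {
    h <- hits[readId == id]
    reason <- NULL
    cH <- h[class == "C"]
    if (!nrow(cH)) reason <- "no_C"
    else {
      cH <- cH[length > minCLength]
      if (!nrow(cH)) reason <- "C_too_short"
    }
    if (is.null(reason)) {
      jH <- h[class == "J"]
      if (!nrow(jH)) reason <- "no_J"
      else {
        jH <- jH[identity > minSegIdentity]
        if (!nrow(jH)) reason <- "J_identity"
      }
    }
    if (is.null(reason)) {
      vH <- h[class == "V"]
      if (!nrow(vH)) reason <- "no_V"
      else {
        vH2 <- vH[identity > minSegIdentity]
        if (!nrow(vH2)) reason <- "V_identity"
        else {
          vH <- vH2[length >= minVLength]
          if (!nrow(vH)) reason <- "V_too_short"
        }
      }
    }
    if (!is.null(reason)) {
      drops[[length(drops) + 1L]] <- data.frame(readId = id,
                                                reason = reason)
      next
    }
    cB <- pickBest(cH); jB <- pickBest(jH); vB <- pickBest(vH)
    rows[[length(rows) + 1L]] <- data.frame(
      readId = id, sample = sub("[|_].*$", "", id),
      v = vB$gene, j = jB$gene, cGene = cB$gene,
      vIdentity = vB$identity, jIdentity = jB$identity,
      vLength = vB$length, cLength = cB$length,
      vReadStart = vB$readStart, vReadEnd = vB$readEnd,
      vGeneStart = vB$geneStart, vGeneEnd = vB$geneEnd,
      vStrand = vB$strand,
      jReadStart = jB$readStart, jReadEnd = jB$readEnd,
      jGeneStart = jB$geneStart, jGeneEnd = jB$geneEnd,
      jStrand = jB$strand,
      cReadStart = cB$readStart, cReadEnd = cB$readEnd,
      cStrand = cB$strand,
      stringsAsFactors = FALSE)
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(readId = character(), sample = character(), v = character(),
               j = character(), cGene = character())
  dropped <- if (length(drops)) do.call(rbind, drops) else
    data.frame(readId = character(), reason = character())
  list(assignments = assignments, dropped = dropped)
}

## Per-gene frame anchors for productivity calling: nucleotide position of
## the 2nd-CYS codon in each V segment and the motif reading frame of each
## J segment.
germlineFrameAnchors <- function(germline, template = loadVTemplate()) {
  segs <- .germlineSegments(germline)
  vAnchor <- list(); jFrame <- list()
  for (k in seq_along(segs$name)) {
    nm <- segs$name[k]; s <- segs$seq[k]
    if (segs$class[k] == "V") {
      aa <- translateFrame(s, 0L)
      num <- imgtNumberV(aa, template)
      idx <- num$positions$index[!is.na(num$positions$imgt) &
                                   num$positions$imgt == 104L]
      vAnchor[[nm]] <- if (length(idx)) 3L * (idx[1L] - 1L) + 1L else
        NA_integer_
    } else if (segs$class[k] == "J") {
      fr <- NA_integer_
      for (f in 0:2) {
        aa <- gsub("*", "X", translateFrame(s, f), fixed = TRUE)
        if (grepl("FG.G", aa) || grepl("FG", aa)) { fr <- f; break }
      }
      jFrame[[nm]] <- if (is.na(fr)) 0L else fr
    }
  }
  list(vCys = unlist(vAnchor), jFrame = unlist(jFrame))
}

#' Call productivity of assigned reads
#'
#' A read is productive iff the V, J and C segments lie in one consistent
#' reading frame on the merged read (each segment in its own germline
#' coding frame) and the translation from the V 2nd-CYS codon through the
#' junction and J motif into the C region is free of stop codons; anything
#' else (frameshifted junctions, junction stops, inconsistent hit strands)
#' is unproductive.
#'
#' @param assignments data.frame from [filterAndDedupe()].
#' @param reads named character vector of merged read sequences (or the
#'   `merged` data.frame of [mergePairs()]).
#' @param germline germline set/annotation/named sequences (see
#'   [assignSegments()]).
#' @param template numbering template for locating the V 2nd-CYS.
#' @return `assignments` with added logical column `productive` and
#'   character column `junction` (nucleotides between V and J matches on
#'   the read).
#' @export
classifyProductivity <- function(assignments, reads, germline,
                                 template = loadVTemplate()) {
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$id)
  anchors <- germlineFrameAnchors(germline, template)
  n <- nrow(assignments)
  productive <- logical(n); junction <- character(n)
  for (i in seq_len(n)) {
    a <- assignments[i, ]
    seq <- reads[[a$readId]]
    res <- .callProductivity(a, seq, anchors)
    productive[i] <- res$productive
    junction[i] <- res$junction
  }
  assignments$productive <- productive
  assignments$junction <- junction
  assignments
}

.callProductivity <- function(a, seq, anchors) {
  len <- nchar(seq)
  strands <- c(a$vStrand, a$jStrand, a$cStrand)
  if (length(unique(strands)) != 1L) {
    warning("inconsistent hit strands for read ", a$readId)
    return(list(productive = FALSE, junction = ""))
  }
  flip <- strands[1L] == "-"
  tr <- function(x) if (flip) len - x + 1L else x
  if (flip) seq <- revComp(seq)
  vRS <- tr(a$vReadStart); vRE <- tr(a$vReadEnd)
  jRS <- tr(a$jReadStart); jRE <- tr(a$jReadEnd)
  cRS <- tr(a$cReadStart)
  if (flip) {
    tmp <- vRS; vRS <- vRE; vRE <- tmp
    tmp <- jRS; jRS <- jRE; jRE <- tmp
    cRS <- tr(a$cReadEnd)
  }
  junction <- if (jRS > vRE + 1L) substr(seq, vRE + 1L, jRS - 1L) else ""
  ## frame offsets of each segment on the read
  fV <- (vRS - a$vGeneStart) %% 3L
  jf <- anchors$jFrame[[a$j]] %||% 0L
  fJ <- (jRS - (a$jGeneStart + jf)) %% 3L
  fC <- (cRS - 1L) %% 3L   # C coding starts at segment position 1, frame 0
  if (is.na(fV) || fV != fJ || fJ != fC)
    return(list(productive = FALSE, junction = junction))
  cys <- anchors$vCys[[a$v]]
  if (is.null(cys) || is.na(cys))
    return(list(productive = FALSE, junction = junction))
  cysRead <- vRS + (cys - a$vGeneStart)
  if (cysRead < 1L || cysRead > len)
    return(list(productive = FALSE, junction = junction))
  stretch <- substr(seq, cysRead, min(len, cRS + 29L))
  list(productive = !hasInFrameStop(stretch), junction = junction)
}
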