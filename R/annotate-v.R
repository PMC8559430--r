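# De novo V gene annotation. Each V-RS hit anchors a search, in gene
# orientation, upstream of the heptamer: the V exon (L-PART2 + V-REGION)
# ends flush at the heptamer and starts at an acceptor AG; the leader intron
# starts with an extended-consensus donor (GTAAGT) and the L-PART1 begins at
# the innermost ATG that yields a stop-free spliced leader in frame.
# Candidates must show credible V-domain homology (template alignment) to be
# emitted; this is what rejects the RS scanner's false positives.

V_SEARCH_DEFAULTS <- list(
  minExon2 = 200L, maxExon2 = 380L,   # L-PART2 + V-REGION (nt)
  minL2 = 8L, maxL2 = 14L,
  minIntron = 60L, maxIntron = 400L,
  minL1 = 20L, maxL1 = 80L,
  context = 900L)

## Gene-oriented sequence context 5' of an RS heptamer plus a mapper from
## context-relative intervals back to genomic coordinates.
orientedContext <- function(seqchar, hit, len) {
  n <- nchar(seqchar)
  if (hit$strand == "+") {
    from <- max(1L, hit$heptamerStart - len)
    s <- substr(seqchar, from, hit$heptamerStart - 1L)
    L <- nchar(s)
    list(seq = s, len = L,
         toGenomic = function(a, b) c(from + a - 1L, from + b - 1L))
  } else {
    heptEnd <- hit$heptamerStart + 6L
    to <- min(n, heptEnd + len)
    s <- revComp(substr(seqchar, heptEnd + 1L, to))
    L <- nchar(s)
    list(seq = s, len = L,
         toGenomic = function(a, b) c(to - b + 1L, to - a + 1L))
  }
}

#' Annotate V genes from RS hits
#'
#' For each candidate V-RS (typically from a relaxed [scanRS()] pass so that
#' genes with degenerate RS motifs are still discovered), searches upstream
#' in RS orientation for an open V exon ending at the heptamer, an acceptor
#' AG preceding L-PART2, an extended-consensus donor after L-PART1 and an
#' ATG-initiated leader. Candidates without credible V-domain homology are
#' discarded; overlapping candidates are reduced to the best-scoring one.
#'
#' @param genome contig sequence.
#' @param rsHits data.frame from [scanRS()] (relaxed thresholds recommended);
#'   strictness of each hit is re-assessed internally against the standard
#'   tolerances and recorded as an `rs_defect` when violated.
#' @param template numbering template (see [loadVTemplate()]).
#' @param params list of search window parameters (see
#'   `V_SEARCH_DEFAULTS`).
#' @return a list with `genes` (data.frame of accepted candidates incl.
#'   genomic feature coordinates, defects and numbering summaries) and
#'   `log` (character, discarded candidates).
#' @export
annotateVGenes <- function(genome, rsHits, template = loadVTemplate(),
                           params = V_SEARCH_DEFAULTS) {
  seqchar <- toupper(asSingleSequence(genome))
  p <- utils::modifyList(V_SEARCH_DEFAULTS, params)
  log <- character()
  cands <- list()
  if (nrow(rsHits)) {
    rsHits <- rsHits[order(rsHits$score), , drop = FALSE]
    rsHits <- rsHits[!duplicated(paste(rsHits$heptamerStart,
                                       rsHits$strand)), , drop = FALSE]
  }
  for (i in seq_len(nrow(rsHits))) {
    hit <- rsHits[i, ]
    cand <- .evaluateVCandidate(seqchar, hit, template, p)
    if (is.character(cand)) {
      log <- c(log, sprintf("V-RS %d%s: %s", hit$heptamerStart,
                            hit$strand, cand))
    } else cands[[length(cands) + 1L]] <- cand
  }
  genes <- if (length(cands)) do.call(rbind, cands) else NULL
  genes <- .dedupeOverlapping(genes)
  list(genes = genes, log = log)
}

## strictness of an RS hit under the standard V tolerances
rsIsStrict <- function(hit, maxHept = 1L, maxNona = 3L) {
  hit$heptMismatch <= maxHept && hit$nonaMismatch <= maxNona && hit$cacExact
}

.evaluateVCandidate <- function(seqchar, hit, template, p) {
  ctx <- orientedContext(seqchar, hit, p$context)
  s <- ctx$seq
  L <- ctx$len
  if (L < p$minExon2 + p$minIntron + p$minL1) return("context too short")
  heptSeq <- if (hit$strand == "+")
    substr(seqchar, hit$heptamerStart, hit$heptamerStart + 6L)
  else revComp(substr(seqchar, hit$heptamerStart, hit$heptamerStart + 6L))
  hit$cacExact <- substr(heptSeq, 1L, 3L) == "CAC"

  ## The V-REGION ends flush at the heptamer, so its genomic frame is fixed
  ## up to mod 3: align the three translations of the tail window once and
  ## derive the position of template residue 1 (the V-REGION start) from
  ## the anchor; acceptors are then enumerated directly from the L-PART2
  ## length window. Template-anchored frames (alignment reaching template
  ## residue <= 2) take precedence so that frameshifted pseudogenes are
  ## delimited by their intact N-terminal segment.
  base <- max(1L, L - (p$maxExon2 + 40L))
  tail_ <- substr(s, base, L)
  pick <- NULL
  anchorInfo <- list()
  for (f in 0:2) {
    al <- alignToTemplate(translateFrame(tail_, f), template)
    if (!is.finite(al$score)) next
    ## The V start (template position 1) is extrapolated from the modal
    ## FR1 alignment diagonal: FR1 (positions 1-26) carries no indels, so
    ## its aligned columns are colinear even when a local-alignment gap
    ## slips the very first columns off the true diagonal. The fallback is
    ## the alignment start anchor.
    ok <- !is.na(al$map) & al$map > 0L
    fr1 <- ok & al$map <= 26L
    anchored <- FALSE
    fr1count <- 0L
    if (any(fr1)) {
      qi <- which(fr1)
      diag <- qi - al$map[fr1]
      tab <- sort(table(diag), decreasing = TRUE)
      dmode <- as.integer(names(tab)[1L])
      vStart <- base + f + 3L * dmode
      fr1count <- tab[[1L]]
      anchored <- fr1count >= 5L && fr1count >= 0.8 * length(qi)
      if (anchored)
        anchorInfo[[length(anchorInfo) + 1L]] <- c(vStart, fr1count)
    } else {
      vStart <- base + f + 3L * (al$qstart - 1L) - 3L * (al$tstart - 1L)
    }
    ## empirical floors: genuine V-domain translations score far above the
    ## best random local alignments (which stay below ~40); an FR1-anchored
    ## candidate (e.g. the intact prefix of a frameshifted pseudogene) is
    ## accepted at a lower floor because the anchor pins the boundary
    if (anchored) {
      if (al$ncols < 15L || al$score < 45) next
    } else {
      if (al$ncols < 25L || al$score < 60) next
    }
    cand <- list(f = f, al = al, vStart = vStart, anchored = anchored,
                 fr1count = fr1count)
    ## a stronger FR1 diagonal identifies the true reading frame even when
    ## a shifted frame aligns more of the domain (frameshifted genes)
    if (is.null(pick) ||
        (cand$anchored && !pick$anchored) ||
        (cand$anchored == pick$anchored &&
           (cand$fr1count > pick$fr1count ||
              (cand$fr1count == pick$fr1count &&
                 al$score > pick$al$score))))
      pick <- cand
  }
  if (is.null(pick)) return("no V-domain homology")
  ## Conflicting FR1 anchors across frames (a frameshift inside FR1 gives
  ## both the prefix and the shifted suffix a diagonal): unless the picked
  ## frame's FR1 evidence dominates, fall back to the widened search.
  if (length(anchorInfo) > 1L) {
    starts <- vapply(anchorInfo, `[`, 0, 1L)
    counts <- vapply(anchorInfo, `[`, 0, 2L)
    others <- counts[starts != pick$vStart]
    if (length(others) && max(others) * 2L > pick$fr1count)
      pick$anchored <- FALSE
  }
  vStart <- pick$vStart
  if (vStart <= p$minIntron + p$minL1 + p$minL2 ||
      L + 1L - vStart < p$minExon2 - p$maxL2)
    return("V region too close to context edge")

  donors <- allMatches(DONOR_SITE, s)
  atgs <- allMatches("ATG", s)
  if (!length(atgs)) return("no ATG in context")

  ## when the template anchor is not N-terminal (frameshifted genes) the
  ## extrapolated V start can be off by the indel size; widen the L-PART2
  ## window accordingly
  acceptorsAt <- function(fallback, slack) {
    a <- vStart - (p$maxL2 + slack):(p$minL2 - slack)
    a <- a[a > p$minIntron + p$minL1 + 2L &
             L + 1L - a >= p$minExon2 & L + 1L - a <= p$maxExon2]
    if (!length(a)) return(integer())
    a <- a[order(abs((vStart - a) - 11L))]  # canonical L-PART2 first
    if (!fallback)
      a[substr(rep(s, length(a)), a - 2L, a - 1L) == "AG"]
    else
      a[substr(rep(s, length(a)), a - 6L, a - 2L) == "TTCCA" &
          substr(rep(s, length(a)), a - 2L, a - 1L) != "AG"]
  }

  tryAcceptors <- function(accepts, accDefect) {
    for (a in accepts) {
      leader <- .findLeader(s, a, vStart - a, donors, atgs, p)
      donorDefect <- FALSE
      if (is.null(leader)) {
        leader <- .findLeader(s, a, vStart - a, .fallbackDonors(s, a, p),
                              atgs, p)
        donorDefect <- !is.null(leader)
      }
      if (!is.null(leader))
        return(c(pick, leader,
                 list(acceptor = a, l2 = vStart - a,
                      accDefect = accDefect || donorDefect)))
    }
    NULL
  }

  ## search order: canonical L-PART2 window first (canonical acceptor,
  ## then degenerate-acceptor fallback); only when the template anchor is
  ## not N-terminal (frameshifted genes, where the extrapolated V start
  ## can be off by the indel plus an alignment slip) retry with a widened
  ## window
  best <- tryAcceptors(acceptorsAt(FALSE, 0L), FALSE)
  if (is.null(best)) best <- tryAcceptors(acceptorsAt(TRUE, 0L), TRUE)
  if (is.null(best) && !pick$anchored) {
    best <- tryAcceptors(acceptorsAt(FALSE, 12L), FALSE)
    if (is.null(best)) best <- tryAcceptors(acceptorsAt(TRUE, 12L), TRUE)
  }
  if (is.null(best)) return("no valid leader/exon structure")
  best$vStart <- vStart

  ## defects
  m <- best$m; d <- best$d; a <- best$acceptor
  l1 <- substr(s, m, d - 1L)
  exon2 <- substr(s, a, L)
  spliced <- paste0(l1, exon2)
  defects <- character()
  if (best$accDefect) defects <- c(defects, "splice_defect")
  if (!rsIsStrict(hit)) defects <- c(defects, "rs_defect")
  if (nchar(spliced) %% 3L != 0L) defects <- c(defects, "frameshift")
  aa <- translateFrame(spliced, 0L)
  if (grepl("*", aa, fixed = TRUE)) defects <- c(defects, "stop_codon")
  vAA <- translateFrame(substr(s, best$vStart, L), 0L)
  num <- imgtNumberV(vAA, template)
  if (num$success &&
      (!identical(num$residues[["23"]], "C") ||
       !identical(num$residues[["41"]], "W") ||
       !identical(num$residues[["104"]], "C")))
    defects <- c(defects, "missing_conserved_residue")

  g <- function(x, y) ctx$toGenomic(x, y)
  ## a widened-window (frameshift) estimate can place the template start
  ## at or before the acceptor; the V exon then has no L-PART2 to report
  vStartFeat <- max(best$vStart, a)
  feat <- rbind(
    data.frame(feature = "L_PART1", gfrom = g(m, d - 1L)[1L],
               gto = g(m, d - 1L)[2L]),
    data.frame(feature = "V_INTRON", gfrom = g(d, a - 1L)[1L],
               gto = g(d, a - 1L)[2L]),
    if (vStartFeat > a)
      data.frame(feature = "L_PART2", gfrom = g(a, vStartFeat - 1L)[1L],
                 gto = g(a, vStartFeat - 1L)[2L]),
    data.frame(feature = "V_REGION", gfrom = g(vStartFeat, L)[1L],
               gto = g(vStartFeat, L)[2L]),
    data.frame(feature = "RSS", gfrom = hit$start, gto = hit$end))
  span <- c(min(feat$gfrom), max(feat$gto))
  data.frame(
    start = span[1L], end = span[2L], strand = hit$strand,
    gene_type = "V", defects = paste(defects, collapse = ";"),
    alnScore = best$al$score, rsMM = hit$heptMismatch + hit$nonaMismatch,
    vAA = vAA, cdr1 = num$cdrLengths[[1L]], cdr2 = num$cdrLengths[[2L]],
    cdr3 = num$cdrLengths[[3L]], res23 = num$residues[["23"]],
    res41 = num$residues[["41"]], res104 = num$residues[["104"]],
    numberingOK = num$success,
    segment = paste0(substr(s, m, d - 1L), exon2),
    featureStr = paste(sprintf("%s:%d:%d", feat$feature, feat$gfrom,
                               feat$gto), collapse = "|"),
    stringsAsFactors = FALSE)
}

## innermost-ATG leader search: canonical donor positions are tried in
## order of increasing intron length; the shortest stop-free in-frame
## leader wins
.findLeader <- function(s, acceptor, l2, donorPos, atgs, p) {
  dOK <- donorPos[acceptor - donorPos >= p$minIntron &
                    acceptor - donorPos <= p$maxIntron]
  if (!length(dOK)) return(NULL)
  for (d in sort(dOK, decreasing = TRUE)) {   # shortest intron first
    ## all valid L-PART2 lengths are 2 mod 3 under the consensus grammar,
    ## so a codon-complete leader requires L-PART1 = 1 mod 3 regardless of
    ## the L-PART2 estimate
    mOK <- atgs[d - atgs >= p$minL1 & d - atgs <= p$maxL1 &
                  (d - atgs) %% 3L == 1L]
    if (!length(mOK)) next
    for (m in sort(mOK, decreasing = TRUE)) { # innermost ATG first
      lead <- paste0(substr(s, m, d - 1L),
                     substr(s, acceptor, acceptor + l2 - 1L))
      if (!hasInFrameStop(lead)) return(list(m = m, d = d))
    }
  }
  NULL
}

## degenerate donor sites: extended consensus with a mutated GT dinucleotide
.fallbackDonors <- function(s, acceptor, p) {
  hits <- sort(unique(c(allMatches("G.AAGT", s), allMatches(".TAAGT", s))))
  hits[substr(rep(s, length(hits)), hits, hits + 1L) != "GT"]
}

## among overlapping same-strand candidates keep the one with the best
## V-domain homology (then fewest RS mismatches, then leftmost)
.dedupeOverlapping <- function(genes) {
  if (is.null(genes) || !nrow(genes)) return(genes)
  genes <- genes[order(-genes$alnScore, genes$rsMM, genes$start), ,
                 drop = FALSE]
  keep <- rep(TRUE, nrow(genes))
  for (i in seq_len(nrow(genes))[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (genes$strand[i] == genes$strand[j] &&
          genes$start[i] <= genes$end[j] && genes$end[i] >= genes$start[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  genes <- genes[keep, , drop = FALSE]
  genes[order(genes$start), , drop = FALSE]
}
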