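# J and D gene annotation inside the constant-gene cluster.
#
# A J gene is a 12-type RS whose heptamer is followed (in gene orientation)
# by a short coding stretch ending at an extended-consensus donor site. The
# reading frame carrying the hallmark FGXG motif defines the J frame; a
# stop-free frame containing at least the FG core is accepted as an
# ORF-class candidate when the motif itself is lost (requires a near-exact
# RS so random matches are not promoted). D genes are 5'D-RS/3'D-RS pairs
# facing each other across a short D-REGION.

J_SEARCH_DEFAULTS <- list(
  minJ = 30L, maxJ = 80L,        # J-REGION length window (nt)
  orfMaxHept = 1L, orfMaxNona = 2L)

#' Annotate J genes from RS hits
#'
#' @param genome contig sequence.
#' @param rsHits data.frame from `scanRS(genome, "J", window = ...)`,
#'   typically restricted to the interval between constant genes.
#' @param chain chain label to assign (`"TRA"` or `"TRD"`); under the TRD
#'   policy a missing FGXG motif (e.g. the salmonid FGKA variant) does not
#'   demote functionality.
#' @param params search parameters (see `J_SEARCH_DEFAULTS`).
#' @return a data.frame of accepted J annotations (one row per gene) with
#'   genomic span (RS through J-REGION), J-REGION coordinates, motif and
#'   defect information.
#' @export
annotateJGenes <- function(genome, rsHits, chain = "TRA",
                           params = J_SEARCH_DEFAULTS) {
  seqchar <- toupper(asSingleSequence(genome))
  p <- utils::modifyList(J_SEARCH_DEFAULTS, params)
  out <- list()
  if (nrow(rsHits)) {
    rsHits <- rsHits[order(rsHits$score), , drop = FALSE]
    rsHits <- rsHits[!duplicated(paste(rsHits$heptamerStart,
                                       rsHits$strand)), , drop = FALSE]
  }
  for (i in seq_len(nrow(rsHits))) {
    hit <- rsHits[i, ]
    cand <- .evaluateJCandidate(seqchar, hit, chain, p)
    if (!is.null(cand)) out[[length(out) + 1L]] <- cand
  }
  genes <- if (length(out)) do.call(rbind, out) else NULL
  if (!is.null(genes)) {
    ## overlapping candidates: keep best RS (fewest mismatches)
    genes <- genes[order(genes$rsMM, genes$start), , drop = FALSE]
    keep <- rep(TRUE, nrow(genes))
    for (i in seq_len(nrow(genes))[-1L])
      for (j in seq_len(i - 1L))
        if (keep[j] && genes$strand[i] == genes$strand[j] &&
            genes$start[i] <= genes$end[j] &&
            genes$end[i] >= genes$start[j]) {
          keep[i] <- FALSE; break
        }
    genes <- genes[keep, , drop = FALSE]
    genes <- genes[order(genes$start), , drop = FALSE]
    rownames(genes) <- NULL
  }
  genes
}

## gene-oriented downstream context: sequence 3' of the heptamer
downstreamContext <- function(seqchar, hit, len) {
  n <- nchar(seqchar)
  if (hit$strand == "+") {
    ## J/D5 gene on '+': pattern was on '-', heptamer rc at
    ## [heptamerStart, +6]; gene continues at heptamerStart + 7
    from <- hit$heptamerStart + 7L
    to <- min(n, from + len - 1L)
    list(seq = substr(seqchar, from, to),
         toGenomic = function(a, b) c(from + a - 1L, from + b - 1L))
  } else {
    to <- hit$heptamerStart - 1L
    from <- max(1L, to - len + 1L)
    list(seq = revComp(substr(seqchar, from, to)),
         toGenomic = function(a, b) c(to - b + 1L, to - a + 1L))
  }
}

.evaluateJCandidate <- function(seqchar, hit, chain, p) {
  ctx <- downstreamContext(seqchar, hit, p$maxJ + 10L)
  s <- ctx$seq
  donors <- allMatches(DONOR_SITE, s)
  donors <- donors[donors - 1L >= p$minJ & donors - 1L <= p$maxJ]
  strictPlus <- hit$heptMismatch <= p$orfMaxHept &&
    hit$nonaMismatch <= p$orfMaxNona
  for (d in donors) {   # smallest span first
    jnt <- substr(s, 1L, d - 1L)
    aa <- vapply(0:2, function(f)
      gsub("*", "X", translateFrame(jnt, f), fixed = TRUE), "")
    stops <- vapply(0:2, function(f) hasInFrameStop(jnt, f), logical(1L))
    motifIn <- grepl("FG.G", aa)
    if (any(motifIn)) {
      frame <- if (any(motifIn & !stops)) which(motifIn & !stops)[1L] - 1L
      else which(motifIn)[1L] - 1L
      return(.emitJ(seqchar, hit, ctx, d, frame, aa[frame + 1L],
                    stops[frame + 1L], missingMotif = FALSE, chain))
    }
    ## motif-less path: only with a near-exact RS and a stop-free frame
    ## retaining the FG core
    fgIn <- grepl("FG", aa)
    if (strictPlus && any(fgIn & !stops)) {
      frame <- which(fgIn & !stops)[1L] - 1L
      return(.emitJ(seqchar, hit, ctx, d, frame, aa[frame + 1L],
                    stops[frame + 1L], missingMotif = TRUE, chain))
    }
  }
  NULL
}

.emitJ <- function(seqchar, hit, ctx, d, frame, aa, hasStop, missingMotif,
                   chain) {
  jg <- ctx$toGenomic(1L, d - 1L)
  span <- c(min(hit$start, jg[1L]), max(hit$end, jg[2L]))
  defects <- character()
  if (missingMotif) defects <- c(defects, "missing_FGXG")
  if (hasStop) defects <- c(defects, "stop_codon")
  if (hit$heptMismatch > 1L || hit$nonaMismatch > 3L)
    defects <- c(defects, "rs_defect")
  data.frame(start = span[1L], end = span[2L], strand = hit$strand,
             gene_type = "J", chain = chain,
             jStart = min(jg), jEnd = max(jg), frame = frame,
             jAA = aa, defects = paste(defects, collapse = ";"),
             rsMM = hit$heptMismatch + hit$nonaMismatch,
             rssStart = hit$start, rssEnd = hit$end,
             segment = substr(ctx$seq, 1L, d - 1L),
             stringsAsFactors = FALSE)
}

#' Annotate D genes from paired RS hits
#'
#' Pairs 5'D-RS (12-type) and 3'D-RS (23-type) hits on the same strand whose
#' heptamers face each other across at most `maxD` nucleotides; the
#' D-REGION is the sequence between the two heptamers. Unpaired hits are
#' not emitted. De novo D discovery uses near-exact RS matches only.
#'
#' @param genome contig sequence.
#' @param rs5,rs3 data.frames from `scanRS(genome, "D5"/"D3", ...)`.
#' @param maxD maximum D-REGION length (nt).
#' @return a data.frame with one row per D gene: genomic span (both RS plus
#'   D-REGION), D-REGION coordinates and an `allFramesOpen` flag (TRUE when
#'   all three reading frames of the D-REGION are stop-free).
#' @export
annotateDGenes <- function(genome, rs5, rs3, maxD = 40L) {
  seqchar <- toupper(asSingleSequence(genome))
  near <- function(h) h[h$heptMismatch == 0L & h$nonaMismatch <= 1L, ,
                        drop = FALSE]
  rs5 <- near(rs5); rs3 <- near(rs3)
  out <- list()
  for (i in seq_len(nrow(rs5))) {
    h5 <- rs5[i, ]
    for (j in seq_len(nrow(rs3))) {
      h3 <- rs3[j, ]
      if (h5$strand != h3$strand) next
      if (h5$strand == "+") {
        dFrom <- h5$heptamerStart + 7L
        dTo <- h3$heptamerStart - 1L
      } else {
        dFrom <- h3$heptamerStart + 7L
        dTo <- h5$heptamerStart - 1L
      }
      dlen <- dTo - dFrom + 1L
      if (dlen < 1L || dlen > maxD) next
      dseq <- substr(seqchar, dFrom, dTo)
      if (h5$strand == "-") dseq <- revComp(dseq)
      open <- !vapply(0:2, function(f)
        hasInFrameStop(paste0(dseq, "AA"), f), logical(1L))
      out[[length(out) + 1L]] <- data.frame(
        start = min(h5$start, h3$start), end = max(h5$end, h3$end),
        strand = h5$strand, gene_type = "D", chain = "TRD",
        dStart = dFrom, dEnd = dTo, dLength = dlen,
        allFramesOpen = all(open), segment = dseq,
        rs5Start = h5$start, rs5End = h5$end,
        rs3Start = h3$start, rs3End = h3$end,
        stringsAsFactors = FALSE)
    }
  }
  genes <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), strand = character(),
               gene_type = character(), chain = character(),
               dStart = integer(), dEnd = integer(), dLength = integer(),
               allFramesOpen = logical(), segment = character(),
               rs5Start = integer(), rs5End = integer(),
               rs3Start = integer(), rs3End = integer())
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}
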