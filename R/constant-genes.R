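# Constant (TRAC/TRDC) gene discovery: seed-and-extend spliced alignment of
# constant-region query sequences against the genomic contig, followed by
# splice-boundary refinement to canonical GT..AG introns. The strand of the
# recovered constant genes defines the locus orientation.

#' Locate constant genes by spliced alignment of query sequences
#'
#' Each query (a spliced constant-region coding sequence, e.g. a published
#' TRAC/TRDC cDNA) is seeded against both strands of the genome with exact
#' 30-mers, candidate windows are refined by iterative local alignment into
#' up to three exons, and exon boundaries are adjusted so introns start with
#' GT and end with AG. The translated product must be stop-free until the
#' terminal codon; models failing boundary refinement are reported with a
#' `splice_defect`.
#'
#' @param genome a `DNAStringSet`/`DNAString`/character contig.
#' @param cQueries named [Biostrings::DNAStringSet] of constant-region
#'   query coding sequences.
#' @param minIdentity identity floor below which a query is considered
#'   absent (a warning is emitted and the query skipped).
#' @return a data.frame with one row per exon: `name`, `strand`, `exon`
#'   (1-based index in transcriptional order), `start`, `end` (genomic),
#'   `identity`, `aaLength`, `splice_defect`. Empty (with a warning) when no
#'   query matches.
#' @export
findConstantGenes <- function(genome, cQueries, minIdentity = 0.75) {
  seqchar <- toupper(asSingleSequence(genome))
  out <- list()
  for (qi in seq_along(cQueries)) {
    qname <- names(cQueries)[qi] %||% paste0("C", qi)
    q <- as.character(cQueries[[qi]])
    best <- NULL
    for (st in c("+", "-")) {
      subj <- if (st == "+") seqchar else revComp(seqchar)
      win <- .seedWindow(q, subj)
      if (is.null(win)) next
      model <- .splicedModel(q, subj, win)
      if (is.null(model)) next
      if (is.null(best) || model$score > best$score) {
        best <- model
        best$strand <- st
        best$subjLen <- nchar(subj)
      }
    }
    if (is.null(best) || best$identity < minIdentity) {
      warning("no constant-gene hit for query ", qname)
      next
    }
    ex <- best$exons
    if (best$strand == "-") {
      n <- best$subjLen
      tmp <- ex
      ex$start <- n - tmp$end + 1L
      ex$end <- n - tmp$start + 1L
    }
    out[[qname]] <- data.frame(
      name = qname, strand = best$strand, exon = seq_len(nrow(ex)),
      start = ex$start, end = ex$end, identity = best$identity,
      aaLength = best$aaLength, splice_defect = best$splice_defect)
  }
  if (!length(out))
    return(data.frame(name = character(), strand = character(),
                      exon = integer(), start = integer(), end = integer(),
                      identity = numeric(), aaLength = integer(),
                      splice_defect = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## exact 30-mer seeding; returns a genomic window c(from, to) or NULL
.seedWindow <- function(q, subj, k = 30L, pad = 1500L) {
  starts <- seq(1L, max(1L, nchar(q) - k + 1L), by = k)
  hits <- integer()
  for (s in starts) {
    h <- patternHits(substr(q, s, s + k - 1L), Biostrings::DNAString(subj))
    hits <- c(hits, h)
  }
  if (!length(hits)) return(NULL)
  ## densest cluster of seed hits within a query-sized neighbourhood
  hits <- sort(hits)
  span <- nchar(q) + 800L
  counts <- vapply(hits, function(h) sum(hits >= h & hits <= h + span), 0L)
  center <- hits[which.max(counts)]
  c(max(1L, center - pad), min(nchar(subj), center + span + pad))
}

## iterative local alignment of the query against the window, masked
## recursion into up to three colinear segments, then boundary refinement
.splicedModel <- function(q, subj, win) {
  wseq <- substr(subj, win[1L], win[2L])
  segs <- list()
  recurse <- function(q1, q2, w1, w2, depth) {
    if (depth > 4L || q2 - q1 < 19L || w2 - w1 < 19L) return()
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(substr(q, q1, q2)),
      Biostrings::DNAString(substr(wseq, w1, w2)),
      type = "local", substitutionMatrix =
        Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3),
      ## gaps are expensive so alignments never bridge an intron; exon
      ## boundaries are found by the masked recursion instead
      gapOpening = 40, gapExtension = 4)
    if (Biostrings::score(aln) < 40) return()
    qs <- q1 + Biostrings::start(Biostrings::pattern(aln)) - 1L
    qe <- q1 + Biostrings::end(Biostrings::pattern(aln)) - 1L
    ws <- w1 + Biostrings::start(Biostrings::subject(aln)) - 1L
    we <- w1 + Biostrings::end(Biostrings::subject(aln)) - 1L
    segs[[length(segs) + 1L]] <<- list(qs = qs, qe = qe, ws = ws, we = we,
                                       score = Biostrings::score(aln))
    recurse(q1, qs - 1L, w1, ws - 1L, depth + 1L)
    recurse(qe + 1L, q2, we + 1L, w2, depth + 1L)
  }
  recurse(1L, nchar(q), 1L, nchar(wseq), 1L)
  if (!length(segs)) return(NULL)
  segs <- segs[order(vapply(segs, `[[`, 0, "qs"))]
  ## colinearity check
  for (i in seq_along(segs)[-1L])
    if (segs[[i]]$ws <= segs[[i - 1L]]$we) return(NULL)

  splice_defect <- FALSE
  ## refine each intron boundary: force query adjacency, slide the split
  ## point to a GT..AG (bonus for the extended GTAAGT donor) intron
  for (i in seq_along(segs)[-1L]) {
    a <- segs[[i - 1L]]; b <- segs[[i]]
    bestShift <- NULL
    for (qsplit in (b$qs - 20L):(b$qs + 19L)) {
      if (qsplit <= a$qs || qsplit > b$qe) next
      aEnd <- a$ws + (qsplit - 1L - a$qs)
      bStart <- b$we - (b$qe - qsplit)
      if (bStart - aEnd < 20L) next
      donor <- substr(wseq, aEnd + 1L, aEnd + 2L)
      accep <- substr(wseq, bStart - 2L, bStart - 1L)
      sc <- (donor == "GT") * 2L + (accep == "AG") * 2L +
        (substr(wseq, aEnd + 1L, aEnd + 6L) == DONOR_SITE)
      if (is.null(bestShift) || sc > bestShift$sc)
        bestShift <- list(qsplit = qsplit, aEnd = aEnd, bStart = bStart,
                          sc = sc)
    }
    if (is.null(bestShift)) return(NULL)
    if (bestShift$sc < 4L) splice_defect <- TRUE
    segs[[i - 1L]]$qe <- bestShift$qsplit - 1L
    segs[[i - 1L]]$we <- bestShift$aEnd
    segs[[i]]$qs <- bestShift$qsplit
    segs[[i]]$ws <- bestShift$bStart
  }
  ## extend terminal exons to full query coverage where the sequence allows
  a <- segs[[1L]]
  ext <- min(a$qs - 1L, a$ws - 1L)
  segs[[1L]]$qs <- a$qs - ext; segs[[1L]]$ws <- a$ws - ext
  b <- segs[[length(segs)]]
  ext <- min(nchar(q) - b$qe, nchar(wseq) - b$we)
  segs[[length(segs)]]$qe <- b$qe + ext; segs[[length(segs)]]$we <- b$we + ext

  exons <- data.frame(
    start = vapply(segs, `[[`, 0, "ws") + win[1L] - 1L,
    end = vapply(segs, `[[`, 0, "we") + win[1L] - 1L)
  cds <- paste0(vapply(segs, function(s) substr(wseq, s$ws, s$we), ""),
                collapse = "")
  aa <- translateFrame(cds, 0L)
  aaCore <- sub("\\*$", "", aa)
  qaln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(cds), Biostrings::DNAString(q), type = "global")
  ident <- Biostrings::nmatch(qaln) / Biostrings::nchar(qaln)
  if (grepl("*", aaCore, fixed = TRUE)) splice_defect <- TRUE
  list(exons = exons, score = sum(vapply(segs, `[[`, 0, "score")),
       identity = ident, aaLength = nchar(aaCore),
       splice_defect = splice_defect)
}
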