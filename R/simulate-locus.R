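# Assemble a synthetic chromosome from a germline set, in the teleost
# layout: on the Watson strand the V array comes first (transcribed '+'),
# followed by the constant-gene cluster in inverted orientation
# (TRAC, TRAJ1..n, TRDC, TRDJ, TRDDn..1 left-to-right, all on '-').
# Read 5'->3' along the transcriptional orientation of the cluster, the
# locus therefore runs TRDD-TRDJ-TRDC-TRAJ-TRAC followed by the V genes in
# opposite orientation, with TRAJ1 the TRAC-proximal J and TRDD1 at the
# locus 5' end.

#' Simulate a complete TRA/TRD locus with exact ground truth
#'
#' Generates a germline set (see [simulateGermlineSet()]) and plants it on a
#' single synthetic contig in the teleost TRA/TRD layout. An optional block
#' of V genes (`invertedBlock` ranks) is emitted in opposite orientation to
#' the rest of the V array. Planted features never overlap; coordinates in
#' the returned truth ranges are exact.
#'
#' @param spec a [LocusSpec()].
#' @param germline optionally, a pre-built [GermlineSet-class] (it must come
#'   from the same spec; by default the germline set is generated as the
#'   first part of the seeded stream).
#' @return a [LocusSim-class].
#' @examples
#' sim <- simulateLocus(LocusSpec(nSubgroups = 2L,
#'   genesPerSubgroup = c(2L, 2L), nTRAJ = 4L, pseudogeneFraction = 0,
#'   orfFraction = 0, seed = 11L))
#' sim
#' @export
simulateLocus <- function(spec, germline = NULL) {
  validObject(spec)
  withSeed(spec@seed, {
    if (is.null(germline)) germline <- .simulateGermlineSet(spec)
    .assembleLocus(spec, germline)
  })
}

.assembleLocus <- function(spec, germline) {
  gd <- as.data.frame(germline@geneData)
  regions <- as.character(germline@regionSeqs)
  inter <- function() randomDNA(sampleRange(spec@intergenicRange[1L],
                                            spec@intergenicRange[2L]))

  ## placement order along the chromosome (left to right)
  vIdx <- which(gd$type == "V")
  vIdx <- vIdx[order(gd$locus_index[vIdx], decreasing = TRUE)]
  jIdx <- which(gd$type == "J" & gd$chain == "TRA")
  jIdx <- jIdx[order(gd$locus_index[jIdx])]
  dIdx <- which(gd$type == "D")
  dIdx <- dIdx[order(gd$locus_index[dIdx], decreasing = TRUE)]
  trdj <- which(gd$type == "J" & gd$chain == "TRD")
  trac <- which(gd$name == "TRAC")
  trdc <- which(gd$name == "TRDC")
  order_ <- c(vIdx, trac, jIdx, trdc, trdj, dIdx)

  strandOf <- function(i) {
    if (gd$type[i] == "V") {
      inv <- length(spec@invertedBlock) == 2L &&
        gd$locus_index[i] >= spec@invertedBlock[1L] &&
        gd$locus_index[i] <= spec@invertedBlock[2L]
      if (inv) "-" else "+"
    } else "-"
  }

  pieces <- character(0L)
  cursor <- 0L
  addPiece <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    cursor <<- cursor + nchar(s)
  }
  addPiece(inter())

  rows <- list()
  for (i in order_) {
    st <- strandOf(i)
    seqi <- regions[[gd$name[i]]]
    L <- nchar(seqi)
    gstart <- cursor + 1L
    addPiece(if (st == "+") seqi else revComp(seqi))
    f <- germline@features[[gd$name[i]]]
    span <- if (gd$type[i] == "C") c(1L, L) else
      c(min(f$from), max(f$to))
    rel <- rbind(data.frame(feature = "gene", from = span[1L],
                            to = span[2L]), f)
    if (st == "+") {
      rel$gfrom <- gstart + rel$from - 1L
      rel$gto <- gstart + rel$to - 1L
    } else {
      rel$gfrom <- gstart + L - rel$to
      rel$gto <- gstart + L - rel$from
    }
    rows[[length(rows) + 1L]] <- data.frame(
      feature = rel$feature, start = rel$gfrom, end = rel$gto,
      strand = st, name = gd$name[i], gene_type = gd$type[i],
      chain = gd$chain[i], functionality = gd$functionality[i],
      subgroup = gd$subgroup[i], defect = gd$defect[i],
      stringsAsFactors = FALSE)
    addPiece(inter())
  }
  genomeSeq <- paste0(pieces, collapse = "")
  tr <- do.call(rbind, rows)

  gr <- GenomicRanges::GRanges(
    seqnames = "synthetic_locus",
    ranges = IRanges::IRanges(start = tr$start, end = tr$end),
    strand = tr$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    feature = tr$feature, name = tr$name, gene_type = tr$gene_type,
    chain = tr$chain, functionality = tr$functionality,
    subgroup = tr$subgroup, defect = tr$defect)

  gene <- gr[gr$feature == "gene"]
  if (!all(IRanges::isDisjoint(GenomicRanges::ranges(gene))))
    stop("overlapping planted features")

  genome <- Biostrings::DNAStringSet(genomeSeq)
  names(genome) <- "synthetic_locus"
  new("LocusSim", genome = genome, truth = gr, germline = germline)
}

#' Write a simulated locus to disk
#'
#' Emits the contig FASTA and the ground-truth annotation as GFF3
#' (1-based inclusive coordinates).
#'
#' @param sim a [LocusSim-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeLocus <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "locus.fasta")
  gff <- file.path(dir, "truth.gff3")
  Biostrings::writeXStringSet(sim@genome, fa)
  gr <- sim@truth
  gr$type <- ifelse(gr$feature == "gene", "gene", gr$feature)
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fa, gff3 = gff))
}
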