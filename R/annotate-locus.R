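# End-to-end germline annotation of a TRA/TRD contig:
# constant-gene anchoring -> genome-wide relaxed V-RS scan + V annotation ->
# cluster-window J/D annotation -> functionality -> subgroup clustering ->
# nomenclature.

#' Annotate a TRA/TRD locus
#'
#' Runs the full germline annotation pipeline on one contig. Constant genes
#' are located first by spliced alignment of the query sequences; their
#' strand defines the locus orientation and their positions delimit the
#' TRAJ window (between TRDC and TRAC) and the TRDJ/TRDD window (beyond
#' TRDC, away from TRAC). V genes are discovered genome-wide from a relaxed
#' RS scan so that genes with degenerate RS motifs are still found and
#' classified ORF.
#'
#' @param genome `DNAStringSet`/`DNAString`/character contig, or path to a
#'   FASTA file.
#' @param cQueries named `DNAStringSet` of constant-region query coding
#'   sequences (names must identify the TRAC and TRDC homologs), or a FASTA
#'   path.
#' @param template numbering template (see [loadVTemplate()]).
#' @param strictConserved see [classifyFunctionality()].
#' @param subgroupThreshold percent V-REGION identity defining subgroups.
#' @param clusterPad bp scanned beyond TRDC for the TRDJ/TRDD window.
#' @return a [TRAnnotation-class].
#' @examples
#' \donttest{
#' sim <- simulateLocus(LocusSpec(nSubgroups = 2L,
#'   genesPerSubgroup = c(2L, 2L), nTRAJ = 3L, pseudogeneFraction = 0,
#'   orfFraction = 0, seed = 2L))
#' ann <- annotateLocus(locusGenome(sim), constantQueries(sim@germline))
#' geneTable(ann)
#' }
#' @export
annotateLocus <- function(genome, cQueries, template = loadVTemplate(),
                          strictConserved = FALSE, subgroupThreshold = 75,
                          clusterPad = 30000L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(cQueries) && length(cQueries) == 1L &&
      file.exists(cQueries))
    cQueries <- Biostrings::readDNAStringSet(cQueries)
  seqchar <- toupper(asSingleSequence(genome))
  contig <- if (methods::is(genome, "DNAStringSet") &&
                !is.null(names(genome))) names(genome)[1L] else "contig"

  ## ---- constant genes ----------------------------------------------------
  cg <- findConstantGenes(seqchar, cQueries)
  cNames <- unique(cg$name)
  orientation <- if (nrow(cg)) names(sort(table(cg$strand),
                                          decreasing = TRUE))[1L] else "+"
  tracName <- grep("TRAC", cNames, value = TRUE)[1L]
  trdcName <- grep("TRDC", cNames, value = TRUE)[1L]

  ## ---- V genes (genome-wide, relaxed RS scan) ---------------------------
  rsV <- scanRS(seqchar, "V", maxHeptMismatch = 2L, maxNonaMismatch = 4L,
                heptCACExact = FALSE)
  vres <- annotateVGenes(seqchar, rsV, template = template)
  vg <- vres$genes

  ## ---- J and D genes inside the cluster ---------------------------------
  jTRA <- NULL; jTRD <- NULL; dg <- NULL
  if (!is.na(tracName) && !is.na(trdcName)) {
    tracSpan <- range(c(cg$start[cg$name == tracName],
                        cg$end[cg$name == tracName]))
    trdcSpan <- range(c(cg$start[cg$name == trdcName],
                        cg$end[cg$name == trdcName]))
    jWin <- if (tracSpan[1L] < trdcSpan[1L])
      c(tracSpan[2L] + 1L, trdcSpan[1L] - 1L)
    else c(trdcSpan[2L] + 1L, tracSpan[1L] - 1L)
    if (jWin[2L] > jWin[1L] + 50L) {
      rsJ <- scanRS(seqchar, "J", window = jWin)
      jTRA <- annotateJGenes(seqchar, rsJ, chain = "TRA")
    }
    dWin <- if (tracSpan[1L] < trdcSpan[1L])
      c(trdcSpan[2L] + 1L,
        min(nchar(seqchar), trdcSpan[2L] + clusterPad))
    else c(max(1L, trdcSpan[1L] - clusterPad), trdcSpan[1L] - 1L)
    if (dWin[2L] > dWin[1L] + 50L) {
      rsJd <- scanRS(seqchar, "J", window = dWin)
      jTRD <- annotateJGenes(seqchar, rsJd, chain = "TRD")
      rs5 <- scanRS(seqchar, "D5", window = dWin)
      rs3 <- scanRS(seqchar, "D3", window = dWin)
      dg <- annotateDGenes(seqchar, rs5, rs3)
    }
  } else if (nrow(cg) == 0L) {
    warning("no constant genes found; J/D annotation skipped")
  }

  ## ---- assemble gene table ----------------------------------------------
  rows <- list(); featRows <- list(); segs <- character()
  addRow <- function(start, end, strand, gene_type, chain, defects,
                     segment, extra = list()) {
    r <- c(list(start = start, end = end, strand = strand,
                gene_type = gene_type, chain = chain,
                defects = defects), extra)
    rows[[length(rows) + 1L]] <<- r
    segs[[length(segs) + 1L]] <<- segment
  }

  if (!is.null(vg)) for (i in seq_len(nrow(vg))) {
    addRow(vg$start[i], vg$end[i], vg$strand[i], "V", "TRA",
           vg$defects[i], vg$segment[i],
           list(cdr1 = vg$cdr1[i], cdr2 = vg$cdr2[i], cdr3 = vg$cdr3[i],
                res23 = vg$res23[i], res41 = vg$res41[i],
                res104 = vg$res104[i], numberingOK = vg$numberingOK[i],
                vAA = vg$vAA[i]))
    for (part in strsplit(vg$featureStr[i], "|", fixed = TRUE)[[1L]]) {
      x <- strsplit(part, ":", fixed = TRUE)[[1L]]
      featRows[[length(featRows) + 1L]] <- data.frame(
        feature = x[1L], start = as.integer(x[2L]), end = as.integer(x[3L]),
        strand = vg$strand[i], parentIdx = length(rows))
    }
  }
  for (jg in list(jTRA, jTRD)) if (!is.null(jg)) for (i in seq_len(nrow(jg))) {
    addRow(jg$start[i], jg$end[i], jg$strand[i], "J", jg$chain[i],
           jg$defects[i], jg$segment[i], list(jAA = jg$jAA[i]))
    featRows[[length(featRows) + 1L]] <- data.frame(
      feature = "RSS", start = jg$rssStart[i], end = jg$rssEnd[i],
      strand = jg$strand[i], parentIdx = length(rows))
    featRows[[length(featRows) + 1L]] <- data.frame(
      feature = "J_REGION", start = jg$jStart[i], end = jg$jEnd[i],
      strand = jg$strand[i], parentIdx = length(rows))
  }
  if (!is.null(dg)) for (i in seq_len(nrow(dg))) {
    addRow(dg$start[i], dg$end[i], dg$strand[i], "D", "TRD", "",
           dg$segment[i], list(allFramesOpen = dg$allFramesOpen[i]))
    featRows[[length(featRows) + 1L]] <- data.frame(
      feature = "RSS", start = dg$rs5Start[i], end = dg$rs5End[i],
      strand = dg$strand[i], parentIdx = length(rows))
    featRows[[length(featRows) + 1L]] <- data.frame(
      feature = "D_REGION", start = dg$dStart[i], end = dg$dEnd[i],
      strand = dg$strand[i], parentIdx = length(rows))
    featRows[[length(featRows) + 1L]] <- data.frame(
      feature = "RSS", start = dg$rs3Start[i], end = dg$rs3End[i],
      strand = dg$strand[i], parentIdx = length(rows))
  }
  for (cn in cNames) {
    ex <- cg[cg$name == cn, , drop = FALSE]
    chain <- if (!is.na(trdcName) && cn == trdcName) "TRD" else
      if (!is.na(tracName) && cn == tracName) "TRA" else "ambiguous"
    cds <- paste0(vapply(order(ex$exon), function(k) {
      s <- substr(seqchar, ex$start[k], ex$end[k])
      if (ex$strand[1L] == "-") s <- revComp(s) else s
    }, ""), collapse = "")
    if (ex$strand[1L] == "-") {
      ## exons were recorded in genomic order; transcriptional order is
      ## reversed on the minus strand
      cds <- paste0(vapply(rev(seq_len(nrow(ex))), function(k)
        revComp(substr(seqchar, ex$start[k], ex$end[k])), ""),
        collapse = "")
    }
    addRow(min(ex$start), max(ex$end), ex$strand[1L], "C", chain,
           if (any(ex$splice_defect)) "splice_defect" else "", cds,
           list(cname = cn, identity = ex$identity[1L]))
    for (k in seq_len(nrow(ex)))
      featRows[[length(featRows) + 1L]] <- data.frame(
        feature = "EXON", start = ex$start[k], end = ex$end[k],
        strand = ex$strand[1L], parentIdx = length(rows))
  }

  if (!length(rows))
    return(new("TRAnnotation",
               genes = GenomicRanges::GRanges(),
               features = GenomicRanges::GRanges(),
               segmentSeqs = Biostrings::DNAStringSet(),
               log = vres$log))

  tab <- data.table::rbindlist(lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)), fill = TRUE)
  tab <- as.data.frame(tab)

  ## ---- functionality -----------------------------------------------------
  tab$functionality <- vapply(seq_len(nrow(tab)), function(i)
    classifyFunctionality(splitDefects(tab$defects[i]), tab$gene_type[i],
                          tab$chain[i], strictConserved), "")

  ## ---- subgroups & names -------------------------------------------------
  tab$subgroup <- NA_integer_
  vSel <- which(tab$gene_type == "V")
  if (length(vSel) > 0L) {
    vSeqs <- vapply(vSel, function(i) {
      f <- featRows[vapply(featRows, function(x)
        x$parentIdx == i && x$feature == "V_REGION", logical(1L))]
      s <- substr(seqchar, f[[1L]]$start, f[[1L]]$end)
      if (tab$strand[i] == "-") revComp(s) else s
    }, "")
    axis <- if (orientation == "-") -tab$start[vSel] else tab$start[vSel]
    ord <- order(axis)
    idm <- identityMatrix(setNames(vSeqs[ord], seq_along(ord)))
    sg <- clusterSubgroups(idm, threshold = subgroupThreshold)
    tab$subgroup[vSel[ord]] <- sg
    tab$vRegionSeq <- NA_character_
    tab$vRegionSeq[vSel] <- vSeqs
  }

  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(tab$start, tab$end), strand = tab$strand)
  mc <- tab[, setdiff(colnames(tab), c("start", "end", "strand")),
            drop = FALSE]
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(mc)
  tracStart <- if (!is.na(tracName) && any(tab$gene_type == "C" &
                                           !is.na(tab$cname) &
                                           tab$cname == tracName))
    tab$start[tab$gene_type == "C" & !is.na(tab$cname) &
                tab$cname == tracName][1L] else NA_integer_
  gr$name <- assignNames(gr, orientation, tracStart)

  ft <- do.call(rbind, featRows)
  fgr <- GenomicRanges::GRanges(
    seqnames = contig, ranges = IRanges::IRanges(ft$start, ft$end),
    strand = ft$strand)
  fgr$feature <- ft$feature
  fgr$Parent <- gr$name[ft$parentIdx]

  segs <- setNames(unlist(segs), gr$name)
  new("TRAnnotation", genes = gr, features = fgr,
      segmentSeqs = Biostrings::DNAStringSet(segs), log = vres$log)
}

#' Constant-region query sequences of a germline set
#'
#' Convenience accessor: the spliced coding sequences of the TRAC and TRDC
#' genes of a (typically simulated) germline set, for use as
#' [annotateLocus()] queries.
#'
#' @param germline a [GermlineSet-class].
#' @return a named `DNAStringSet`.
#' @export
constantQueries <- function(germline) {
  gd <- germline@geneData
  sel <- which(gd$type == "C")
  out <- germline@segmentSeqs[sel]
  names(out) <- gd$name[sel]
  out
}
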