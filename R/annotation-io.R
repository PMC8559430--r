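# Annotation serialization: GFF3 + per-class FASTA + census TSV.

#' Write an annotation to disk
#'
#' Emits `annotation.gff3` (gene and sub-feature records, 1-based
#' inclusive coordinates, functionality and defect attributes), one FASTA
#' per gene class with functionality and coordinates in the headers, and a
#' Table-1-style subgroup census TSV.
#'
#' @param ann a [TRAnnotation-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeAnnotation <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(dir, "annotation.gff3")
  genes <- ann@genes
  paths <- gff
  if (length(genes)) {
    g1 <- genes
    mc <- S4Vectors::mcols(g1)
    keep <- c("name", "gene_type", "chain", "functionality", "defects",
              "subgroup")
    S4Vectors::mcols(g1) <- mc[, intersect(keep, colnames(mc)),
                               drop = FALSE]
    g1$type <- "gene"
    g1$ID <- g1$name
    f1 <- ann@features
    f1$type <- f1$feature
    f1$feature <- NULL
    rtracklayer::export(c(GenomicRanges::granges(g1, use.mcols = TRUE)[
      , c("type", "ID", "name", "gene_type", "chain", "functionality",
          "defects", "subgroup")],
      GenomicRanges::granges(f1, use.mcols = TRUE)), gff, format = "gff3")
  } else {
    writeLines("##gff-version 3", gff)
  }
  gt <- geneTable(ann)
  for (cls in intersect(c("V", "J", "D", "C"), unique(gt$gene_type))) {
    sel <- which(gt$gene_type == cls)
    fa <- file.path(dir, sprintf("genes_%s.fasta", cls))
    hdr <- sprintf("%s|%s|%s:%d-%d(%s)", gt$name[sel],
                   gt$functionality[sel],
                   as.character(GenomicRanges::seqnames(gt))[sel],
                   GenomicRanges::start(gt)[sel],
                   GenomicRanges::end(gt)[sel],
                   as.character(GenomicRanges::strand(gt))[sel])
    seqs <- as.character(ann@segmentSeqs[gt$name[sel]])
    writeLines(paste0(">", hdr, "\n", seqs), fa)
    paths <- c(paths, fa)
  }
  cen <- subgroupCensus(ann)
  cp <- file.path(dir, "subgroup_census.tsv")
  utils::write.table(cen, cp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, cp))
}

#' Read back an annotation GFF3
#'
#' Reconstructs the gene-level `GRanges` (with typed metadata columns)
#' from a file written by [writeAnnotation()].
#'
#' @param path GFF3 path.
#' @return list with `genes` and `features` `GRanges`.
#' @export
readAnnotationGFF <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  feats <- gr[gr$type != "gene"]
  out <- GenomicRanges::granges(genes)
  out$name <- as.character(genes$name)
  out$gene_type <- as.character(genes$gene_type)
  out$chain <- as.character(genes$chain)
  out$functionality <- as.character(genes$functionality)
  out$defects <- as.character(genes$defects)
  out$defects[is.na(out$defects)] <- ""
  out$subgroup <- suppressWarnings(as.integer(genes$subgroup))
  f <- GenomicRanges::granges(feats)
  f$feature <- as.character(feats$type)
  list(genes = out, features = f)
}

#' Subgroup census table (Table-1 shape)
#'
#' Per V subgroup: gene counts by functionality and the CDR length
#' triplets (`[cdr1.cdr2.cdr3]`) observed among its F/ORF members.
#'
#' @param ann a [TRAnnotation-class].
#' @return data.frame with one row per subgroup.
#' @export
subgroupCensus <- function(ann) {
  gt <- geneTable(ann)
  sel <- gt$gene_type == "V"
  if (!any(sel))
    return(data.frame(subgroup = integer(), nF = integer(),
                      nORF = integer(), nP = integer(),
                      cdrTriplets = character()))
  df <- data.frame(subgroup = gt$subgroup[sel],
                   functionality = gt$functionality[sel],
                   cdr1 = gt$cdr1[sel], cdr2 = gt$cdr2[sel],
                   cdr3 = gt$cdr3[sel])
  sgs <- sort(unique(df$subgroup))
  out <- lapply(sgs, function(s) {
    d <- df[df$subgroup == s, ]
    fo <- d[d$functionality %in% c("F", "ORF"), ]
    trip <- unique(sprintf("[%d.%d.%d]", fo$cdr1, fo$cdr2, fo$cdr3))
    data.frame(subgroup = s, nF = sum(d$functionality == "F"),
               nORF = sum(d$functionality == "ORF"),
               nP = sum(d$functionality == "P"),
               cdrTriplets = paste(trip, collapse = " "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
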