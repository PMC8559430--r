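# Figure rendering. Figures are pure views: every plotted value is written
# as TSV by the stage that computed it before any image is drawn.

#' Locus ideogram
#'
#' Draws annotated genes as oriented glyphs along the contig, colored by
#' functionality, one track per gene type.
#'
#' @param genes gene-level `GRanges` (from [geneTable()] or
#'   [readAnnotationGFF()]).
#' @return a ggplot object.
#' @export
locusIdeogram <- function(genes) {
  df <- data.frame(start = GenomicRanges::start(genes),
                   end = GenomicRanges::end(genes),
                   strand = as.character(GenomicRanges::strand(genes)),
                   type = genes$gene_type,
                   functionality = genes$functionality)
  df$y <- match(df$type, c("V", "J", "D", "C"))
  df$mid <- (df$start + df$end) / 2
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = ifelse(strand == "+", start, end),
      xend = ifelse(strand == "+", end, start),
      y = y, yend = y, colour = functionality),
      arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt")),
      linewidth = 2) +
    ggplot2::scale_y_continuous(breaks = 1:4,
                                labels = c("V", "J", "D", "C"),
                                limits = c(0.5, 4.5)) +
    ggplot2::scale_colour_manual(values = c(F = "#c0392b",
                                            ORF = "#e67e22",
                                            P = "#7f8c8d")) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = "TRA/TRD locus map") +
    ggplot2::theme_minimal()
}

#' Distance heatmap
#' @param d symmetric distance matrix.
#' @param file PNG path.
#' @return invisibly, `file`.
#' @export
distanceHeatmap <- function(d, file) {
  grDevices::png(file, width = 1200, height = 1100, res = 130)
  pheatmap::pheatmap(d, cluster_rows = TRUE, cluster_cols = TRUE,
                     main = "Poisson pairwise distances")
  grDevices::dev.off()
  invisible(file)
}

#' V x J usage heatmap
#' @param mat numeric matrix (V x J), e.g. one sample slice of a
#'   [UsageProfile-class] normalized matrix.
#' @param file PNG path.
#' @param main title.
#' @return invisibly, `file`.
#' @export
usageHeatmap <- function(mat, file, main = "V x J usage (log2)") {
  grDevices::png(file, width = 1400, height = 1100, res = 130)
  pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE,
                     main = main)
  grDevices::dev.off()
  invisible(file)
}

#' Render figures for a pipeline run directory
#'
#' Reads the TSV artifacts already present in the run directory and draws
#' the locus ideogram, the distance heatmap and the usage heatmaps.
#' Missing inputs skip the corresponding figure with a note.
#'
#' @param runDir run directory of [runPipeline()].
#' @param ann optional in-memory [TRAnnotation-class] (avoids re-reading).
#' @return character vector of figure paths written.
#' @export
renderReports <- function(runDir, ann = NULL) {
  figDir <- file.path(runDir, "figures")
  dir.create(figDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  gff <- file.path(runDir, "annotate", "annotation.gff3")
  genes <- if (!is.null(ann)) geneTable(ann) else if (file.exists(gff))
    readAnnotationGFF(gff)$genes else NULL
  if (!is.null(genes) && length(genes)) {
    p <- file.path(figDir, "locus_map.png")
    grDevices::png(p, width = 1600, height = 700, res = 130)
    print(locusIdeogram(genes))
    grDevices::dev.off()
    paths <- c(paths, p)
  } else message("report: no annotation; locus map skipped")
  dtsv <- file.path(runDir, "phylo", "poisson_distances.tsv")
  if (file.exists(dtsv)) {
    d <- as.matrix(utils::read.table(dtsv, sep = "\t", header = TRUE,
                                     row.names = 1, check.names = FALSE))
    paths <- c(paths, distanceHeatmap(d, file.path(figDir,
                                                   "distance_heatmap.png")))
  } else message("report: no distance matrix; heatmap skipped")
  ntsv <- file.path(runDir, "repertoire", "vj_normalized_log2.tsv")
  if (file.exists(ntsv)) {
    m <- as.matrix(utils::read.table(ntsv, sep = "\t", header = TRUE,
                                     row.names = 1, check.names = FALSE))
    p <- file.path(figDir, "usage_heatmap.png")
    if (nrow(m) && !all(is.na(m))) {
      vj <- do.call(rbind, strsplit(rownames(m), "|", fixed = TRUE))
      mat <- matrix(m[, 1L], nrow = length(unique(vj[, 1L])),
                    dimnames = list(unique(vj[, 1L]), unique(vj[, 2L])))
      paths <- c(paths, usageHeatmap(mat, p))
    } else {
      grDevices::png(p, width = 600, height = 400)
      graphics::plot.new(); graphics::title("empty usage matrix")
      grDevices::dev.off()
      paths <- c(paths, p)
    }
  } else message("report: no usage matrix; heatmap skipped")
  paths
}
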