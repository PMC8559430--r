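# Subgroup clustering at the 75% V-REGION identity threshold, ortholog
# mapping between assemblies, and IMGT-style nomenclature.

#' Cluster V genes into subgroups at an identity threshold
#'
#' Single-linkage connected components of the graph whose edges join genes
#' with pairwise identity greater than or equal to `threshold` (the
#' boundary value itself joins, i.e. exactly 75.0 is the same subgroup).
#' Subgroups are numbered by the first member's position in the row order
#' of the matrix, which callers should arrange to be the locus order.
#'
#' @param idMat symmetric percent-identity matrix (rows in locus order).
#' @param threshold percent identity threshold (default 75).
#' @param linkage `"single"` (default) or `"complete"`.
#' @return integer vector of subgroup ids, one per row of `idMat`.
#' @export
clusterSubgroups <- function(idMat, threshold = 75, linkage = c("single",
                                                                "complete")) {
  linkage <- match.arg(linkage)
  n <- nrow(idMat)
  if (n == 0L) return(integer())
  if (linkage == "single") {
    adj <- idMat >= threshold
    comp <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (!is.na(comp[i])) next
      queue <- i
      comp[i] <- i
      while (length(queue)) {
        v <- queue[[1L]]; queue <- queue[-1L]
        nb <- which(adj[v, ] & is.na(comp))
        comp[nb] <- i
        queue <- c(queue, nb)
      }
    }
  } else {
    d <- stats::as.dist(100 - idMat)
    hc <- stats::hclust(d, method = "complete")
    comp <- stats::cutree(hc, h = 100 - threshold)
    comp <- match(comp, comp)   # representative = first member
  }
  ## renumber by first occurrence along the row (locus) order
  match(comp, unique(comp))
}

#' Map orthologous genes between two assemblies
#'
#' Greedy mutual best-identity matching above `threshold`: the highest
#' remaining cross-identity pair is matched until no pair clears the
#' threshold. Unmatched genes are reported; a gene whose best counterpart
#' was already consumed by a better match (a duplication signature) is
#' flagged `"duplicate"`.
#'
#' @param seqsA,seqsB named character vectors or `DNAStringSet`s.
#' @param threshold percent identity floor for a match (default 90).
#' @return a data.frame with columns `geneA`, `geneB`, `identity`,
#'   `status` (`matched`, `duplicate`, `unmatched`); unmatched genes of
#'   either set appear with `NA` in the opposite column.
#' @export
mapOrthologs <- function(seqsA, seqsB, threshold = 90) {
  seqsA <- asNamedCharacter(seqsA); seqsB <- asNamedCharacter(seqsB)
  nA <- length(seqsA); nB <- length(seqsB)
  m <- matrix(NA_real_, nA, nB, dimnames = list(names(seqsA), names(seqsB)))
  for (i in seq_len(nA)) for (j in seq_len(nB))
    m[i, j] <- pairwiseIdentity(seqsA[[i]], seqsB[[j]])
  bestOfA <- apply(m, 1L, max)
  rows <- list()
  usedA <- logical(nA); usedB <- logical(nB)
  work <- m
  repeat {
    if (!any(is.finite(work)) || max(work, na.rm = TRUE) < threshold) break
    ij <- which(work == max(work, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    rows[[length(rows) + 1L]] <- data.frame(
      geneA = rownames(m)[ij[1L]], geneB = colnames(m)[ij[2L]],
      identity = m[ij[1L], ij[2L]], status = "matched",
      stringsAsFactors = FALSE)
    usedA[ij[1L]] <- TRUE; usedB[ij[2L]] <- TRUE
    work[ij[1L], ] <- NA_real_; work[, ij[2L]] <- NA_real_
  }
  for (i in which(!usedA))
    rows[[length(rows) + 1L]] <- data.frame(
      geneA = rownames(m)[i], geneB = NA_character_,
      identity = bestOfA[i],
      status = if (bestOfA[i] >= threshold) "duplicate" else "unmatched",
      stringsAsFactors = FALSE)
  for (j in which(!usedB))
    rows[[length(rows) + 1L]] <- data.frame(
      geneA = NA_character_, geneB = colnames(m)[j],
      identity = max(m[, j]),
      status = if (max(m[, j]) >= threshold) "duplicate" else "unmatched",
      stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign IMGT-style names to annotated genes
#'
#' V genes are named `TRAV<subgroup>-<rank>` with the rank counted within
#' the subgroup along the locus 5'->3' transcriptional orientation (defined
#' by the constant-gene strand); single-gene subgroups drop the rank
#' suffix. TRAJ genes are numbered ascending from the TRAC-proximal gene
#' (TRAJ1), TRDD genes from the locus 5' end (TRDD1), the TRDJ gene is
#' TRDJ1.
#'
#' @param genes a `GRanges` of gene spans with mcols `gene_type`, `chain`
#'   and (for V) `subgroup`.
#' @param orientation locus orientation: `"+"` or `"-"` strand of the
#'   constant genes on the contig.
#' @param tracStart genomic start of the TRAC gene (used to order TRAJ).
#' @return character vector of names aligned with `genes`.
#' @export
assignNames <- function(genes, orientation, tracStart = NA_integer_) {
  name <- rep(NA_character_, length(genes))
  pos <- GenomicRanges::start(genes)
  ## position along the locus 5'->3' axis
  axis <- if (orientation == "-") -pos else pos

  vSel <- which(genes$gene_type == "V")
  if (length(vSel)) {
    ord <- rank(axis[vSel])
    name[vSel] <- vdjNames(genes$subgroup[vSel], ord, prefix = "TRAV")
  }
  jaSel <- which(genes$gene_type == "J" & genes$chain == "TRA")
  if (length(jaSel)) {
    ## TRAJ1 is the closest to TRAC
    dist <- abs(pos[jaSel] - tracStart)
    name[jaSel] <- paste0("TRAJ", rank(dist))
  }
  jdSel <- which(genes$gene_type == "J" & genes$chain == "TRD")
  if (length(jdSel))
    name[jdSel] <- paste0("TRDJ", rank(axis[jdSel]))
  dSel <- which(genes$gene_type == "D")
  if (length(dSel))
    name[dSel] <- paste0("TRDD", rank(axis[dSel]))
  cSel <- which(genes$gene_type == "C")
  if (length(cSel)) name[cSel] <- genes$cname[cSel] %||%
    paste0("TRC", seq_along(cSel))
  if (anyDuplicated(stats::na.omit(name)))
    stop("name collision while assigning gene names")
  name
}
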