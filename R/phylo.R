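# Poisson-corrected amino-acid distances, neighbor-joining trees and
# bootstrap supports over V protein sequences.

#' Poisson-corrected distance between two aligned amino-acid sequences
#'
#' Sites where either sequence has a gap are excluded (pairwise deletion);
#' with `p` the proportion of differing compared sites, the distance is
#' `d = -ln(1 - p)` substitutions per site.
#'
#' @param a,b equal-length aligned amino-acid strings (gaps `-` or `.`).
#' @return numeric distance; `Inf` (with a warning) when `p >= 1`.
#' @examples
#' poissonDistance("ACDEFGHI", "ACDEFGHI")        # 0
#' round(poissonDistance("AAAA", "AACC"), 4)       # -ln(0.5)
#' @export
poissonDistance <- function(a, b) {
  a <- strsplit(as.character(a), "")[[1L]]
  b <- strsplit(as.character(b), "")[[1L]]
  stopifnot(length(a) == length(b))
  gap <- a %in% c("-", ".") | b %in% c("-", ".")
  a <- a[!gap]; b <- b[!gap]
  if (!length(a)) stop("no comparable (gap-free) sites")
  p <- mean(a != b)
  if (p >= 1) {
    warning("saturated distance: all compared sites differ")
    return(Inf)
  }
  -log(1 - p)
}

#' Poisson distance matrix over an alignment
#'
#' @param aln named character vector or `AAStringSet` of equal-length
#'   aligned sequences.
#' @return symmetric numeric matrix (substitutions per site).
#' @export
poissonDistMatrix <- function(aln) {
  aln <- asNamedCharacter(aln)
  n <- length(aln)
  m <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L))
    for (j in seq(i + 1L, n))
      m[i, j] <- m[j, i] <- poissonDistance(aln[[i]], aln[[j]])
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \code{\link[ape]{nj}}); negative branch
#' lengths arising from non-additive inputs are clamped to zero with a
#' warning. Exact on additive matrices.
#'
#' @param d symmetric numeric distance matrix (>= 3 taxa, finite).
#' @return an [ape::phylo] tree (unrooted).
#' @export
njTree <- function(d) {
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(d))) stop("undefined distances present")
  tree <- ape::nj(stats::as.dist(d))
  if (any(tree$edge.length < 0)) {
    warning("negative branch lengths clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-distance NJ tree for each replicate and reports, for every
#' internal edge of the original tree, the percentage of replicate trees
#' containing the same bipartition (stored in `node.label`).
#'
#' @param aln named character vector or `AAStringSet` of aligned sequences.
#' @param nReps number of bootstrap replicates (default 500).
#' @param seed RNG seed.
#' @return list with `tree` (the original-tree [ape::phylo], `node.label`
#'   set to support percentages) and `supports` (numeric vector).
#' @export
bootstrapSupport <- function(aln, nReps = 500L, seed = 1L) {
  aln <- asNamedCharacter(aln)
  stopifnot(length(aln) >= 3L)
  cols <- nchar(aln[[1L]])
  mat <- do.call(rbind, strsplit(aln, ""))
  rownames(mat) <- names(aln)
  tree <- njTree(poissonDistMatrix(aln))
  reps <- withSeed(seed, lapply(seq_len(nReps), function(r) {
    idx <- sample.int(cols, cols, replace = TRUE)
    sub <- apply(mat[, idx, drop = FALSE], 1L, paste0, collapse = "")
    ## routine in replicates: clamp warnings are display conventions
    suppressWarnings(njTree(poissonDistMatrix(sub)))
  }))
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- 100 * counts / nReps
  tree$node.label <- round(supports, 1)
  list(tree = tree, supports = supports)
}

#' Bootstrap support of a specific leaf set
#'
#' Percentage of bootstrap agreement for the bipartition separating `taxa`
#' from the remaining leaves, read off a [bootstrapSupport()] result (0 if
#' the original tree does not contain that bipartition).
#'
#' @param boot result of [bootstrapSupport()].
#' @param taxa character vector of tip labels.
#' @return numeric support percentage, or `NA` if the split is absent.
#' @export
cladeSupport <- function(boot, taxa) {
  tree <- boot$tree
  if (!all(taxa %in% tree$tip.label)) return(NA_real_)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  want <- sort(match(taxa, labs))
  all_ <- seq_along(labs)
  for (k in seq_along(parts)) {
    p <- sort(parts[[k]])
    if (identical(p, want) || identical(sort(setdiff(all_, p)), want)) {
      node <- length(tree$tip.label) + k
      ## prop.part order matches internal node order used by prop.clades
      return(boot$supports[k])
    }
  }
  NA_real_
}

#' Simple center-star progressive protein aligner
#'
#' Aligns every sequence to a center sequence (the one of median length)
#' with global pairwise alignments and merges the induced gap patterns.
#' Intended for closely related V-domain sets (synthetic tests); any
#' externally produced alignment can be supplied to the distance/tree
#' functions instead.
#'
#' @param seqs named character vector or `AAStringSet`.
#' @return named character vector of equal-length aligned sequences.
#' @export
alignProteins <- function(seqs) {
  seqs <- asNamedCharacter(seqs)
  n <- length(seqs)
  if (n == 1L) return(seqs)
  center <- order(nchar(seqs))[(n + 1L) %/% 2L]
  cseq <- seqs[[center]]
  clen <- nchar(cseq)
  alns <- lapply(seqs, function(s) {
    a <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(s), Biostrings::AAString(cseq),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
      type = "global")
    list(p = strsplit(as.character(Biostrings::pattern(a)), "")[[1L]],
         s = strsplit(as.character(Biostrings::subject(a)), "")[[1L]])
  })
  ## insertion capacity before each center position (and after the last)
  ins <- integer(clen + 1L)
  for (a in alns) {
    cpos <- 1L; run <- 0L
    for (k in seq_along(a$s)) {
      if (a$s[k] == "-") run <- run + 1L
      else {
        ins[cpos] <- max(ins[cpos], run)
        run <- 0L; cpos <- cpos + 1L
      }
    }
    ins[clen + 1L] <- max(ins[clen + 1L], run)
  }
  width <- sum(ins) + clen
  out <- vapply(alns, function(a) {
    res <- character(0L)
    cpos <- 1L; buf <- character(0L)
    flush <- function(cap, buf) c(buf, rep("-", cap - length(buf)))
    for (k in seq_along(a$s)) {
      if (a$s[k] == "-") buf <- c(buf, a$p[k])
      else {
        res <- c(res, flush(ins[cpos], buf), a$p[k])
        buf <- character(0L); cpos <- cpos + 1L
      }
    }
    res <- c(res, flush(ins[clen + 1L], buf))
    paste0(res, collapse = "")
  }, "")
  stopifnot(all(nchar(out) == width))
  names(out) <- names(seqs)
  out
}

#' Write a distance matrix in square PHYLIP format
#' @param d numeric matrix with dimnames.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
writePhylipDist <- function(d, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(sprintf("%-10s", rownames(d)[i]),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  invisible(file)
}
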