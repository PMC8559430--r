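# FLASH-style overlap merging of read pairs.

#' Merge paired-end reads by overlap
#'
#' For each pair, all overlap lengths of at least `minOverlap` are scanned
#' and the overlap with the lowest mismatch fraction (ties: longest) is
#' chosen; pairs whose best overlap exceeds `maxMismFrac` mismatches are
#' dropped. Disagreeing overlap bases are resolved toward the mate whose
#' flanking non-overlap segment is longer. Merged reads not longer than
#' `minLen` are discarded and counted.
#'
#' @param r1,r2 named character vectors of read sequences (R2 in sequencing
#'   orientation; it is reverse-complemented internally), or paths to FASTQ
#'   files. Ids must match pairwise.
#' @param minLen minimum merged length retained (exclusive; default 150).
#' @param minOverlap minimum overlap length (default 10).
#' @param maxMismFrac maximum mismatch fraction in the overlap (default
#'   0.25).
#' @param sample optional sample label prepended to read ids.
#' @return list with `merged` (data.frame: id, sample, seq, length,
#'   overlap, mismatches) and `dropped` (data.frame: id, reason; reasons
#'   `no_overlap` or `too_short`).
#' @export
mergePairs <- function(r1, r2, minLen = 150L, minOverlap = 10L,
                       maxMismFrac = 0.25, sample = NULL) {
  if (is.character(r1) && length(r1) == 1L && file.exists(r1)) {
    r1 <- readFastqSeqs(r1)
    r2 <- readFastqSeqs(r2)
  }
  if (length(r1) != length(r2)) stop("unequal read counts in the two files")
  if (!is.null(names(r1)) && !is.null(names(r2)) &&
      !identical(names(r1), names(r2)))
    stop("read id mismatch between mates")
  ids <- names(r1) %||% sprintf("read%06d", seq_along(r1))
  if (!is.null(sample) &&
      !all(startsWith(ids, paste0(sample, "|")) |
             startsWith(ids, paste0(sample, "_"))))
    ids <- paste0(sample, "|", ids)
  r2rc <- vapply(unname(r2), revComp, "", USE.NAMES = FALSE)
  mergedRows <- vector("list", length(r1))
  dropRows <- list()
  for (i in seq_along(r1)) {
    m <- .mergePair(r1[[i]], r2rc[[i]], as.integer(minOverlap), maxMismFrac)
    if (is.na(m$merged)) {
      dropRows[[length(dropRows) + 1L]] <- data.frame(
        id = ids[i], reason = "no_overlap", stringsAsFactors = FALSE)
    } else if (nchar(m$merged) <= minLen) {
      dropRows[[length(dropRows) + 1L]] <- data.frame(
        id = ids[i], reason = "too_short", stringsAsFactors = FALSE)
    } else {
      mergedRows[[i]] <- data.frame(
        id = ids[i], seq = m$merged, length = nchar(m$merged),
        overlap = m$overlap, mismatches = m$mismatches,
        stringsAsFactors = FALSE)
    }
  }
  merged <- do.call(rbind, mergedRows[!vapply(mergedRows, is.null,
                                              logical(1L))])
  if (is.null(merged))
    merged <- data.frame(id = character(), seq = character(),
                         length = integer(), overlap = integer(),
                         mismatches = integer())
  merged$sample <- if (is.null(sample)) sub("\\|.*$", "", merged$id) else
    sample
  dropped <- if (length(dropRows)) do.call(rbind, dropRows) else
    data.frame(id = character(), reason = character())
  list(merged = merged, dropped = dropped)
}

## minimal FASTQ reader (qualities ignored throughout the pipeline)
readFastqSeqs <- function(path) {
  lines <- readLines(path)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1L, length(lines), 4L)]))
  seqs <- lines[seq(2L, length(lines), 4L)]
  setNames(seqs, ids)
}
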