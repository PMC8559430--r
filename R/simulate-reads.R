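# Simulated 5'-RACE repertoire read pairs. Each amplicon is
#   spliced leader + V-REGION (3' trimmed) + N nucleotides + J-REGION
#   (5' trimmed) + the 5' part of the constant exon 1 up to the end of the
#   constant-primer site.
# Productivity is controlled by construction: productive reads receive an
# N-insert length that keeps the J (and hence C) reading frame in phase
# with the V frame and a junction free of stop codons; unproductive reads
# are frameshifted or carry an in-frame junction stop.

#' Uniform V x J usage weights over the functional genes of a germline set
#'
#' @param germline a [GermlineSet-class].
#' @return numeric matrix summing to 1, dimnames = functional TRAV / TRAJ
#'   gene names.
#' @export
uniformUsage <- function(germline) {
  gd <- as.data.frame(germline@geneData)
  v <- gd$name[gd$type == "V" & gd$functionality == "F"]
  j <- gd$name[gd$type == "J" & gd$chain == "TRA" & gd$functionality == "F"]
  stopifnot(length(v) > 0L, length(j) > 0L)
  matrix(1 / (length(v) * length(j)), length(v), length(j),
         dimnames = list(v, j))
}

#' Simulate constant-primed repertoire read pairs
#'
#' Draws V-J combinations from `usageWeights` (multinomial), builds
#' amplicons with uniform junction trimming and N addition, plants the
#' requested productive fraction exactly (by frame and stop control at the
#' junction), extracts overlapping read pairs of `readLength` and applies
#' per-base substitution errors. Qualities are constant.
#'
#' @param germline a [GermlineSet-class] containing at least one functional
#'   V, J and the TRAC gene.
#' @param spec a [RepertoireSpec()]; row/column names of its `usageWeights`
#'   must name genes of `germline`.
#' @param sample sample label recorded in read ids and the truth table.
#' @return list with `r1`, `r2` (named character vectors of read
#'   sequences), `truth` (data.frame: id, v, j, trimV, trimJ, nIns,
#'   productive, ampliconLength), and `amplicons` (character).
#' @export
simulateRepertoireReads <- function(germline, spec, sample = "sample1") {
  validObject(spec)
  gd <- as.data.frame(germline@geneData)
  segs <- as.character(germline@segmentSeqs)
  vNames <- rownames(spec@usageWeights)
  jNames <- colnames(spec@usageWeights)
  if (!all(c(vNames, jNames) %in% gd$name))
    stop("usageWeights name genes absent from the germline set")

  ## V unit: spliced leader + V-REGION; the stored V segment is exactly that
  vSeqs <- segs[vNames]
  jSeqs <- segs[jNames]
  cSeq <- segs[["TRAC"]]
  cFeat <- germline@features[["TRAC"]]
  ## amplicon C part: exon 1 up to the primer-site end
  primerEnd <- as.integer(regexpr(revComp(GSP1_PRIMER), cSeq, fixed = TRUE))
  if (primerEnd < 0L) stop("TRAC gene lacks the constant primer site")
  cPart <- substr(cSeq, 1L, primerEnd + nchar(GSP1_PRIMER) - 1L)

  withSeed(spec@seed, .simulateReads(spec, vSeqs, jSeqs, cPart, sample))
}

.simulateReads <- function(spec, vSeqs, jSeqs, cPart, sample) {
  n <- spec@nReads
  w <- as.vector(spec@usageWeights)
  cells <- arrayInd(sample.int(length(w), n, replace = TRUE, prob = w),
                    dim(spec@usageWeights))
  vDraw <- rownames(spec@usageWeights)[cells[, 1L]]
  jDraw <- colnames(spec@usageWeights)[cells[, 2L]]
  nProd <- round(spec@productiveFraction * n)
  prodFlag <- shuffleVec(c(rep(TRUE, nProd), rep(FALSE, n - nProd)))

  r1 <- character(n); r2 <- character(n); amp <- character(n)
  tv <- integer(n); tj <- integer(n); ni <- integer(n)
  RL <- spec@readLength
  for (i in seq_len(n)) {
    v <- vSeqs[[vDraw[i]]]; j <- jSeqs[[jDraw[i]]]
    a <- .buildAmplicon(v, j, cPart, spec@junctionTrimMax,
                        spec@nAdditionMax, prodFlag[i])
    amp[i] <- a$seq; tv[i] <- a$trimV; tj[i] <- a$trimJ; ni[i] <- a$nIns
    len <- nchar(a$seq)
    if (2L * RL - len < 10L)
      stop("read_length too short to cover the amplicon with overlap")
    r1[i] <- substr(a$seq, 1L, min(RL, len))
    r2[i] <- revComp(substr(a$seq, max(1L, len - RL + 1L), len))
  }
  if (spec@errorRate > 0) {
    r1 <- vapply(r1, .addErrors, "", rate = spec@errorRate,
                 USE.NAMES = FALSE)
    r2 <- vapply(r2, .addErrors, "", rate = spec@errorRate,
                 USE.NAMES = FALSE)
  }
  ids <- sprintf("%s_read%06d", sample, seq_len(n))
  names(r1) <- names(r2) <- names(amp) <- ids
  list(r1 = r1, r2 = r2, amplicons = amp,
       truth = data.frame(id = ids, sample = sample, v = vDraw, j = jDraw,
                          trimV = tv, trimJ = tj, nIns = ni,
                          productive = prodFlag,
                          ampliconLength = nchar(amp),
                          stringsAsFactors = FALSE))
}

## Local alignments of the germline segments against the read must end
## exactly at the trimmed segment boundaries: a junction whose bases extend
## a segment alignment with net-positive score (match +2 / mismatch -3, the
## blastn defaults) would be indistinguishable from a shorter trim and
## would drag the reported identity below the exact-match filter. Such
## junctions are redrawn.
.extendsBoundary <- function(readFlank, refFlank) {
  n <- min(nchar(readFlank), nchar(refFlank))
  if (n == 0L) return(FALSE)
  a <- utf8ToInt(substr(readFlank, 1L, n))
  b <- utf8ToInt(substr(refFlank, 1L, n))
  cum <- cumsum(ifelse(a == b, 2L, -3L))
  any(cum > 0L)
}

## Frame bookkeeping: the V unit length is 0 mod 3 (codon-complete leader +
## V-REGION), the J-REGION is frame 0 and 0 mod 3 so the C exon continues
## in phase. A junction is in frame iff nIns = (trimV + trimJ) mod 3.
.buildAmplicon <- function(v, j, cPart, trimMax, nMax, productive) {
  boundaryClean <- function(vPart, ins, jPart, tV, tJ) {
    ## J alignment extending 5' past the junction (reversed comparison)
    left <- paste0(vPart, ins)
    revstr <- function(x) paste(rev(strsplit(x, "")[[1L]]), collapse = "")
    jCut <- substr(j, 1L, tJ)
    ok1 <- !.extendsBoundary(revstr(substr(left,
                                           max(1L, nchar(left) - tJ + 1L),
                                           nchar(left))),
                             revstr(jCut))
    ## V alignment extending 3' past the junction
    right <- paste0(ins, jPart)
    vCut <- substr(v, nchar(v) - tV + 1L, nchar(v))
    ok2 <- !.extendsBoundary(substr(right, 1L, tV), vCut)
    ok1 && ok2
  }
  for (tries in 1:100) {
    tV <- sample.int(trimMax + 1L, 1L) - 1L
    tJ <- sample.int(trimMax + 1L, 1L) - 1L
    vPart <- substr(v, 1L, nchar(v) - tV)
    jPart <- substr(j, tJ + 1L, nchar(j))
    need <- (tV + tJ) %% 3L
    feas <- seq(0L, nMax)
    inFrame <- feas[feas %% 3L == need]
    outFrame <- feas[feas %% 3L != need]
    if (productive) {
      if (!length(inFrame)) next
      a <- inFrame[sample.int(length(inFrame), 1L)]
      ins <- if (a > 0L) randomDNA(a) else ""
      body <- paste0(vPart, ins, jPart, cPart)
      if (!hasInFrameStop(body) &&
          boundaryClean(vPart, ins, jPart, tV, tJ)) {
        return(list(seq = body, trimV = tV, trimJ = tJ, nIns = a))
      }
    } else {
      mode <- sample(c("shift", "stop"), 1L)
      if (mode == "shift" && length(outFrame)) {
        a <- outFrame[sample.int(length(outFrame), 1L)]
        ins <- if (a > 0L) randomDNA(a) else ""
        if (!boundaryClean(vPart, ins, jPart, tV, tJ)) next
        return(list(seq = paste0(vPart, ins, jPart, cPart), trimV = tV,
                    trimJ = tJ, nIns = a))
      }
      ## in-frame stop in the junction: place TAA on the first codon
      ## boundary inside the N stretch
      vlen <- nchar(vPart)
      off <- (3L - vlen %% 3L) %% 3L
      aOK <- inFrame[inFrame >= off + 3L]
      if (!length(aOK)) next
      a <- aOK[sample.int(length(aOK), 1L)]
      ins <- paste0(if (off > 0L) randomDNA(off) else "", "TAA",
                    if (a - off - 3L > 0L) randomDNA(a - off - 3L) else "")
      if (!boundaryClean(vPart, ins, jPart, tV, tJ)) next
      return(list(seq = paste0(vPart, ins, jPart, cPart), trimV = tV,
                  trimJ = tJ, nIns = a))
    }
  }
  stop("could not realize junction constraints; check trim/N bounds")
}

.addErrors <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "")[[1L]]
  for (p in pos) chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  paste0(chars, collapse = "")
}

#' Write simulated read pairs as FASTQ
#'
#' Constant quality characters are used (the pipeline never consumes
#' qualities).
#'
#' @param reads result of [simulateRepertoireReads()].
#' @param dir output directory.
#' @param prefix file prefix.
#' @return invisibly, the two FASTQ paths.
#' @export
writeRepertoireFastq <- function(reads, dir, prefix = "sample") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_1.fastq"))
  p2 <- file.path(dir, paste0(prefix, "_2.fastq"))
  wr <- function(seqs, path) {
    qual <- vapply(nchar(seqs), function(k) strrep("I", k), "")
    writeLines(paste0("@", names(seqs), "\n", seqs, "\n+\n", qual), path)
  }
  wr(reads$r1, p1)
  wr(reads$r2, p2)
  invisible(c(p1, p2))
}
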