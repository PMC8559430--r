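# Synthetic germline TR gene generator.
#
# Gene architecture (gene orientation, 5'->3'):
#   V: L-PART1 (ATG..., length = 1 mod 3) | intron (GTAAGT ... ttccAG) |
#      L-PART2 (8/11/14 nt) + V-REGION | V-RS (CACAGTG + 22-23 nt + nonamer)
#   J: J-RS (revcomp nonamer + 11-13 nt + CACTGTG) | J-REGION (FGXG, frame 0)
#      | donor GTAAGT
#   D: 12-type RS | D-REGION | 23-type RS
#   C: 3 exons (phase-0 canonical splice sites), 110 codons + stop
#
# Splice contexts are written with canonical extended consensus motifs and
# local uniqueness guards (no AG inside L-PART2, no in-frame ATG inside
# L-PART1, no spurious AAGT/GTAAG/TTCCA inside introns, no GTAAG or
# off-frame FGXG inside J-REGIONs) so that each planted gene has a unique
# structural interpretation under the annotator's consensus grammar.

RS_HEPTAMER <- "CACAGTG"
RS_NONAMER <- "ACAAAAACC"
DONOR_SITE <- "GTAAGT"
ACCEPTOR_TAIL <- "TTCCTTCCTCTTCCAG"  # 16 nt; AG only at the terminal site
GSP1_PRIMER <- "GATTACGCCAAGCTTGGCAAGCTGTGGTATTGCTTGAGTTC"

## Per-lineage substitution fraction m such that two sequences independently
## mutated from a common source at rate m have expected identity `target`
## (a site matches if both copies kept it or both mutated it to the same of
## the three alternatives). `conservedFrac` sites are never mutated.
solveMutRate <- function(target, conservedFrac = 0) {
  s <- (target - conservedFrac) / (1 - conservedFrac)
  if (s >= 1) return(0)
  if (s <= 1 / 3 + 1e-6)
    stop("infeasible identity constraints: target identity ", target,
         " cannot be generated by independent substitution")
  stats::uniroot(function(w) (1 - w)^2 + w^2 / 3 - s, c(0, 1))$root
}

drawCodons <- function(n, pool = senseCodons()) {
  if (n == 0L) return(character())
  pool[sample.int(length(pool), n, replace = TRUE)]
}

shuffleVec <- function(x) x[sample.int(length(x))]

## Codon table of the V-REGION root: one row per codon with its numbered
## position and region, seeded by back-translating the numbering template.
vRegionRoot <- function(tpl) {
  aa <- strsplit(tpl$aa, "")[[1L]]
  data.frame(codon = unname(BACKTRANSLATE[aa]), pos = tpl$pos,
             region = tpl$region, stringsAsFactors = FALSE)
}

## Resize CDR blocks at codon granularity (subgroup-level structural edits).
editCDRs <- function(tab, cdr1, cdr2, cdr3) {
  resize <- function(tab, region, n) {
    idx <- which(tab$region == region)
    cur <- length(idx)
    if (n < cur) {
      drop <- idx[sample.int(cur, cur - n)]
      tab <- tab[-drop, , drop = FALSE]
    } else if (n > cur) {
      stopifnot(cur > 0L)
      add <- data.frame(codon = drawCodons(n - cur), pos = NA_integer_,
                        region = region, stringsAsFactors = FALSE)
      at <- max(idx)
      rest <- if (at < nrow(tab)) tab[seq(at + 1L, nrow(tab)), ] else NULL
      tab <- rbind(tab[seq_len(at), ], add, rest)
    }
    tab
  }
  tab <- resize(tab, "CDR1", cdr1)
  tab <- resize(tab, "CDR2", cdr2)
  tab <- resize(tab, "CDR3", cdr3)
  rownames(tab) <- NULL
  tab
}

mutateCodon <- function(codon, rate) {
  b <- strsplit(codon, "")[[1L]]
  for (tries in 1:50) {
    nb <- b
    mut <- runif(3L) < rate
    for (i in which(mut)) nb[i] <- sample(setdiff(BASES, b[i]), 1L)
    nc <- paste0(nb, collapse = "")
    if (!nc %in% STOP_CODONS) return(nc)
  }
  codon
}

## Mutate a codon table at per-base `rate`; conserved anchor positions
## (1st-CYS 23, Trp 41, 2nd-CYS 104) are frozen.
mutateTable <- function(tab, rate, freeze = c(23L, 41L, 104L)) {
  frozen <- !is.na(tab$pos) & tab$pos %in% freeze
  tab$codon[!frozen] <- vapply(tab$codon[!frozen], mutateCodon, "",
                               rate = rate)
  tab
}

## L-PART2: no AG dinucleotide (keeps the acceptor unambiguous) and a final
## codon that cannot extend a V-domain alignment leftwards past the true
## V-REGION start (the template begins with Gly; G/A/N/S score >= 0 there)
randomL2 <- function(len) {
  repeat {
    l2 <- randomDNA(len)
    if (grepl("AG", l2)) next
    lastAA <- translateFrame(substr(l2, len - 2L, len), 0L)
    if (!lastAA %in% c("G", "A", "N", "S", "*")) return(l2)
  }
}

## L-PART1: ATG + sense codons free of internal in-frame ATG + one split base
randomL1 <- function(len) {
  stopifnot(len %% 3L == 1L)
  k <- (len - 1L) %/% 3L
  pool <- senseCodons(exclude = "ATG")
  paste0("ATG", paste0(drawCodons(k - 1L, pool), collapse = ""),
         sample(BASES, 1L))
}

## Intron with canonical extended donor/acceptor consensus and uniqueness
## guards: no AAGT besides the donor's own, no GTAAG elsewhere, no TTCCA
## except in the acceptor tail.
randomIntron <- function(len) {
  stopifnot(len >= nchar(DONOR_SITE) + nchar(ACCEPTOR_TAIL) + 4L)
  repeat {
    body <- randomDNA(len - nchar(DONOR_SITE) - nchar(ACCEPTOR_TAIL))
    intron <- paste0(DONOR_SITE, body, ACCEPTOR_TAIL)
    if (identical(allMatches("AAGT", intron), 3L) &&
        identical(allMatches("GTAAG", intron), 1L) &&
        identical(allMatches("TTCCA", intron), len - 5L))
      return(intron)
  }
}

## ---------------------------------------------------------------------------
## Gene builders: each returns list(placed, features, segment) with
## `features` a data.frame of 1-based coordinates relative to `placed`.
## ---------------------------------------------------------------------------

buildVGene <- function(vnt, defect = "none", spacer = 22L) {
  l1len <- sample(c(43L, 46L, 49L, 52L, 55L), 1L)
  l2len <- sample(c(8L, 11L, 14L), 1L)
  intlen <- sample(80:150, 1L)
  repeat {
    l1 <- randomL1(l1len)
    l2 <- randomL2(l2len)
    ## spliced leader (incl. the codon straddling the intron) must be
    ## stop-free; V-REGION codons are controlled upstream
    if (!hasInFrameStop(paste0(l1, l2))) break
  }
  intron <- randomIntron(intlen)
  hept <- RS_HEPTAMER
  if (defect == "rs_defect") hept <- "CACTCTG"   # 2 mismatches past CAC
  if (defect == "splice_defect")                 # acceptor AG -> AC
    substr(intron, intlen, intlen) <- "C"
  sp <- randomDNA(spacer)
  placed <- paste0(l1, intron, l2, vnt, hept, sp, RS_NONAMER)
  vlen <- nchar(vnt)
  f <- data.frame(
    feature = c("L_PART1", "V_INTRON", "L_PART2", "V_REGION", "RSS"),
    from = c(1L, l1len + 1L, l1len + intlen + 1L,
             l1len + intlen + l2len + 1L,
             l1len + intlen + l2len + vlen + 1L),
    to = c(l1len, l1len + intlen, l1len + intlen + l2len,
           l1len + intlen + l2len + vlen,
           l1len + intlen + l2len + vlen + 16L + spacer))
  list(placed = placed, features = f, segment = paste0(l1, l2, vnt))
}

## J-REGION codons with the hallmark motif near the 3' end, reading frame 0.
## Guards: the FG.G regex matches in frame 0 only (and not at all for the
## FGKA variant); no GTAAG inside the region.
buildJRegion <- function(ncod = 19L, motif = "FGSG", stopAt = NA_integer_) {
  at <- ncod - 7L
  motifCod <- unname(BACKTRANSLATE[strsplit(motif, "")[[1L]]])
  repeat {
    cods <- drawCodons(ncod)
    cods[at:(at + 3L)] <- motifCod
    if (!is.na(stopAt)) cods[stopAt] <- "TAA"
    jnt <- paste0(cods, collapse = "")
    aa <- vapply(0:2, function(f)
      gsub("*", "X", translateFrame(jnt, f), fixed = TRUE), "")
    hasMotif <- grepl("FG.G", aa)
    if (grepl("GTAAG", jnt)) next
    if (motif == "FGSG" && (!hasMotif[1L] || any(hasMotif[2:3]))) next
    if (motif == "FGKA" && any(hasMotif)) next
    return(jnt)
  }
}

buildJGene <- function(motif = "FGSG", stopAt = NA_integer_, spacer = 12L) {
  ncod <- sample(18:20, 1L)
  jnt <- buildJRegion(ncod, motif, stopAt)
  sp <- randomDNA(spacer)
  rs <- paste0(revComp(RS_NONAMER), sp, revComp(RS_HEPTAMER))
  placed <- paste0(rs, jnt, DONOR_SITE)
  rslen <- 16L + spacer
  f <- data.frame(feature = c("RSS", "J_REGION"),
                  from = c(1L, rslen + 1L),
                  to = c(rslen, rslen + nchar(jnt)))
  list(placed = placed, features = f, segment = jnt)
}

buildDGene <- function(dlen = 8L) {
  repeat {
    d <- randomDNA(dlen)
    stops <- vapply(0:2, function(f) hasInFrameStop(paste0(d, "AA"), f),
                    logical(1L))
    if (!any(stops)) break
  }
  sp5 <- randomDNA(12L); sp3 <- randomDNA(23L)
  placed <- paste0(revComp(RS_NONAMER), sp5, revComp(RS_HEPTAMER),
                   d, RS_HEPTAMER, sp3, RS_NONAMER)
  f <- data.frame(feature = c("RSS", "D_REGION", "RSS"),
                  from = c(1L, 29L, 29L + dlen),
                  to = c(28L, 28L + dlen, 28L + dlen + 39L))
  list(placed = placed, features = f, segment = d)
}

## Constant gene: 3 phase-0 exons, 110 codons + terminal stop; exon 1 of the
## TRAC homolog carries the constant-primer binding site (reverse complement
## of the gene-specific primer) placed at a stop-free frame offset.
buildCGene <- function(withPrimer = TRUE) {
  site <- revComp(GSP1_PRIMER)  # 41 nt
  repeat {
    e1 <- paste0(drawCodons(40L), collapse = "")
    if (withPrimer)
      e1 <- paste0(substr(e1, 1L, 38L), site, substr(e1, 80L, 120L))
    if (nchar(e1) == 120L && !hasInFrameStop(e1)) break
  }
  e2 <- paste0(drawCodons(40L), collapse = "")
  e3 <- paste0(paste0(drawCodons(30L), collapse = ""), "TGA")
  i1 <- randomIntron(sample(80:120, 1L))
  i2 <- randomIntron(sample(80:120, 1L))
  placed <- paste0(e1, i1, e2, i2, e3)
  b <- cumsum(c(nchar(e1), nchar(i1), nchar(e2), nchar(i2), nchar(e3)))
  f <- data.frame(feature = c("EXON", "EXON", "EXON"),
                  from = c(1L, b[2L] + 1L, b[4L] + 1L),
                  to = c(b[1L], b[3L], b[5L]))
  list(placed = placed, features = f, segment = paste0(e1, e2, e3),
       primerEnd = if (withPrimer) 79L else NA_integer_)
}

## ---------------------------------------------------------------------------
## Germline set
## ---------------------------------------------------------------------------

#' Simulate a ground-truthed germline TR gene set
#'
#' Generates V genes in `nSubgroups` subgroups with controlled within- and
#' between-subgroup V-REGION nucleotide identity, TRAJ/TRDJ/TRDD genes and
#' two constant genes (TRAC, TRDC homologs). Pseudogenes carry a stop codon
#' or a 1-nt frameshift; ORF-class genes carry exactly one defect (a
#' degenerate RS heptamer or a broken acceptor splice site for V; loss of
#' the FGXG motif for J). Functional V genes have an intact leader ORF,
#' Cys 23, Trp 41 and Cys 104 and a canonical RS; functional J genes carry
#' the FGXG motif. The single TRDJ gene carries the salmonid-type FGKA motif
#' and is functional under the TRDJ motif policy.
#'
#' @param spec a [LocusSpec()].
#' @return a [GermlineSet-class] with one record per planted gene.
#' @examples
#' gs <- simulateGermlineSet(LocusSpec(nSubgroups = 3L,
#'   genesPerSubgroup = c(2L, 2L), pseudogeneFraction = 0, orfFraction = 0,
#'   seed = 7L))
#' table(geneTable(gs)$type)
#' @export
simulateGermlineSet <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, .simulateGermlineSet(spec))
}

.simulateGermlineSet <- function(spec) {
  tpl <- loadVTemplate()
  root <- vRegionRoot(tpl)
  conservedFrac <- 9 / (3 * nrow(root))
  w <- solveMutRate(spec@withinIdentity, conservedFrac)
  uEff <- solveMutRate(spec@betweenIdentity, conservedFrac)
  if (uEff <= w)
    stop("infeasible identity constraints: betweenIdentity implies less ",
         "divergence than withinIdentity")
  q <- 1 - (1 - uEff) / (1 - w)

  nPer <- sampleRange(spec@genesPerSubgroup[1L], spec@genesPerSubgroup[2L],
                      spec@nSubgroups)
  nV <- sum(nPer)

  ## subgroup ancestors: CDR-resized, then mutated away from the root
  ancestors <- lapply(seq_len(spec@nSubgroups), function(s) {
    tab <- editCDRs(root, cdr1 = sample(4:9, 1L), cdr2 = sample(0:8, 1L),
                    cdr3 = sample(2:4, 1L))
    mutateTable(tab, q)
  })

  ## V locus order: random permutation; subgroups renumbered by first
  ## occurrence along the locus
  sgOfGene <- rep(seq_len(spec@nSubgroups), nPer)
  locusOrder <- sample.int(nV)
  sgAlong <- sgOfGene[locusOrder]
  sgRelabel <- match(seq_len(spec@nSubgroups), unique(sgAlong))

  nP <- round(spec@pseudogeneFraction * nV)
  nO <- round(spec@orfFraction * nV)
  vFunc <- shuffleVec(c(rep("P", nP), rep("ORF", nO),
                        rep("F", nV - nP - nO)))
  if (!any(vFunc == "F")) vFunc[1L] <- "F"

  genes <- list(); feats <- list(); segs <- list()
  meta <- data.frame(name = character(), type = character(),
                     chain = character(), subgroup = integer(),
                     locus_index = integer(), functionality = character(),
                     defect = character(), cdr1 = integer(), cdr2 = integer(),
                     cdr3 = integer(), stringsAsFactors = FALSE)

  addGene <- function(id, built, type, chain, subgroup, locus_index,
                      functionality, defect, cdr = c(NA, NA, NA)) {
    genes[[id]] <<- built$placed
    feats[[id]] <<- built$features
    segs[[id]] <<- built$segment
    meta[nrow(meta) + 1L, ] <<- list(id, type, chain, subgroup, locus_index,
                                     functionality, defect,
                                     cdr[1L], cdr[2L], cdr[3L])
  }

  ## ---- V genes (in locus order) -----------------------------------------
  for (k in seq_len(nV)) {
    sgOld <- sgAlong[k]
    sg <- sgRelabel[sgOld]
    tab <- mutateTable(ancestors[[sgOld]], w)
    func <- vFunc[k]
    defect <- "none"
    if (func == "P") {
      defect <- sample(c("stop_codon", "frameshift"), 1L)
      i <- sample(10:(nrow(tab) - 10L), 1L)
      if (defect == "stop_codon") {
        while (!is.na(tab$pos[i]) && tab$pos[i] %in% c(23L, 41L, 104L))
          i <- i + 1L
        tab$codon[i] <- "TAA"
      } else {
        tab$codon[i] <- paste0(substr(tab$codon[i], 1L, 1L), "C",
                               substr(tab$codon[i], 2L, 3L))  # +1 nt insert
      }
    } else if (func == "ORF") {
      defect <- sample(c("rs_defect", "splice_defect"), 1L)
    }
    vnt <- paste0(tab$codon, collapse = "")
    built <- buildVGene(vnt, defect = defect,
                        spacer = sample(c(22L, 23L), 1L,
                                        prob = c(0.8, 0.2)))
    cdr <- c(sum(tab$region == "CDR1"), sum(tab$region == "CDR2"),
             sum(tab$region == "CDR3"))
    addGene(sprintf("V%03d", k), built, "V", "TRA", sg, k, func, defect, cdr)
  }

  ## ---- TRAJ genes --------------------------------------------------------
  nJ <- spec@nTRAJ
  nPj <- round(spec@pseudogeneFraction * nJ)
  nOj <- round(spec@orfFraction * nJ)
  jFunc <- shuffleVec(c(rep("P", nPj), rep("ORF", nOj),
                        rep("F", nJ - nPj - nOj)))
  if (!any(jFunc == "F")) jFunc[1L] <- "F"
  for (k in seq_len(nJ)) {
    func <- jFunc[k]
    defect <- switch(func, P = "stop_codon", ORF = "missing_FGXG", "none")
    built <- buildJGene(
      motif = if (func == "ORF") "FGKA" else "FGSG",
      stopAt = if (func == "P") 5L else NA_integer_,
      spacer = sample(c(11L, 12L, 13L), 1L, prob = c(0.1, 0.8, 0.1)))
    addGene(sprintf("TRAJ%d", k), built, "J", "TRA", NA_integer_, k,
            func, defect)
  }

  ## ---- TRDJ (single, FGKA motif, functional under the TRDJ policy) ------
  addGene("TRDJ1", buildJGene(motif = "FGKA", spacer = 12L), "J", "TRD",
          NA_integer_, 1L, "F", "none")

  ## ---- TRDD genes --------------------------------------------------------
  for (k in seq_len(spec@nTRDD))
    addGene(sprintf("TRDD%d", k), buildDGene(dlen = sample(6:13, 1L)),
            "D", "TRD", NA_integer_, k, "F", "none")

  ## ---- Constant genes ----------------------------------------------------
  addGene("TRAC", buildCGene(withPrimer = TRUE), "C", "TRA", NA_integer_,
          1L, "F", "none")
  addGene("TRDC", buildCGene(withPrimer = FALSE), "C", "TRD", NA_integer_,
          2L, "F", "none")

  ## final V names: subgroup + within-subgroup rank along the locus
  vRows <- meta$type == "V"
  meta$name[vRows] <- vdjNames(meta$subgroup[vRows],
                               meta$locus_index[vRows], prefix = "TRAV")
  names(genes) <- names(feats) <- names(segs) <- meta$name

  new("GermlineSet",
      geneData = S4Vectors::DataFrame(meta),
      regionSeqs = Biostrings::DNAStringSet(unlist(genes)),
      segmentSeqs = Biostrings::DNAStringSet(unlist(segs)),
      features = feats)
}

## Shared nomenclature helper: subgroup + locus order -> names (TRAV2-2
## style); single-member subgroups are named without the rank suffix.
vdjNames <- function(subgroup, locusIndex, prefix = "TRAV") {
  ord <- order(locusIndex)
  rank <- integer(length(subgroup))
  cnt <- new.env(parent = emptyenv())
  for (i in ord) {
    s <- as.character(subgroup[i])
    n <- (get0(s, envir = cnt) %||% 0L) + 1L
    assign(s, n, envir = cnt)
    rank[i] <- n
  }
  sizes <- table(subgroup)
  single <- as.integer(names(sizes)[sizes == 1L])
  ifelse(subgroup %in% single,
         paste0(prefix, subgroup),
         paste0(prefix, subgroup, "-", rank))
}
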