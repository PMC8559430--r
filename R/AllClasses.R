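#' @importClassesFrom Biostrings DNAStringSet AAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
NULL

# ---------------------------------------------------------------------------
# Simulation parameter classes
# ---------------------------------------------------------------------------

#' Parameters of a synthetic TRA/TRD locus
#'
#' `LocusSpec` captures everything the synthetic-locus generator needs: the
#' number of V subgroups and genes per subgroup, the nucleotide identity
#' structure that defines subgroups (within-subgroup identity must exceed the
#' 75\% clustering threshold, between-subgroup identity must fall below it, so
#' the planted subgroup structure is recoverable), the fraction of V and J
#' genes carrying pseudogenizing (stop/frameshift) or ORF-class (RS or splice
#' site) defects, the number of TRAJ and TRDD genes, intergenic spacing, an
#' optional block of V genes placed in inverted orientation, and the RNG seed.
#'
#' @slot nSubgroups integer, number of V subgroups.
#' @slot genesPerSubgroup integer(2), inclusive range of genes per subgroup.
#' @slot withinIdentity target mean pairwise V-REGION nucleotide identity
#'   within a subgroup, fraction in (0.75, 1].
#' @slot betweenIdentity target identity between subgroups, in [0, 0.75).
#' @slot pseudogeneFraction fraction of V/J genes planted as pseudogenes.
#' @slot orfFraction fraction planted as ORF (RS or splice defect).
#' @slot nTRAJ,nTRDD integer counts of TRAJ and TRDD genes.
#' @slot intergenicRange integer(2), intergenic spacer length range (bp).
#' @slot invertedBlock integer(0) or integer(2): V rank range (by position in
#'   the array) emitted in opposite orientation to the rest of the V array.
#' @slot seed integer RNG seed.
#' @export
setClass("LocusSpec", representation(
  nSubgroups = "integer", genesPerSubgroup = "integer",
  withinIdentity = "numeric", betweenIdentity = "numeric",
  pseudogeneFraction = "numeric", orfFraction = "numeric",
  nTRAJ = "integer", nTRDD = "integer",
  intergenicRange = "integer", invertedBlock = "integer",
  seed = "integer"))

setValidity("LocusSpec", function(object) {
  msg <- character()
  if (object@nSubgroups < 1L) msg <- c(msg, "nSubgroups must be >= 1")
  if (length(object@genesPerSubgroup) != 2L ||
      any(object@genesPerSubgroup < 1L) ||
      diff(object@genesPerSubgroup) < 0L)
    msg <- c(msg, "genesPerSubgroup must be an increasing integer pair >= 1")
  if (!(object@withinIdentity > 0.75))
    msg <- c(msg, "withinIdentity must exceed the 0.75 subgroup threshold")
  if (!(object@betweenIdentity < 0.75))
    msg <- c(msg, "betweenIdentity must be below the 0.75 subgroup threshold")
  if (object@withinIdentity > 1 || object@betweenIdentity < 0)
    msg <- c(msg, "identities must be fractions in [0, 1]")
  if (object@pseudogeneFraction < 0 || object@orfFraction < 0 ||
      object@pseudogeneFraction + object@orfFraction > 1)
    msg <- c(msg, "pseudogeneFraction + orfFraction must lie in [0, 1]")
  if (object@nTRAJ < 1L) msg <- c(msg, "nTRAJ must be >= 1")
  if (object@nTRDD < 1L) msg <- c(msg, "nTRDD must be >= 1")
  if (length(object@intergenicRange) != 2L ||
      any(object@intergenicRange < 50L))
    msg <- c(msg, "intergenicRange must be an integer pair >= 50")
  if (!length(object@invertedBlock) %in% c(0L, 2L))
    msg <- c(msg, "invertedBlock must be empty or an integer pair of V ranks")
  if (length(msg)) msg else TRUE
})

#' @param nSubgroups,genesPerSubgroup,withinIdentity,betweenIdentity
#'   see slot documentation.
#' @param pseudogeneFraction,orfFraction,nTRAJ,nTRDD,intergenicRange
#'   see slot documentation.
#' @param invertedBlock,seed see slot documentation.
#' @return `LocusSpec()` returns a validated parameter object.
#' @rdname LocusSpec-class
#' @examples
#' LocusSpec(nSubgroups = 3L, genesPerSubgroup = c(2L, 2L),
#'           pseudogeneFraction = 0, orfFraction = 0, seed = 1L)
#' @export
LocusSpec <- function(nSubgroups = 8L, genesPerSubgroup = c(3L, 5L),
                      withinIdentity = 0.88, betweenIdentity = 0.60,
                      pseudogeneFraction = 0.3, orfFraction = 0.1,
                      nTRAJ = 12L, nTRDD = 3L,
                      intergenicRange = c(300L, 600L),
                      invertedBlock = integer(), seed = 1L) {
  new("LocusSpec", nSubgroups = as.integer(nSubgroups),
      genesPerSubgroup = as.integer(genesPerSubgroup),
      withinIdentity = withinIdentity, betweenIdentity = betweenIdentity,
      pseudogeneFraction = pseudogeneFraction, orfFraction = orfFraction,
      nTRAJ = as.integer(nTRAJ), nTRDD = as.integer(nTRDD),
      intergenicRange = as.integer(intergenicRange),
      invertedBlock = as.integer(invertedBlock), seed = as.integer(seed))
}

#' Parameters of a simulated 5'-RACE repertoire read set
#'
#' Describes a constant-primed TR-alpha amplicon sequencing experiment:
#' V x J sampling probabilities, read count, the fraction of reads built with
#' an in-frame, stop-free junction (productivity is enforced by construction,
#' not by rejection sampling), uniform junction trimming and N-addition
#' bounds, read length, and a per-base substitution error rate. Qualities are
#' constant: the downstream pipeline never uses them.
#'
#' @slot usageWeights numeric V x J matrix of sampling probabilities
#'   (dimnames = germline gene names); must sum to 1.
#' @slot nReads integer number of read pairs.
#' @slot productiveFraction fraction of reads with productive junctions.
#' @slot junctionTrimMax max nucleotides trimmed from V 3' and J 5' ends.
#' @slot nAdditionMax max untemplated N nucleotides at the junction.
#' @slot readLength read length (nt) of each mate.
#' @slot errorRate per-base substitution error probability.
#' @slot seed integer RNG seed.
#' @export
setClass("RepertoireSpec", representation(
  usageWeights = "matrix", nReads = "integer",
  productiveFraction = "numeric", junctionTrimMax = "integer",
  nAdditionMax = "integer", readLength = "integer",
  errorRate = "numeric", seed = "integer"))

setValidity("RepertoireSpec", function(object) {
  msg <- character()
  if (abs(sum(object@usageWeights) - 1) > 1e-8)
    msg <- c(msg, "usageWeights must sum to 1")
  if (any(object@usageWeights < 0)) msg <- c(msg, "usageWeights must be >= 0")
  if (is.null(rownames(object@usageWeights)) ||
      is.null(colnames(object@usageWeights)))
    msg <- c(msg, "usageWeights needs V rownames and J colnames")
  if (object@productiveFraction < 0 || object@productiveFraction > 1)
    msg <- c(msg, "productiveFraction must lie in [0, 1]")
  if (object@errorRate < 0 || object@errorRate > 0.2)
    msg <- c(msg, "errorRate must lie in [0, 0.2]")
  if (object@readLength < 50L) msg <- c(msg, "readLength must be >= 50")
  if (length(msg)) msg else TRUE
})

#' @param usageWeights,nReads,productiveFraction,junctionTrimMax,nAdditionMax
#'   see slot documentation.
#' @param readLength,errorRate,seed see slot documentation.
#' @return `RepertoireSpec()` returns a validated parameter object.
#' @rdname RepertoireSpec-class
#' @export
RepertoireSpec <- function(usageWeights, nReads = 1000L,
                           productiveFraction = 0.8,
                           junctionTrimMax = 6L, nAdditionMax = 6L,
                           readLength = 300L, errorRate = 0, seed = 1L) {
  new("RepertoireSpec", usageWeights = usageWeights,
      nReads = as.integer(nReads), productiveFraction = productiveFraction,
      junctionTrimMax = as.integer(junctionTrimMax),
      nAdditionMax = as.integer(nAdditionMax),
      readLength = as.integer(readLength), errorRate = errorRate,
      seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# Germline set and simulated locus
# ---------------------------------------------------------------------------

#' A set of germline TR genes with per-gene ground truth
#'
#' Container emitted by [simulateGermlineSet()] and consumed by
#' [simulateLocus()] and [simulateRepertoireReads()]. `geneData` holds one row
#' per gene (name, type, chain, subgroup, functionality, planted defect);
#' `regionSeqs` the full gene-oriented genomic region of each gene (leader,
#' intron, coding, RS for V; RS through donor for J; RS-flanked D; exons and
#' introns for C); `segmentSeqs` the rearranging/coding unit used by the
#' repertoire stage (spliced leader+V-REGION for V, J-REGION for J, D-REGION
#' for D, spliced CDS for C).
#'
#' @slot geneData a [S4Vectors::DataFrame] of per-gene metadata.
#' @slot regionSeqs [Biostrings::DNAStringSet] of full gene regions.
#' @slot segmentSeqs [Biostrings::DNAStringSet] of coding/rearranging units.
#' @slot features named list of per-gene feature coordinate tables (1-based,
#'   relative to the gene region, gene orientation).
#' @export
setClass("GermlineSet", representation(
  geneData = "DataFrame", regionSeqs = "DNAStringSet",
  segmentSeqs = "DNAStringSet", features = "list"))

#' A simulated locus: genome sequence plus exact ground truth
#'
#' @slot genome [Biostrings::DNAStringSet] with the single synthetic contig.
#' @slot truth [GenomicRanges::GRanges] of planted features (gene spans and
#'   sub-features, functionality, subgroup, names).
#' @slot germline the [GermlineSet] the locus was assembled from.
#' @export
setClass("LocusSim", representation(
  genome = "DNAStringSet", truth = "GRanges", germline = "GermlineSet"))

# ---------------------------------------------------------------------------
# Annotation result
# ---------------------------------------------------------------------------

#' Germline annotation of a TRA/TRD locus
#'
#' Result of [annotateLocus()]: `genes` holds one range per annotated gene
#' (gene span = coding region plus RS for V/D/J, exon span for C) with
#' gene_type, chain, functionality, defect list, subgroup and final name;
#' `features` holds sub-features (L-PART1, L-PART2, V-REGION, J-REGION,
#' D-REGION, exons, RSS) with a Parent pointer; `segmentSeqs` the extracted
#' coding/rearranging units keyed by gene name.
#'
#' @slot genes [GenomicRanges::GRanges], one row per gene.
#' @slot features [GenomicRanges::GRanges] of sub-features.
#' @slot segmentSeqs [Biostrings::DNAStringSet].
#' @slot log character vector of discarded-candidate log lines.
#' @export
setClass("TRAnnotation", representation(
  genes = "GRanges", features = "GRanges",
  segmentSeqs = "DNAStringSet", log = "character"))

# ---------------------------------------------------------------------------
# Usage profile
# ---------------------------------------------------------------------------

#' V-J usage profile of one or more repertoire samples
#'
#' @slot samples character vector of sample labels.
#' @slot vGenes,jGenes character vectors of germline gene names (locus order).
#' @slot vjProductive,vjUnproductive integer arrays [V, J, sample] of
#'   assigned-read counts.
#' @slot freqV,freqJ numeric matrices (gene x sample) of percentages of total
#'   productive rearrangements.
#' @slot normalized numeric matrix (V x J combination x sample) of
#'   size-factor-normalized log2 counts (productive set).
#' @slot conditionalJ numeric array [V, J, sample]: per-V conditional J usage
#'   (percent of productive reads with that V).
#' @export
setClass("UsageProfile", representation(
  samples = "character", vGenes = "character", jGenes = "character",
  vjProductive = "array", vjUnproductive = "array",
  freqV = "matrix", freqJ = "matrix", normalized = "matrix",
  conditionalJ = "array"))

# ---------------------------------------------------------------------------
# Accessors and show methods
# ---------------------------------------------------------------------------

#' Per-gene metadata table
#' @param x a `GermlineSet` or `TRAnnotation`.
#' @return a `DataFrame` (GermlineSet) or `GRanges` (TRAnnotation) with one
#'   entry per gene.
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' @rdname geneTable
#' @export
setMethod("geneTable", "GermlineSet", function(x) x@geneData)

#' @rdname geneTable
#' @export
setMethod("geneTable", "TRAnnotation", function(x) x@genes)

#' Coding/rearranging unit sequences
#' @param x a `GermlineSet` or `TRAnnotation`.
#' @return a `DNAStringSet` keyed by gene name.
#' @export
setGeneric("segmentSequences", function(x) standardGeneric("segmentSequences"))

#' @rdname segmentSequences
#' @export
setMethod("segmentSequences", "GermlineSet", function(x) x@segmentSeqs)

#' @rdname segmentSequences
#' @export
setMethod("segmentSequences", "TRAnnotation", function(x) x@segmentSeqs)

#' Genome sequence of a simulated locus
#' @param x a `LocusSim`.
#' @return a `DNAStringSet` with one contig.
#' @export
setGeneric("locusGenome", function(x) standardGeneric("locusGenome"))

#' @rdname locusGenome
#' @export
setMethod("locusGenome", "LocusSim", function(x) x@genome)

#' Ground-truth feature ranges of a simulated locus
#' @param x a `LocusSim`.
#' @return a `GRanges` of planted features.
#' @export
setGeneric("locusTruth", function(x) standardGeneric("locusTruth"))

#' @rdname locusTruth
#' @export
setMethod("locusTruth", "LocusSim", function(x) x@truth)

#' Annotated sub-features (exons, regions, RSS)
#' @param x a `TRAnnotation`.
#' @return a `GRanges` of sub-features with Parent pointers.
#' @export
setGeneric("featureRanges", function(x) standardGeneric("featureRanges"))

#' @rdname featureRanges
#' @export
setMethod("featureRanges", "TRAnnotation", function(x) x@features)

setMethod("show", "LocusSpec", function(object) {
  cat("LocusSpec:", object@nSubgroups, "V subgroups x",
      paste(object@genesPerSubgroup, collapse = "-"), "genes;",
      object@nTRAJ, "TRAJ;", object@nTRDD, "TRDD;",
      sprintf("identity within/between = %.2f/%.2f;",
              object@withinIdentity, object@betweenIdentity),
      sprintf("P/ORF fractions = %.2f/%.2f; seed %d\n",
              object@pseudogeneFraction, object@orfFraction, object@seed))
})

setMethod("show", "RepertoireSpec", function(object) {
  cat("RepertoireSpec:", object@nReads, "read pairs;",
      nrow(object@usageWeights), "V x", ncol(object@usageWeights), "J;",
      sprintf("productive fraction %.2f; read length %d; error %.2g; seed %d\n",
              object@productiveFraction, object@readLength,
              object@errorRate, object@seed))
})

setMethod("show", "GermlineSet", function(object) {
  tab <- table(object@geneData$type)
  cat("GermlineSet with", nrow(object@geneData), "genes (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
})

setMethod("show", "LocusSim", function(object) {
  cat("LocusSim:", names(object@genome), "of",
      Biostrings::width(object@genome), "bp;",
      sum(object@truth$feature == "gene"), "planted genes\n")
})

setMethod("show", "TRAnnotation", function(object) {
  tab <- table(object@genes$gene_type, object@genes$functionality)
  cat("TRAnnotation with", length(object@genes), "genes\n")
  if (length(object@genes)) print(tab)
})

setMethod("show", "UsageProfile", function(object) {
  cat("UsageProfile:", length(object@samples), "sample(s);",
      length(object@vGenes), "V x", length(object@jGenes), "J;",
      sum(object@vjProductive), "productive /",
      sum(object@vjUnproductive), "unproductive assigned reads\n")
})
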