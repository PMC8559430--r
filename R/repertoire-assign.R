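# Segment assignment: the germline C/J/V sequences are searched against a
# BLAST database built from the merged reads (NCBI BLAST+), mirroring the
# reference pipeline. Hits below the 97% identity floor are discarded at
# scan time; the stricter per-read assignment filters are applied later.

#' @importFrom data.table data.table fread rbindlist setnames :=
NULL

blastAvailable <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

#' Assign C/J/V segments to merged reads
#'
#' Builds a nucleotide BLAST database from the merged reads and queries it
#' with every germline segment sequence, one class at a time. Only hits
#' with at least `minIdentity` percent identity are retained. The
#' expectancy reported is the BLAST e-value (monotone decreasing in
#' alignment score, increasing in search space).
#'
#' @param reads data.frame from [mergePairs()] (`$merged`), or a named
#'   character vector of read sequences.
#' @param germline a [GermlineSet-class]/[TRAnnotation-class] (segment
#'   sequences and gene classes are taken from it) or a named
#'   `DNAStringSet` whose names start with TRAV/TRAJ/TRDJ/TRDD/TRAC/TRDC.
#' @param minIdentity percent identity floor for a valid hit (default 97).
#' @param wordSize BLAST word size (default 9; J segments are short).
#' @return a `data.table` with one row per hit: `readId`, `class` (C/J/V),
#'   `gene`, `identity`, `length`, `evalue`, `readStart`, `readEnd`,
#'   `geneStart`, `geneEnd`, `strand`.
#' @export
assignSegments <- function(reads, germline, minIdentity = 97,
                           wordSize = 9L) {
  if (!blastAvailable())
    stop("NCBI BLAST+ (makeblastdb/blastn) not found on PATH")
  if (is.data.frame(reads)) {
    seqs <- setNames(reads$seq, reads$id)
  } else seqs <- reads
  if (!length(seqs)) stop("no reads to assign")
  segs <- .germlineSegments(germline)
  if (!length(segs$seq)) stop("empty germline database")

  td <- tempfile("blastdb")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  dbfa <- file.path(td, "reads.fasta")
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), dbfa)
  system2("makeblastdb",
          c("-in", dbfa, "-dbtype", "nucl", "-out",
            file.path(td, "readsdb"), "-logfile",
            file.path(td, "makedb.log")))

  out <- list()
  for (cls in unique(segs$class)) {
    qfa <- file.path(td, paste0("q_", cls, ".fasta"))
    sel <- segs$class == cls
    writeLines(paste0(">", segs$name[sel], "\n", segs$seq[sel]), qfa)
    resf <- file.path(td, paste0("hits_", cls, ".tsv"))
    ## ungapped: the pipeline's error model is substitution-only, and
    ## gapped extension across the junction would blur segment boundaries
    system2("blastn",
            c("-task", "blastn", "-query", qfa, "-db",
              file.path(td, "readsdb"), "-out", resf,
              "-outfmt", shQuote(paste("6 qseqid sseqid pident length",
                                       "evalue qstart qend sstart send")),
              "-word_size", wordSize, "-dust", "no", "-ungapped",
              "-perc_identity", minIdentity, "-evalue", "1e-3",
              "-max_target_seqs", "1000000"))
    if (file.size(resf) > 0L) {
      h <- data.table::fread(resf, header = FALSE,
                             col.names = c("gene", "readId", "identity",
                                           "length", "evalue", "geneStart",
                                           "geneEnd", "readStart",
                                           "readEnd"))
      h[, `:=`(class = cls,
               strand = ifelse(readStart <= readEnd, "+", "-"))]
      out[[cls]] <- h
    }
  }
  if (!length(out))
    return(data.table::data.table(
      readId = character(), class = character(), gene = character(),
      identity = numeric(), length = integer(), evalue = numeric(),
      readStart = integer(), readEnd = integer(), geneStart = integer(),
      geneEnd = integer(), strand = character()))
  hits <- data.table::rbindlist(out, use.names = TRUE)
  hits <- hits[identity >= minIdentity]
  hits[, .(readId, class, gene, identity, length, evalue, readStart,
           readEnd, geneStart, geneEnd, strand)]
}

## class of each germline segment: V (spliced leader + V-REGION), J
## (J-REGION), C (spliced CDS); D segments are too short for this stage and
## are excluded
.germlineSegments <- function(germline) {
  if (methods::is(germline, "GermlineSet")) {
    gd <- as.data.frame(germline@geneData)
    seq <- as.character(germline@segmentSeqs)
    cls <- gd$type
    name <- gd$name
  } else if (methods::is(germline, "TRAnnotation")) {
    gd <- geneTable(germline)
    seq <- as.character(segmentSequences(germline))
    cls <- gd$gene_type
    name <- gd$name
  } else {
    seq <- as.character(germline)
    name <- names(seq)
    cls <- rep(NA_character_, length(seq))
    cls[grepl("^TRAV|^TRDV", name)] <- "V"
    cls[grepl("^TRAJ|^TRDJ", name)] <- "J"
    cls[grepl("^TRDD", name)] <- "D"
    cls[grepl("^TRAC|^TRDC", name)] <- "C"
    if (anyNA(cls)) stop("germline names must start with TRAV/TRAJ/TRDJ/",
                         "TRDD/TRAC/TRDC")
  }
  keep <- cls %in% c("V", "J", "C")
  list(seq = seq[keep], name = name[keep], class = cls[keep])
}
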