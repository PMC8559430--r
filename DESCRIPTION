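Package: tralocus
Title: Annotation, Nomenclature and Repertoire Profiling of Teleost
    TRA/TRD Loci
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the germline annotation of teleost T-cell receptor
    alpha/delta (TRA/TRD) loci and for processing 5'-RACE TR-alpha
    repertoire sequencing data. Discovers V, D, J and C genes in genomic
    sequence by constant-gene anchoring, recombination-signal (RS) motif
    scanning and splice-site delimitation; classifies gene functionality
    (F/ORF/P) under IMGT-style rules; clusters V genes into subgroups at
    75 percent V-REGION nucleotide identity and assigns IMGT-style names
    by subgroup and locus rank; builds Poisson-corrected distance
    matrices, neighbor-joining trees and bootstrap supports over V
    protein sequences; and turns paired-end constant-primed amplicon
    reads into productive/unproductive V-J usage profiles. A fully
    ground-truthed synthetic-data generator emulates both artificial loci
    and simulated repertoire read sets so every stage can be exercised
    and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    data.table,
    jsonlite,
    yaml,
    ggplot2,
    pheatmap,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
SystemRequirements: NCBI BLAST+ (makeblastdb, blastn)
Config/testthat/edition: 3
biocViews: Annotation, Genetics, SequenceMatching, Alignment,
    Phylogenetics, ImmunoOncology
RoxygenNote: 7.3.3
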