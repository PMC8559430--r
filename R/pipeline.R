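# Unified pipeline driver: configuration, stage execution, manifest.

PIPELINE_STAGES <- c("simulate", "annotate", "classify", "phylo",
                     "repertoire", "report")

CONFIG_KEYS <- c(
  "stages", "out_dir", "seed",
  ## simulate
  "n_subgroups", "genes_per_subgroup_min", "genes_per_subgroup_max",
  "within_identity", "between_identity", "pseudogene_fraction",
  "orf_fraction", "n_traj", "n_trdd", "intergenic_min", "intergenic_max",
  "inverted_block_start", "inverted_block_end",
  ## annotate
  "genome_fasta", "c_query_fasta", "strict_conserved",
  "subgroup_threshold",
  ## phylo
  "bootstrap_reps",
  ## repertoire
  "fastq_r1", "fastq_r2", "sample_name", "n_reads", "productive_fraction",
  "junction_trim_max", "n_addition_max", "read_length", "error_rate",
  "min_merged_length")

#' Default pipeline configuration
#' @return named list of all recognized configuration keys with defaults.
#' @export
defaultConfig <- function() {
  list(stages = "all", out_dir = "tralocus_run", seed = 1L,
       n_subgroups = 8L, genes_per_subgroup_min = 3L,
       genes_per_subgroup_max = 5L, within_identity = 0.88,
       between_identity = 0.60, pseudogene_fraction = 0.3,
       orf_fraction = 0.1, n_traj = 12L, n_trdd = 3L,
       intergenic_min = 300L, intergenic_max = 600L,
       inverted_block_start = NA, inverted_block_end = NA,
       genome_fasta = NA, c_query_fasta = NA, strict_conserved = FALSE,
       subgroup_threshold = 75, bootstrap_reps = 500L,
       fastq_r1 = NA, fastq_r2 = NA, sample_name = "sample1",
       n_reads = 1000L, productive_fraction = 0.8, junction_trim_max = 6L,
       n_addition_max = 6L, read_length = 300L, error_rate = 0,
       min_merged_length = 150L)
}

#' Load and validate a pipeline configuration
#'
#' Reads a flat YAML document, rejects unknown keys, and fills unset keys
#' from [defaultConfig()].
#'
#' @param path YAML file path, or a named list.
#' @return validated configuration list.
#' @export
loadConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaultConfig(), cfg)
}

specFromConfig <- function(cfg) {
  inv <- if (!is.na(cfg$inverted_block_start) &&
             !is.na(cfg$inverted_block_end))
    c(cfg$inverted_block_start, cfg$inverted_block_end) else integer()
  LocusSpec(nSubgroups = cfg$n_subgroups,
            genesPerSubgroup = c(cfg$genes_per_subgroup_min,
                                 cfg$genes_per_subgroup_max),
            withinIdentity = cfg$within_identity,
            betweenIdentity = cfg$between_identity,
            pseudogeneFraction = cfg$pseudogene_fraction,
            orfFraction = cfg$orf_fraction, nTRAJ = cfg$n_traj,
            nTRDD = cfg$n_trdd,
            intergenicRange = c(cfg$intergenic_min, cfg$intergenic_max),
            invertedBlock = inv, seed = cfg$seed)
}

#' Run the pipeline
#'
#' Executes the selected stages (`simulate`, `annotate`, `classify`,
#' `phylo`, `repertoire`, `report`; `"all"` selects every stage) and
#' writes every artifact plus a JSON manifest (configuration, input
#' checksums, outputs) into the run directory. With a `simulate` stage the
#' synthetic locus provides the genome, queries and reads for the later
#' stages; otherwise `genome_fasta`/`c_query_fasta`/`fastq_r1`/`fastq_r2`
#' must point at user inputs.
#'
#' @param config a config list or YAML path (see [loadConfig()]).
#' @return invisibly, the run directory path.
#' @export
runPipeline <- function(config) {
  cfg <- loadConfig(config)
  stages <- cfg$stages
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  logLine <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  manifest <- list(tool = "tralocus",
                   version = as.character(utils::packageVersion("tralocus")),
                   config = cfg, outputs = list(), skipped = list())
  logLine("config: ", jsonlite::toJSON(cfg, auto_unbox = TRUE))

  sim <- NULL; ann <- NULL; reads <- NULL
  addOut <- function(stage, paths) {
    manifest$outputs[[stage]] <<- lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  }

  if ("simulate" %in% stages) {
    logLine("stage simulate")
    spec <- specFromConfig(cfg)
    sim <- simulateLocus(spec)
    paths <- writeLocus(sim, file.path(cfg$out_dir, "simulate"))
    uw <- uniformUsage(sim@germline)
    rspec <- RepertoireSpec(uw, nReads = cfg$n_reads,
                            productiveFraction = cfg$productive_fraction,
                            junctionTrimMax = cfg$junction_trim_max,
                            nAdditionMax = cfg$n_addition_max,
                            readLength = cfg$read_length,
                            errorRate = cfg$error_rate, seed = cfg$seed)
    reads <- simulateRepertoireReads(sim@germline, rspec,
                                     sample = cfg$sample_name)
    fq <- writeRepertoireFastq(reads, file.path(cfg$out_dir, "simulate"),
                               prefix = cfg$sample_name)
    tt <- file.path(cfg$out_dir, "simulate", "read_truth.tsv")
    utils::write.table(reads$truth, tt, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    addOut("simulate", c(paths, fq, tt))
  } else manifest$skipped$simulate <- TRUE

  if ("annotate" %in% stages) {
    logLine("stage annotate")
    genome <- if (!is.null(sim)) locusGenome(sim) else cfg$genome_fasta
    queries <- if (!is.null(sim)) constantQueries(sim@germline) else
      cfg$c_query_fasta
    if (is.null(genome) || (is.character(genome) && is.na(genome)))
      stop("annotate stage needs genome_fasta or a simulate stage")
    ann <- annotateLocus(genome, queries,
                         strictConserved = cfg$strict_conserved,
                         subgroupThreshold = cfg$subgroup_threshold)
    paths <- writeAnnotation(ann, file.path(cfg$out_dir, "annotate"))
    addOut("annotate", paths)
  } else manifest$skipped$annotate <- TRUE

  if ("classify" %in% stages && !is.null(ann)) {
    logLine("stage classify")
    d <- file.path(cfg$out_dir, "classify")
    dir.create(d, showWarnings = FALSE)
    vSel <- geneTable(ann)$gene_type == "V"
    vSeqs <- setNames(geneTable(ann)$vRegionSeq[vSel],
                      geneTable(ann)$name[vSel])
    idm <- identityMatrix(vSeqs)
    idp <- file.path(d, "identity_matrix.tsv")
    utils::write.table(idm, idp, sep = "\t", quote = FALSE, col.names = NA)
    cen <- subgroupCensus(ann)
    cp <- file.path(d, "subgroup_census.tsv")
    utils::write.table(cen, cp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    addOut("classify", c(idp, cp))
  } else manifest$skipped$classify <- TRUE

  if ("phylo" %in% stages && !is.null(ann)) {
    logLine("stage phylo")
    d <- file.path(cfg$out_dir, "phylo")
    dir.create(d, showWarnings = FALSE)
    gt <- geneTable(ann)
    sel <- gt$gene_type == "V" & gt$functionality == "F"
    aas <- setNames(gt$vAA[sel], gt$name[sel])
    if (length(aas) >= 3L) {
      aln <- alignProteins(aas)
      dm <- poissonDistMatrix(aln)
      dp <- file.path(d, "poisson_distances.phy")
      writePhylipDist(dm, dp)
      dt <- file.path(d, "poisson_distances.tsv")
      utils::write.table(dm, dt, sep = "\t", quote = FALSE, col.names = NA)
      boot <- bootstrapSupport(aln, nReps = cfg$bootstrap_reps,
                               seed = cfg$seed)
      tp <- file.path(d, "nj_tree.nwk")
      ape::write.tree(boot$tree, tp)
      addOut("phylo", c(dp, dt, tp))
    } else {
      logLine("phylo skipped: fewer than 3 functional V genes")
      manifest$skipped$phylo <- "fewer than 3 functional V genes"
    }
  } else manifest$skipped$phylo <- TRUE

  if ("repertoire" %in% stages) {
    logLine("stage repertoire")
    d <- file.path(cfg$out_dir, "repertoire")
    dir.create(d, showWarnings = FALSE)
    db <- if (!is.null(ann)) ann else if (!is.null(sim)) sim@germline else
      NULL
    if (is.null(db)) stop("repertoire stage needs an annotation or ",
                          "simulated germline")
    if (!is.null(reads)) {
      r1 <- reads$r1; r2 <- reads$r2
    } else {
      r1 <- cfg$fastq_r1; r2 <- cfg$fastq_r2
      if (is.na(r1)) stop("repertoire stage needs fastq_r1/fastq_r2")
    }
    rep_ <- runRepertoire(r1, r2, db, sample = cfg$sample_name,
                          minLen = cfg$min_merged_length)
    ap <- file.path(d, "rearrangements.tsv")
    writeRearrangements(rep_$assignments, ap)
    up <- writeUsageTables(rep_$usage, d)
    sp <- file.path(d, "filter_stats.tsv")
    utils::write.table(data.frame(metric = names(rep_$stats),
                                  value = as.integer(rep_$stats)),
                       sp, sep = "\t", quote = FALSE, row.names = FALSE)
    logLine("filter attrition: ",
            paste(names(rep_$stats), rep_$stats, sep = "=",
                  collapse = ", "))
    addOut("repertoire", c(ap, up, sp))
    manifest$repertoireStats <- as.list(rep_$stats)
  } else manifest$skipped$repertoire <- TRUE

  if ("report" %in% stages) {
    logLine("stage report")
    paths <- renderReports(cfg$out_dir, ann = ann)
    if (length(paths)) addOut("report", paths)
  } else manifest$skipped$report <- TRUE

  manifest$configHash <- digestConfig(cfg)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  logLine("done")
  invisible(cfg$out_dir)
}

## hash of the analysis parameters; paths are volatile and excluded
digestConfig <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), c("out_dir", "genome_fasta",
                                   "c_query_fasta", "fastq_r1",
                                   "fastq_r2"))]
  tf <- tempfile()
  writeLines(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE),
             tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

#' Write read assignments as an AIRR-style rearrangement table
#'
#' One row per assigned read with `sequence_id`, `sample`, `v_call`,
#' `j_call`, `c_call`, `productive` and `junction` columns.
#'
#' @param assignments data.frame from [classifyProductivity()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeRearrangements <- function(assignments, path) {
  out <- data.frame(sequence_id = assignments$readId,
                    sample = assignments$sample,
                    v_call = assignments$v, j_call = assignments$j,
                    c_call = assignments$cGene,
                    productive = ifelse(assignments$productive, "T", "F"),
                    junction = assignments$junction)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
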