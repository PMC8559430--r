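# Germline annotation against planted truth.

truthVsAnnotation <- function(sim, ann) {
  tg <- locusTruth(sim)
  tg <- tg[tg$feature == "gene"]
  ag <- geneTable(ann)
  key <- function(g) paste(GenomicRanges::start(g), GenomicRanges::end(g),
                           GenomicRanges::strand(g), g$gene_type,
                           g$functionality)
  list(truth = tg, ann = ag,
       precision = mean(key(ag) %in% key(tg)),
       recall = mean(key(tg) %in% key(ag)))
}

test_that("a mutation-free locus is recovered exactly, sub-features too", {
  sim <- cleanLocus()
  ann <- annotationOf(sim, "cleanAnn")
  cmp <- truthVsAnnotation(sim, ann)
  expect_equal(cmp$precision, 1)
  expect_equal(cmp$recall, 1)
  ## every truth interval (leader parts, regions, RSS, exons) is matched
  tf <- locusTruth(sim)
  tf <- tf[!tf$feature %in% c("gene", "V_INTRON")]
  af <- featureRanges(ann)
  tkey <- paste(GenomicRanges::start(tf), GenomicRanges::end(tf),
                sub("EXON", "EXON", tf$feature))
  akey <- paste(GenomicRanges::start(af), GenomicRanges::end(af),
                af$feature)
  expect_true(all(tkey %in% akey))
  ## names agree with the generator's nomenclature
  m <- merge(
    data.frame(s = GenomicRanges::start(cmp$truth), n1 = cmp$truth$name),
    data.frame(s = GenomicRanges::start(cmp$ann), n2 = cmp$ann$name))
  expect_identical(m$n1, m$n2)
})

test_that("planted defect classes map to the annotated F/ORF/P classes", {
  sim <- defectLocus()
  ann <- annotationOf(sim, "defectAnn")
  cmp <- truthVsAnnotation(sim, ann)
  expect_equal(cmp$precision, 1)
  expect_equal(cmp$recall, 1)
  ## per-defect category check
  tg <- cmp$truth
  ag <- cmp$ann
  m <- match(paste(GenomicRanges::start(tg), GenomicRanges::strand(tg)),
             paste(GenomicRanges::start(ag), GenomicRanges::strand(ag)))
  expect_false(anyNA(m))
  planted <- tg$defect
  got <- ag$functionality[m]
  expect_true(all(got[planted %in% c("stop_codon", "frameshift")] == "P"))
  vsel <- tg$gene_type == "V"
  expect_true(all(got[vsel & planted %in% c("rs_defect",
                                            "splice_defect")] == "ORF"))
  ## annotated defect codes contain the planted class
  adef <- ag$defects[m]
  for (k in which(planted == "rs_defect" & vsel))
    expect_match(adef[k], "rs_defect")
  for (k in which(planted == "splice_defect" & vsel))
    expect_match(adef[k], "splice_defect")
  ## ORF TRAJ: missing FGXG; TRDJ keeps F despite FGKA
  jsel <- tg$gene_type == "J" & tg$chain == "TRA"
  expect_true(all(got[jsel & planted == "missing_FGXG"] == "ORF"))
  expect_equal(got[tg$name == "TRDJ1"], "F")
})

test_that("constant genes are recovered with exact exon structure", {
  sim <- cleanLocus()
  cg <- findConstantGenes(locusGenome(sim),
                         constantQueries(sim@germline))
  tf <- locusTruth(sim)
  for (cn in c("TRAC", "TRDC")) {
    ex <- cg[cg$name == cn, ]
    te <- tf[tf$name == cn & tf$feature == "EXON"]
    expect_equal(nrow(ex), 3L)
    expect_setequal(ex$start, GenomicRanges::start(te))
    expect_setequal(ex$end, GenomicRanges::end(te))
    expect_equal(unique(ex$strand),
                 as.character(unique(GenomicRanges::strand(te))))
    expect_equal(ex$identity[1L], 1)
    expect_false(any(ex$splice_defect))
  }
  ## genome without any C homolog: empty result with a warning
  expect_warning(
    none <- findConstantGenes(testDNA(4000, 9),
                              constantQueries(sim@germline)),
    "no constant-gene hit")
  expect_equal(nrow(none), 0L)
})

test_that("GFF round trip preserves the gene table", {
  sim <- cleanLocus()
  ann <- annotationOf(sim, "cleanAnn")
  td <- tempfile("annio")
  writeAnnotation(ann, td)
  back <- readAnnotationGFF(file.path(td, "annotation.gff3"))
  g0 <- geneTable(ann)
  g1 <- back$genes
  m <- match(g0$name, g1$name)
  expect_false(anyNA(m))
  expect_identical(GenomicRanges::start(g0), GenomicRanges::start(g1)[m])
  expect_identical(GenomicRanges::end(g0), GenomicRanges::end(g1)[m])
  expect_identical(as.character(GenomicRanges::strand(g0)),
                   as.character(GenomicRanges::strand(g1))[m])
  expect_identical(g0$functionality, g1$functionality[m])
  expect_identical(g0$gene_type, g1$gene_type[m])
  expect_identical(as.integer(g0$subgroup), g1$subgroup[m])
  ## census equals the planted census
  cen <- subgroupCensus(ann)
  gd <- as.data.frame(geneTable(sim@germline))
  v <- gd[gd$type == "V", ]
  planted <- table(v$subgroup)
  expect_identical(as.integer(cen$nF + cen$nORF + cen$nP),
                   as.integer(planted[as.character(cen$subgroup)]))
  unlink(td, recursive = TRUE)
})

test_that("empty annotation writes a valid empty GFF3", {
  ann <- new("TRAnnotation", genes = GenomicRanges::GRanges(),
             features = GenomicRanges::GRanges(),
             segmentSeqs = Biostrings::DNAStringSet(), log = character())
  td <- tempfile("annempty")
  writeAnnotation(ann, td)
  expect_true(file.exists(file.path(td, "annotation.gff3")))
  expect_match(readLines(file.path(td, "annotation.gff3"))[1L],
               "gff-version 3")
  unlink(td, recursive = TRUE)
})
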