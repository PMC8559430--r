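# Synthetic germline/locus/read generator: planted structure and
# determinism.

test_that("germline generator plants the requested gene census", {
  gs <- simulateGermlineSet(LocusSpec(nSubgroups = 3L,
                                      genesPerSubgroup = c(2L, 2L),
                                      pseudogeneFraction = 0,
                                      orfFraction = 0, seed = 1L))
  gd <- as.data.frame(geneTable(gs))
  v <- gd[gd$type == "V", ]
  expect_equal(nrow(v), 6L)
  expect_true(all(v$functionality == "F"))
  expect_equal(length(unique(v$subgroup)), 3L)

  gs2 <- simulateGermlineSet(LocusSpec(nSubgroups = 5L,
                                       genesPerSubgroup = c(2L, 2L),
                                       pseudogeneFraction = 0.5,
                                       orfFraction = 0, seed = 2L))
  v2 <- as.data.frame(geneTable(gs2))
  v2 <- v2[v2$type == "V", ]
  expect_equal(sum(v2$functionality == "P"), 5L)
  expect_true(all(v2$defect[v2$functionality == "P"] %in%
                    c("stop_codon", "frameshift")))
})

test_that("planted subgroup identity separation is realized", {
  gs <- simulateGermlineSet(LocusSpec(nSubgroups = 3L,
                                      genesPerSubgroup = c(3L, 3L),
                                      withinIdentity = 0.85,
                                      betweenIdentity = 0.60,
                                      pseudogeneFraction = 0,
                                      orfFraction = 0, seed = 7L))
  gd <- as.data.frame(geneTable(gs))
  v <- gd[gd$type == "V", ]
  getV <- function(nm) {
    f <- gs@features[[nm]]
    reg <- as.character(gs@regionSeqs[[nm]])
    vv <- f[f$feature == "V_REGION", ]
    substr(reg, vv$from, vv$to)
  }
  seqs <- vapply(v$name, getV, "")
  within <- c(); between <- c()
  for (i in seq_len(nrow(v) - 1L)) for (j in seq(i + 1L, nrow(v))) {
    id <- pairwiseIdentity(seqs[[i]], seqs[[j]]) / 100
    if (v$subgroup[i] == v$subgroup[j]) within <- c(within, id)
    else between <- c(between, id)
  }
  expect_gte(mean(within), 0.80)
  expect_lte(mean(between), 0.65)
})

test_that("infeasible identity constraints fail loudly", {
  expect_error(simulateGermlineSet(
    LocusSpec(withinIdentity = 0.76, betweenIdentity = 0.10, seed = 1L)),
    "infeasible")
  expect_error(LocusSpec(withinIdentity = 0.70), "withinIdentity")
  expect_error(LocusSpec(pseudogeneFraction = 0.8, orfFraction = 0.5),
               "orfFraction|pseudogene")
})

test_that("locus layout follows the teleost architecture", {
  sim <- cleanLocus()
  tr <- locusTruth(sim)
  g <- tr[tr$feature == "gene"]
  v <- g[g$gene_type == "V"]
  cl <- g[g$gene_type != "V"]
  expect_true(all(as.character(GenomicRanges::strand(v)) == "+"))
  expect_true(all(as.character(GenomicRanges::strand(cl)) == "-"))
  ## V array upstream (left) of the inverted cluster
  expect_lt(max(GenomicRanges::end(v)), min(GenomicRanges::start(cl)))
  ## TRAJ1 is the TRAC-proximal J
  trac <- g[g$name == "TRAC"]
  ja <- g[g$gene_type == "J" & g$chain == "TRA"]
  d <- abs(GenomicRanges::start(ja) - GenomicRanges::start(trac))
  expect_equal(ja$name[which.min(d)], "TRAJ1")
  ## requested TRDD count
  expect_equal(sum(g$gene_type == "D"),
               cleanSpec()@nTRDD)
  ## no overlapping planted genes
  expect_true(all(IRanges::isDisjoint(GenomicRanges::ranges(g))))
})

test_that("inverted V block is emitted in opposite orientation", {
  spec <- LocusSpec(nSubgroups = 3L, genesPerSubgroup = c(2L, 2L),
                    pseudogeneFraction = 0, orfFraction = 0, nTRAJ = 3L,
                    invertedBlock = c(2L, 3L), seed = 31L)
  sim <- simulateLocus(spec)
  g <- locusTruth(sim)
  g <- g[g$feature == "gene" & g$gene_type == "V"]
  ## ranks 2-3 along the locus are flipped
  axis <- -GenomicRanges::start(g)   # cluster on '-': locus 5'->3' is right
  ord <- order(axis)
  strands <- as.character(GenomicRanges::strand(g))[ord]
  expect_equal(strands, c("+", "-", "-", "+", "+", "+"))
})

test_that("generation is deterministic under a fixed seed", {
  spec <- cleanSpec(seed = 77L)
  s1 <- simulateLocus(spec)
  s2 <- simulateLocus(spec)
  expect_identical(as.character(locusGenome(s1)),
                   as.character(locusGenome(s2)))
  uw <- uniformUsage(s1@germline)
  rs <- RepertoireSpec(uw, nReads = 50L, seed = 5L)
  r1 <- simulateRepertoireReads(s1@germline, rs)
  r2 <- simulateRepertoireReads(s1@germline, rs)
  expect_identical(r1$r1, r2$r1)
  expect_identical(r1$truth, r2$truth)
})

test_that("simulated reads are truth-consistent and overlap-mergeable", {
  sim <- cleanLocus()
  uw <- uniformUsage(sim@germline)
  rs <- RepertoireSpec(uw, nReads = 60L, productiveFraction = 0.75,
                       errorRate = 0, seed = 3L)
  reads <- simulateRepertoireReads(sim@germline, rs)
  gd <- as.data.frame(geneTable(sim@germline))
  expect_true(all(reads$truth$v %in% gd$name[gd$type == "V"]))
  expect_true(all(reads$truth$j %in% gd$name[gd$type == "J"]))
  expect_equal(sum(reads$truth$productive), round(0.75 * 60))
  ## pairs overlap: merged length reachable from the two mates
  expect_true(all(2L * rs@readLength - reads$truth$ampliconLength >= 10L))
  ## error-free reads reconstruct the amplicon exactly
  mg <- mergePairs(reads$r1, reads$r2)
  expect_equal(nrow(mg$merged), 60L)
  expect_identical(unname(mg$merged$seq),
                   unname(reads$amplicons[mg$merged$id]))
})
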