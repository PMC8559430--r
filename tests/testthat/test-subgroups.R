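# Identity computation, subgroup clustering, ortholog mapping, naming.

test_that("pairwise identity follows the alignment-column definition", {
  s <- strrep("ACGT", 75)   # 300 nt
  expect_equal(pairwiseIdentity(s, s), 100)
  ## 75 substitutions in 300 nt, no indels -> 75%
  set.seed(1)
  chars <- strsplit(s, "")[[1L]]
  pos <- sample(300L, 75L)
  for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1L]
  mutated <- paste0(chars, collapse = "")
  expect_equal(pairwiseIdentity(s, mutated), 75)
  ## end gaps count as mismatch columns
  expect_equal(pairwiseIdentity("ACGT", "ACG"), 75)
})

test_that("single-linkage clustering recovers planted subgroups", {
  gs <- simulateGermlineSet(LocusSpec(nSubgroups = 4L,
                                      genesPerSubgroup = c(2L, 4L),
                                      pseudogeneFraction = 0.2,
                                      orfFraction = 0.1, seed = 13L))
  gd <- as.data.frame(geneTable(gs))
  v <- gd[gd$type == "V", ]
  v <- v[order(v$locus_index), ]
  getV <- function(nm) {
    f <- gs@features[[nm]]
    vv <- f[f$feature == "V_REGION", ]
    substr(as.character(gs@regionSeqs[[nm]]), vv$from, vv$to)
  }
  seqs <- setNames(vapply(v$name, getV, ""), v$name)
  idm <- identityMatrix(seqs)
  cl <- clusterSubgroups(idm, threshold = 75)
  expect_equal(length(unique(cl)), 4L)
  expect_identical(unname(cl), unname(v$subgroup))
})

test_that("clustering degenerate cases and invariances", {
  seqs <- rep("ACGTACGTACGT", 4L)
  idm <- identityMatrix(setNames(seqs, paste0("g", 1:4)))
  expect_identical(unique(clusterSubgroups(idm)), 1L)
  expect_identical(clusterSubgroups(idm, threshold = 101),
                   1:4)
  ## order invariance up to relabeling
  set.seed(5)
  m <- matrix(60, 6, 6); diag(m) <- 100
  m[1:2, 1:2] <- 90; m[3:4, 3:4] <- 90; m[5:6, 5:6] <- 90
  dimnames(m) <- list(paste0("g", 1:6), paste0("g", 1:6))
  cl <- clusterSubgroups(m)
  perm <- sample(6L)
  cl2 <- clusterSubgroups(m[perm, perm])
  expect_identical(cl[perm] == cl[perm][1L], cl2 == cl2[1L])
  ## the boundary identity (exactly 75) joins
  m2 <- matrix(c(100, 75, 75, 100), 2, 2)
  expect_identical(unique(clusterSubgroups(m2)), 1L)
  m3 <- matrix(c(100, 74.9, 74.9, 100), 2, 2)
  expect_identical(clusterSubgroups(m3), 1:2)
})

test_that("ortholog mapping is greedy mutual best with duplicate flags", {
  a <- c(x = strrep("ACGT", 30), y = strrep("TGCA", 30))
  b <- c(x2 = strrep("ACGT", 30), z = strrep("GATC", 30))
  om <- mapOrthologs(a, b)
  expect_equal(om$geneB[om$geneA == "x" & !is.na(om$geneA)], "x2")
  expect_equal(om$identity[om$geneA == "x" & !is.na(om$geneA)], 100)
  expect_true("unmatched" %in% om$status[om$geneA == "y" |
                                           om$geneB == "z"])
  ## 85% best identity stays unmatched at the default 90 threshold
  s <- strrep("ACGT", 25)   # 100 nt
  chars <- strsplit(s, "")[[1L]]
  for (p in seq(1, 60, 4)) chars[p] <- "T"
  om2 <- mapOrthologs(c(g = s), c(h = paste0(chars, collapse = "")))
  expect_true(all(om2$status != "matched"))
  ## duplicated gene: one match, one duplicate flag
  dup <- c(d1 = strrep("ACGT", 30), d2 = strrep("ACGT", 30))
  om3 <- mapOrthologs(dup, c(t1 = strrep("ACGT", 30)))
  expect_equal(sum(om3$status == "matched"), 1L)
  expect_equal(sum(om3$status == "duplicate"), 1L)
})

test_that("names encode subgroup and within-subgroup locus rank", {
  sim <- cleanLocus()
  ann <- annotationOf(sim, "cleanAnn")
  gt <- geneTable(ann)
  v <- gt[gt$gene_type == "V"]
  ## ranks count along the locus 5'->3' (cluster transcribed right-to-left
  ## on this layout, so rank 1 is the rightmost V of each subgroup)
  for (sg in unique(v$subgroup)) {
    vs <- v[v$subgroup == sg]
    if (length(vs) == 1L) {
      expect_match(vs$name, sprintf("^TRAV%d$", sg))
    } else {
      ord <- order(-GenomicRanges::start(vs))
      expect_identical(vs$name[ord],
                       sprintf("TRAV%d-%d", sg, seq_along(ord)))
    }
  }
  ## TRAJ1 is adjacent to TRAC; TRDD1 at the locus 5' end
  ja <- gt[gt$gene_type == "J" & gt$chain == "TRA"]
  trac <- gt[!is.na(gt$cname) & gt$cname == "TRAC"]
  expect_equal(ja$name[which.min(abs(GenomicRanges::start(ja) -
                                       GenomicRanges::start(trac)))],
               "TRAJ1")
  dd <- gt[gt$gene_type == "D"]
  expect_equal(dd$name[which.max(GenomicRanges::start(dd))], "TRDD1")
  ## name collision detection
  g <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 10), c(5, 15)),
                              gene_type = "V", chain = "TRA",
                              subgroup = c(1L, 1L))
  g2 <- g
  g2$cname <- NA_character_
  expect_silent(assignNames(g2, "+"))
})

test_that("naming is invariant under reverse complementation", {
  sim <- cleanLocus()
  ann <- annotationOf(sim, "cleanAnn")
  rc <- Biostrings::reverseComplement(locusGenome(sim)[[1L]])
  ann2 <- annotateLocus(Biostrings::DNAStringSet(c(rc = as.character(rc))),
                        constantQueries(sim@germline))
  n <- Biostrings::width(locusGenome(sim))
  gt1 <- geneTable(ann); gt2 <- geneTable(ann2)
  expect_setequal(gt1$name, gt2$name)
  m <- match(gt1$name, gt2$name)
  ## coordinates mirror, strands flip
  expect_identical(GenomicRanges::start(gt1),
                   n - GenomicRanges::end(gt2)[m] + 1L)
  s1 <- as.character(GenomicRanges::strand(gt1))
  s2 <- as.character(GenomicRanges::strand(gt2))[m]
  expect_true(all(s1 != s2))
  expect_identical(gt1$functionality, gt2$functionality[m])
})
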