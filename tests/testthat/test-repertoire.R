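# Read merging, segment assignment, filters, productivity, normalization,
# usage tables.

repFixture <- function() fixture("repFixture", function() {
  sim <- cleanLocus()
  uw <- uniformUsage(sim@germline)
  spec <- RepertoireSpec(uw, nReads = 400L, productiveFraction = 0.8,
                         junctionTrimMax = 6L, nAdditionMax = 6L,
                         readLength = 300L, errorRate = 0, seed = 41L)
  reads <- simulateRepertoireReads(sim@germline, spec, sample = "s1")
  list(sim = sim, spec = spec, reads = reads)
})

test_that("constructed pairs merge to the expected length", {
  a <- testDNA(120, 21)
  b <- testDNA(90, 22)
  amp <- paste0(a, b)
  r1 <- substr(amp, 1, 120)
  r2 <- revComp(substr(amp, 91, 210))   # exact 30 nt overlap
  mg <- mergePairs(setNames(r1, "p1"), setNames(r2, "p1"), minLen = 100L)
  expect_equal(mg$merged$length, 120L + 120L - 30L)
  expect_equal(mg$merged$overlap, 30L)
  expect_identical(mg$merged$seq, amp)
  ## pair with no plausible overlap is dropped and counted
  mg2 <- mergePairs(setNames(testDNA(80, 23), "q"),
                    setNames(testDNA(80, 24), "q"), minLen = 50L)
  expect_equal(nrow(mg2$merged), 0L)
  expect_equal(mg2$dropped$reason, "no_overlap")
  ## id mismatch errors
  expect_error(mergePairs(setNames("ACGT", "x"), setNames("ACGT", "y")),
               "id mismatch")
})

test_that("error-free simulated pairs all merge to the exact amplicons", {
  fx <- repFixture()
  mg <- mergePairs(fx$reads$r1, fx$reads$r2)
  expect_equal(nrow(mg$merged), fx$spec@nReads)
  expect_identical(unname(mg$merged$seq),
                   unname(fx$reads$amplicons[mg$merged$id]))
  expect_true(all(mg$merged$length > 150L))
})

test_that("assignment filters implement the stated boundaries literally", {
  mkHits <- function(cLen = 60L, jId = 100, vId = 100, vLen = 300L) {
    data.table::data.table(
      readId = "r1", class = c("C", "J", "V"),
      gene = c("TRAC", "TRAJ1", "TRAV1-1"),
      identity = c(100, jId, vId),
      length = c(cLen, 50L, vLen), evalue = c(1e-30, 1e-20, 1e-40),
      readStart = c(400L, 350L, 1L), readEnd = c(460L, 400L, 300L),
      geneStart = 1L, geneEnd = c(60L, 50L, vLen), strand = "+")
  }
  pass <- function(h) nrow(filterAndDedupe(h)$assignments) == 1L
  reason <- function(h) filterAndDedupe(h)$dropped$reason
  expect_true(pass(mkHits()))
  ## C aligned length: 30 fails (strictly greater required), 31 passes
  expect_false(pass(mkHits(cLen = 30L)))
  expect_equal(reason(mkHits(cLen = 30L)), "C_too_short")
  expect_true(pass(mkHits(cLen = 31L)))
  ## identity 99.9 exactly fails (strict >), 100 passes
  expect_false(pass(mkHits(jId = 99.9)))
  expect_equal(reason(mkHits(jId = 99.9)), "J_identity")
  expect_false(pass(mkHits(vId = 99.9)))
  expect_equal(reason(mkHits(vId = 99.9)), "V_identity")
  ## V aligned length: 49 fails, 50 passes
  expect_false(pass(mkHits(vLen = 49L)))
  expect_equal(reason(mkHits(vLen = 49L)), "V_too_short")
  expect_true(pass(mkHits(vLen = 50L)))
})

test_that("among multiple hits the lowest expectancy wins", {
  h <- data.table::data.table(
    readId = "r1", class = c("C", "J", "V", "V"),
    gene = c("TRAC", "TRAJ1", "TRAV9", "TRAV2-1"),
    identity = c(100, 100, 100, 100),
    length = c(60L, 50L, 300L, 300L),
    evalue = c(1e-30, 1e-20, 1e-10, 1e-30),
    readStart = 1L, readEnd = 300L, geneStart = 1L, geneEnd = 300L,
    strand = "+")
  asg <- filterAndDedupe(h)$assignments
  expect_equal(asg$v, "TRAV2-1")
  ## expectancy tie: higher identity, then lexicographic name
  h2 <- data.table::copy(h)
  h2$evalue[3:4] <- 1e-30
  h2$identity[3:4] <- c(100, 99.95)
  expect_equal(filterAndDedupe(h2)$assignments$v, "TRAV9")
})

test_that("productivity calls follow frame and stop logic", {
  fx <- repFixture()
  gs <- fx$sim@germline
  gd <- as.data.frame(geneTable(gs))
  v <- gd$name[gd$type == "V" & gd$functionality == "F"][1L]
  j <- gd$name[gd$type == "J" & gd$chain == "TRA" &
                 gd$functionality == "F"][1L]
  segs <- as.character(segmentSequences(gs))
  cSeq <- segs[["TRAC"]]
  primerAt <- regexpr(revComp(tralocus:::GSP1_PRIMER), cSeq, fixed = TRUE)
  cPart <- substr(cSeq, 1L, primerAt + 40L)
  mkRead <- function(ins) paste0(segs[[v]], ins, segs[[j]], cPart)
  mkAsg <- function(seq) {
    vL <- nchar(segs[[v]]); jL <- nchar(segs[[j]])
    jS <- as.integer(regexpr(segs[[j]], seq, fixed = TRUE))
    cS <- as.integer(regexpr(cPart, seq, fixed = TRUE))
    data.frame(readId = "r", sample = "s", v = v, j = j, cGene = "TRAC",
               vReadStart = 1L, vReadEnd = vL, vGeneStart = 1L,
               vGeneEnd = vL, vStrand = "+",
               jReadStart = jS, jReadEnd = jS + jL - 1L, jGeneStart = 1L,
               jGeneEnd = jL, jStrand = "+",
               cReadStart = cS, cReadEnd = nchar(seq), cStrand = "+")
  }
  ## in-frame, stop-free junction -> productive
  good <- mkRead("GGAGGA")
  out <- classifyProductivity(mkAsg(good), setNames(good, "r"), gs)
  expect_true(out$productive)
  ## 1 nt insertion -> frameshift -> unproductive
  shift <- mkRead("GGAGG")
  out2 <- classifyProductivity(mkAsg(shift), setNames(shift, "r"), gs)
  expect_false(out2$productive)
  ## in-frame junction stop -> unproductive
  stopRead <- mkRead("TAAGGA")
  out3 <- classifyProductivity(mkAsg(stopRead), setNames(stopRead, "r"),
                               gs)
  expect_false(out3$productive)
})

test_that("normalization matches the median-of-ratios arithmetic", {
  ## single sample (0, 1, 3): size factor 1 -> log2(x + 1)
  n1 <- normalizeCounts(matrix(c(0, 1, 3), ncol = 1))
  expect_equal(as.vector(n1$normalized), c(0, 1, 2))
  expect_equal(n1$sizeFactors, 1)
  ## doubling one sample changes only its size factor, not its normalized
  ## values
  m <- matrix(c(4, 8, 16, 8, 16, 32), ncol = 2)
  n2 <- normalizeCounts(m)
  expect_equal(n2$normalized[, 1], n2$normalized[, 2])
  ## monotonicity within a sample
  set.seed(3)
  cnt <- matrix(rpois(40, 20) + 1, ncol = 2)
  n3 <- normalizeCounts(cnt)$normalized
  for (j in 1:2) {
    o <- order(cnt[, j])
    expect_true(all(diff(n3[o, j]) >= 0))
  }
  expect_error(normalizeCounts(matrix(c(0, 0), ncol = 1)), "all-zero")
})

test_that("usage tables partition reads and report percentages", {
  asg <- data.frame(
    readId = sprintf("r%03d", 1:100), sample = "s1",
    v = c(rep("TRAV2-1", 40), rep("TRAV3", 60)),
    j = rep(c("TRAJ1", "TRAJ2"), 50),
    productive = rep(TRUE, 100))
  asg$productive[96:100] <- FALSE
  u <- usageTables(asg)
  expect_equal(sum(u@vjProductive) + sum(u@vjUnproductive), 100)
  ## 40 of 95 productive reads use TRAV2-1
  p <- asg[asg$productive, ]
  expect_equal(unname(u@freqV["TRAV2-1", "s1"]),
               100 * sum(p$v == "TRAV2-1") / nrow(p))
  expect_equal(sum(u@freqV[, "s1"]), 100)
  expect_equal(sum(u@freqJ[, "s1"]), 100)
  ## conditional J usage sums to 100 within each used V
  expect_equal(unname(rowSums(u@conditionalJ[, , 1L])),
               rep(100, 2))
})

test_that("end-to-end repertoire run recovers truth on error-free reads", {
  fx <- repFixture()
  rep_ <- runRepertoire(fx$reads$r1, fx$reads$r2, fx$sim@germline,
                        sample = "s1")
  tr <- fx$reads$truth
  ## 100% merge
  expect_equal(nrow(rep_$merged), nrow(tr))
  ## every read assigned its true V and J
  m <- match(rep_$assignments$readId, tr$id)
  expect_false(anyNA(m))
  expect_equal(nrow(rep_$assignments), nrow(tr))
  expect_identical(rep_$assignments$v, tr$v[m])
  expect_identical(rep_$assignments$j, tr$j[m])
  ## productive fraction reproduced exactly
  expect_identical(rep_$assignments$productive, tr$productive[m])
  expect_equal(sum(rep_$assignments$productive),
               round(0.8 * fx$spec@nReads))
  ## conservation: merged = assigned + dropped
  expect_equal(nrow(rep_$merged),
               nrow(rep_$assignments) + nrow(rep_$droppedFilter))
})

test_that("usage frequencies match the planted weights within 3 SD", {
  fx <- repFixture()
  rep_ <- fixture("repRun", function()
    runRepertoire(fx$reads$r1, fx$reads$r2, fx$sim@germline,
                  sample = "s1"))
  tr <- fx$reads$truth
  w <- fx$spec@usageWeights
  counts <- table(factor(rep_$assignments$v, rownames(w)),
                  factor(rep_$assignments$j, colnames(w)))
  n <- sum(counts)
  for (i in seq_len(nrow(w))) for (j in seq_len(ncol(w))) {
    p <- w[i, j]
    sd3 <- 3 * sqrt(p * (1 - p) / n)
    expect_lte(abs(counts[i, j] / n - p), sd3 + 1e-9)
  }
})
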