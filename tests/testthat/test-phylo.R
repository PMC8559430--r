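# Poisson distances, neighbor joining, bootstrap.

test_that("Poisson distance matches the closed form", {
  expect_identical(poissonDistance("ACDEFG", "ACDEFG"), 0)
  ## p = 0.5 -> -ln(0.5)
  expect_equal(poissonDistance("AAAA", "AACC"), -log(0.5),
               tolerance = 1e-12)
  expect_equal(poissonDistance("AAAAAAAAAA", "AAAAAAAAAC"), -log(0.9),
               tolerance = 1e-12)
})

test_that("gap handling uses pairwise deletion (column-count oracle)", {
  a <- "AC-DE.FGH"
  b <- "ACXD-WFG-"
  ## brute-force column oracle
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  keep <- !(av %in% c("-", ".")) & !(bv %in% c("-", "."))
  p <- mean(av[keep] != bv[keep])
  expect_equal(poissonDistance(a, b), -log(1 - p), tolerance = 1e-12)
  ## no comparable sites -> error; saturation -> Inf with warning
  expect_error(poissonDistance("--", "AA"), "comparable")
  expect_warning(d <- poissonDistance("AC", "CA"), "saturated")
  expect_identical(d, Inf)
})

test_that("distance matrix is symmetric with zero diagonal", {
  aln <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKV", c = "ACDWFGHIKV")
  m <- poissonDistMatrix(aln)
  expect_identical(m, t(m))
  expect_identical(unname(diag(m)), rep(0, 3))
  expect_true(m["a", "b"] < m["a", "c"])
})

test_that("NJ recovers topology and branch lengths of additive matrices", {
  ## ((A:2,B:3):1,(C:4,D:5)) -> additive distances
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 2 + 3
  d["A", "C"] <- d["C", "A"] <- 2 + 1 + 4
  d["A", "D"] <- d["D", "A"] <- 2 + 1 + 5
  d["B", "C"] <- d["C", "B"] <- 3 + 1 + 4
  d["B", "D"] <- d["D", "B"] <- 3 + 1 + 5
  d["C", "D"] <- d["D", "C"] <- 4 + 5
  tree <- njTree(d)
  ## the (A,B) | (C,D) split is recovered
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  splits <- lapply(parts, function(p) sort(labs[p]))
  expect_true(any(vapply(splits, identical, TRUE, c("A", "B"))) ||
                any(vapply(splits, identical, TRUE, c("C", "D"))))
  ## pairwise path lengths reproduce the input exactly
  expect_equal(as.matrix(ape::cophenetic.phylo(tree))[rownames(d),
                                                      colnames(d)],
               d, tolerance = 1e-9)
  ## 3 taxa: closed-form branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- njTree(d3)
  el <- setNames(t3$edge.length,
                 t3$tip.label[t3$edge[, 2L]])
  expect_equal(unname(el[c("x", "y", "z")]), c(1, 2, 3), tolerance = 1e-9)
  expect_error(njTree(d3[1:2, 1:2]), "3 taxa")
  dInf <- d3; dInf[1, 2] <- dInf[2, 1] <- Inf
  expect_error(njTree(dInf), "undefined")
})

test_that("bootstrap gives full support to clean clades, deterministically", {
  ## two well-separated clades; a shared constant block keeps every
  ## pairwise p below saturation
  aln <- c(a1 = "GAAAAAAAAAWWWWWDDDDDEEEEEKKKKKLLLLL", a2 = "AAAAAAAAAAWWWWWDDDDDEEEEEKKKKKLLLLL",
           b1 = "GCCCCCCCCCHHHHHDDDDDEEEEEKKKKKLLLLL", b2 = "CCCCCCCCCCHHHHHDDDDDEEEEEKKKKKLLLLL")
  boot <- bootstrapSupport(aln, nReps = 100L, seed = 4L)
  expect_true(all(boot$supports >= 0 & boot$supports <= 100))
  expect_equal(unname(cladeSupport(boot, c("a1", "a2"))), 100)
  boot2 <- bootstrapSupport(aln, nReps = 100L, seed = 4L)
  expect_identical(boot$supports, boot2$supports)
})

test_that("planted subgroups are monophyletic with strong support", {
  gs <- simulateGermlineSet(LocusSpec(nSubgroups = 4L,
                                      genesPerSubgroup = c(3L, 3L),
                                      pseudogeneFraction = 0,
                                      orfFraction = 0, seed = 19L))
  gd <- as.data.frame(geneTable(gs))
  v <- gd[gd$type == "V", ]
  ## align the V domains only (leaders are not subgroup-structured)
  aas <- setNames(vapply(v$name, function(nm) {
    f <- gs@features[[nm]]
    vv <- f[f$feature == "V_REGION", ]
    translateFrame(substr(as.character(gs@regionSeqs[[nm]]),
                          vv$from, vv$to), 0L)
  }, ""), v$name)
  aln <- alignProteins(aas)
  boot <- bootstrapSupport(aln, nReps = 100L, seed = 2L)
  for (sg in unique(v$subgroup)) {
    sup <- cladeSupport(boot, v$name[v$subgroup == sg])
    expect_gte(sup, 80)
  }
})

test_that("center-star aligner preserves sequences and equalizes length", {
  seqs <- c(s1 = "ACDEFGHIKLM", s2 = "ACDEGHIKLM", s3 = "ACDEFGWHIKLM")
  aln <- alignProteins(seqs)
  expect_equal(length(unique(nchar(aln))), 1L)
  expect_identical(gsub("-", "", aln), seqs)
})
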