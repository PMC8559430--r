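# RS motif scanner: planted motifs, mismatch ranking, brute-force oracle.

test_that("a planted canonical V-RS is the single top hit", {
  s <- paste0(testDNA(50, 1), "CACAGTG", strrep("A", 22), "ACAAAAACC",
              testDNA(50, 2))
  hits <- scanRS(s, "V")
  expect_gte(nrow(hits), 1L)
  top <- hits[1L, ]
  expect_equal(top$heptamerStart, 51L)
  expect_equal(top$spacer, 22L)
  expect_equal(top$heptMismatch + top$nonaMismatch, 0L)
  expect_equal(top$strand, "+")
})

test_that("mismatched heptamers are reported and ranked below exact hits", {
  s <- paste0("CACAGTG", strrep("T", 22), "ACAAAAACC", strrep("G", 20),
              "CACAGTT", strrep("T", 22), "ACAAAAACC")
  hits <- scanRS(s, "V")
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$heptMismatch, c(0L, 1L))
  expect_true(hits$score[1L] < hits$score[2L])
  ## beyond tolerance: dropped
  s2 <- sub("CACAGTT", "CACAGAA", s)
  hits2 <- scanRS(s2, "V")
  expect_equal(nrow(hits2), 1L)
  ## CAC core must be exact by default
  s3 <- sub("CACAGTT", "CTCAGTG", s)
  expect_equal(nrow(scanRS(s3, "V")), 1L)
  expect_equal(nrow(scanRS(s3, "V", heptCACExact = FALSE)), 2L)
})

test_that("J-kind hits report the gene strand opposite to the pattern", {
  ## J-RS in gene orientation: rc(nonamer) + 12 + rc(heptamer)
  s <- paste0(testDNA(30, 3), "GGTTTTTGT", strrep("C", 12), "CACTGTG",
              testDNA(30, 4))
  hits <- scanRS(s, "J")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  ## same motif reverse-complemented: gene strand flips
  src <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  hits2 <- scanRS(src, "J")
  expect_equal(hits2$strand, "-")
})

test_that("scanner agrees with the brute-force window oracle on 10 kb", {
  s <- testDNA(10000, 42)
  for (kind in c("V", "J")) {
    spacers <- if (kind == "V") 22:23 else 11:13
    hits <- scanRS(s, kind)
    oracle <- bruteForceRS(s, spacers)
    nOracle <- sum(!is.null(oracle$fwd) && nrow(oracle$fwd),
                   !is.null(oracle$rev) && nrow(oracle$rev))
    nOracle <- (if (is.null(oracle$fwd)) 0L else nrow(oracle$fwd)) +
      (if (is.null(oracle$rev)) 0L else nrow(oracle$rev))
    expect_equal(nrow(hits), nOracle)
    ## positions agree: oracle forward-strand pattern starts
    if (!is.null(oracle$fwd)) {
      patPlus <- if (kind %in% c("V", "D3")) "+" else "-"
      got <- sort(hits$start[hits$strand == if (kind == "V") "+" else "-"])
      expect_equal(got, sort(unname(oracle$fwd[, "start"])))
    }
  }
})

test_that("window argument restricts the scan", {
  s <- paste0(testDNA(100, 5), "CACAGTG", strrep("A", 22), "ACAAAAACC",
              testDNA(100, 6))
  expect_equal(nrow(scanRS(s, "V", window = c(1L, 90L))), 0L)
  expect_gte(nrow(scanRS(s, "V", window = c(50L, 200L))), 1L)
  expect_error(scanRS(s, "V", window = c(1L, 10000L)))
})
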