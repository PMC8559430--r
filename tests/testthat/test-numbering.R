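# IMGT-style numbering against the packaged template.

test_that("the template numbers itself with canonical anchors", {
  tpl <- loadVTemplate()
  num <- imgtNumberV(tpl$aa, tpl)
  expect_true(num$success)
  expect_equal(unname(num$residues[c("23", "41", "104")]),
               c("C", "W", "C"))
  ## template CDR lengths: 8 / 6 / 3
  expect_equal(unname(num$cdrLengths), c(8L, 6L, 3L))
  expect_equal(cdrTriplet(num), "[8.6.3]")
})

test_that("CDR edits are measured through the alignment", {
  tpl <- loadVTemplate()
  chars <- strsplit(tpl$aa, "")[[1L]]
  reg <- tpl$region
  ## CDR1 trimmed to 7, CDR2 to 6 (unchanged), CDR3 kept at 3 -> [7.6.3]
  keep <- rep(TRUE, length(chars))
  keep[which(reg == "CDR1")[1L]] <- FALSE
  v763 <- paste0(chars[keep], collapse = "")
  expect_equal(cdrTriplet(imgtNumberV(v763, tpl)), "[7.6.3]")
  ## CDR2 deleted entirely -> length 0 (legitimate)
  v0 <- paste0(chars[reg != "CDR2"], collapse = "")
  num0 <- imgtNumberV(v0, tpl)
  expect_equal(unname(num0$cdrLengths[["cdr2"]]), 0L)
  expect_true(num0$success)
  ## CDR1 grown by two residues
  at <- max(which(reg == "CDR1"))
  vplus <- paste0(c(chars[1:at], "K", "R", chars[(at + 1L):length(chars)]),
                  collapse = "")
  expect_equal(unname(imgtNumberV(vplus, tpl)$cdrLengths[["cdr1"]]), 10L)
})

test_that("substituted anchors are reported at their positions", {
  tpl <- loadVTemplate()
  chars <- strsplit(tpl$aa, "")[[1L]]
  chars[which(tpl$pos == 23L)] <- "Y"   # TRAV1-style Tyr23
  num <- imgtNumberV(paste0(chars, collapse = ""), tpl)
  expect_equal(unname(num$residues[["23"]]), "Y")
  expect_equal(unname(num$residues[["104"]]), "C")
})

test_that("numbering fails gracefully on non-V input", {
  tpl <- loadVTemplate()
  set.seed(8)
  junk <- paste0(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], 90,
                        replace = TRUE), collapse = "")
  num <- imgtNumberV(junk, tpl)
  expect_false(num$success)
})
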