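# Deterministic functionality mapping.

test_that("defects map to F/ORF/P as specified", {
  expect_equal(classifyFunctionality(character(), "V", "TRA"), "F")
  expect_equal(classifyFunctionality("rs_defect", "V", "TRA"), "ORF")
  expect_equal(classifyFunctionality("splice_defect", "V", "TRA"), "ORF")
  expect_equal(classifyFunctionality("stop_codon", "V", "TRA"), "P")
  expect_equal(classifyFunctionality("frameshift", "V", "TRA"), "P")
  ## P dominates ORF-class defects
  expect_equal(classifyFunctionality(c("rs_defect", "stop_codon"),
                                     "V", "TRA"), "P")
  expect_equal(classifyFunctionality("missing_FGXG", "J", "TRA"), "ORF")
})

test_that("TRDJ is exempt from the FGXG requirement", {
  expect_equal(classifyFunctionality("missing_FGXG", "J", "TRD"), "F")
  expect_equal(classifyFunctionality(c("missing_FGXG", "stop_codon"),
                                     "J", "TRD"), "P")
})

test_that("conserved-residue changes demote only under the strict policy", {
  expect_equal(classifyFunctionality("missing_conserved_residue",
                                     "V", "TRA"), "F")
  expect_equal(classifyFunctionality("missing_conserved_residue",
                                     "V", "TRA", strictConserved = TRUE),
               "ORF")
  ## with imperfect RS evidence the gene is ORF anyway
  expect_equal(classifyFunctionality(c("missing_conserved_residue",
                                       "rs_defect"), "V", "TRA"), "ORF")
})
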