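# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

## small, defect-free locus (fast; used for exact-recovery checks)
cleanSpec <- function(seed = 11L)
  LocusSpec(nSubgroups = 3L, genesPerSubgroup = c(2L, 2L),
            pseudogeneFraction = 0, orfFraction = 0, nTRAJ = 4L,
            nTRDD = 2L, intergenicRange = c(200L, 400L), seed = seed)

cleanLocus <- function() fixture("cleanLocus", function()
  simulateLocus(cleanSpec()))

## small locus carrying every defect class
defectSpec <- function(seed = 23L)
  LocusSpec(nSubgroups = 3L, genesPerSubgroup = c(3L, 4L),
            pseudogeneFraction = 0.3, orfFraction = 0.2, nTRAJ = 6L,
            nTRDD = 2L, intergenicRange = c(200L, 400L), seed = seed)

defectLocus <- function() fixture("defectLocus", function()
  simulateLocus(defectSpec()))

annotationOf <- function(sim, name, ...) fixture(name, function()
  annotateLocus(locusGenome(sim), constantQueries(sim@germline), ...))

## brute-force RS oracle: enumerate every window on both strands
bruteForceRS <- function(seqchar, spacers, maxHept = 1L, maxNona = 3L,
                         cacExact = TRUE) {
  hept <- "CACAGTG"; nona <- "ACAAAAACC"
  mism <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))
  scan1 <- function(s) {
    n <- nchar(s)
    out <- list()
    for (sp in spacers) {
      lastStart <- n - (16L + sp) + 1L
      if (lastStart < 1L) next
      for (i in seq_len(lastStart)) {
        h <- substr(s, i, i + 6L)
        if (cacExact && substr(h, 1L, 3L) != "CAC") next
        hm <- mism(h, hept)
        if (hm > maxHept) next
        ns <- i + 7L + sp
        nm <- mism(substr(s, ns, ns + 8L), nona)
        if (nm <= maxNona)
          out[[length(out) + 1L]] <- c(start = i, spacer = sp,
                                       hm = hm, nm = nm)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seqchar)))
  list(fwd = scan1(seqchar), rev = scan1(rc))
}

## deterministic random DNA for tests
testDNA <- function(n, seed) {
  set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
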