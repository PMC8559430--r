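#' @import methods
#' @importFrom stats median rbinom runif setNames
#' @importFrom utils head tail write.table read.table
NULL

.datatable.aware <- TRUE

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

## All 61 sense codons, and the subset that is also not ATG (used when a
## reading frame must stay free of internal initiation codons).
senseCodons <- function(exclude = character()) {
  cod <- apply(expand.grid(BASES, BASES, BASES), 1L, paste0, collapse = "")
  setdiff(cod, c(STOP_CODONS, exclude))
}

#' Run code under a locally-seeded RNG without touching the global stream
#' @noRd
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

randomDNA <- function(n) {
  paste0(sample(BASES, n, replace = TRUE), collapse = "")
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Translate a nucleotide string from a 0-based frame offset; incomplete
## trailing codons are dropped; stops appear as '*', ambiguous codons as
## 'X'. Direct lookup against the standard genetic code (hot path).
translateFrame <- local({
  code <- NULL
  function(x, frame = 0L) {
    if (is.null(code)) code <<- Biostrings::GENETIC_CODE
    x <- substr(x, frame + 1L, nchar(x))
    n <- nchar(x) - nchar(x) %% 3L
    if (n < 3L) return("")
    cods <- substring(x, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
    aa <- unname(code[cods])
    aa[is.na(aa)] <- "X"
    paste0(aa, collapse = "")
  }
})

hasInFrameStop <- function(x, frame = 0L) {
  grepl("*", translateFrame(x, frame), fixed = TRUE)
}

## Mismatch count between two equal-length strings (vectorised over chars)
strMismatch <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

## All start positions of a fixed-length pattern within `subject` allowing
## `max.mismatch` mismatches (thin wrapper kept for clarity)
patternHits <- function(pattern, subject, max.mismatch = 0L) {
  Biostrings::start(Biostrings::matchPattern(pattern, subject,
                                             max.mismatch = max.mismatch))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## sample() treats a length-1 vector as 1:n; this draws from [lo, hi]
sampleRange <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

## as.character() drops names; sequence sets must keep them
asNamedCharacter <- function(x) {
  nm <- names(x)
  x <- as.character(x)
  names(x) <- nm
  x
}

## all (overlapping) match positions of a regex/literal motif
allMatches <- function(pattern, s) {
  g <- gregexpr(paste0("(?=", pattern, ")"), s, perl = TRUE)[[1L]]
  out <- as.integer(g)
  out[out > 0L]
}
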