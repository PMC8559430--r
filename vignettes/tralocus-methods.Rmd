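---
title: "Annotating teleost TRA/TRD loci and profiling TR-alpha repertoires with tralocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating teleost TRA/TRD loci and profiling TR-alpha repertoires with tralocus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`tralocus` implements two connected analyses for teleost T-cell receptor
alpha/delta (TRA/TRD) loci.

The first is **germline annotation**: given a genomic contig and a small set
of constant-region (TRAC/TRDC) query sequences, the package locates the
constant genes by spliced alignment, and uses their transcriptional strand to
define the locus orientation. V, D and J genes are then discovered from their
recombination signal (RS) sequences — the conserved heptamer
(`CACAGTG`)/spacer/nonamer (`ACAAAAACC`) motifs that flank every rearranging
segment — combined with splice-site delimitation of the coding regions: an
L-PART1 leader exon starting at ATG and ending at a donor site, an acceptor
site opening the L-PART2 + V-REGION exon that runs flush into the V
heptamer, a J-REGION running from the J heptamer to a donor site, and a
D-REGION bracketed by its 5' (12-spacer) and 3' (23-spacer) RS. Genes are
classified under IMGT-style functionality rules: a stop codon or frameshift
makes a pseudogene (P); an intact reading frame with a defective splice
site, defective RS, or (for TRAJ) a lost FGXG hallmark motif makes an ORF;
everything else is functional (F). V domains are numbered against a gapped
template so that the conserved 1st-CYS sits at position 23, the conserved
tryptophan at 41 and the 2nd-CYS at 104, which also yields the CDR1/CDR2
and germline-CDR3 lengths reported in census tables. Functional/ORF V genes
sharing at least 75% V-REGION nucleotide identity form a subgroup, and
names follow the rank-in-locus convention (`TRAV2-2` = subgroup 2, second
gene of that subgroup along the locus 5'→3' orientation; single-gene
subgroups drop the suffix; `TRAJ1` is the TRAC-proximal J; TRDD numbering
starts at the locus 5' end).

The second analysis is **repertoire profiling** of constant-primed 5'-RACE
TR-alpha amplicon sequencing: read pairs are overlap-merged (FLASH-style),
the germline C/J/V segments are matched against the merged reads with
BLAST+, and a read is assigned when it carries a C region longer than 30
bp, a J hit above 99.9% identity and a V hit above 99.9% identity covering
at least 50 bp; among competing hits the lowest expectancy wins. Each
assigned read is called productive when the V, J and C segments share one
reading frame and the translation from the V 2nd-CYS through the junction
into the C region is stop-free; frameshifted or stop-containing junctions
are unproductive. Counts are normalized with median-of-ratios size factors
followed by `log2(x + 1)`, and reported as V/J marginal frequencies
(percent of productive rearrangements), V×J matrices and per-V conditional
J-usage profiles.

## Phylogenetics

Functional V protein sequences are compared with Poisson-corrected
distances, `d = -ln(1 - p)` with `p` the fraction of differing sites under
pairwise gap deletion, followed by neighbor joining and non-parametric
bootstrap (columns resampled with replacement; default 500 replicates;
supports are the percentage of replicate trees containing each bipartition
of the original tree). Maximum-likelihood tree search is deliberately out
of scope; the Poisson/NJ stack is the quantitative backbone and is exact
on additive distance matrices. A small center-star progressive aligner is
included for self-contained analyses of closely related V sets; externally
computed alignments can be supplied instead.

## The synthetic-data generator

Every stage can be exercised without downloads through a ground-truthed
generator, and the generator's defaults define the package's validation
conditions:

* **Locus architecture.** The teleost layout is emitted exactly: on the
  Watson strand a V-gene array (transcribed `+`) followed by the
  TRAC–TRAJ–TRDC–TRDJ–TRDD cluster in inverted orientation, so that the
  locus read along the cluster's transcription runs
  TRDD–TRDJ–TRDC–TRAJ–TRAC with the V genes downstream in opposite
  orientation. An optional block of V genes can be planted inverted.
* **Subgroup structure.** V-REGIONs descend from a common root by
  substitution at rates solved numerically so that the expected
  within-subgroup identity (default 0.88) and between-subgroup identity
  (default 0.60) straddle the 75% clustering threshold; conserved anchor
  codons (23/41/104) are frozen. CDR1/CDR2/germline-CDR3 lengths vary per
  subgroup (4–9, 0–8, 2–4 codons). Requested identities that substitution
  cannot realize raise an explicit error.
* **Defects.** Default fractions: 30% pseudogenes (stop codon or 1-nt
  frameshift, 1:1) and 10% ORF-class genes (degenerate RS heptamer or
  broken acceptor site for V; FGXG→FGKA motif loss for TRAJ), applied to V
  and TRAJ genes. The single TRDJ gene carries the salmonid-type FGKA
  motif and stays functional under the TRDJ policy. Conserved-residue
  substitutions are not planted as ORF defects because, under the default
  classification policy, they do not demote functionality on their own
  (the TRAV1-type Tyr-23 gene remains F); that path is exercised in unit
  tests with the strict policy flag.
* **Unambiguous splice context.** Donors are written with the extended
  consensus `GTAAGT`, acceptors with a pyrimidine-rich tail ending in
  `AG`, and local redraw-guards remove competing motifs (no in-frame ATG
  inside L-PART1, no AG inside L-PART2, no spurious `AAGT`/`GTAAG`/`TTCCA`
  inside introns, no `GTAAG` or off-frame FGXG inside J-REGIONs). This
  makes each planted gene's structure uniquely parseable, which is what
  turns "perfect recovery" into a well-defined property. Real loci do not
  satisfy these guarantees — degenerate splice sites, nested ATGs and
  repeat content all occur — so passing the planted-locus tests
  demonstrates correctness of the search logic, not field accuracy on
  arbitrary genomes.
* **Reads.** Amplicons are leader + V-REGION (3'-trimmed, uniform 0–6 nt)
  + 0–6 untemplated N nucleotides + 5'-trimmed J-REGION + the start of the
  constant exon up to the constant-primer site (the TRAC exon 1 carries
  the reverse complement of the gene-specific primer at a stop-free frame
  offset). The productive fraction is planted exactly by construction:
  productive reads get an N-length that keeps V, J and C in one frame and
  a stop-free junction; unproductive reads are frameshifted or receive an
  in-frame junction stop (1:1). Sequencing error is substitution-only;
  qualities are constant because the pipeline never reads them. Reads are
  2×300 nt so pairs always overlap across the ~500 bp amplicon.

## Numerical and design choices

* **RS scanning tolerances** (the source protocols leave them
  unspecified): ≤1 heptamer mismatch with the CAC core exact and ≤3
  nonamer mismatches; V/3'D spacers 22–23 nt, J/5'D spacers 11–13 nt. V
  discovery runs a relaxed scan (≤2/≤4, CAC free) so genes with degenerate
  RS are still found and annotated ORF; candidates must then show credible
  V-domain homology. De novo D discovery and motif-less (ORF) J
  candidates demand near-exact RS matches, because no coding-homology
  evidence is available to reject random motif hits.
* **Template-homology floors.** A candidate's translated tail must align
  to the numbering template with score ≥60 over ≥25 columns (BLOSUM62,
  gap 10/1). For N-terminally anchored alignments (the intact prefix of a
  frameshifted pseudogene) the floor drops to 45/15: anchoring pins the
  boundary and empirically the best random alignments stay below 40.
* **Boundary determination.** Because the V-REGION ends flush at the
  heptamer, its reading frame is fixed modulo 3; the template alignment is
  therefore computed once per frame, and the position of template residue
  1 is extrapolated from the modal FR1 alignment diagonal (FR1, positions
  1-26, carries no indels, so its aligned columns stay colinear even when
  a local-alignment gap slips the first columns). The strongest FR1
  diagonal identifies the true reading frame; a frameshifted gene shows
  FR1 evidence in both the prefix and the shifted-suffix frame, and the
  pick counts as anchored only when its FR1 evidence clearly dominates.
  Acceptors are enumerated from the
  L-PART2 length window (8–14 nt, always 2 mod 3, hence leaders need
  L-PART1 ≡ 1 mod 3); the canonical window is searched first and only
  non-anchored (frameshift) candidates retry with a widened window.
  Leader search prefers the shortest intron and the innermost ATG.
* **Identity definition.** Percent identity is matches over all alignment
  columns of a global, end-gap-penalized alignment, so length differences
  count against identity. Exactly 75.0% joins a subgroup (inclusive
  threshold). Single linkage is the default because IMGT subgroup
  membership is any-member similarity; complete linkage is available.
* **Normalization.** The median-of-ratios + `log2(x+1)` transform is a
  stand-in for the regularized log transform of count-based differential
  expression frameworks; it reproduces size-factor cancellation (a
  library-size duplicate of a sample normalizes to identical values) and
  within-sample monotonicity but not that estimator's variance shrinkage.
* **Expectancy.** BLAST e-values order competing hits; any
  monotone-equivalent score would give the same dedup decisions, which is
  the only property the pipeline relies on.
* **Ties.** Overlapping V candidates keep the best template score, then
  fewest RS mismatches, then the leftmost; J candidates keep the best RS.
  NJ tie-breaking follows taxon input order; negative NJ branch lengths
  are clamped to zero with a warning.

## Validation problem sizes

The packaged test-suite and the acceptance script validate on: 20 seeded
synthetic loci of ~50 genes each (exact recovery of coordinates, strand,
type, functionality and names), subgroup recovery on 5 germline sets, RS
scanner equivalence with exhaustive enumeration on 10 kb, closed-form
Poisson/NJ checks, a 10,000-pair error-free repertoire (100% merge and
assignment, exact productive fraction, V×J frequencies within 3 binomial
standard deviations of the planted weights) and normalization invariances.
These sizes keep a full validation run in the minutes range on one core
while giving each property enough events to fail loudly when broken.

## Known limitations

* The annotator's splice model assumes near-consensus sites; highly
  degenerate acceptors/donors are reported as splice defects rather than
  resolved, and leaders interrupted by in-frame upstream ATGs can be
  mis-delimited.
* Sub-feature boundaries (L-PART2/V-REGION split) of frameshifted
  pseudogenes are defined only up to the template alignment's anchor.
* No repeat masking and no screening for embedded non-TR genes: the input
  is assumed to be a candidate TRA/TRD contig.
* Clonotype collapsing, diversity indices, somatic hypermutation analysis
  and tissue-preference statistics are out of scope; the package reports
  frequencies, not tests.
* The `>99.9%` assignment identity filter effectively demands an exact
  segment match for references shorter than 1 kb; with realistic
  sequencing error rates a substantial fraction of reads is discarded by
  design, exactly as in the reference protocol.
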