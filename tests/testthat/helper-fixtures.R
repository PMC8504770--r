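# Small shared fixtures, all generated in code.

# Compact bundle: 2 chromosomes + 1 scaffold, 3 families, a few context
# plants; fast enough for per-test regeneration.
miniBundle <- function(seed = 11L, geneCount = 8L) {
  families <- list(
    FamilySpec("famA", "RLX", 400L),
    FamilySpec("famB", "DTX", 300L, tirLength = 20L, tsdLength = 2L,
               tsdMotif = "TA"),
    FamilySpec("famC", "MITE", 250L, tirLength = 15L, tsdLength = 8L,
               tsdMotif = "random-8"))
  bursts <- list(
    BurstSpec("famA", 6L, 0.02, deletionProb = 0.2),
    BurstSpec("famB", 6L, 0.05),
    BurstSpec("famC", 5L, 0.00))
  plan <- data.frame(
    category = c("next_to_gene", "te_inside_gene_exonic",
                 "te_inside_gene_intronic", "gene_inside_te",
                 "overlap_5prime", "overlap_3prime",
                 "boundary_gene_start_eq_te_end",
                 "boundary_gene_end_eq_te_start"),
    count = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  gspec <- GenomeSpec(
    chromosomeLengths = c(chr1 = 60000, chr2 = 60000, scaf1 = 30000),
    geneCount = geneCount, exonsPerGene = c(2L, 4L),
    teGeneDistancePlan = plan, seed = seed)
  buildGenome(gspec, families, bursts)
}

# Burst-recovery study conditions: ten 1-kb families, two bursts of
# nPerBurst copies at 0.02 and 0.20 each, no genes (ages only).
burstSweepBundle <- function(seed, nPerBurst = 15L) {
  sp <- defaultMobilomeSpecs(seed = seed, nPerBurst = nPerBurst)
  gspec <- GenomeSpec(
    chromosomeLengths = c(c1 = 340000, c2 = 340000, c3 = 340000,
                          c4 = 340000),
    geneCount = 0L, seed = seed)
  buildGenome(gspec, sp$families, sp$bursts)
}

# Divergence-based age histogram peaks for a bundle.
bundleBurstPeaks <- function(bundle, binWidth = 0.01) {
  cs <- extractCopySequences(genomeSeq(bundle), teCopies(bundle))
  fams <- names(consensusLibrary(bundle))
  div <- unlist(lapply(fams, function(fam) {
    ids <- teCopies(bundle)$ID[teCopies(bundle)$family == fam]
    msa <- alignFamily(as.character(consensusLibrary(bundle)[[fam]]),
                       cs[ids], consensusId = fam)
    copyConsensusDivergence(msa)
  }))
  detectBursts(burstHistogram(div[!is.na(div)], binWidth = binWidth))
}

randomSeq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
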