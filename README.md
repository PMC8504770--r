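# TEmobilome

Survey the transposable-element (TE) content of a draft genome assembly:
coverage accounting over TE annotations, copy-age estimation from
master–slave alignments, structural MITE discovery, and TE–gene
insertion-context classification — with a seeded synthetic-mobilome
generator so that every stage can be validated against known ground
truth.

The package targets the situation typical of draft insect assemblies
(the motivating system is the Hessian fly, *Mayetiola destructor*, a
~153 Mb dipteran genome): a de novo TE consensus library, a GFF3 of
annotated copies, and a gene annotation, from which one wants the
repeat landscape, the timing of transposition bursts, and the
relationship between mobile elements and genes.

## What it computes

**Inventory.** Copies are flagged full-length (FLC) when they cover
strictly more than 95% of their family consensus. The consensus
library is filtered by the survey rules: drop SSR consensuses, drop
unclassified (noCat) consensuses built from fewer than 10 copies, drop
consensuses without a single FLC. Genome coverage per class / order /
family / chromosome is the length of the *union* of the group's
intervals divided by the total assembly length (an "Un"
pseudo-chromosome pools unplaced scaffolds).

**Copy ages.** Copies longer than 100 bp are globally aligned to their
consensus (Needleman–Wunsch with affine gaps; defaults +1/−1, gap open
−4, extend −1) and stacked into a master–slave multiple alignment whose
columns are consensus positions (slave-only insertions are dropped and
logged). The age of a copy is its p-distance from the consensus —
substitutions per base pair over columns where both rows carry an
unambiguous base. Terminal-fork ("cherry") pairs of a neighbor-joining
tree built on pairwise p-distances date the most recent transposition
events. The age distribution is binned at 0.01 substitutions/bp and
local maxima of a 3-bin smoothed profile are reported as transposition
bursts.

**MITEs.** A structural scan reports every interval (50–800 bp by
default) whose ends form a terminal inverted repeat (TIR ≥ 10 bp, ≤ 2
mismatches), validates the target-site duplication (TSD; largest
identical flanking k-mer, k = 2..10), clusters candidates into families
by greedy centroid clustering at 80% global-alignment identity, and
assigns superfamilies from a TSD/TIR signature table (TA →
Tc1/mariner, TTAA → PiggyBac, 8-bp TSD → hAT/P, TAA/TTA →
Pif-Harbinger, CACT-initial TIR → CACTA).

**Gene context.** Each copy is related to its nearest gene(s)
(edge-to-edge gap, ties on both sides kept) and classified into
positional categories — gene inside TE, TE inside gene
(exonic/intronic), overlap of the strand-aware 5′ or 3′ gene end, exact
boundary abutment, within 2 kb, or none — with sense/antisense
orientation. Orientation bias is tested per category (Pearson
goodness-of-fit against 50:50, df 1) and across categories (Pearson
independence on the k×2 table, df k−1). Copies below 2% divergence
feed a recent-insertion report by superfamily and insertion site.

**Synthetic mobilome.** `buildGenome()` plants TE families (with TIRs
and TSDs for class II), mutates copies under a single-hit HKY85-style
substitution process at chosen divergences (the default study
conditions put two bursts, at 0.02 and 0.20 substitutions/bp, in each
of ten 1-kb families), applies internal deletions/truncations, and
places genes in controlled positional contexts — returning the genome,
annotations and a ground-truth table.

## Worked example

```r
library(TEmobilome)

sp     <- defaultMobilomeSpecs(seed = 1)
bundle <- buildGenome(sp$genome, sp$families, sp$bursts)
bundle
#> MobilomeBundle: 6 sequences, 10 consensi, 300 TE copies, 60 genes
#>   genome: 2500000 bp

gl <- setNames(Biostrings::width(genomeSeq(bundle)),
               names(genomeSeq(bundle)))
coverageTable(teCopies(bundle), gl, groupBy = "class")
#>   group consensus_count coverage_bp coverage_pct
#> 1     I               5      144083      5.76332
#> 2    II               5      139838      5.59352

cs  <- extractCopySequences(genomeSeq(bundle), teCopies(bundle))
div <- unlist(lapply(names(consensusLibrary(bundle)), function(fam) {
  ids <- teCopies(bundle)$ID[teCopies(bundle)$family == fam]
  msa <- alignFamily(as.character(consensusLibrary(bundle)[[fam]]),
                     cs[ids], consensusId = fam)
  copyConsensusDivergence(msa)
}))
detectBursts(burstHistogram(div[!is.na(div)]))
#>     mid count smoothed
#> 1 0.025    74 49.33333
#> 2 0.205    42 35.00000
```

The two detected peaks sit within one 0.01-wide bin of the planted
burst divergences (0.02 and 0.20): the copies mutated at 2% and 20%
substitutions/bp are recovered as two waves of transposition. On the
published survey's orientation table the omnibus test gives

```r
orientationChiSquare(publishedOrientationCounts())$omnibus
#> $statistic  10.14075
#> $df         4
#> $p_value    0.03812231
```

i.e. a significant orientation bias across the five positional
categories at df 4, driven by the 5′-side counts (per-category
statistic 7.78, p < 0.01).

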