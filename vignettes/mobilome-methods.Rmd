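---
title: "Methods: TE inventory, copy ages, MITE discovery and gene context"
author: "TEmobilome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE inventory, copy ages, MITE discovery and gene context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind each analysis stage, the parameters a user may want to change,
and what the synthetic-data validation does and does not demonstrate.

## Inventory: full-length copies and coverage

A copy is a *full-length copy* (FLC) of its family when its length
exceeds 95% of the consensus length, strictly: a copy at exactly 95%
is not full-length, a copy longer than its consensus is. The threshold
(`flcThreshold`, fraction of consensus length, default 0.95) and its
strictness follow the survey convention the package implements; all
boundary semantics in the package ("more than 100 bp", "less than 2%",
"less than 2 kb") are strict in the same way, and the test suite pins
each boundary explicitly.

Library filtering applies three ordered rules: drop consensuses
classified as simple sequence repeats (SSR); drop unclassified
(`noCat`) consensuses generated from fewer than 10 copies; drop any
consensus without at least one FLC. Each removal is logged with the
rule that fired, so a curated library can be audited.

Coverage of a group (class, order, family or chromosome) is the length
of the **union** of its copy intervals — overlapping fragments of the
same group count once. Whether published repeat-coverage figures
union-merge or sum raw fragment lengths is generally not stated; union
is the default here because double-counting overlapping fragments can
exceed the sequence length, and a raw-sum mode (`method = "sum"`) is
provided for comparison. Copies of *different* groups may cover the
same base, so grouped percentages need not sum to the all-copies
total. Percent denominators always use the total assembly length
(including N runs); per-chromosome views pool sequences not listed as
anchored chromosomes into an `"Un"` pseudo-chromosome. Report tables
round half-up (`roundHalfUp()`) to two decimals for display; raw
values are kept exact.

Intervals live in `GRanges` (1-based, closed), the standard container
of this ecosystem; GFF3 input is therefore coordinate-conversion-free
and interval widths equal feature lengths. The GFF3 reader is a thin
parser that reports malformed lines by line number and skips (with a
warning) features lacking a family attribute — diagnostics the generic
importers do not provide.

## Master–slave alignment

Each family's copies longer than 100 bp are aligned globally to the
family consensus with Needleman–Wunsch under affine gap costs, then
stacked into a matrix whose columns are consensus positions 1..L.
Slave characters aligned to master gaps (insertions relative to the
consensus) are dropped from the matrix and counted per copy in an
insertion log; positions outside a truncated or deleted copy appear as
`-`.

Scoring defaults are match +1, mismatch −1, gap open −4, gap extend
−1. The tool the convention derives from does not publish its
parameters, so these are an explicit package choice: affine rather
than linear gaps because decayed TE copies carry single long deletions
that linear costs over-penalize, and a mild open penalty so a 1-kb
copy with a 40% internal deletion still aligns as one gap run. A gap
run of length $L$ costs $\mathrm{open} + L \cdot \mathrm{extend}$
(open is a run-start surcharge; every gapped column pays extend). `N`
is neutral: it scores 0 against any base and is excluded from all
divergence statistics downstream. Traceback ties are broken
deterministically (diagonal, then gap-in-slave, then gap-in-master),
so alignments are reproducible byte for byte. The DP kernel is
implemented in C++ (Rcpp) with rolling score rows and a packed
traceback; an exhaustive enumeration oracle in the test suite verifies
optimal scores for short sequences.

## Copy ages and bursts

The age statistic is the **raw p-distance**: mismatches divided by
compared sites, where compared sites exclude any column containing `-`
or `N` in either row. No multiple-hit correction is applied, because
the statistic of interest is "substitution number per base pair", not
evolutionary time; at the divergences relevant here (≤ ~0.25) the bias
is modest and, crucially, the same convention is used consistently in
simulation and estimation. Pairs sharing fewer than `minSites = 50`
comparable sites are uncomparable and excluded; 50 sites caps the
standard error of a p-distance near 0.07 at the divergences of
interest and discards alignment slivers.

Two age views are produced:

- **Copy-from-consensus divergence** — the per-copy age against the
  putative ancestral sequence. This is the quantity binned into the
  age histogram and scanned for bursts, matching the convention of
  repeat-landscape plots whose x-axis is percent substitutions from
  the consensus.
- **Cherry ages** — for each family a neighbor-joining tree is built
  on pairwise p-distances and every *terminal fork* (pair of leaves
  whose path crosses exactly one internal node) contributes the raw
  pairwise distance of its two copies, dating the most recent
  transposition events. Note that two copies independently diverged
  $d$ from their consensus sit ~$2d$ apart, so the two views have
  different scales by construction.

The terminal-fork statistic could also be read as the sum of the two
terminal branch lengths; the pairwise-distance reading is implemented
as the default because it is invariant to how NJ distributes length
onto the two branches, and because only cherry *membership* — which is
robust between NJ and likelihood trees for well-separated synthetic
families — feeds the statistic. Tree inference uses `ape::nj` on
p-distances rather than a likelihood search: the tree is only a device
for selecting closest-pair copies. Negative NJ branch lengths are
clamped to zero. Degenerate families are handled explicitly: two
comparable copies form a single-edge tree whose length is their
distance; fewer than two comparable copies skip the family with a
message; copies causing uncomparable pairs are dropped greedily
(most-missing first) until the distance matrix is complete.

Bursts are local maxima of the binned age distribution (bin width
0.01 substitutions/bp, half-open bins $[kw, (k+1)w)$; the bin width of
published burst figures is typically unstated, and 1% matches their
axis granularity). Counts are smoothed with a centred 3-bin moving
average (truncated at the edges) and maxima below 10% of the smoothed
maximum are discarded; both knobs are arguments. Local maxima are
plateau-aware — a run of equal smoothed values bounded by strictly
smaller neighbours is one peak, located at its highest raw-count bin
(leftmost on ties) — so a flat histogram yields at most one peak and
equal-top modes are not lost. Peaks are reported sorted by recency.

## MITE discovery

The structural scan enumerates every interval of length 50–800 bp
whose prefix of some length $t \in [10, 200]$ matches the reverse
complement of its suffix with at most 2 mismatches (`N` always
mismatches), keeping the maximal $t$ per interval. The defaults
bracket the short, TIR-bounded, non-autonomous elements of interest
(median MITE sizes of ~500 bp, TIRs from tens to hundreds of bp);
all five knobs are arguments. The scan is strand-symmetric by
construction, so one forward pass finds elements on both strands.

As a standalone operation the scan resolves overlapping candidates
longest-TIR-first, then leftmost. The full `miteScan()` pipeline,
however, validates TSDs **before** any overlap handling and then keeps
all validated candidates. The reason is structural: an element flanked
by a TSD always admits a wider spurious candidate whose "TIR" absorbs
the TSD on both sides (the left flank pairs with the right flank in
reverse complement because the TSD is a direct repeat), and that wider
candidate always has the longer TIR. Resolving overlaps before the
TSD is known would therefore systematically pick the wrong boundary,
and any post-validation resolution rule still loses true elements
whenever the wider candidate picks up an accidental flank repeat.
Strict TSD validation removes the nested redundancy instead; the rare
survivors that still overlap are genuinely ambiguous boundary calls
and are all reported.

TSD validation records the **largest** $k \in [2, 10]$ with identical
flanking k-mers. This occasionally extends a true short TSD (a `TA`
element whose flanks happen to read `TATA…TATA` is recorded with the
longer repeat); that ambiguity is inherent to the definition and left
visible rather than special-cased.

Families are built by greedy centroid clustering: candidates in
decreasing length order join the first centroid reaching 80%
global-alignment identity (matching columns over alignment length), or
found a new family. Superfamilies are assigned per candidate from its
own TSD/TIR via an ordered signature table (defaults encode standard
conventions: `TA` → Tc1/mariner, `TTAA` → PiggyBac, 8-bp TSD with
`CAG`-initial TIR → hAT, other 8-bp TSD → P, `TAA`/`TTA` →
Pif-Harbinger, 2–4-bp TSD with `CACT`-initial TIR → CACTA, else
unclassified; fully override-able). The family label is the majority
vote of its members — more robust than labelling from the centroid
alone, since a boundary-variant member with a spurious TSD can be the
longest sequence in its family.

## Gene context

Nearest-gene search minimizes the edge-to-edge gap (0 on overlap or
exact abutment); a TE equidistant from genes on both sides yields one
context row per tied gene. The generic nearest-range utilities return
an arbitrary tie, so the search is implemented as vectorized interval
arithmetic per sequence and checked against an all-pairs brute force
in the tests.

Positional categories are evaluated in a fixed order: gene contained
in the TE (kept as its own category with the contexts flagged rather
than silently dropped — such cases usually indicate TE
mis-annotation); TE contained in the gene, sub-typed exonic if any
exon is touched, else intronic; TE overlapping the transcription start
(5′) or end (3′) coordinate, **strand-aware** — the 5′ side of a minus
gene is its right end — because orientation effects are asymmetric
with respect to transcription; exact boundary abutment (TE end equal
to gene start or vice versa, a distinct published category); within
the 2-kb proximity threshold (strict); otherwise none. Gap distances
are unsigned. Orientation is sense when TE and gene strands agree,
undetermined for strand-less TEs.

Orientation bias is tested two ways and both are reported: a
per-category Pearson goodness-of-fit of sense/antisense counts against
50:50 (df 1, no continuity correction) and an omnibus Pearson
independence test on the categories × 2 table (df = categories − 1).
No multiple-testing correction is applied across the per-category
tests — the convention of the survey tables this mirrors — and the df
is always printed so the reader can see which test is quoted.
Zero-total categories are excluded with a message. The recency filter
for the recent-insertion report is strict (`divergence < 0.02`); a
copy at exactly 2% is excluded.

## The synthetic mobilome

`buildGenome()` emulates the features the downstream statistics
depend on: multiple chromosomes plus unplaced scaffolds; TE families
of both classes with copies planted at controlled divergences;
TSD-flanked class II insertions and TIR-bounded MITE-like elements;
internal deletions and terminal truncations; and genes with
exon/intron structure placed in controlled positional relations to TE
copies.

Substitutions follow a single-hit process: each site flips at most
once, with probability equal to the target divergence, choosing the
transition with probability $\kappa/(\kappa+2)$ (default $\kappa = 2$,
uniform base frequencies — the substitution model is named in the
survey convention but its parameters are not, so only its
transition/transversion asymmetry is retained). Single-hit is a
deliberate calibration choice: the estimator being validated is raw
substitutions per base pair, so the generator's dial is expressed in
the same units, and realized divergence is Binomial$(L, d)/L$ with no
model-correction gap between truth and estimate.

Default study conditions (`defaultMobilomeSpecs()`): ten 1-kb
families — five Class I, five Class II including two MITE-like
families with TIRs of 15–40 bp and TSDs of 2, 3 or 8 bp — each hit by
two bursts of 15 copies at 0.02 and 0.20 substitutions/bp, with
per-copy deletion probability 0.15 (removing 10–50% of the copy) and
truncation probability 0.05, on a 2.5-Mb genome (four chromosomes of
0.5–0.6 Mb, two scaffolds) carrying 60 genes, 38 of them in planned
TE-gene contexts. The burst positions are the study conditions the
package is validated against; copy counts and genome size are scaled
to desk-size problems — the tests and the acceptance script state
their exact sizes (e.g. 20 seeds × 300 copies × 1 kb for burst
recovery, 50 planted MITEs across 10 genomes for recall) — chosen so a
full validation run completes in minutes on one CPU while keeping
binomial noise well inside the ±1-bin recovery band.

Placement uses non-overlapping units separated by 2.05–4 kb random
gaps, so copies planted without a gene context are always farther than
the 2-kb proximity threshold from any gene and ground-truth category
counts are exact. All randomness flows from one explicit seed through
an RNG-state-preserving helper; identical specifications produce
byte-identical bundles.

What passing on synthetic data does **not** show: real TE copies
violate several generator assumptions — nested and overlapping
insertions, indel-rich divergence, gene conversion between copies,
segmental duplications that mimic bursts, N-gap-truncated copies, and
consensus sequences that are themselves imperfect reconstructions.
Results on the synthetic mobilome validate the estimators under their
stated model, not the biology of any particular genome.

## Degenerate inputs and numerical conventions

- Empty inputs return empty, correctly-typed results throughout
  (empty GFF3 body, zero plants, empty age vector, all-zero
  histogram).
- Saturated burst specifications (divergence ≥ 0.75) are rejected at
  construction.
- p-distances are exact rational arithmetic (counts over counts); no
  tolerance is involved. Alignment scores are computed in single
  precision in the DP kernel, ample for integer-valued scoring
  schemes.
- `roundHalfUp()` provides conventional half-up display rounding
  (base `round()` rounds half to even, which disagrees with hand
  arithmetic on published tables).
- Pipeline reports embed a 12-hex-digit configuration hash so outputs
  of different parameterizations cannot be confused; reruns with the
  same configuration are byte-identical.

## Interfaces

The package is used from R: the stage functions
(`buildGenome`, `coverageTable`, `alignFamily`, `familyAges`,
`detectBursts`, `miteScan`, `classifyContexts`,
`recentInsertionReport`) compose freely, and
`runPipeline(pipelineConfig(...))` orchestrates the full survey from
files to a report directory with per-stage error messages.
`scripts/acceptance.R` is the reproducibility entry point (see the
README).
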