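---
title: "Gene-based soybean origin discrimination: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based soybean origin discrimination: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soyOrigin)
```

## The model

The assay types each soybean grain at 11 allele-specific InDel markers.
Allele-specific PCR turns genotyping into a binary call per marker —
product present or absent — so a grain's genotype over the panel is an
11-bit word. Marker 1 amplifies an endogenous soybean gene in every true
soybean sample; it validates the assay rather than discriminating, and a
marker-1-negative sample is rejected as "not soybean" (error class
`soyNotSoybeanError`), never scored as 0. Marker $k$ carries the score
$2^{k-1}$, and the judgment value of a grain is the sum of the scores of
its amplified markers:

$$J \;=\; \sum_{k \,\in\, \text{amplified}} 2^{\,k-1}.$$

Because the scores are distinct powers of two, $J$ determines the
amplification pattern uniquely (`decodeJudgmentValue()`), every scoreable
value is odd (marker 1 always contributes 1), and an $n$-marker panel
distinguishes $2^n$ theoretical patterns — 2048 for the full panel, of
which the 1024 odd values are scoreable fingerprints.

Classification is membership lookup in a **discrimination table**: the
set of judgment values observed among labeled reference samples of each
origin, with observed multiplicities. The packaged reference table pools
1096 samples (630 domestic over 53 distinct values, 466 foreign over 70,
one of which — the Williams 82 reference pattern 2047 — is carried with
multiplicity 0 as a known-variety anchor). A value seen in only one
origin classifies a sample to that origin; a value seen in both
("overlapping": 671, 1183, 1215, 1695 in the packaged table) leaves the
sample undetermined; a value never seen returns `unknown_value` and is by
default excluded from performance tallies, since the reference
collection defines the assay's universe.

## Overlap handling and the morphology resolution

One overlapping value, 1215, separates by seed morphology (the domestic
cultivar Pungsannamul versus Chinese varieties). We model such external
evidence conservatively: a value can be marked *resolved*
(`resolvedValues(tab) <- 1215`), which removes it from the overlap set
for table-level statistics — both origins' samples at a resolved value
count as correctly classified, because the combined genetic+morphology
procedure does recover them — but an *individual* sample at that value
still needs an explicit per-sample morphology call (`sideHint`) to
receive an origin from `classifyValue()`. The genetic assay alone never
decides a resolved value.

The confusion tallies follow directly: for the packaged table,
TD = 595, FD = 35, TF = 446, FF = 20, where FD counts domestic samples
at unresolved overlapping values (failures on the domestic side) and FF
the foreign counterpart. The three metrics are

$$\mathrm{sensitivity} = \frac{TD}{TD+FD}\,100,\quad
  \mathrm{selectivity} = \frac{TF}{TF+FF}\,100,\quad
  \mathrm{efficiency} = \frac{TD+TF}{TD+FD+TF+FF}\,100,$$

giving 94.4, 95.7 and 95.0 here. Efficiency is algebraically the
count-weighted mean of the other two, a property the test suite checks
on random tallies. Reported percentages round half-up to one decimal
(`roundHalfUp()`); raw ratios are available with `rounded = FALSE`.

Overlap summaries use the **union** of distinct judgment values across
both origins as the denominator (119 in the packaged table, not the
53 + 70 sum): 4/119 = 3.4% of values, 55/1096 = 5.0% of samples
undetermined; resolving 1215 gives 3 overlaps, 2.5% and 3.2%. The sum
double-counts shared values and is not a meaningful share of anything.

## The panel reduction experiment

`reducePanel()` simulates dropping markers from an existing table: each
value maps to itself minus the dropped scores present in its
decomposition, and collapsed entries merge with counts summing. The
dropped markers keep their original score basis (values stay comparable
to the full table); `dropMarkers()` on a `MarkerPanel` builds a genuinely
re-indexed smaller assay instead. Reduction conserves counts per origin,
never increases the number of distinct values, and maps old overlaps
into new overlaps — so discrimination can only degrade. Dropping
marker 11 from the packaged table collapses it to 47 domestic and 57
foreign values with 8 overlaps:

```{r reduce}
red <- reducePanel(soyDiscriminationTable(), 11L)
performanceSummary(confusionCounts(red))
```

This table-level collapse is the only 10-marker computation the packaged
data supports: per-sample raw profiles are not available, so any
10-marker figure derived differently (e.g. from raw re-scoring) cannot
be reproduced here, and the reduction is validated through its
invariants rather than against fixed external numbers.

## Lot sampling statistics

Lots are sampled as single grains. Under independent draws, the chance
that $n$ grains include at least one off-origin grain at admixture
fraction $p$ is $1-(1-p)^n$; `minGrains(p, conf)` inverts this as
$\lceil \log(1-\text{conf})/\log(1-p) \rceil$. The standard 24-grain lot
sample corresponds to 95% detection at $p \approx 0.1175$. The
independent-draw form is the right default because commercial lots
(200 g ≈ thousands of grains) dwarf the 24-grain sample; a
hypergeometric variant (`lotSize =`) is provided for small finite lots
and matches exhaustive enumeration in the tests. The admixture fraction
behind "95% reliability" is deliberately a parameter, not a constant:
the assay's operating point depends on the contamination level one must
detect. Lot verdicts aggregate grain verdicts by unanimity over
informative grains (both origins present → `mixed`; no informative
grains → `undetermined`), a deliberately simple, order-invariant rule;
regulatory users may want thresholded rules instead, which can be built
on `classifyProfiles()` output.

## Marker discovery: variation blocks

Soybean chromosomes partition into dense variation blocks (dVBs) —
~100 kb regions of high SNP density where cultivars differ — and sparse
blocks (sVBs). Markers are sought among InDels inside dVBs.
`windowDensity()` tiles each chromosome into non-overlapping 100 kb
windows (the only scale at which dVBs are described; non-overlapping
tiling keeps segmentation deterministic and mergeable) and counts SNPs
per kb; `segmentBlocks()` thresholds and merges adjacent same-class
windows, recomputing merged densities as count-weighted means so blocks
tile the chromosome exactly.

No universal density threshold exists — it depends on sequencing depth
and the cultivar set — so the threshold is a required parameter with a
data-driven default: `densityThreshold()` splits the log-densities by
exact 1-D two-means (all split points of the sorted values are tried;
deterministic, unlike randomly initialized k-means) and returns the
midpoint of the cluster means, back-transformed. A pseudo-count of half
a SNP per window keeps empty windows finite on the log scale. Degenerate
(constant-density) inputs raise an error rather than fabricating a
split. Coordinates are 1-based closed `GRanges` internally (the
Bioconductor convention); BED export converts to 0-based half-open. A
variant at position $p$ belongs to window $\lfloor (p-1)/w \rfloor + 1$,
tested explicitly at window edges. Only biallelic records are used;
multiallelic VCF records are skipped with a logged count.

## The synthetic generator

The generator exists so the whole chain can be exercised and scored
without the (undeposited) reference collection. Its defaults mirror that
collection's shape: 53 domestic and 70 foreign variety fingerprints (the
distinct judgment values observed per origin), 12 grains per variety
(≈ 630/53), 24-grain lots, and a mixed-lot admixture of 11.75% — the
fraction a 24-grain sample detects with 95% confidence. Per-marker assay
noise defaults to 1% dropout and 1% false amplification: optimized
allele-specific PCR is near-binary, but a small error rate keeps tests
honest about noise propagation. Fingerprints draw markers 2–11
independently at probability 0.5 (the maximal-entropy choice over the
1024-pattern space; `fitMarkerFrequencies()` can estimate real per-marker
frequencies from a table for more realistic draws, though their realism
is untested). `forceSeparable = TRUE` draws the two origins' fingerprints
disjointly by judgment value, giving a zero-overlap table by
construction — the configuration under which perfect 100.0/100.0/100.0
recovery is expected and tested.

One master seed drives a named sub-stream per generator (varieties,
population, lots, VCF), so adding one draw never shifts another's
output; a fixed seed reproduces VCFs byte for byte.

What the generator does *not* emulate: linkage between markers, pedigree
structure, allele-frequency clines, or the wet-lab attrition that
whittled 17 candidate markers down to 11 (a nonspecific-amplification
criterion with no computational counterpart). Passing synthetic tests
therefore demonstrates the correctness of the scoring, table and
segmentation machinery under the stated noise model — not field
performance on real collections, which is established by the packaged
reference table itself.

## Problem sizes and numerical choices

Tests run the encode/decode round trip exhaustively (1024 values), the
metric identities on 1000 random tallies, the noise-rate check on 10^4
grains against binomial 99% bounds, and block recovery on a 1 Mb
chromosome with two planted 100 kb dVBs at 10× density contrast (5 vs
0.5 SNPs/kb) — sizes chosen so the full suite completes in well under a
minute while still hitting every code path at realistic densities.
Half-up rounding is applied only at the reporting edge; all internal
comparisons use raw ratios. Ties in `aggregateLot()` cannot occur (the
rule is set-based); merge order in `reducePanel()` is ascending by value
with notes concatenated.

## Known limitations

* Classification is strictly membership-based: a judgment value absent
  from the reference table yields `unknown_value`, never a guess.
* The morphology resolution is modeled as an oracle bit per sample; the
  package does not analyze seed images.
* Variety identification is out of scope — variety notes are carried as
  annotations only, since distinct cultivars can share a judgment value
  (two reference cultivars share 665).
* The dVB stage reconstructs a segmentation procedure whose original
  threshold and window-overlap choices are unpublished; results should
  be read relative to the configurable threshold.
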