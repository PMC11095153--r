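---
title: "Models, parameters and design choices in chromreprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in chromreprog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chromreprog)
```

`chromreprog` compares two cellular conditions across four data layers —
expression counts, promoter/enhancer histone marks, promoter–enhancer
contacts and genome-wide contact maps — and ships a synthetic generator
with planted ground truth so every stage can be validated without large
sequencing inputs. This vignette records the models behind each stage,
the parameters that matter, the numerical choices, and what the
synthetic validation does and does not establish.

## Coordinate and container conventions

All interval arithmetic is 0-based half-open (BED convention); the bin
holding base-pair position `p` at bin width `b` is `floor(p / b)` (or
`+1` in R's 1-based indexing). The TSS of a minus-strand gene is its
interval end minus one. Contact maps are exchanged as 5-column bin-pair
triple text (chromA, startA, chromB, startB, count): cis counts populate
both `(i, j)` and `(j, i)`, trans matrices are stored once per unordered
chromosome pair, and the map total counts each unique pair once. We keep
one `contact_map` per resolution (25 kb for compartment work, 5 kb for
ABC scoring) rather than a multi-resolution store: at desk scale two
text files are simpler to audit than one container. bedGraph intervals
that are not aligned to the bin grid are binned by length weighting,
which is deterministic and order-independent.

## Pathway activity

For gene `g` and condition `c`, with `m_gc` the mean library-normalised
expression over replicates, the relative expression is
`r_gc = m_gc / mean_c(m_gc)`, so a gene expressed identically in all
conditions scores 1 everywhere and the per-gene mean of ratios is 1 by
construction. The pathway activity is the weighted mean of `r_gc` over
the pathway's measured genes. The weighting is the one genuinely open
choice: we default to `w_g = 1 / n_pathways(g)` so that genes shared by
many pathways (cofactor metabolism, for instance) do not dominate every
pathway containing them, and expose `uniform` as an alternative. Ratios
are computed on library-size-normalised counts, not raw counts —
otherwise the ratio is confounded by sequencing depth. Two-condition
comparisons report `score_2 − score_1` and the divergence filter keeps
pathways with `|difference| > 0.1`, a strict inequality: a pathway
sitting exactly on the threshold is dropped. No outlier trimming or
permutation significance is applied; the score is a descriptive summary
and the package keeps it that way.

## Differential statistics

The package deliberately does not re-implement shrinkage-based
differential tools. Its two-group test is a transparent stand-in with
the same output semantics (`log2fc`, `pvalue`, `padj`): a Welch t-test
on `log2(x + 1)` per feature, or an exact permutation test (all label
splits enumerated) when replicate counts are too small for the t-test.
The pseudocount of 1 avoids minus infinity at zero counts; fold changes
are `log2((m2 + 1) / (m1 + 1))` on the normalised scale. Adjustment is
Benjamini–Hochberg and the significance rule is
`padj <= 0.05 & |log2fc| >= 0.5` with both boundaries inclusive.
Peak-level differentials sum signal-track coverage over each peak, scale
by spike-in factors (`geomean(spikes) / spike_i`, invariant to a common
rescaling of all spike counts), then apply the same test. Externally
computed differential tables can be substituted anywhere a
`(feature_id, log2fc, padj)` table is accepted.

## Chromatin landscape

Peak dynamics are presence/absence by interval overlap (at least 1 bp by
default): a condition-1 peak with any condition-2 overlap is conserved,
otherwise lost; unmatched condition-2 peaks are gained. The three
categories partition the input union and swapping conditions swaps
lost and gained exactly — both properties are tested. Differential
significance is *not* the criterion here because presence/absence is
what Venn-style peak comparisons measure; the significance route exists
separately through the peak-level differential.

The promoter window is TSS ± 2.5 kb everywhere in the package — one
width, used consistently for state typing, enhancer exclusion, promoter
signal and the ABC `P` score. Promoter states follow the 2×2 truth table
of the active (H3K4me3-type) and repressive (H3K27me3-type) marks;
carrying both is bivalent. In the transition table at bivalent promoters
"losing" a mark means the promoter window's overlap status changes, not
that a genome-wide peak identity disappeared; a promoter losing both
marks is counted under the repressive-mark loss column. Region
annotation assigns one category per peak by its midpoint with precedence
promoter > exon > intron > distal — a declared convention chosen for
determinism, not a reconstruction of any specific annotator.

Active enhancers are the activity-mark (H3K27ac) peaks with no promoter
window overlap; the invariant "no enhancer overlaps any promoter window"
is asserted by direct interval intersection in the tests.

## ABC and ABC-P² scoring

Candidate enhancers of a gene are those whose midpoint lies in
[TSS − 1 Mb, TSS + 1 Mb). Per enhancer, `A` is the calibrated activity
signal and `C` the raw TSS-bin-to-enhancer-bin contact count at 5 kb
resolution divided by the chromosome's cis total per million. The
contacts-per-million choice is the simplest normalisation that makes `C`
— and therefore every downstream score — exactly invariant to sequencing
depth; matrix-balanced values can be substituted by supplying a balanced
map. The gene score is the plain sum `ABC = Σ_e A_e C_e` with no
denominator over candidate elements, and `ABC-P² = ABC · P²` where `P`
is the calibrated mean promoter-mark signal over TSS ± 2.5 kb. Whether
`A` and `P` aggregate by sum or mean is not canonical; we default to sum
for `A` (a broad strong enhancer contributes more) and mean for `P` (a
promoter score should not grow with window clipping at chromosome ends),
and expose both as options. The enhancer position used for the contact
lookup is its midpoint bin, deterministic at 5 kb resolution.

## 3D genome analytics

**Expected and O/E.** The expected contact at distance `d` is the mean
over the matrix's offset-`d` diagonal; O/E divides by it and masks
offsets with zero expectation. No iterative matrix balancing is applied
by default: O/E already removes the dominant distance effect at the
scales this package targets, and balancing can be layered on externally.

**Compartment PC1.** Per chromosome, O/E rows are smoothed with a
centered running mean spanning 100 kb at 25 kb bins. The window is
rounded up to an odd bin count (five bins here): an even-width filter is
necessarily asymmetric and shifts every block edge by half a bin, which
systematically misclassifies boundary bins of compartment blocks. The
leading eigenvector of the Pearson correlation matrix of the smoothed
columns is the compartment score; its sign is anchored so that PC1
correlates positively with GC content (compartment A is GC-rich), which
makes the track reproducible across runs and comparable between
conditions. PC1 is computed per chromosome — the standard practice for
eigenvector compartment analysis, since inter-chromosomal scale
differences otherwise leak into the sign structure. A chromosome whose
leading eigenvalue explains less than 10 % of the correlation-matrix
variance is declared to have no compartment signal and is rejected
rather than silently returning noise; on compartment-free simulated maps
(`delta = 0`) the leading share is an order of magnitude below this
threshold, while genuine checkerboards sit several times above it.

**Change classification.** The seven categories are defined by PC1
differences and signs with threshold `t = 0.2`. The definitions overlap
(a bin with `c1 = 0.3, c2 = −0.3` satisfies both "A to B" and "A to
weaker A"), so the classifier applies the rules in a fixed listed order
and takes the first match; the order places the conversion categories
(B to A, A to B) ahead of the within-type weakening rules they overlap
with. The classifier is verified against an independently coded rule
evaluator on 10^5 random PC1 pairs, including boundary constructions.

**Saddle.** Bins are ranked by PC1 genome-wide, the extreme 2.5 % of the
eigenvector is removed at each tail, remaining ranks are split into 50
equal groups and each cell is the mean cis O/E over the group pair;
corner summaries average the extreme 5×5 blocks. Because the
aggregation is rank-based, permuting bin order leaves the saddle
unchanged.

**P(s) and crossings.** The curve reports, per log-spaced distance bin,
the summed cis count divided by the number of bin pairs at those offsets
and by the map's cis total, so maps differing only in depth give
identical curves. Between-condition log2 ratios are defined where both
curves are positive; crossing points are interpolated linearly in
log10(s) between adjacent bin midpoints, matching how intersections are
read off a log-x plot.

**Insulation and domains.** The insulation score at bin `i` is
`log2(diamond_i / mean(diamonds))`, where the diamond is the
`w × w` upstream-by-downstream submatrix excluding bin `i` itself
(default `w = 10` bins) and the reference is the chromosome-wide mean of
valid diamond means; bins whose diamond does not fit carry NA.
Boundaries are local minima below `−prominence` (default 0.2), with
minima closer than `min_sep` bins collapsed keeping the lowest; domains
are the inter-boundary intervals including chromosome ends. Loop calling
is out of scope — domain sizes come from insulation boundaries.

**Trans region pairs.** Trans matrices are aggregated to 2 Mb coarse
bins, compared as log2 fold changes of per-map contact fractions with a
pseudocount of 1 on counts, ranked by signed change (coordinate order
breaks ties, making the selection deterministic), and the selected top
fraction (default 0.5 %) is merged into region pairs by 8-neighbour
connectivity. Signed log2 fold change is used as the ranking statistic;
a formal test per coarse pair would require replicate-level maps, which
the package does not consume.

## The synthetic generator

The generator emulates the statistical structure each stage assumes,
with planted truth emitted alongside so recovery is exactly checkable.
All generators are deterministic given their seed, and the demo derives
one sub-seed per modality from a master seed so adding a modality never
perturbs the others.

*Expression*: negative-binomial counts, 3 replicates × 2 conditions.
Defaults: 2000 genes, 200 differential at |log2FC| = 2 (alternating
direction), dispersion 0.02 — the scale typical of isogenic cell-line
replicates — and per-sample depth 2.5 × 10^6, which gives a mean of
~1250 counts per simulated gene, matching the per-gene coverage of a
25 M-read library over a 20 k-gene transcriptome. Validation at these
settings shows the Welch + BH stand-in flags the planted set with
empirical FDR below 0.1 and sensitivity at or above 0.8 (computed by the
test suite and the acceptance script, not quoted from elsewhere).

*Marks*: three marks per condition (promoter-active, repressive,
activity/enhancer). Promoter peaks (1.5 kb wide, height 10 in arbitrary
calibrated units) follow planted per-gene states; the activity mark
combines planted enhancers — with conserved/lost/gained labels — and
active-promoter peaks. Tracks are 250 bp-binned peak coverage plus
truncated Gaussian noise of sd `height / snr`, and the emitted peak sets
are re-called from the noisy track at half peak height with a two-bin
minimum width (the width floor rejects isolated noise bins, as any
real peak caller does). Recovery is exact at infinite snr and remains
at or above 95 % at snr 5.

*Contacts*: cis expected counts follow `s^decay` (default decay −1)
times `1 + delta` for same-compartment bin pairs (default `delta = 1`),
Poisson sampled and scaled to a read budget; trans maps are uniform with
planted enriched blocks. Compartment flips between conditions relabel
whole blocks without re-drawing the genome, isolating the classifier's
signal. The GC track can be generated correlated with compartment A so
the PC1 sign anchor works as it does on real genomes.

What the generator does **not** emulate: replicate-level contact maps
(and hence replicate concordance), copy-number variation — a real
concern in cancer lines, where amplifications inflate both coverage and
contact rows — mappability and blacklist artefacts, peak-width and
signal heterogeneity, fragment-level noise, and any read-level process
(alignment, duplication, spike-in capture efficiency). Passing the
planted-truth checks therefore demonstrates correctness of the
computations under their stated models, not robustness to the artefacts
of real sequencing data.

## Validation problem sizes

The suite validates PC1/saddle recovery on a 400-bin chromosome
(10 Mb at 25 kb) with 5 × 10^6 Poisson reads and 10-bin checkerboard
blocks; P(s) slope recovery on the same maps; differential calling on
2000 genes with 200 planted; promoter-state recovery on 240 genes over
two 2 Mb chromosomes; dominant-enhancer identification on 100 genes with
three candidates each (5× activity and contact advantage for the planted
one); and the classifier on 10^5 random PC1 pairs. The demo pipeline
uses two 2 Mb chromosomes, 240 genes, 20 pathways and ~0.6 M/1.2 M read
contact maps — sizes chosen so a complete end-to-end run with planted
truth finishes in well under a minute while every analytic still has
enough signal to be meaningfully checked.

## Known limitations

The differential stand-in has no dispersion shrinkage, so its power at
very low counts is below that of dedicated count models; multi-factor
designs are not supported. The compartment eigenvector uses the leading
component only and will mis-rank chromosomes whose first component
captures arm-level or copy-number structure rather than
compartmentalisation. Insulation boundaries are a minima heuristic, not
a domain model. ABC scoring imputes nothing: enhancer–promoter pairs
with zero observed contacts score zero even where a power-law fit would
predict otherwise. The pipeline assumes one replicate-pooled map, track
and peak set per condition for the chromatin layers; replicate-aware
inputs must be pooled upstream.
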