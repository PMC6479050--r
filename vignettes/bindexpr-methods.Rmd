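---
title: "Methods: integrating binding with differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating binding with differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindexpr)
```

# The question the pipeline answers

Given where a chromatin factor binds (a peak set), how a partner factor's
binding relates to it, how a chromatin mark responds to the factor's loss
(paired signal tracks), and how transcription responds (a differential
expression table), does the factor *directly* activate or repress genes —
and which genes are its direct targets?

The pipeline decomposes this into five analyses: peak co-occupancy
classification, genomic-feature annotation, signal profiling around binding
sites, regulatory-potential target inference against a static-gene
background, and a nearest-binding distance comparison.  A seeded synthetic
study with planted direct targets stands in for real data so every stage is
testable end to end with known truth.

# Coordinates and containers

All in-memory coordinates are 0-based half-open, the native convention of
every on-disk format the pipeline touches (BED, narrowPeak, refFlat,
bedGraph), so no shifting ever occurs at I/O boundaries.  Two intervals
overlap when they share at least one base; abutting intervals do not.  A
peak is anchored at its integer midpoint `floor((start + end) / 2)`, which is
always inside the interval.  Peak callers disagree about summits (narrowPeak
allows an absent summit, `-1`), so the midpoint is the only anchor that is
always defined; the summit column is parsed and retained but not used as an
anchor.

A transcript's TSS is `txStart` on the plus strand and `txEnd - 1` on the
minus strand — the last covered base, keeping the TSS a genomic point inside
the transcript.  Signed peak-to-TSS distances are measured midpoint to TSS
and oriented by strand (positive = downstream of the gene); all scoring uses
the absolute distance.

# Peak classes and annotation

`classify_peaks()` partitions the focal factor's peaks into Class I (overlap
at least one partner peak by >= 1 bp) and Class II (no partner overlap);
partner peaks overlapping no focal peak are Class III.  One shared base is
the simplest defensible reading of "overlap"; the threshold is an argument
(`min_overlap`) for sensitivity analysis.  Class labels attach to the peaks
themselves, not to merged regions, because downstream profiling centres
windows on the focal peak's own span.

`annotate_distribution()` assigns each peak a single category by its
midpoint with precedence promoter > 5'UTR > 3'UTR > coding exon > intron >
distal intergenic, applied jointly across all transcripts covering the
midpoint.  The promoter is TSS +/- 1 kb by default — a common convention,
configurable since no single value is canonical.  UTRs are the
transcript-end segments outside the CDS (mirrored on the minus strand),
coding exon is exon intersected with the CDS, and intron is the residual
transcript body.  Midpoint assignment makes the categories a true partition,
so the reported fractions always sum to 1 — unlike span-overlap voting,
which double-counts wide peaks.

# Signal profiling

Signal is piecewise constant (bedGraph steps; uncovered bases are 0).
`binned_matrix()` computes, for each peak, base-pair-weighted means over
50 bp bins spanning 5 kb up- and downstream of the midpoint.  Internally a
per-chromosome cumulative integral `F(x)` is evaluated at bin edges, so bin
means are exact (the per-base expansion is kept as a test oracle only) and
binning is linear in the track and conserves the window integral to
rounding.  The 5 kb flank matches heatmap convention for co-occupancy
displays; 50 bp bins give 200 columns.  Windows truncated at a chromosome
start contribute zeros and keep the full-width denominator.

`site_signal_change()` compares two conditions at each site as
`log2((mean_B + 1) / (mean_A + 1))` over midpoint +/- 1 kb.  The pseudocount
of 1 (on depth-normalised signal whose baseline is order 1) bounds the ratio
at empty sites: zero signal in both conditions gives a change of exactly 0.
`proximal_distal_correlation()` splits sites at 2 kb nearest-TSS distance —
approximating promoter-like versus enhancer-like positions — and
rank-correlates the signal change with the nearest gene's log2 fold change.
Spearman is the default because normalised ChIP signal has heavy-tailed
outliers at strong peaks; Pearson is available by argument.  The 1 kb site
window and the 2 kb proximal cutoff are conventions of this package, exposed
as arguments, and worth a sensitivity check on real data.

# Regulatory potential and target inference

Each gene's regulatory potential sums exponentially distance-decayed peak
contributions within 100 kb of the TSS:

$$S_g = \sum_{i=1}^{k} e^{-(0.5 + 4\,\Delta_i)}, \qquad
\Delta_i = \frac{|d_i|}{100\,\mathrm{kb}},$$

so a peak on the TSS contributes $e^{-0.5} \approx 0.6065$, one at 10 kb
($\Delta = 0.1$) contributes $e^{-0.9}$, and one at the window edge
contributes $e^{-4.5} \approx 0.011$.  The window boundary is closed
(a peak at exactly 100 kb counts with $\Delta = 1$); the inclusion weight at
the boundary is negligible either way.  Genes with several transcripts are
credited with their best-scoring transcript, the usual practice when a
single promoter dominates regulation.  Ranking ties are broken by gene id
for determinism.

`group_genes()` selects the `da = 500` most significant genes per direction
(ascending p, then descending |log2FC|), mirroring the `--da 500` convention
of binding/expression target analysis; both directions are capped
separately.  Static genes — the null background — are all remaining genes
with p >= 0.1.  The floor excludes near-significant genes that would
otherwise contaminate the background and dilute the contrast; its exact
value matters little because the bulk of a null p-value distribution is flat.

`ks_activating_repressive()` compares the $S_g$ distribution of each group
against static genes with a two-sample Kolmogorov–Smirnov test.  The
headline p-value is one-sided for "group scores stochastically greater than
static" — the directional question target inference asks — with the
two-sided p co-reported.  Cumulative rank curves sweep genes from highest to
lowest $S_g$ and record the fraction of each group accumulated.  Genes tied
on score (notably the $S_g = 0$ block) accumulate jointly: the curve is the
group's empirical CDF evaluated at score thresholds.  Evaluating inside a
tie block by arbitrary gene order would inject rank noise that is not a
property of the score distributions the curves visualize.

`direct_targets()` implements the conjunction "bound and responsive": a
candidate must be in a differential group *and* have $S_g > 0$.  Candidates
are ordered by the rank product of their regulatory-potential rank and their
differential-expression rank — a scale-free combination that favours genes
strong on both axes and needs no cross-calibration between binding and
expression scales.

`distance_comparison()` asks the converse question — is binding closer to
regulated genes than to static genes? — using each gene's nearest-peak
|midpoint − TSS| distance and one-sided Mann–Whitney tests.

# What the synthetic study emulates

`simulation_config()` defaults define the study conditions: a 100 Mb genome
(4 × 25 Mb), 2000 genes, 200 planted up-targets and 200 down-targets with
one focal peak each at an exponential 5 kb distance scale from the TSS,
1000 focal and 1000 partner peaks with half the focal peaks co-occupied
(the "nearly half" regime), log-normal peak widths around 500 bp with
co-occupied peaks 1.5× wider, planted |log2FC| of 2 over a 0.25-sd static
background, and trapezoidal signal enrichment (height 10 over baseline 1,
10% relative noise) in which 30% of up-target-linked peaks gain and 30% of
down-target-linked peaks lose signal after the knockout, coupling mark
change to expression direction.

Choices a scientist would recognise as realistic but that are still choices:
gene density (one gene per 50 kb) keeps most random peaks within some gene's
100 kb window so regulatory potentials are continuous rather than
zero-inflated; expression p-values are the exact normal tail of the
simulated log2FC, which makes static p-values exactly Uniform(0,1) and keeps
the differential ranking coherent with effect size without simulating
counts; each generator stage draws from its own RNG substream derived from
the master seed, so changing the peak count cannot perturb the expression
draws.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: read-level sampling noise and peak-calling
uncertainty; replicate structure and dispersion estimation (p-values come
from a clean normal model, not from count models); correlated peak
clustering, CpG-island promoter structure, or chromatin domains; multiple
transcripts per gene; trans effects, secondary regulation, and the
time-dependence of knockout responses.  The planted effects are also strong
by design (so recovery is expected, and failures indicate bugs rather than
bad luck); real effect sizes will sit closer to the detection boundary.

# Numerical and testing notes

Degenerate inputs are handled explicitly: empty tracks read as all-zero
signal; classes with fewer than two peaks mark the width test not
applicable; groups with fewer than three scored genes mark the KS result not
applicable; an empty static background is an error, not a silent NaN.
Readers reject malformed files with the offending line number; the bedGraph
reader refuses overlapping steps.  Run metadata deliberately omits
timestamps so identical runs are byte-identical.

The test suite checks each operation against an independent oracle route:
brute-force all-pairs scans for classification, nearest-gene and regulatory
potential (the latter with compensated summation), a per-base expansion for
binning, permutation tests for the KS and Mann–Whitney inferences, and a
500-replicate null calibration of the one-sided KS size at the 5% level
(run at 300 genes × 300 peaks on a 3 Mb chromosome).  Planted-recovery
checks run at the full default conditions (2000 genes, 1000 + 1000 peaks);
the signal-carrying pipeline checks use a 2 × 5 Mb, 200-gene configuration
with `da = 25` scaled proportionately.  These sizes are the package's
standard verification set-up and run in a few minutes on one core.

# Known limitations

The annotation precedence hides any 5'UTR shorter than the promoter
half-width (simulated genes carry 1.4 kb 5'UTRs so the category is
observable).  `--da`-style grouping fills its quota from positive-direction
nulls when fewer truly differential genes exist; the KS contrast is then
diluted but unbiased.  One-sided KS p-values from `ks.test` are asymptotic
at these group sizes and underflow to 0 for very large effects.  The
pipeline consumes called peaks and differential tables; it neither calls
peaks nor fits expression models, and conclusions inherit whatever biases
those upstream tools introduced.
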