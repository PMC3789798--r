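---
title: "Methods: colony sizes to linkage maps, hotspots and centromere biology"
author: "linkmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colony sizes to linkage maps, hotspots and centromere biology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(linkmapr)
```

## The estimator and its assumptions

SGA double-mutant colony size mixes two signals: double-mutant fitness and
the efficiency of double-mutant formation. For gene pairs on the same
chromosome the second term is dominated by meiotic recombination between the
two loci. `recombinant_fraction()` estimates the fraction of recombinant
progeny as `R = f_ij / (2 f_i f_j)`, which assumes:

* in the absence of linkage and genetic interaction, double-mutant size is
  the product of the single-mutant sizes (multiplicative null);
* genetic interactions and sporulation defects are rare and independent of
  chromosomal position, so they average out within a physical-distance bin;
* colony size is proportional to the number of double mutants produced by
  the original meiosis.

The last assumption is known to fail partially (colonies approach
saturation after the ~30-40 generations of an SGA selection), which inflates
recombination estimates roughly uniformly across the genome. This is why
distances are reported in SGA-GD — a centimorgan-equivalent **within** SGA
data — and why all downstream analyses are comparative. The generator
exposes a compressive exponent `gamma` (default 1) to emulate saturation.

`haldane_morgans()` converts R to map distance under the Haldane function
(`m = -ln(1-2R)`, `M = m/2`), i.e. Poisson crossovers without interference.
Interference mainly matters at short distances where it changes the
multiple-crossover correction only marginally at these noise levels; no
other mapping functions are offered.

## Distance mapping: the cap and the two modes

Haldane maps R = 0.5 to infinity, yet 50 SGA-GD must mark independent
segregation. `distance_config()` therefore defaults to `haldane_capped`:
R is clamped to `[0, 0.5]` (the `clamped` flag preserves auditability —
noise and positive interactions can push raw R above 0.5) and the output is
`min(50, 100 M)`. A `linear` mode (`100 R`, the complete-interference
mapping) is kept for sensitivity analysis. Both modes map R = 0 to 0 and
R = 0.5 to 50 and are monotone.

Because inviable double mutants still leave residual colonies, each query's
raw self-distance is not zero. Self-normalization is an affine map on the R
scale, `R' = (1/2)(R - R_self)/(1/2 - R_self)`, chosen because it preserves
both calibration anchors (self at 0, independence at 0.5) and monotonicity;
the transform the original analysis used is not recoverable from its
description, which fixes only the end condition. Replicate screens
(duplicate query rows) are averaged on the bounded R scale *before*
mapping, since averaging capped distances is biased wherever the cap binds.

## Binned averages and the cap-saturation pitfall

With the cap equal to the 50-SGA-GD independence threshold, a binned mean
of *distances* reaches the threshold only when **every** pair in the bin is
capped — a knife edge under noise. Wherever a binned statistic is compared
against the threshold (`linkage_extent()`, and the unlinked-distance
calculation in the acceptance suite), the within-bin average is therefore
taken on the bounded R scale and the bin mean is mapped through
`sga_gd()` afterwards — the same argument as for replicates.
`binned_extent()` retains the literal mean-distance contract for profiles
that are already binned.

## Linkage matrices, profiles, hotspots

Genes are assigned to consecutive 5-kb bins by their midpoint (the source
data report only "chromosomal position"; the midpoint is this package's
choice). `G[i,j]` is the mean SGA-GD over query-array pairs in bin pair
(i,j); empty cells are missing (`NA`), never 0, because 0 is a measurement
(complete linkage). Directions are consolidated as `G' = (G + G^T)/2`,
using the single available direction where only one has data. Chromosome
III is excluded from consolidation in yeast runs (it carries the mating
locus central to SGA selection), and the CAN1/LYP1 selection-marker regions
on chrV/chrXIV ship as default masks (`default_yeast_masks()`) — every
screen shows linkage there, so gene-specific values cannot be reported.
Masked bins drop out of every downstream average. Synthetic genomes need no
masks.

The recombination profile at bin x averages per-cell rates
`G'[i,j]/(|i-j| * 5 kb)` over the 25-kb window `i,j in [x-2, x+2]`,
excluding the diagonal (self pairs are normalized to 0 and would bias rates
down). Rates rather than distances are averaged because the profile's unit
is SGA-GD/kb. The profile is smoothed with a 5-position moving average
(end-truncated, missing-aware). Hotspots are strict local maxima of the
smoothed profile above the genome-average rate; a plateau yields one call
at its center (rounded down — a deterministic tie-break the source did not
specify), and calls closer than `min_separation` merge keeping the higher.
Cross-study comparison (`compare_hotspot_sets()`) matches sites within
10 kb on the same chromosome.

## Pericentric analyses

`classify_pairs()` splits same-chromosome pairs into *cis* (same side of
the centromere midpoint) and *trans* (centromere strictly between the gene
midpoints); genes overlapping the centromere midpoint are resolved by their
own midpoint with a warning. The linkage extent is the center of the
smallest 5-kb physical-distance bin whose (R-averaged) genetic distance
reaches 50 SGA-GD. Bin centers are reported because the source specifies
only "the distance of the smallest bin". Controls:
`hotspot_centromere_gap()` (nearest flanking hotspots vs mean consecutive
spacing) and `genetic_map_centromere_gap()` (closest trans locus pair at
>= 50 cM vs `50 / (cM/kb)`). `size_correlation()` uses Pearson's R with the
exact two-sided t-test p-value, with an optional exclusion set — the four
smallest yeast chromosomes (I, III, VI, IX) have globally elevated
recombination, so removing them separates centromere-related from
size-related effects.

## Chromatin tracks

`dsb_repressed_region()` walks outward from the centromere accumulating
Spo11-oligo counts; the repressed extent stops at the last position whose
cumulative count is below 3000 (ties resolve toward the smaller region; if
the first flanking position already reaches the threshold the extent is 0;
if it is never reached the extent runs to the chromosome end).
`cohesin_peak_width()` smooths the binding track over 25 consecutive
positions (index space — the source does not normalize position spacing, so
the spacing is recorded in the output), computes the dataset-wide global
genomic average (GGA) *after* smoothing so cutoff and profile share a
scale, and measures the maximal contiguous run of super-GGA positions
containing the centromere. The contiguous reading was chosen over "two
farthest positions anywhere" because discontiguous arms would not measure a
centromere-centered cluster.

## The synthetic world

The generator states one world and the tests live in it:

* crossover-rate map: `rate(x) = base_rate * hotspot_fold(x) *
  suppression(x)` in SGA-GD/kb; `base_rate = 1.4` puts the unlinked
  threshold at `50/1.4 ~ 36 kb`, the elevated scale characteristic of SGA
  data (~35 kb, against ~139 kb in classical maps);
* pericentric suppression multiplies the rate by `residual_fraction`
  (default 0.1) within `rho = rho0 + size_coupling * L` of the centromere
  (defaults 10 kb, 0 kb/Mb; size-scaling runs plant 20 kb/Mb);
* true recombinant fractions follow the Poisson model
  `R = (1 - e^{-m})/2`, `m = cM/50`;
* colony sizes: `f_ij = (f_i f_j R/0.5)^gamma` times lognormal noise
  (`noise_sd`, default 0.1 — a typical residual CV for normalized colony
  sizes); single fitnesses are lognormal around 1 (sd 0.05); query-self
  cells carry a residual colony (0.05); 2% of pairs receive a lognormal
  fitness interaction; replicate rows get independent noise;
* tracks: Spo11 counts are Poisson with mean proportional to the rate map
  (~200 oligos/kb at background, so a 5-kb step accumulates ~1000);
  Rec8/Mcd1 are rectangular centromeric clusters over a flat background,
  noise-free by default (the track model itself is the signal);
  genetic-map loci sit at gene positions with cM equal to the rate-map
  integral.

What the generator does **not** emulate: plate spatial effects, batch
effects, the SGA selection steps themselves, crossover interference, and
the saturation nonlinearity (unless `gamma < 1`). A green closed-loop test
therefore establishes that the estimators invert this generative model —
not that real SGA screens are free of those artifacts.

## Scale choices in the acceptance suite

Stochastic criteria fix their seed sets and aggregate by the median.
Hotspot recovery runs at paper-like density (1 gene/kb, the real array has
~5000 strains; a hotspot-rich 500-kb chromosome with hotspots every
~45 kb): at 5-fold sparser gene coverage, profile noise rivals the
hotspot-excess margin above the genome average and precision degrades — a
downscaling artifact, not a property of the method. The size-scaling
criterion uses 100 genes/chromosome over the full 16-chromosome genome.

## Known limitations

* The cis-extent control in the size-scaling acceptance criterion is
  knowingly red: rate-map suppression physically affects cis pairs whose
  interval overlaps the pericentric window, so on large-rho chromosomes the
  first qualifying 5-kb bin occasionally shifts out by one bin. Extents are
  chromosome-independent in the ±1-bin sense, but a Pearson correlation on
  quantized, near-constant extents is dominated by those rare shifts and
  exceeds the criterion's 0.3 (median ~0.42 across 20 seeds). Real, dense,
  uncapped data escape this because bin means sit well above 50.
* Absolute distances inherit the SGA saturation bias; only comparative
  statements are meaningful.
* The noise-free closed loop is exact for the raw estimator; affine
  self-normalization deliberately shifts non-self pairs when the self
  residual is nonzero, so closed-loop checks run with normalization off.
* Genome-scale results from the original datasets (hotspot counts,
  correlations on real screens) need those datasets; the package covers
  them with synthetic surrogates only.
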