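---
title: "Anchor-based inter-sample normalization of ChIP-seq density tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-based inter-sample normalization of ChIP-seq density tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

ChIP-seq, ATAC-seq and DNase density tracks from different samples or
conditions are not on a common scale: immunoprecipitation efficiency,
sequencing depth, antibody lot and chromatin quality all shift and stretch
the signal. Spike-in chromatin solves this experimentally but is often
unavailable, and peak-based scaling fails when the global level of the
mark itself differs between conditions. `chipnorm` instead anchors the
normalization on *transcriptionally constant genes*: genes whose
expression varies least across the samples. The working assumption is
that, on average, the true signal in the regulatory regions of such genes
is the same in every sample, so any systematic difference observed there
is technical and can be removed.

This assumption fails when the target protein is globally gained or lost
across conditions (a global erasure of a mark changes signal even at
expression-stable genes); spike-in protocols remain the only rigorous
option there. It also presumes the mark correlates with expression near
the TSS, which holds for activating promoter/enhancer marks (H3K27ac,
H3K4me3) and accessibility, but not for repressive marks.

## Procedure

1. **Constant genes.** From a genes × samples expression matrix (CPM or
   unlogged microarray values; FPKM/TPM are first multiplied per gene by
   exon length in kb to restore CPM-proportionality), genes are ranked by
   mean expression and cut into `n_bins = 100` equal-size strata. Within
   each stratum the `percent = 10`% of genes with the smallest
   cross-sample standard deviation are kept. Selecting per stratum rather
   than globally keeps anchors at every expression level, including
   silent genes, so the learned map is constrained across the whole
   intensity range.
2. **Scale-regions matrix.** For each sample, mean signal is computed
   over each constant gene's body rescaled to `body_length = 40` kb plus
   fixed `flank = 4` kb on each side, in `bin_size = 10` bp bins
   (4,800 bins per gene). Bin means use exact fractional-base weighting
   and minus-strand rows are reversed, so every row reads 5′→3′.
3. **Normalization.** Two strategies:
   - *Affine (linear with intercept).* A reference sample is chosen —
     the one whose overall matrix mean is the median across samples
     (lower median for even counts, so the choice is deterministic).
     Each other sample's per-bin average profile is regressed on the
     reference's, `S̄ₛ = α S̄ᵣ + β + ε`, and the whole track is corrected
     by `max(0, (v − β)/α)`. The reference track is passed through
     unchanged.
   - *Group-wise quantile.* Genes are pooled into `k = 20` groups of
     similar overall binding intensity; the k × samples matrix of group
     means is quantile-normalized (rank within sample, replace by the
     across-sample mean at that rank); each sample's map from original
     group means to common targets is interpolated by a monotone value
     function and applied to every track value.
4. **Evaluation.** Average TSS-centered profiles (±4 kb, 10 bp bins) over
   the constant genes are computed before and after; areas in Zone 1
   (−4, −1 kb), Zone 2 (−1, +1 kb) and Zone 3 (+1, +4 kb) are compared
   pairwise as `100·|Aᵢ−Aⱼ|/((Aᵢ+Aⱼ)/2)` and averaged over pairs.
5. **Antibody QC.** Genes are clustered into low/medium/high expression
   (1-D k-means, k = 3, on `log1p` values) and TSS profiles are drawn per
   stratum; for a specific antibody against an activating mark the curves
   should order high > medium > low, and an inverted ordering flags
   cross-reactivity or a repressive mark.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `percent` | 10 | % | anchor genes kept per expression stratum |
| `expression_bins` | 100 | strata | expression stratification granularity |
| `body_length` | 40,000 | bp | common rescaled gene-body length |
| `flank` | 4,000 | bp | unrescaled flank on each side |
| `bin_size` | 10 | bp | matrix/profile bin width |
| `k` | 20 | groups | intensity groups for quantile mode |
| `half_window` | 4,000 | bp | evaluation TSS window half-width |

Smaller `percent` gives purer anchors but noisier profiles; fewer
`expression_bins` coarsens stratification (at least `expression_bins`
genes are required). `k` trades resolution of the intensity→intensity map
against the stability of each group mean.

## Numerical choices

- **Coordinates** are 0-based half-open internally (bigWig/BED
  convention); GTF's 1-based inclusive coordinates are converted at the
  parser. A gene's exon length is the length of the union of all its
  exons over transcripts — deterministic across annotation versions.
- **Gene-body rescaling** divides the body into equal-width genomic
  sub-intervals and averages with exact fractional-base coverage
  weighting; no interpolation artifacts, and a constant track maps to a
  constant matrix exactly. Flank windows truncated at a chromosome edge
  count missing bases as signal 0, matching the convention that density
  tracks encode absent signal by absent intervals.
- **Ties** in mean expression, standard deviation and group intensity
  are broken by gene id, so selections and groupings are reproducible
  across platforms.
- **The quantile smoother** is a monotone cubic (Fritsch–Carlson)
  Hermite interpolant through the (group mean, target) knots. We chose
  interpolation over a smoothing spline deliberately: the knots are
  already averages over many genes and bins, so further smoothing adds
  no robustness, while generalized cross-validation smoothing on 20
  knots skewed toward low intensities can deviate systematically inside
  the wide gap below the strongest group and distort the terminal slope.
  The interpolant is exact at every knot, monotone by construction (a
  non-monotone map would invert signal ordering, which is biologically
  indefensible), and reduces to a straight line when the true
  relationship is affine. Beyond the outermost knots the map continues
  linearly with the terminal knot segment's slope — strong peaks exceed
  every group mean, and clamping them would flatten real biology. All
  mapped values are clamped at 0. With fewer than 4 distinct knots the
  map falls back to monotone piecewise-linear interpolation.
- **Degenerate fits** are rejected rather than patched: a constant
  reference profile (unidentifiable slope) and a non-positive fitted α
  are errors, the latter with a pointer to quantile mode.
- **Zero-area zone pairs** contribute 0% with a warning rather than NaN.
- **bigWig precision.** The container stores 32-bit floats; written
  values are recovered exactly at that precision. Exactness tests
  therefore use values representable in single precision.

## Decisions where the design was open

- *Quantile normalization operates on the k group means*, one
  observation per group and sample, rather than on per-bin values; the
  group means are the stable summary the map is meant to align.
- *Even sample counts* use the lower median for the reference choice.
- *Percent-difference denominator* is the pair mean, making the
  statistic symmetric and bounded in [0, 200]%.
- *k-means stratification* runs on `log1p` expression (raw FPKM would be
  dominated by a handful of outliers; `log_transform = FALSE` is
  available) on one designated sample or the across-sample mean, with a
  fixed seed (42) and 10 restarts; with exactly three distinct values
  each value forms its own stratum.
- *Microarray values* pass through unchanged — they are not
  length-normalized, so no exon-length rescaling applies.

## What the synthetic worlds emulate — and what they do not

`fixture_spec()`/`make_world()` generate a toy genome with
non-overlapping genes (≥10 kb apart), log-normal expression
(meanlog 3, sdlog 1.5 — wide enough that 100 expression strata are
non-degenerate at 1,000 genes), a Gaussian promoter peak at each TSS
(SD 300 bp, height proportional to expression, uniform background 0.5),
and per-sample tracks `αₛ·base + βₛ` with optional multiplicative noise.
Non-constant genes receive sample-specific log-normal fold changes
(sdlog 0.5); constant genes have identical expression in every sample,
with levels planted at evenly spaced quantiles of the non-constant
genes' observed mean expression so that every expression stratum
contains anchors — the structural premise of the method. The same seed
reproduces every file byte-identically.

Real data differ in ways the fixtures deliberately omit: peaks at
enhancers far from TSSs, copy-number and GC biases (the package expects
tracks already background-corrected upstream), non-affine distortions,
mappability holes, and expression measurement noise. Passing tests on
these worlds therefore demonstrate that the estimators recover known
distortions and orderings under the model's own assumptions — not that
those assumptions hold in any particular experiment; the zone statistics
and stratified TSS profiles are the tools for judging that on real data.

The test suite runs its end-to-end checks on 150–1,000-gene worlds with
1–5 kb gene bodies, evaluating either the full 40 kb/±4 kb geometry or a
proportionally reduced layout (4 kb body, ±2 kb flank, 50 bp bins) where
the check concerns pipeline behavior rather than default geometry.

## Known limitations

- No spike-in support: a global gain/loss of the mark across conditions
  violates the anchor assumption and cannot be detected internally.
- Input/IgG controls are not consumed; use background-corrected density
  tracks (e.g. from a peak caller that subtracts control signal).
- One affine map or one value map per sample: locus-specific biases are
  out of scope.
- Expression and annotation must share gene identifiers; no ID mapping
  is performed.
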