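---
title: "Methods: spike-in normalization, co-occupancy supersets and enrichment filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-in normalization, co-occupancy supersets and enrichment filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipcooc)
```

## What this package computes

`chipcooc` implements a quantitative ChIP-seq workflow for comparing factor
occupancy and histone-mark levels across genotypes, built around four
statistical ideas:

1. **Spike-in normalization.** When a chromatin mark changes globally between
   genotypes (e.g. H3K4me3 collapse in an H3K4 methyltransferase mutant),
   within-sample normalizations are blind to the change. Mixing a fixed
   proportion of chromatin from a second species into every extract gives an
   internal yardstick: the spike-in ratio *r* (spike-in reads / target reads
   in the input library) captures the mixing proportion, and the per-ChIP
   scaling factor

   *s = r / (spike-in ChIP reads in spike-in peak regions / 10⁶)*

   converts raw target coverage into units comparable across samples.
   Background is then removed by subtracting the mode of the scaled
   bin-value distribution and clamping at zero.

2. **Consensus peaks and the co-occupancy superset.** Peak summits are
   extended ±150 bp into fixed 300 bp regions; replicate (and, for SIN-3,
   antibody) calls are intersected and re-extended to 300 bp; regions over
   blacklisted or poorly mappable (< 25% uniquely mappable) sequence are
   discarded. The union of all factors' calls is split into connected
   overlap components, each represented by one 300 bp region flagged for
   overlap with every factor's calls — a disjoint "superset" on which
   co-occupancy can be tabulated.

3. **Strong/weak target classification and notch comparison.** CFP-1-bound
   regions are clustered (k-means, k = 2) on standardized per-region mean
   signals, one feature per track; the cluster with the higher H3K4me3
   centroid is "strong". Region-set signal is summarized as per-region
   means with Tukey box-plot notches, median ± 1.58·IQR/√n; non-overlap of
   two notch intervals is the informal criterion for a significant median
   difference.

4. **Enrichment filters and overlap tests.** AP-MS interactor lists are
   filtered on spectral counts: IP SC ≥ 3 and (control SC = 0 or IP/control
   ≥ 5) in at least one replicate; setting the ratio threshold to ∞ gives
   the stricter control-must-be-zero variant. Differential-expression lists
   (universe: baseMean > 10; significance: BH-adjusted p < 0.05, strict)
   are compared pairwise with a one-sided hypergeometric upper tail
   (Fisher's exact enrichment test), computed by log-factorial summation.

## Coordinate and interval conventions

All coordinates are 0-based, half-open (BED convention); narrowPeak summit
offsets are converted to absolute positions on read. Overlap means ≥ 1
shared base; book-ended intervals do not overlap. The midpoint of a region
is `floor((start + end) / 2)`. Fixed-width windows that would cross a
chromosome end are **shifted, never truncated**, so every region the
pipeline emits is exactly 300 bp; a chromosome shorter than the window is a
hard error. Strand is ignored everywhere except gene starts, which are the
strand-resolved 5′ ends. Output ordering is always (chrom, start, end).

These choices are conventions, not data facts: the interval algebra is
verified against a base-pair enumeration oracle in the test suite, so any
change to the conventions would surface as an oracle disagreement.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `mapq_min` | 10 (inclusive) | mapping quality | unique-alignment filter |
| `flank` | 150 | bp | summit extension, so regions are 300 bp |
| `width` | 300 | bp | consensus / superset region width |
| `map_min_fraction` | 0.25 | fraction | minimum per-bin mappability |
| `max_dist` | 500 (inclusive) | bp | region-to-gene-start promoter distance |
| `min_sc` | 3 | spectral counts | IP abundance threshold |
| `min_ratio` | 5 (`Inf` allowed) | ratio | IP/control enrichment threshold |
| `basemean_min` | 10 (strict >) | normalized counts | expressed-gene universe |
| `alpha` | 0.05 (strict <) | FDR | DE significance |
| `bin` | 10 | bp | coverage track resolution |
| `seed` | 13 | — | k-means initialization |

Threshold directions follow the stated filters exactly: mapq ≥ 10 keeps a
read at exactly 10; baseMean = 10 is excluded; padj = 0.05 is excluded;
IP/control = 5 passes; a gene start exactly 500 bp away is assigned.

## Numerical choices

- **Mode estimation.** The background mode of a scaled track is taken over
  all bins: effectively discrete samples (zero IQR or ≤ 64 unique values)
  use the exact most-frequent value (ties toward the smaller value);
  otherwise a histogram with Freedman–Diaconis width is built over the
  value range and the midpoint of the tallest bin is returned (ties toward
  the lower bin). The estimate is attached to the track and recorded in the
  run manifest. An all-zero track warns and is returned unchanged.
- **Z-scores** use the population (divisor *n*) standard deviation over all
  bins genome-wide, so a z-scored track has mean 0 and SD 1 exactly;
  zero-variance tracks are an error rather than a silent NaN.
- **Input normalization** (a documented stand-in for external
  input-correction pipelines, which are out of scope) scales both tracks to
  equal total mass and takes per-bin log2 ratios with a configurable
  pseudocount (default 1).
- **The hypergeometric tail** is summed term by term on the log scale
  (`lchoose`); tests cross-check it against `phyper`, full enumeration and
  Monte-Carlo resampling. The two-sided option sums the probabilities of
  all tables no more likely than the observed one.
- **The ratio branch** of the spectral-count filter compares
  `ip ≥ min_ratio · control` in exact arithmetic, so a zero control never
  reaches a division and `min_ratio = Inf` cleanly disables the branch.
- **k-means** uses 10 random starts under a fixed seed (restored
  afterwards, so callers' RNG streams are untouched) and is deterministic
  given the seed; a centroid tie on the ranking track falls back to the
  next track.

## Design decisions that were genuinely open

- *"Intersected, also keeping regions with only one factor"* is
  operationalized as: connected overlap components of the union, one 300 bp
  representative per component. A pairwise-intersection reading would
  produce overlapping, factor-count-dependent fragments unsuitable for
  disjoint co-occupancy tabulation; the component reading yields a
  partition, and since a component is a contiguous covered run, its centre
  is always covered by at least one contributing factor, so every superset
  region carries at least one flag.
- Replicate consensus emits one region per overlapping pair (then
  deduplicates), the closest operationalization of "intersecting regions
  were kept"; consensus is symmetric in its inputs, and self-consensus of an
  internally disjoint set reproduces it.
- Promoter distance is edge-to-point and inclusive at 500 bp; a region
  containing the gene start has distance 0. Assignment prefers an annotated
  promoter overlap; otherwise the nearest gene start within range wins,
  ties broken by distance then lexicographic gene id.
- Clustering features are per-region mean signals (one scalar per track)
  rather than full binned profiles: the scalar features match the
  "high/low signal level" definition of the two classes, are robust at low
  region counts, and keep the classification deterministic and cheap. The
  classification is defined over CFP-1-bound regions, mirroring the
  method's own scope.
- Whether the annotated mappability/blacklist filters should use a minimum
  overlap fraction is unstated in the source method; any-overlap (≥ 1 bp)
  removal is used for the blacklist and any-low-bin for mappability.

## The synthetic-data world

Every pipeline input can be generated with known ground truth, seeded and
bit-reproducible (each generator runs in its own RNG substream derived from
the seed and the generator name, and restores the caller's RNG state):

- **Dual-genome reads**: input reads fall on the spike-in genome with
  probability r/(1+r) (default r = 0.10, the stated spike-in proportion for
  the H3K4me3 design; 0.05 matches the HDA-1 design) and uniformly along
  the genome; ChIP reads concentrate around planted summits (150 bp reads,
  Gaussian placement jitter SD 40 bp), with 85% of ChIP reads in peaks by
  default; 10% of reads draw mapq < 10 so the filter is exercised.
- **Peak landscape**: sites ≥ 600 bp apart (so 300 bp regions cannot merge
  by accident), factor combinations drawn from a co-occupancy probability
  table in which most sites carry CFP-1 and triple co-occupancy is the
  most common state; 40% of sites are strong. Replicate calls jitter
  around the planted summit (SD 20 bp; 0 reproduces the planted regions
  exactly).
- **Signal tracks**: uniform background plus Gaussian bin noise, with
  per-site boxcar amplitudes log-normal around the class mean (strong ≫
  weak, e.g. H3K4me3 10 vs 2); mutant tracks scale strong-site amplitudes
  only. With the default spreads the two classes are separated by well
  over 5 within-class SDs in the per-region mean feature.
- **Spectral counts**: planted interactors pass the filter by construction
  (replicate 1: IP ≥ 3, control 0); background proteins fail by low IP or
  by controls that cap the ratio strictly below 5.
- **DE tables**: a 2,000-gene world with 60% expressed and 180 up + 180
  down planted per genotype (~15% of the universe per direction, the
  scaled-down analogue of thousands of DE genes among 11,630 expressed).
  With `overlap = NULL` the genotype sets are drawn independently — the
  null used for type-I calibration, whose analytic attained size at these
  margins is 0.048; a planted-overlap plan fixes exact triple and pairwise
  shared counts.

What the generators do **not** emulate: fragment-length and GC biases, read
sequences, duplicated reads, copy-number structure, overdispersed
background, or realistic gene-length effects. A green test therefore
establishes that the *computations* are correct on data matching their
stated model, not that the model captures every artifact of real
chromatin data.

## Limitations

- BEADS-style input correction, peak calling, alignment and DE estimation
  are consumed as inputs, not re-implemented; `input_normalize` is an
  explicit stand-in.
- Coverage is binned (default 10 bp); per-base quantities are reconstructed
  from bins, so sub-bin structure is invisible.
- The notch criterion is the standard informal McGill rule, not a formal
  test; the package reports the intervals and leaves inference to the
  reader.
- Chromosomes shorter than the region width cannot carry regions at all —
  a deliberate hard error rather than a silent truncation.

All quantitative claims above (ratio recovery, scaling linearity, oracle
equivalence, zero-jitter identity, ARI recovery, filter exactness, the
1/252 enumeration anchor, notch arithmetic, and the null calibration band)
are computed by `tests/testthat/test-acceptance.R`; this vignette states no
number the suite does not itself verify.
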