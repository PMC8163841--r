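---
title: "Nucleosome positioning from reconstitution MNase-seq: methods and design"
author: "nucposlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleosome positioning from reconstitution MNase-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`nucposlab` analyses mononucleosomal MNase-seq data from genome-wide in
vitro chromatin reconstitutions (salt-gradient-dialysis assembly, with or
without ATP-dependent remodelers such as INO80, optionally with the
general regulatory factor Reb1). A nucleosome is represented by its dyad,
the central bp of the ~147-bp wrapped DNA; a paired-end fragment's center
is the dyad estimate. The package covers four layers:

1. **Dyad tracks.** Paired-end fragments are reduced to their center
   (`fragmentCenters()`; floor rule for even lengths). Single-end reads
   are shifted 73 bp towards the dyad and extended to a 50-bp window
   (`singleEndDyads()`); for region counting, fragments are trimmed to
   40 bp around the dyad (`trimmedCoverage()`).
2. **Dyad calling.** Two callers. The greedy caller smooths dyad counts
   with a Gaussian kernel (width 100, i.e. 101 taps, SD 25 bp), then
   iteratively takes the highest value, masks ±120 bp, and finally keeps
   the top 90% of calls by value. The FFT caller low-pass filters
   dyad-trimmed coverage keeping a fraction `pcKeepComp = 0.02` of the
   frequency components and reports strict local maxima above the 99th
   percentile of the filtered signal. +1/−1 nucleosomes are annotated per
   gene: the +1 is the called dyad nearest to the TSS within 0..+500 bp
   downstream, the −1 the first call upstream of the +1
   (`annotatePlus1Minus1()`).
3. **Cross-condition clustering.** Per-sample calls are enlarged to
   20 bp, unioned across samples, and filtered (≥250 bp from tile
   borders, blacklist removed). Fragment centers are counted per region
   and sample and normalized as
   `v = log2(((x / sum(x)) * 1000) + 0.001)`. The region×sample matrix
   goes through PCA (centered, unscaled) and K-means (k = 8, k-means++
   seeding, 25 restarts, best inertia), and clusters are summarized by
   mean occupancy per sample, row-scaled z-scores, and a hierarchical
   display order (`clusterRegions()`).
4. **DNA shape and mechanics.** Per-bp shape profiles come from a
   pentamer lookup table with a 5-bp rolling mean (`shapeProfile()`).
   The DNA rigidity score of a position is the length of the longest
   A(n)T(m) element (n ≥ 0, m ≥ 0, n + m ≥ 2, no TpA step or G/C inside)
   containing it (`rigidityProfile()`); poly(dA)/poly(dT) coverage counts
   overlapping hexamer matches, one unit per covered base
   (`polyATCoverage()`). Composite profiles, heatmaps, upstream Reb1
   signal scores, promoter groups and dyad-density distributions align
   these signals at anchors (TSS, +1 dyads, Reb1 sites, cut sites) in
   gene/motif orientation.

# Coordinates

In memory everything is Bioconductor-native: 1-based closed `GRanges`,
per-bp tracks indexing base *i* at position *i*. Files (BED, BEDPE,
bedGraph) are read and written in their native 0-based half-open
convention; the converters live only at the I/O boundary. Anchors are
single bases: interval start for `+`/unstranded BED rows, `end − 1` for
`-` rows, so a width-1 BED interval denotes the same base on both
strands.

# Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| dyad shift | 73 | bp | single-end 5′-to-dyad distance (half a nucleosome) |
| extension | 50 | bp | dyad-centered window for single-end coverage |
| trim | 40 | bp | dyad-trimmed fragment window for the FFT caller |
| smooth width / SD | 100 / 25 | taps / bp | Gaussian kernel of the greedy caller |
| exclusion | 120 | bp | minimum spacing of greedy calls (≈ nucleosome size − linker tolerance) |
| keep fraction | 0.90 | — | discards the weakest 10% of greedy calls |
| pcKeepComp | 0.02 | — | FFT low-pass cutoff (fraction of components) |
| threshold | 99 | percentile | FFT peak threshold, per contig |
| +1 window | 0..500 | bp | TSS-downstream search window |
| enlarge | 20 | bp | dyad → region window (±10) |
| border exclusion | 250 | bp | distance to tile borders for region filtering |
| k | 8 | — | K-means cluster count |
| composite window | 2001 | bp | per-gene normalization window |
| feature window | 320 | bp | shape/rigidity window around dyads |
| Reb1 window / offset | 120 / 160 | bp | upstream signal scoring for bound/unbound ranking |
| PWM co-location | ±50 | bp | Reb1 hit ↔ PWM matching |
| upstream limit | 400 | bp | Reb1 hit to +1 distance for promoter grouping |

All of these live in `analysisConfig()`, which validates ranges and
rejects unknown keys; `writeAnalysisConfig()`/`readAnalysisConfig()`
round-trip it for reproducible manifests.

# Design choices in ambiguous spots

Several procedural details admit more than one reading; the package
fixes each one explicitly and, where reasonable, exposes the
alternative:

* **Even-length fragment centers** use the floor rule
  (`start + len %/% 2`), so results are deterministic and documented.
* **Single-end extension** is centered on the dyad
  (`[d − extend/2, d + extend/2)`); read-anchored extension would shift
  coverage by half a window. A dyad-centered even window is asymmetric
  by half a bp, which is why exact mirror-symmetry tests use odd
  windows.
* **FFT component count** is `ceiling(pcKeepComp * floor(N/2))` non-DC
  components per contig, no padding or windowing; edge ringing is
  accepted. The percentile threshold is computed per contig over all
  positions, zeros included, matching per-tile processing of a plasmid
  library. Call merging is off by default (`minDistance = 0`).
* **The +1 rule** takes the call nearest to the TSS by absolute
  distance within the window, not the highest-scoring one. For distance
  statistics between two annotations, the compared +1 is assigned by the
  same TSS rule, not by nearest-matching to the reference.
* **PCA** centers but does not scale variables — normalized occupancies
  already share a log2 scale (`scaleVariables = TRUE` is available).
  K-means runs on all principal components by default (Euclidean-
  equivalent to clustering the occupancies); a component subset can be
  selected. R's `kmeans` has no k-means++ initialization, so seeding is
  implemented explicitly with a fixed RNG seed; labels are renumbered by
  decreasing cluster size for stable output.
* **Greedy ties** resolve to the earlier contig and smaller coordinate;
  the top-90% cut is `ceiling(0.9 n)` with ties at the cut kept in
  coordinate order.
* **Rigidity outside any A(n)T(m) element** is 0, reading "no element
  contains the position" as "no rigidity contribution". Poly(dA/dT)
  hexamer matches are counted overlapping (binary mode is available;
  composite shapes are insensitive to the distinction).
* **Rolling means at edges** are undefined whenever the window touches
  an undefined value — no shrinking windows, no silent edge bias.
* **Region filtering order** is join-first, then border/blacklist
  filters on the joined regions.
* **Tile borders** are contig starts and ends plus any internal
  boundaries recorded on the genome object, so a contig models one tile
  unless told otherwise.
* **"Within 400 bp upstream"** for promoter grouping is measured from
  the Reb1 hit to the +1 dyad in gene orientation; the 120-bp Reb1
  scoring window is measured from the +1 dyad (not the nucleosome edge).
* **+1 annotation is condition-specific**: `runPositioningAnalysis()`
  pools the samples named in `plus1Samples` for greedy calling, so a
  two-condition experiment annotates each condition from its own data.

# The synthetic forward model

`syntheticConfig()`/`generateReference()`/`simulateFragments()` generate
a tiled genome (default 50 tiles × 10 kb, GC 0.38, 3 genes per tile)
with planted, sequence-linked positioning information per gene:

* a true +1 dyad, with the TSS 60 bp upstream (a typical yeast
  TSS-to-+1-dyad distance);
* a rigid A-tract (A12, rigidity 12) centered 100 bp upstream of the
  dyad, and a flexible TpA/GC element (rigidity 0) centered at −55,
  mirroring the promoter NDR geometry the analysis is designed to
  detect;
* optionally a Reb1 motif (TTACCC) whose 5′ base sits exactly 145 bp
  upstream of the true dyad, in gene orientation;
* an alternative dyad 70 bp downstream with a weak A-tract of its own.

Two conditions differ only in their dyad preference: the first
("remodeled") places non-background fragments on the true dyad with
probability 0.85 and on the alternative dyad otherwise; the second
("sgd") mirrors the weights. The 0.85/0.15 split is a choice — strong
but noisy preference, enough to make the two position sets separable by
occupancy without being trivial. Fragments are N(147, 10) clipped to
[120, 180] bp, dyad jitter is N(0, 5) rounded (ties to even), and 30%
of fragments are uniform background. Everything is deterministic given
a seed; a different seed redraws the background but never the plant
geometry.

What the model does **not** emulate: MNase sequence bias and end
preferences, histone-density-dependent spacing/phasing, fragment-length
deconvolution, histone variants, and any real-genome base composition
beyond uniform GC. Passing the recovery benchmark therefore shows the
pipeline's operations are correct and well-calibrated on data that obey
its assumptions — it does not certify performance on real libraries.

# Benchmark and problem sizes

`runSyntheticBenchmark()` generates 2 conditions × 2 replicates at
2×10^5 fragments per sample over 50 tiles × 10 kb (150 genes), runs the
full pipeline and reports: the fraction of genes whose +1 is called
within ±20 bp of the planted dyad; the adjusted Rand index between
planted region preferences and K-means clusters grouped by their
preferred condition (regions are matched to planted dyads within half
the alternative-dyad offset); the offsets of the rigidity-composite
maximum and of its minimum within the NDR search band −90..−20 (both as
midpoints of the extremal plateau); and the mode of the Reb1-anchored
dyad density (5-bp bins). The same quantities are what
`scripts/acceptance.R` writes to JSON. The unit-test suite uses smaller
instances (3–6 tiles, 10^3–10^4 fragments) for everything except the
one full-scale benchmark fixture, which is computed once and shared
across the recovery tests.

# Known limitations

* The FFT caller's resolution is bounded by the retained band
  (~`N / kept components` bp); closely spaced alternative positions
  merge into one call. Region labels in the benchmark are therefore
  assigned by nearest planted dyad rather than strict containment.
* The greedy caller calls weak local maxima in background regions; its
  exclusion zone, not a significance test, is what protects +1
  assignment. Downstream consumers should filter by score when working
  with sparse data.
* `readTrack()` fills positions absent from a bedGraph with a constant,
  so NaN gaps do not round-trip (they are written as gaps by design).
* Pentamer shape tables are consumed as input; the package ships no
  shape parameters of its own.
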