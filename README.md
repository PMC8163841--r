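# nucposlab

Nucleosome positioning analysis for genome-wide **in vitro
reconstitution MNase-seq**.

Cell-free chromatin assembled on genomic DNA by salt gradient dialysis
(SGD), with or without ATP-dependent remodelers such as INO80 and
barrier factors such as Reb1, is read out by sequencing
MNase-protected mononucleosomal fragments. Each paired-end fragment's
center estimates a nucleosome **dyad** — the central bp of the ~147-bp
wrapped DNA. `nucposlab` turns mapped fragments into positioning
biology:

* **Dyad tracks** — fragment centers, 73-bp-shifted/50-bp-extended
  single-end reads, 40-bp dyad-trimmed coverage.
* **Two dyad callers** — a Gaussian-smoothed greedy caller (width 100,
  SD 25; iterative maxima with a ±120 bp exclusion zone; top 90% by
  value) and an FFT low-pass caller (`pcKeepComp = 0.02`, strict local
  maxima above the per-contig 99th percentile), plus per-gene +1/−1
  nucleosome annotation (+1 = called dyad nearest the TSS within
  0..+500 bp downstream).
* **Cross-condition clustering** — per-sample calls enlarged to 20 bp
  and unioned into a joint, border/blacklist-filtered region set;
  fragment-center counts normalized as

  ```
  v = log2(((x / sum(x)) * 1000) + 0.001)
  ```

  then PCA (centered) and K-means (k = 8, k-means++ seeding, 25
  restarts) to separate, e.g., remodeler-positioned from SGD-preferred
  nucleosome positions.
* **DNA shape & mechanics** — pentamer-table shape profiles (5-bp
  rolling mean), poly(dA)/poly(dT) hexamer coverage, and a **DNA
  rigidity score**: the score of a position is the length of the
  longest A<sub>n</sub>T<sub>m</sub> element (n ≥ 0, m ≥ 0, n + m ≥ 2;
  no TpA step or G/C inside) containing it.
* **Anchor-aligned profiles** — oriented composites, sorted heatmaps,
  Reb1 signal scoring 160 bp upstream of +1 dyads, promoter grouping
  by Reb1 PWM orientation, +1 distance statistics, dyad-density
  distributions.
* **A synthetic forward model** — tiled genomes with planted
  sequence-linked dyad preferences (rigid A-tract at −100, flexible
  element at −55, Reb1 motif 145 bp upstream of the +1 dyad, an
  alternative dyad at +70 with condition-specific weights), so every
  stage is testable against ground truth.

Standard formats (FASTA, BED, BEDPE, bedGraph, TSV) in, Bioconductor
containers (`GRanges`, `DNAStringSet`, `RangedSummarizedExperiment`)
throughout.

## Worked example

Simulate a small two-condition experiment and run the full recovery
benchmark:

```r
library(nucposlab)

cfg <- syntheticConfig(nTiles = 6, nFragments = 20000)
res <- runSyntheticBenchmark(cfg, seed = 1)
print(res$metrics, row.names = FALSE)
#>                    metric  value  n
#>        plus1_recovery_pct  100.0 18
#>               cluster_ari    1.0 36
#>      rigidity_peak_offset -100.5 18
#>       rigidity_dip_offset  -56.0 18
#>  reb1_density_mode_offset  147.5 18

res$clustering
#> NucClusterResult: 36 regions, 8 clusters, 4 samples
#>   explained variance: 99.6%, 0.2%, 0.1%, 0.1%
```

Reading the numbers: every one of the 18 genes gets its +1 nucleosome
called within ±20 bp of the planted dyad (`plus1_recovery_pct`); the 36
joint dyad regions, clustered by K-means on PCA scores and grouped by
which condition occupies them more, reproduce the planted
condition-preference labels perfectly (`cluster_ari = 1`); the rigidity
composite around the recovered +1 dyads peaks at −100.5 bp (the planted
rigid A-tract) and dips at −56 bp (the planted flexible element); and
the dyad density aligned at Reb1 motifs has its mode in the 5-bp bin at
+147.5, matching the planted 145-bp motif-to-dyad distance.

The same functions run on real data: `readGenome()`,
`readFragments()` (BED/BEDPE) and `readAnchors()` (BED6) load mapped
fragments and annotation, `runPositioningAnalysis()` orchestrates the
stages and writes tables plus a reproducibility manifest, and the
feature/profile functions take any stranded anchors.

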