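# rodsig

Chromatin-signature classification of alternative transcription start
sites (TSS).

Many cell-type-restricted transcripts arise from an *alternative* TSS of
an otherwise broadly expressed gene. In the developing mouse retina, rod
photoreceptor genes show a characteristic promoter signature that can be
read directly from developmental epigenome tracks, without expression
data: accumulation of H3K4me2 across development (and its loss in the
rod-less RD1 mutant), a DNase I hypersensitive site that appears
postnatally, increasing RNA polymerase II occupancy, and binding of the
rod transcription factors CRX and NRL. Constitutive ("common") TSS of the
same genes carry active marks at every age instead.

`rodsig` implements the full analysis:

* **Feature extraction** — each TSS is characterized by 13 features in
  the window TSS ± 1000 bp: H3K4me2 at E17/PN1/PN7/PN15/RD1, DHS at
  1D/1W/8W, PolII at PN2/PN25, CRX (two samples) and NRL. Read-based
  assays aggregate by counting overlapping scored entries; DHS by
  intersecting basepairs × score.
* **Derived statistics and rules** — the H3K4me2 developmental ratio
  (PN15+1)/(PN1+1), ΔPolII = PN25 − PN2 grouped at 0 and 182
  (mean + 2 SD), the DHS ratio 8W/1D grouped at 1 and 1.35
  (mean + 2 SD), and bimodal binding calls (0 reads = unbound). A TSS is
  called **rod** when it gains H3K4me2 (ratio ≥ 3), is depleted in RD1,
  and does not lose DHS; CRX/NRL/PolII feed a confidence score.
* **Cluster validation** — average-linkage hierarchical clustering on
  z-scaled features with distance (1 − r)/2, validated by silhouette
  coefficients s = (B − A)/max(A, B) (> 0.5 reasonable partition,
  < 0.2 no structure).
* **Genome scan** — sliding windows (2000 bp / step 500 bp) outside
  annotated promoters are tested for the rod signature, either by the
  explicit rule or by nearest-centroid correlation distance, merged into
  sites, and annotated by genomic context (promoter / TES / exon /
  intron / intergenic).
* **Synthetic data** — `simulate_dataset()` generates a complete study
  dataset (BED/GTF/bedGraph/manifest plus ground truth) with the
  documented class-conditional laws, so every stage runs and is tested
  without downloads.

## Worked example

```r
library(rodsig)

sim <- simulate_dataset(sim_config(seed = 1), dir = "sim")
res <- run_pipeline("sim", "out")

table(rule = res$rule_class$class, cluster = res$cluster_class[res$rule_class$tss_id])
#>         cluster
#> rule     rod common
#>   rod     61     19
#>   common  22     48

head(res$stats[, c("tss_id", "k4_ratio", "delta_polii", "dhs_ratio",
                   "crx_bound", "nrl_bound", "dhs_group")])
#>    tss_id k4_ratio delta_polii dhs_ratio crx_bound nrl_bound dhs_group
#> 1 G001.T1     9.18          -2      3.72      TRUE     FALSE        up
#> 2 G002.T1    10.22         150      2.99      TRUE     FALSE        up
#> 3 G003.T1     2.43          -4      4.17      TRUE     FALSE        up
#> 4 G004.T1     1.38         120      3.97      TRUE      TRUE        up
#> 5 G005.T1     4.11         -10      3.11      TRUE      TRUE        up
#> 6 G006.T1     1.50          62      3.47      TRUE     FALSE        up

res$clusters$average_sc
#> [1] 0.593

table(res$hits$context)
#>   promoter        TES       exon     intron intergenic
#>          0          0          0          9         10
```

The 150 simulated TSS (107 genes; every multi-TSS gene carries exactly
one rod TSS) are classified twice — by the explicit signature rule and by
the unsupervised 2-cluster partition — and the genome scan reports 19
merged sites outside annotated promoters, recovering the planted
intronic/intergenic signature loci with their genomic contexts. The
average silhouette of 0.59 says the 2-cluster partition is a reasonable
one. `out/` contains the full report bundle: `features.tsv` (features,
derived statistics, both classifications), `clusters.tsv` (per-TSS
silhouettes), `group_summary.tsv` (marker bookkeeping per class),
`scan_sites.bed`/`.tsv`, and `run_log.txt` with the thresholds actually
applied.

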