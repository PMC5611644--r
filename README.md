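# methdyn

Context-specific methylome dynamics from whole-genome bisulfite sequencing
(WGBS) call tables.

In plants, cytosine methylation in the CG, CHG and CHH contexts (H = A, C
or T) is laid down by different pathways with very different developmental
behaviour: CG/CHG methylation over transposable elements (TEs) is largely
stable, while CHH methylation rises sharply through embryogenesis — up to
fully methylated individual sites in mature embryos — and falls back after
germination. `methdyn` is an R toolkit for quantifying such dynamics from
per-cytosine methylation call tables (Bismark-style cytosine reports),
aimed at plant epigenomics analysts comparing developmental stages,
tissues or genotypes.

## What it computes

* **Methylated regions (MRs)** — non-overlapping 100-nt windows are scored
  methylated when the pooled level `sum(meth) / sum(meth + unmeth)` reaches
  at least 40% (CG), 20% (CHG) or 10% (CHH), then merged into regions.
* **Differentially methylated regions (DMRs)** — per 100-bp bin, sites
  covered 10–100× in both samples are pooled (bins with < 4 such sites are
  dropped); each bin gets an exact two-sided Fisher test on its 2×2 count
  table and a Benjamini–Hochberg q-value across all bins. A bin is
  significant iff |Δ level| ≥ 0.40 (CG) / 0.20 (CHG, CHH) and q < 0.01;
  same-direction runs merge across a gap of one window.
* **Overlap enrichment** — for two region sets touching `n1`, `n2` of `N`
  annotations with intersection `k`, the representation factor
  `RF = k·N/(n1·n2)` with a direction-matched hypergeometric tail p-value.
* **Meta-TE profiles** — TE ends aligned per length class, pooled levels in
  10-nt intervals over 4-kb flanks and an interior budget fixed so the
  shortest TE of the class is fully covered without overlapping bins.
* **Saturated CHH sites** — cytosines with every covering read methylated
  (coverage-gated), with TE association and relative-position histograms.
* **siRNA quantification** — 21–22-nt / 24-nt size classes, reads-per-million
  over region sets (normalised by the full mapped library), Student's t
  contrasts.
* **Genome-scale views** — 100-kb stage-ratio profiles with polynomial
  trends, and a DMR × (stage × context) methylation heat matrix ordered by
  complete-linkage clustering (Manhattan distance on the CG columns) with a
  deterministic, permutation-invariant leaf order.
* **A seeded synthetic-data generator** that plants known dynamics
  (stage/compartment methylation levels, DMRs, saturated sites, siRNA
  enrichment) so the whole pipeline can be exercised and benchmarked
  without external data.

## Worked example

Simulate a four-stage study (2 × 1 Mb genome, 20× coverage) and run the
pipeline:

```r
library(methdyn)

cfg <- sim_config(seed = 1)
ex  <- simulate_experiment(cfg)
ex$methylomes$mature_embryo
#> stage_methylome 'mature_embryo': 250000 cytosines on 2 chromosome(s)
#>   contexts: CG=33356 CHG=49921 CHH=166723

## CHH MRs: mature embryos carry long, highly methylated regions,
## seedlings short fragmented ones
mr_me <- call_mrs(ex$methylomes$mature_embryo, "CHH")
mr_sd <- call_mrs(ex$methylomes$seedling_4d,   "CHH")
summarize_mrs(rbind(mr_me, mr_sd))[, c("stage", "context", "n",
                                       "length_median", "level_median")]
#>           stage context   n length_median level_median
#> 1 mature_embryo     CHH 188          1700    0.4530136
#> 2   seedling_4d     CHH 898           100    0.1115791

## CHH DMRs, mature embryo vs 4-day seedling, annotated with TEs
tes  <- subset(ex$genome$annotations, kind == "TE")
dmrs <- call_dmrs(ex$methylomes$mature_embryo, ex$methylomes$seedling_4d,
                  "CHH", annotations = tes)
nrow(dmrs)                      # 110 DMRs, all hyper in the mature embryo
head(dmrs[, c("chrom", "start", "end", "direction", "n_bins",
              "mean_diff", "annotation")], 3)
#>   chrom  start    end direction n_bins mean_diff annotation
#> 1  Chr1 119300 121900     hyper     25 0.3969485        TE1
#> 2  Chr1 143800 149400     hyper     55 0.3773677        TE2
#> 3  Chr1 170000 173300     hyper     33 0.3785027        TE3

## saturated CHH sites (every covering read methylated, >= 5x)
sat <- find_saturated_chh(ex$methylomes$mature_embryo, min_cov = 5, tes = tes)
nrow(sat)                       # 202 sites, all on TEs

## overlap enrichment: RF = observed / expected overlap of annotation sets
representation_factor(n_universe = 1000, n_set1 = 100, n_set2 = 50,
                      n_overlap = 20)
#> overlap: 20 of (100 x 50) in universe 1000; expected 5.000, RF = 4.000, p = 6.38e-09

## 24-nt siRNA abundance over the CHH-hyper DMRs (RPM against the full library)
r24 <- select_size_class(ex$sirna, "24")
q   <- quantify_regions(r24, dmrs, attr(ex$sirna, "library_total"))
median(q$rpm)
#> [1] 1872.5

## clustered heat matrix across all four stages
hm <- order_heat_matrix(build_heat_matrix(dmrs, ex$methylomes))
dim(hm)                         # 110 DMRs x 12 stage-context columns
round(hm[1, c("mature_embryo.CHH", "seedling_4d.CHH")], 3)
#> mature_embryo.CHH   seedling_4d.CHH
#>             0.491             0.088
```

The numbers show the planted biology end to end: CHH MRs an order of
magnitude longer in mature embryos than in seedlings, every DMR hyper in
the mature embryo and sitting on a TE, saturated CHH sites confined to
TEs, strong 24-nt siRNA signal over the hypermethylated regions, and a
heat matrix whose CHH columns peak in the mature embryo.

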