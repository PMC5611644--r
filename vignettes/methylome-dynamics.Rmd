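---
title: "Window-based methylome dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based methylome dynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdyn)
```

## The problem

In flowering plants, cytosine methylation occurs in three sequence contexts
— CG, CHG and CHH (H = A, C or T) — maintained by different pathways. CG and
CHG methylation over transposable elements (TEs) is largely stable through
development, while CHH methylation is dynamic: it is low (~10–20%) in
seedlings, rises through embryogenesis, and in mature embryos can reach
complete saturation at individual sites, driven by the 24-nt-siRNA-guided
RdDM pathway at TE edges and by CMT2 in long heterochromatic TE bodies.
`methdyn` implements the window-based analysis stack needed to quantify
these dynamics from whole-genome bisulfite sequencing (WGBS) call tables:
methylated-region (MR) calling, differentially methylated region (DMR)
calling, annotation-overlap enrichment, end-aligned meta-TE profiles,
saturated-CHH-site catalogues, small-RNA quantification over regions,
chromosome-scale stage comparisons, and a clustered DMR heat matrix.

The input is the Bismark-style cytosine report: one row per cytosine with
counts of reads calling C (methylated) and T (converted, unmethylated).
The methylation level of any unit (site, window, region) is the pooled
ratio `sum(meth) / sum(meth + unmeth)` unless stated otherwise. Read
alignment, deduplication and conversion-rate QC are upstream of this
package and out of scope.

### Coordinates

Every interval inside the package is 0-based half-open, the BED convention.
The cytosine report (1-based positions) and GFF3 (1-based inclusive) are
converted at the I/O boundary and nowhere else; a single internal
convention eliminates off-by-one drift between window tiling and annotation
overlap. Strands are kept separate — symmetric CG collapsing is *not*
performed — so counts remain auditable against the input report.

## MR calling

Chromosomes are tiled from coordinate 0 into non-overlapping 100-nt
windows. A window is *methylated* when its pooled level reaches at least
40% (CG), 20% (CHG) or 10% (CHH); the comparison is inclusive, so a CHH
window at exactly 10% is methylated. Windows with no covered site of the
context are unscored: they are neither methylated nor unmethylated.
Maximal runs of methylated windows merge into MRs; `max_gap_windows`
(default 0) controls how many intervening non-methylated or unscored
windows may be bridged. The MR level pools counts over member methylated
windows only.

Two choices here were genuinely open:

* *Window level is the pooled count ratio*, not the mean of per-site
  levels, consistent with counting called Cs and Ts directly; the two
  differ when coverage is uneven across sites.
* *The MR merge rule is a parameter.* Published MR length distributions do
  not pin down a merge rule; we default to strict adjacency (gap 0) as the
  conservative choice and expose the gap budget, mirroring the DMR rule
  below. A minimum site count per window is likewise exposed
  (`min_sites`, default 1); the ≥ 4-site rule belongs to the DMR caller.

## DMR calling

Two samples are compared per context on the same 100-bp tiling:

1. **Site gate.** A cytosine participates only if covered by 10–100 reads
   in *both* samples (low coverage is noise; extreme coverage flags
   collapsed repeats).
2. **Bin gate.** Bins with fewer than 4 passing cytosines are dropped —
   bins with three or fewer sites are never tested.
3. **Statistic.** Each retained bin yields one 2×2 table of pooled counts
   (meth/unmeth × sample). `fisher_exact_2x2()` computes the exact
   two-sided p-value by the sum-of-small-p rule: conditioning on the
   margins, it sums hypergeometric point probabilities not exceeding the
   observed one (relative guard 1 + 1e-7 against floating-point ties). The
   implementation is vectorised over bins via `dhyper`; an independent
   `lchoose`-based enumeration oracle and `stats::fisher.test` back it in
   the tests.
4. **FDR.** Benjamini–Hochberg across all retained bins genome-wide, per
   context and comparison (`stats::p.adjust` behind a validating wrapper).
   Per-chromosome correction was rejected: the tiling is genome-wide.
5. **Selection.** A bin is significant iff `|diff| >= ` 0.40 (CG) / 0.20
   (CHG, CHH) *and* `q < 0.01`. The difference threshold is inclusive, the
   FDR strict. `diff` is the difference of pooled bin levels (sample A −
   sample B); direction `hyper` means A more methylated.
6. **Merging.** Runs of same-direction significant bins merge, bridging up
   to one non-significant bin (regions within 100 bp of each other merge).
   Hyper and hypo bins never merge. The DMR `mean_diff` is the
   site-count-weighted mean of member-bin differences; thresholds apply at
   the bin level, the merged mean is reported.

A consensus mode (`call_dmrs(replicates=)`) optionally requires a bin to be
significant in every supplied replicate comparison; the default uses the
single comparison. Note that consensus filtering can split a merged region
when it removes a bridging bin.

The degenerate 2×2 table with an empty sample row returns p = 1 with a
warning: no evidence either way.

## Overlap statistics

Two annotated region sets are reduced to the distinct annotation ids they
touch (≥ 1 bp overlap; half-open adjacency is not overlap; regions touching
nothing are `intergenic`). For sets of sizes $n_1, n_2$ in a universe of
$N$ annotations with observed intersection $k$:

$$\mathrm{RF} = \frac{k}{n_1 n_2 / N},$$

the representation factor. Significance is the one-sided hypergeometric
tail matched to direction: $P(X \ge k)$ when RF ≥ 1, $P(X \le k)$ when
RF < 1, $X \sim \mathrm{Hypergeom}(N, n_1, n_2)$. The universe defaults to
every annotation of the compared kind in the supplied file — the only
defensible default when no explicit universe is given.

## Meta-TE profiles

TEs are grouped into three length classes (defaults < 1 kb, 1–2 kb,
≥ 2 kb; the boundaries are parameters since only the middle class is
conventionally named). Within a class, TE ends are aligned and pooled
methylation is averaged in 10-nt intervals: 4 kb of flank on each side,
and an interior budget of `floor(shortest_length / 2 / bin)` intervals per
side counted from each border toward the middle — so intervals are common
to all members and never overlap within the shortest TE; longer TEs leave
their middle unprofiled. Minus-strand TEs are mirrored so bin 1 is always
the 5′ border; TEs with strand "." are treated as plus strand
(deterministic fallback). Sites in overlapping flanks of nearby TEs
contribute to each TE — excluding them would bias dense pericentromeric
regions. Bins with no contributing sites are `NA`, never 0.

`relative_positions()` maps saturated sites or DMR midpoints to [0, 1]
within their TE (strand-mirrored) and bins the occurrences; each item
carries one `feature_id`, so the histogram total equals the input count.

## Small-RNA quantification

Reads are size-selected (24 nt, or 21–22 nt), counted over regions by ≥ 1
bp overlap (once per region they overlap), and normalised to RPM against
the *total* mapped library size — not the size-class subtotal, since the
denominator of record is all mapped small RNAs. Group contrasts use the
pooled-variance Student's t-test by default (Welch by flag); groups of one
region are rejected.

## Genome-scale views

* `chrom_profile()` pools counts into 100-kb windows per stage and reports
  `level_a / (level_b + 0.001)` (pseudocount against empty denominators;
  a difference mode is available since a "ratio" can be read either way).
  The trend is a least-squares polynomial over window midpoints: degree 1
  is a literal regression line; the default degree 3 can follow the
  pericentromeric bump that a line cannot.
* `find_saturated_chh()` catalogues CHH sites with `n_unmeth = 0` and
  coverage ≥ `min_cov` (default 5: a 100% level on one or two reads is not
  evidence of saturation).
* `build_heat_matrix()` fills one row per DMR and one column per
  stage × context with the *unweighted mean of per-site levels* of covered
  cytosines overlapping the DMR — deliberately different from the callers'
  pooled ratios, because here every covered cytosine counts equally. Rows
  uncovered in any stage/context are dropped and counted.
* `cluster_rows()` orders rows by complete-linkage clustering with
  Manhattan distance on the CG columns only, the other contexts following
  the same permutation. On top of `stats::hclust` we impose a
  deterministic leaf order: at every merge the smaller subtree comes
  first, ties broken by the lexicographically smallest member row. The
  tie-break is content-based rather than index-based on purpose — an
  index-based rule would make the display order depend on input row order,
  and permutation invariance of the ordered matrix is a property we test.

## The synthetic-data generator

`simulate_experiment()` is first-class, tested code: it plants known
methylation dynamics so every downstream stage can be benchmarked without
external data, and its defaults define the package's reference study
conditions.

**Genome.** Per chromosome (default 2 × 1 Mb): a centred pericentromere
(20% of the chromosome), non-overlapping TEs (80 per chromosome, 0.5–6 kb,
70% placed inside the pericentromere, making it ~9× denser than the arms),
genes on the arms, and cytosines at 0.125 sites/bp with context drawn
CG : CHG : CHH = 1 : 1.5 : 5 — CHH much more frequent than CG, as in a
plant genome. Feature layouts are drawn uniformly over admissible
non-overlapping placements.

**Stages.** Each site's true methylation probability is looked up by
(context, compartment, stage), where compartments are TE edge (200 bp at
each end), TE interior, gene body and background. The default profiles
encode the qualitative biology: CG on TEs 0.85 at all stages; CHH on TEs
0.10/0.08 in seedlings, 0.25 in early embryos (with a +0.10 pericentromeric
boost), 0.60 at edges / 0.45 interior in mature embryos; CHG intermediate.
These are shapes, not claims about exact published levels, and are fully
overridable. Planted DMRs override their interval in exactly two stages
(`base_level + diff` vs `base_level`); 200 planted saturated CHH sites get
probability exactly 1.0 in the mature embryo. Coverage is
Poisson(20) floored at 1 (a floor rather than a zero-truncated resample —
the difference is negligible at mean 20 and the floor keeps one draw per
site); methylated counts are Binomial(coverage, p).

**siRNAs.** 24-nt reads are generated so the per-bp start rate inside
target intervals (the planted mature-embryo CHH-hyper DMRs) is exactly
`enrichment_fold` (default 10) times the outside rate, plus a 30% fraction
of uniformly scattered 21–22-nt reads; the library total is recorded for
RPM normalisation.

**Reproducibility.** All draws happen in labelled substreams hashed from
the master seed ("genome", "stage:<label>", "sirna"), so identical
configurations are bit-identical and adding a stage never perturbs another
stage's data.

**What the generator does not emulate** — and therefore what passing tests
do *not* show about real data: bisulfite conversion failure, mapping bias
and multi-mapping, strand-asymmetric coverage, sequence-composition effects
on cytosine spacing, TE family structure, and mechanistic endosperm
demethylation (representable only as a planted hypomethylated stage).
Recovery rates measured here are upper bounds for field performance.

## Numerical choices and degenerate inputs

* Fisher p-values: vectorised `dhyper` with the 1 + 1e-7 relative tie
  guard; exhaustive agreement with the enumeration oracle to < 1e-12 on
  all tables with margins ≤ 30 is part of the test suite.
* Undefined levels (zero coverage) are `NA`, never 0; unscored windows
  count toward merge-gap budgets only.
* Empty region lists round-trip as empty files; empty methylomes tile to
  all-`NA` windows when chromosome lengths are known.
* `chrom_profile` with a window larger than the chromosome emits a single
  window with a warning.
* Heat-matrix rows failing coverage in any stage are dropped and counted;
  an all-dropped matrix is an error, as is clustering on `NA` anchors.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run: the exhaustive Fisher sweep
over ~163,000 tables (margins ≤ 30); 10,000 random BH vectors; a null
comparison with ~6,800 retained CHH bins at 20× on a 700-kb chromosome; 30
planted CHH DMRs (difference 0.3, 300–1,000 bp) on a 1-Mb chromosome; and
the full four-stage study on a 2-Mb genome with 10 planted DMRs and 200
saturated sites. These sizes give stable statistics (binomial standard
errors of a few percent or less on every reported rate) while the whole
suite completes in about two minutes.

## Known limitations

* MR/DMR calling is thresholded-window based by design; no smoothing, HMM
  segmentation or beta-binomial dispersion model is provided.
* Multi-mapping small RNAs are counted at their given coordinates with
  weight 1; fractional allocation is out of scope.
* The consensus ("replicates") mode is a set intersection of significant
  bins, not a joint model across replicates.
* Three-set overlaps report pairwise representation factors only.
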