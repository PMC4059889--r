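---
title: "Methods: co-occupancy clustering and target classification with chipcooc"
author: "chipcooc maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occupancy clustering and target classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipcooc)
```

# The analysis this package implements

`chipcooc` reconstructs, as a tested and reusable pipeline, a multi-factor
ChIP-seq co-occupancy analysis of the kind used to dissect how a shared
catalytic subunit (the histone acetyltransferase MOF) distributes between
two distinct protein complexes (MSL and NSL) across cell states (embryonic
stem cells, ESC, and neuronal progenitors, NPC). The scientific questions
such an analysis answers are: where do the subunits bind alone or together;
how do binding patterns group genome-wide; which genes does each
factor regulate from the promoter versus from a distance; and how does
knocking a factor down change the expression of its targets.

The pipeline stages, in dependency order:

1. **Replicate-consensus peak filtering.** Peaks are called per replicate
   and on the pooled replicates; only pooled-replicate ("merged") peaks
   supported by at least one overlapping peak in *each* replicate are kept,
   with borders, summits and scores taken from the merged calls. Peaks with
   $-10\log_{10} p < 50$ or an FDR $> 0.1\%$ are then excluded. Both
   exclusion rules are strict inequalities, so peaks exactly on a threshold
   survive.
2. **Input normalization with signal extraction scaling (SES).** Coverage
   is binned (50 bp by default); ChIP and input tracks are depth-matched on
   their background. Bins are ordered by increasing ChIP signal; writing
   $P_c(k)$ and $P_i(k)$ for the cumulative fractions of total ChIP and
   input signal in the $k$ lowest-ChIP bins, the background cut is
   $k^* = \arg\max_k |P_i(k) - P_c(k)|$ (smallest $k$ on ties, and only
   $k$ with positive cumulative ChIP signal are candidates). The scale
   factor is $f = \sum_{j \le k^*} i_j / \sum_{j \le k^*} c_j$, the
   multiplier that equalizes the two backgrounds. The normalized track is
   the per-bin $\log_2\!\big((f\,c + \psi)/(i + \psi)\big)$ with pseudocount
   $\psi = 1$ on both sides, so a ChIP track identical to its input maps to
   exactly zero.
3. **Region signal matrices.** The cross-sample union of consensus peaks
   (merged as `bedtools merge` would, i.e. book-ended intervals join)
   defines the region set. For each region and sample a 2 kb window
   centered on the region midpoint is cut into 50 bp bins whose values are
   per-base means of the normalized track; bases outside the genome
   contribute zero. A scale-regions mode (region linearly rescaled to the
   window before binning) is available for profile-style analyses such as
   sub-clustering enhancer-like regions.
4. **Rank-transform Ward clustering.** Each matrix column is replaced by
   its ranks across regions (average ranks on ties) divided by the row
   count. Ranking each sample separately removes dynamic-range differences
   between antibodies and depths, which is precisely what lets the
   clustering reflect *co-binding patterns* rather than amplitudes; it also
   makes the labels invariant under any strictly increasing per-sample
   transform of the raw signal. Rows are clustered on Euclidean distances
   with Ward's minimum-variance criterion and the dendrogram is cut at
   $k = 2 \dots 10$; the main analysis uses $k = 5$.
5. **Annotation and target classification.** Regions are assigned to
   mutually exclusive compartments (1 kb upstream of a TSS > gene body >
   intergenic). Genes are classified per factor as **TSS targets** (a peak
   overlaps TSS $\pm$ 1 kb), **TSS-distal targets** (a globally TSS-distal
   peak overlaps the gene's typical/super enhancer, falls in its
   basal-plus-extension regulatory domain, or overlaps one of its introns),
   **bound-unclassified** (some binding evidence but no target criterion),
   or **non-targets** (no promoter, gene-body or distal evidence from any
   analyzed factor). Complex-level calls: a gene is an MSL target when MOF
   and MSL1|MSL2 are tied to it through the same route (both at the TSS
   window, or both distally assigned); NSL targets analogously with
   KANSL3|MCRS1.
6. **Expression integration.** Active genes have mean FPKM $\ge 4$ across
   replicates. Genes are split into low/intermediate/high tertiles of mean
   FPKM among nonzero genes. Knockdown differential-expression tables
   (gene, log2 fold change, adjusted p) are cross-tabulated by target class
   and group: significant means adjusted $p \le 0.01$, direction is the
   sign of the fold change, and fractions are taken within each cell.
   Group-expression comparisons use Welch's unequal-variance t test;
   cross-species co-binding of homolog pairs is tested with Pearson's
   chi-square on the 2x2 table (Yates correction off by default, available
   behind a flag since the convention differs between software).

# Design choices where the design was genuinely open

* **Coordinate convention.** All interval containers are `GRanges`
  (1-based, closed), the standard of the Bioconductor stack this package
  builds on; BED-family files are converted from 0-based half-open
  coordinates on read and back on write. A window phrased "position
  $\pm N$ bp" covers exactly $2N$ bases, clipped at chromosome ends
  (whether such windows should be clipped is not obvious; we clip).
* **Ward variant.** "Ward's method" historically meant two different
  `hclust` updates; we use `ward.D2`, the variant that is variance-correct
  when fed unsquared Euclidean distances (each merge height equals
  $\sqrt{2\,\Delta\mathrm{SSE}}$). The test-suite verifies the whole merge
  tree against an exhaustive $O(n^3)$ agglomeration oracle on small
  instances. Cluster labels are canonicalized by first occurrence in row
  order, so identical inputs give identical labels everywhere.
* **Rank direction.** Ranks are taken within columns (each sample/bin
  feature across regions), not within rows: column-wise ranking is what
  makes samples with different dynamic ranges comparable, which is the
  purpose of the transform.
* **Window anchoring.** The clustering matrix anchors a fixed 2 kb window
  on each region's midpoint rather than rescaling regions; unscaled peaks
  of varying width keep their shape that way. Scale-regions mode is one
  config switch away.
* **Regulatory domains.** The web-service association of distal peaks to
  genes is re-implemented in-repo as the documented basal-plus-extension
  rule (basal = 5 kb upstream / 1 kb downstream of the TSS; extension up to
  1 Mb per side, stopping at the nearest other gene's basal domain, which
  is inviolate). Distal assignment uses the extended domain.
* **Expression bins.** "High/intermediate/low" are tertiles of mean FPKM
  among nonzero genes — equal-count bins with stable tie handling; the cut
  points are emitted alongside the bins.
* **Non-target harmonization.** A gene bound only in its gene body, or
  bound by some other profiled factor, is "bound-unclassified", never a
  non-target: non-target status requires the absence of promoter,
  gene-body and distal evidence across *all* analyzed factors, which is
  the strictest reading consistent with using non-targets as a negative
  control group.

# The synthetic-data generator

Every stage is exercised end-to-end on generated data with known ground
truth; nothing is downloaded. The generator's defaults define the standard
study conditions used by the acceptance checks:

* a 3 x 10 Mb genome with 500 non-overlapping multi-exon genes (1-10
  exons), CpG islands at 60% of promoters, ~700 bp typical enhancers and
  10-30 kb super enhancers in intergenic space, each assigned to the
  nearest TSS;
* five planted co-occupancy patterns of 200 regions each (1,000 regions)
  over 10 samples (5 factors x 2 cell types), mirroring the canonical
  archetypes: all factors at promoters (A), MOF+NSL at promoters (B),
  solitary MSL2 away from promoters (C), stem-cell-specific MOF+NSL at
  intergenic sites (D) and stem-cell-specific MOF+MSL over gene bodies
  (E); pattern widths range from ~850 bp (E) to ~1800 bp (A);
* negative-binomial input coverage (mean 10 per 50 bp bin, dispersion
  0.2), one shared input per cell type; each ChIP track inherits the
  input's bin-to-bin background shape scaled by a per-sample depth factor
  (default cycle 0.5/1/2) plus a Gaussian enrichment profile peaking at
  $2^a - 1$ times the local background, with planted amplitude $a = 2$
  log2 units. ChIP noise is therefore inherited from the input draw rather
  than redrawn — the ratio structure that input normalization assumes —
  which makes the true background ratio exactly the depth factor and gives
  SES a well-defined truth to recover;
* peak calls with replicate borders jittered $\pm$50 bp, 2% of merged
  peaks drawn below the quality filter, and false peaks (10% rate) that
  appear in the merged calls and exactly one replicate, so that replicate
  consensus is what removes them;
* log-normal baseline FPKM with promoter-bound genes drawn from a
  higher-mean component; per knockdown, planted promoter targets are
  downregulated with probability 0.8 (log2 fold change
  $\mathcal{N}(-1.5, 0.3)$, adjusted p below $10^{-3}$), everything else
  is null with uniform adjusted p, so the expected false-positive rate at
  any $\alpha$ equals $\alpha$ by construction.

What the generator deliberately does **not** emulate: read-level artifacts
(mappability, GC bias, duplicates — the pipeline's unit is binned
coverage), local background waves in the input, partially overlapping or
nested binding sites, correlated replicate noise, and any sequence content.
A green test-suite therefore shows that the *computations* are correct
under the stated model, not that the model captures every failure mode of
real chromatin data.

# Numerical choices and degenerate inputs

* SES ties at the argmax break to the smallest $k$; bins with zero
  cumulative ChIP signal are never chosen, and proportional tracks (no
  background/enrichment contrast) fall back to the lowest informative bin,
  which yields the exact total ratio.
* The pseudocount ($\psi = 1$ by default on raw counts) bounds the log
  ratio at low coverage; identity tracks map to exactly 0 for any
  $\psi > 0$.
* Matrix windows that reach past a chromosome end impute zero signal over
  the missing bases but keep the nominal bin width in the denominator, so
  row lengths are constant.
* An empty consensus (e.g. an impossibly strict score filter) propagates
  as empty-but-valid outputs: the pipeline warns, skips clustering, writes
  every table it can, and exits cleanly.
* Zero-variance tracks get `NA` correlation entries rather than
  propagating `NaN`; the diagonal stays 1.
* All generator stages derive their RNG stream from one master seed;
  rerunning any stage or the whole pipeline with the same config is
  byte-identical, and output files contain no timestamps for that reason.

# Problem sizes in the test-suite

Unit tests run on toy chromosomes (kilobases, tens of intervals) against
per-base bitmap oracles, exhaustive rule evaluators and closed-form
statistics. The end-to-end checks use the default 1,000-region /
10-sample conditions for cluster recovery (adjusted Rand index against the
planted labels), a 200-gene annotation for exact target-classification
agreement, 100 generator seeds for the knockdown cross-tab recovery, and
8,000 null genes for the false-positive-rate check. These sizes were chosen
as the smallest that make the statistical assertions sharp.

# Known limitations

* The generator plants non-overlapping regions; the pipeline handles
  overlapping peaks (the union step merges them) but cluster-recovery
  claims are only tested on disjoint truth.
* GC-bias correction and other read-level normalizations are out of scope;
  coverage enters the pipeline already binned.
* Automatic selection of $k$ is intentionally absent — the pruning scan
  over $k = 2 \dots 10$ is provided and the choice is left to inspection,
  as in the analysis this package reconstructs.
* The DE model itself is consumed, not implemented: the pipeline ingests
  (gene, log2FC, adjusted p) tables from any upstream tool.
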