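---
title: "Methods: simulating and scoring a tandem-reporter autophagy screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring a tandem-reporter autophagy screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxscreen)
```

## The screen and its readout

The pipeline in this package is built around the tandem mCherry-EGFP-LC3B
autophagic-flux reporter. Both fluorophores travel with LC3B into the
autophagosome; when the autophagosome fuses with a lysosome the acidic lumen
quenches EGFP but not mCherry. A starved cell with functional flux therefore
loses GFP signal, while a cell in which flux is blocked (for example by
knockdown of a fusion regulator) keeps it. In the pooled screen each cell
carries a single shRNA; after starvation the population is sorted into a
"GFP high" gate (flux defective) and a "GFP low" gate (flux functional), and
the integrated guides in each sorted population are amplified with
sample-specific barcodes and sequenced. Guides enriched in the GFP-high
population mark candidate autophagy regulators.

## Scoring model

Scoring is deliberately the screen's own deterministic rule rather than a
statistical test:

1. **Normalization.** Each sample's counts are scaled to reads per million:
   `rpm = (count + pc) / total * 1e6`, where `total` is the raw column sum.
   The pseudocount enters the numerator only, so with `pc = 0` every column
   sums to exactly $10^6$. `pc` defaults to 0.5 when any zero count is
   present (keeping fold changes finite) and 0 otherwise.
2. **Fold enrichment.** For each shRNA and replicate,
   $FC_r = \mathrm{RPM}_{\mathrm{high},r} / \mathrm{RPM}_{\mathrm{low},r}$.
3. **Replicate geometric mean.** $G = (\prod_r FC_r)^{1/R}$, computed in log
   space as `exp(mean(log(FC)))` for numerical stability; on small inputs
   this equals the literal product form to machine precision.
4. **Scoring shRNA.** $G \ge 3$. The threshold is inclusive: "at least
   three-fold" is read literally, so $G = 3.00$ scores.
5. **Hit gene.** At least 3 scoring shRNAs (again inclusive). The reported
   `avg_geomean` is the arithmetic mean of the scoring shRNAs' geometric
   means only.
6. **Ranking.** Number of scoring shRNAs descending, then average geomean
   descending, then gene name ascending. The published hit list has no exact
   ties, but a deterministic tie-break is required for reproducibility;
   alphabetical order is the neutral choice.

No p-values or FDR control are attached: the procedure is thresholding, and
matching it exactly is the point. `normalize_rpm()` uses reads-per-million
because it is the minimal depth correction consistent with ratio scoring;
any per-sample scale factor cancels in $FC_r$, which the scale-invariance
tests assert.

## What the screen simulator emulates

`simulate_screen_counts()` generates counts from an explicit causal chain
rather than from a count distribution directly:

* **Library.** `simulate_library()` allocates shRNAs to genes as evenly as
  possible (the integer split of 4,184 guides over 710 genes, remainder
  assigned in deterministic gene order — only the totals of the real library
  are published). Guides and barcodes are sampled uniquely.
* **Cells.** Per replicate, `coverage` cells per shRNA (default 1,000, the
  screen's own representation target). Each cell blocks flux with
  probability `gene_effect * shrna_efficacy`.
* **Fluorescence.** Basal GFP is log-normal. Flux-competent cells are
  quenched by a single multiplicative `quench_factor` (default 0.2); blocked
  cells keep basal GFP. The quenching magnitude is only described
  qualitatively for the real reporter, so it is a tunable scalar.
* **Gates.** Cells above the 90th / below the 10th percentile of the pooled
  starved GFP distribution form the high/low pools. The real gate bounds
  were drawn on the cytometer and are not published; outer deciles are a
  conservative default and are configurable.
* **Sequencing.** Per pool, counts are multinomial over the pool's shRNA
  composition at `sequencing_depth` reads (default 100 reads per shRNA), so
  column sums equal the depth exactly and the null is analytically centred
  at fold change 1. Dirichlet overdispersion is available but off by
  default for exactly that reason.
* **Reads.** `simulate_fastq()` writes error-free reads (barcode
  immediately followed by guide, constant Q40). Real read layouts vary and
  include errors; the error-free convention keeps
  `count_guides(simulate_fastq(M)) = M` an exact identity, which is the
  oracle the counting module is tested against. Counting is exact-match
  only — no mismatch rescue — for the same reason.

What the generator does *not* emulate: transduction and selection kinetics,
multiple integrations per cell (single copy is assumed), PCR amplification
bias, sequencing errors, or cell-cycle and expression heterogeneity beyond
the log-normal. Passing the recovery tests therefore shows the scoring
procedure is correct and well calibrated under the stated generative model,
not that the thresholds are optimal for any particular real dataset.

`plan_experiment()` carries the bench arithmetic that sets the simulator's
scale: 4,184 shRNAs at 1,000x coverage gives 4.184 million transduced
cells, ~49.2 million seeded at 8.5% transduction efficiency, and 27 µg of
genomic PCR template at 1,000x representation using 6.5 pg per diploid
mouse genome.

## Flux quantification

`summarize_flux()` follows the cytometry convention: arithmetic mean of raw
(linear) fluorescence per cell line x replicate x condition — the readout
is reported as "mean of relative fluorescence units", not a log mean — the
control condition (full medium or vehicle) set to 100% within each
replicate, and mean ± SD (n−1) across replicates. With the event simulator
at quench factor $q$ and no blocking, the starved percentage converges to
$100q$; the tests assert agreement within three standard errors.

`derive_gates()` places the GFP-low gate below the $(1-\alpha)$ quantile of
a flux-competent (starved) control and the GFP-high gate above the
$\alpha$ quantile of a flux-blocked control, erroring when the gates would
overlap ("controls not separable"). Gate membership is inclusive-lower /
exclusive-upper, so disjoint gates partition at most 100% of events.
$\alpha$ defaults to 0.05.

## 3D spot detection and colocalization

`detect_spots()` mirrors an object-based vesicle quantification: a
band-pass filter implemented as a difference of Gaussians (`sigma_low = 1`,
`sigma_high = 5` voxels), a threshold (Otsu's method on the filtered stack
by default, or a fixed value), a 3x3x3 morphological closing to reshape the
binary mask, 26-connected components, and false-positive filters on volume
(`min_size = 5` voxels), mean intensity and coefficient of variation.
Object statistics are always computed on the original intensities, never on
the filtered ones. The original analysis software's kernel and filter
values are not published, so `intensity_min` and `cv_max` default to "off"
and must be calibrated per dataset.

Overlap is computed on binary voxel supports, making it invariant to
intensity rescaling. "More than 40% overlap" leaves the denominator
ambiguous, so both directional fractions
$|A \cap B|/|A|$ and $|A \cap B|/|B|$ are reported and a pair is double
positive when **either** strictly exceeds 0.40 — the most permissive
literal reading, and strict so that exactly 40% does not qualify.
`containment_percent()` calls a vesicle "containing" when at least one
cargo centroid (rounded to a voxel) lies inside it. `line_profile()`
samples channels by trilinear interpolation at `round(L/s) + 1` equally
spaced points over a segment of length $L$ and spacing $s$ (a 6 µm segment
at 0.1 µm spacing gives 61 samples).

The stack simulator renders spherical spots and reports ground-truth
supports and pairwise overlaps; `spot_pair_at_overlap()` searches the
centre distance by bisection until the voxelized sphere intersection
matches a target fraction (the voxelized overlap is a step function of
distance, so targets are met within ±0.05). The default intensity profile
is **flat** (uniform over the support): overlap ground truth is defined on
binary supports, and a Gaussian-profile spot's thresholded mask is
systematically smaller than its nominal support, which would bias measured
overlap low by more than the ±0.05 closure tolerance. A `"gaussian"`
profile remains available for visually realistic spots and for
peak-position tests. Noise (Poisson shot noise, additive Gaussian read
noise) is applied after rendering.

## Numerical and interface conventions

* Every generator takes an integer `seed`; a fixed seed gives bit-identical
  output.
* Voxel coordinates are 0-based with the origin at voxel (0,0,0); physical
  positions are `coordinate * voxel_size` µm. Stacks are `[channel, z, y,
  x]` arrays, written as channel-major multi-page TIFF with a JSON sidecar
  holding dimensions, voxel size and the intensity scale (TIFF samples are
  stored in [0,1]).
* A read whose barcode matches no sample cannot be attributed to one, so
  the `no_barcode_match` tally is pool-wide; `no_guide_match` is per
  sample.
* The null-calibration and parameter-recovery suites run at reduced scale
  (tens of genes, about a hundred cells per shRNA, 100–200 reads per
  shRNA, ten seeds) — large enough that the binomial and multinomial
  standard errors leave the pass margins wide, and small enough to keep the
  suite fast.

## Known limitations

* Flow event tables are CSV only; no FCS parsing, compensation or spillover
  modelling.
* Per-cell aggregation of image results takes an optional label mask; no
  cell segmentation is performed.
* Exact matching in `count_guides()` undercounts libraries sequenced with
  appreciable error rates; a mismatch-tolerant mode would need a different
  recovery oracle.
* The published hit-list values themselves are not recomputable — the
  screen's raw sequencing data were never deposited — so the printed table
  functions as a worked example for the filtering and ranking rules, and
  all statistical validation runs on simulated data.
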