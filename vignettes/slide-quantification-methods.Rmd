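---
title: "Methods: automated area quantification of whole-slide immunofluorescence"
author: "SliceQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated area quantification of whole-slide immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SliceQuant)
```

## The measurement problem

Organotypic tissue slice cultures — living, ~350 µm sections of patient
tissue kept at a liquid/air interface — preserve tissue architecture and are
increasingly used to test tumor therapies ex vivo. Their histological
readout, however, is usually scored by eye on small fields. SliceQuant
implements an automated, whole-slide alternative: multichannel fluorescence
scans (DAPI for nuclei, Ki67 or TUNEL for the proliferation or apoptosis
marker, plus intrinsic green autofluorescence that outlines the tissue) are
segmented into binary masks, and biology is reported as **area ratios**:

* proliferation (or apoptosis) ratio = marker-positive *and* nuclear pixel
  area / total nuclear pixel area,
* cellular density = nuclear pixel area / total tissue pixel area.

Area ratios, not cell counts: whole-slide scans of dense brain tissue do not
support reliable instance segmentation of single nuclei, and the ratio of
double-positive to nuclear area is robust to touching nuclei. Component
counts are available as a diagnostic only.

## The segmentation procedure

For each image (8- or 16-bit grayscale channels, canonically 0.325 µm/px):

1. **Artifact exclusion.** Hand-drawn binary masks (tissue folds, bubbles,
   dirt, blooming) zero the affected pixels in every channel; the excluded
   area is also removed from every histogram and every denominator.
2. **Spectral unmixing (optional).** Bleedthrough between fluorophores is
   modelled linearly: observed = M · pure, with a user-supplied square mixing
   matrix M whose entry (i, j) is the fraction of fluorophore j detected in
   channel i. Correction multiplies each pixel vector by M⁻¹, clamps
   negatives to zero and re-quantises. The matrix is configuration, never
   estimated from data. Pixels that saturated the detector (or the 8-bit
   range) during mixing are not recoverable; the round-trip guarantee of
   ±1 intensity level holds for unsaturated signal.
3. **Tissue mask.** Tissue is delineated almost entirely by the DAPI and
   autofluorescence signals. The two channels are merged pixelwise (maximum
   by default; sum available) — the merge rule is a design choice, since
   either signal may dominate locally — then smoothed with a Gaussian filter
   of total width 5 px and binarised with **Otsu's method** (between-class
   variance maximisation). "Width 5" is read as the full kernel footprint:
   a 5×5 kernel with σ = 5/3, truncated at ±2.5 px (`smoothWidth`
   configurable). Smoothing precedes binarisation of the merged raster.
4. **Nuclei mask.** Otsu binarisation of the raw DAPI channel.
5. **Marker mask.** **Kapur's maximum-entropy method** on the Ki67/TUNEL
   channel. Kapur's criterion is sometimes loosely described as an entropy
   *minimisation*; the literature-defined objective (Kapur, Sahoo & Wong
   1985) maximises the sum of Shannon entropies of the background and
   foreground class distributions, and that is what is implemented. The full
   criterion curve is kept on the result object so either convention can be
   audited.
6. **Nuclear restriction.** Specific marker staining can only occur within
   nuclei, so the marker and nuclei masks are multiplied (pixelwise AND).
7. **Speck clearing.** Connected components of up to 20 px ("up to"
   inclusive; the 20/21 px boundary is pinned by tests) are removed from the
   nuclear-restricted marker mask to eliminate sub-nuclear fluorescent
   particles. Connectivity is 8 by default (the permissive choice for speck
   detection; 4 available). Clearing of the nuclei mask itself is off by
   default but available (`clearNuclei`), as that step is a judgement call
   rather than part of the canonical chain.

Both thresholders operate on a 256-bin histogram regardless of bit depth —
16-bit rasters are rescaled by their observed maximum — which keeps the
exhaustive 256-candidate optimum exact and fast. Foreground is strictly
`intensity > t` everywhere, and criterion plateaus resolve to the smallest
threshold; both conventions are fixed so results are bit-reproducible.
Degenerate (blank or single-valued) channels yield empty masks plus a logged
warning rather than an error, so batch runs survive empty sections.

Nuclei pixels falling outside the smoothed tissue mask are counted, not
clipped; the three masks are computed independently and the discrepancy is
reported per image (`nuclei_outside_tissue_px`).

## Quantification, aggregation, statistics

`quantifyBundle()` counts mask areas in pixels (µm² derivable via the pixel
size) and computes the two ratios; zero denominators flag the record instead
of erroring. For apoptosis cohorts, section-level ratios are arithmetic-mean
aggregated per originating tissue slice before any group statistics, because
sections from one slice are technical replicates. Groups (tissue ×
condition) are summarised as **median and interquartile range**.

Hypothesis testing is nonparametric throughout: a Shapiro–Wilk screen per
group is reported as advisory context, the omnibus is the **Kruskal–Wallis**
test (mid-ranks, standard tie correction — ratios can tie at 0), and a
significant omnibus (α = 0.05) is followed by all pairwise **Dunn** post-hoc
z-tests. The multiplicity adjustment inside the Dunn procedure defaults to
Bonferroni — the most conservative common pairing — with Holm and Šidák
available; adjusted p-values are never below unadjusted ones.

Manual verification mirrors the automatic path: independent observers'
masks are pushed through the *same* counting code (`observerBundle()` +
`quantifyBundle()`), per-observer areas are averaged per image, and manual
vs automatic values are compared by **Spearman's rank correlation**. The
squared Pearson coefficient is reported alongside ρ because R² is the
customary reporting scale for this comparison; neither replaces the other.

## The synthetic slide generator

Real whole-slide scans of the original tissue are not redistributable, so
every stage is validated against simulated slides with exact ground truth.
`generateSlide()` draws, per image:

* a tissue region (union of three random ellipses, roughly half the frame);
* `nNuclei` non-overlapping elliptical nuclei (default 200 at 512×512),
  placed around cluster centres with a uniform component so packing cannot
  stall, with ≥1 px clearance so every nucleus is one component;
* exactly `floor(p · nNuclei)` marker-positive nuclei;
* blooming halos (2 px wide at 35% intensity) around nuclei in both stained
  channels — the acquisition artifact that inflates manual DAPI scoring;
* fluorescent specks of 1–12 px in the marker channel, inside and outside
  nuclei, kept ≥1 px apart so the ≤20 px clearing rule is exercised;
* optional linear bleedthrough via a mixing matrix;
* additive Gaussian noise, default SD 25.5 = 10% of the 8-bit range,
  clipped to [0, 255].

Ground truth (masks, label matrix, centres, areas) is recorded **pre-noise
and pre-mixing**, so segmentation accuracy is measurable against an
uncorrupted reference. Intensity levels (background 8, autofluorescence 110,
nuclei 190, marker 200) were fixed once at values where each scene component
is separable by the method the scene exercises — in real slides the green
autofluorescence visibly delineates tissue against the dark glass
background, so the simulated level sits clearly above background. Default
nucleus radii of 5–9 px correspond to 6–12 µm nuclear diameters at
0.325 µm/px.

What the generator does **not** emulate: point-spread blur, shot-noise
physics, intensity gradients across the slide, out-of-focus tiles, and
texture within nuclei. Passing tests therefore demonstrate the correctness
and calibration of the algorithms under controlled corruption, not
performance on any particular scanner's output.

## Verified properties and the scales used

The test suite fixes these properties (scales chosen to keep the default
run on one CPU in the tens of minutes):

* both thresholders return the exact exhaustive-search argmax on 1,000
  random histograms, with smallest-t tie-break;
* mask algebra (restriction subsets, exact ≤20 px clearing against an
  independent flood-fill labeller, idempotence) on 100 random bundles;
* programmed positive fractions p ∈ {0.1, 0.3, 0.5} recovered within
  ±0.05 (mean over 20 seeds) at 512×512 / 200 nuclei / noise SD 25.5.
  The residual bias is physical, not numerical: noise and blooming dilate
  the nuclei mask slightly more than the double-positive mask, so ratios
  run ~5–8% relatively low — well inside the tolerance;
* unmixing round trip within 1 intensity level on random unsaturated
  scenes; with 0.3 crosstalk, corrected ratios sit within 0.02 of
  bleed-free runs while uncorrected ones drift further;
* Kruskal–Wallis type-I error 0.05 ± 0.02 over 1,000 simulated two-group
  cohorts (20 images/group) pushed through the *full image pipeline* at
  reduced scale (96×96, 14 nuclei — small enough to simulate 40,000 slides,
  large enough for separable nuclei), and > 90% detection of a 0.4 vs 0.1
  positive-fraction effect over 100 seeds;
* the manual-validation path returns ρ = 1 on identical masks and matches
  an independent rank-transform oracle under monotone noise;
* two pipeline runs on the same cohort and seed produce byte-identical
  result tables.

## A small worked example

```{r example, eval = FALSE}
set.seed(1)
sl <- generateSlide(sceneSpec(positiveFraction = 0.3), seed = 7)
bundle <- segmentImage(sl$image)
quantifyBundle(bundle)

# a cohort with a programmed treatment effect
groups <- data.frame(
  tissue = c("tumor", "tumor"), condition = c("untreated", "treated"),
  positive_fraction = c(0.4, 0.15), n_images = c(10L, 10L))
co <- generateCohort(groups, seed = 1, dir = tempfile("cohort"))
res <- runPipeline(co$sheet, tempfile("run"))
res$summary
res$comparisons
```

## Known limitations

* Global thresholds per channel: strong illumination gradients across a
  slide are not handled (no local/adaptive thresholding by design).
* The linear unmixing model cannot recover saturated pixels and does not
  model spatially varying or nonlinear crosstalk.
* Area ratios conflate marker intensity with extent; intensity-weighted
  scores are out of scope.
* The Shapiro–Wilk screen is advisory: the pipeline never switches to a
  parametric branch.
* Proprietary scanner formats, stitching and pyramidal/tiled slide handling
  are out of scope; inputs are flat single-channel PNG/TIFF exports.
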