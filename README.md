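# SliceQuant

Automated quantification of whole-slide immunofluorescence for organotypic
tissue slice cultures.

Slice cultures of patient tumors (e.g. glioblastoma and its peritumoral
brain tissue) are an ex-vivo model for testing therapies, but their
histological readout — how much of the tissue proliferates (Ki67) or dies
(TUNEL) — is usually scored manually on small fields. SliceQuant scores the
**whole slide** automatically and reproducibly. It is aimed at imaging and
histology groups who export flat grayscale channels (DAPI / marker /
autofluorescence) from a slide scanner and want per-image area ratios plus
group statistics without hand thresholding.

## Method

For each image the pipeline builds four binary masks and two ratios:

1. optional **artifact exclusion** (hand-drawn masks; excluded pixels leave
   every histogram and denominator) and **linear spectral unmixing**
   (observed = M · pure; correction by M⁻¹ with non-negativity clamping);
2. **tissue mask** — pixelwise max of DAPI and autofluorescence, smoothed
   with a 5-px Gaussian, binarised by **Otsu's method** (threshold t
   maximising ω₀(t)·ω₁(t)·(μ₀(t) − μ₁(t))²);
3. **nuclei mask** — Otsu on the raw DAPI channel;
4. **marker mask** — **Kapur's maximum-entropy threshold** (t maximising
   H_bg(t) + H_fg(t), the Shannon entropies of the two normalised class
   distributions) on the Ki67/TUNEL channel;
5. **nuclear restriction** — marker × nuclei (specific staining is nuclear),
   then removal of connected components ≤ 20 px (sub-nuclear specks);
6. **quantification** — marker-in-nuclei area / nuclei area (proliferation
   or apoptosis ratio) and nuclei area / tissue area (cell density), with
   per-slice averaging for apoptosis sections, group medians + IQR,
   Kruskal–Wallis omnibus and Dunn post-hoc tests, and Spearman correlation
   of manual-observer vs automatic measurements.

Both thresholders are implemented from scratch on 256-bin histograms and are
tested against exhaustive search; a synthetic slide generator with exact
ground truth (clustered elliptical nuclei, blooming halos, specks,
bleedthrough, Gaussian noise) backs every stage.

## Worked example

```r
library(SliceQuant)

# one synthetic 512x512 slide: 200 nuclei, 30% marker-positive
sl <- generateSlide(sceneSpec(positiveFraction = 0.3), seed = 7)
bundle <- segmentImage(sl$image)
bundle
#> SegmentationBundle 'synthetic': 512 x 512 px
#>   tissue            111442 px  (otsu threshold 78)
#>   nuclei             33401 px  (otsu threshold 100)
#>   marker             13229 px  (kapur threshold 72)
#>   markerInNuclei      9173 px

rec <- quantifyBundle(bundle)
rec$ratio_marker_per_nuclei
#> [1] 0.2746325
rec$ratio_nuclei_per_tissue
#> [1] 0.2997164
```

The recovered proliferation ratio (0.275) sits close to the programmed
positive fraction (0.3); the small deficit is the expected physical bias —
noise and blooming dilate the nuclei mask slightly more than the
double-positive mask. A treated-vs-untreated cohort goes through
`generateCohort()` → `runPipeline()`, which writes `results.csv` (one row
per image: areas in pixels, ratios, flags), `summary.csv` (median/IQR per
tissue × condition group), `comparisons.csv` (Kruskal–Wallis + Dunn),
`thresholds.json`, per-image mask PNGs and a config-hashed manifest.

A batch interface is installed at `exec/slicequant`
(`slicequant simulate | run | stats`).

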