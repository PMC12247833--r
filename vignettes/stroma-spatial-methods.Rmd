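---
title: "Methods: quantifying marker distributions relative to a stromal border"
author: "stromaSpatial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying marker distributions relative to a stromal border}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromaSpatial)
```

## The problem

Stroma-rich tumors such as pancreatic ductal adenocarcinoma embed nests of
cancer cells in a dense, largely acellular connective-tissue compartment.
Where a cell sits relative to that compartment matters: matrix-sensing
signals, drug exposure and proliferative activity all change with distance
from the tumor-stroma interface. Given a multi-channel immunofluorescence
image — a nuclear stain, an epithelial marker such as pan-cytokeratin, a
matrix protein such as fibronectin, and one or more analysis markers —
this package quantifies how a marker's per-cell intensity varies with the
signed Euclidean distance between each cell and the border of the stromal
compartment, and does so reproducibly across image batches whose staining
intensity varies.

The pipeline has six stages, each usable on its own:

1. **Stromal model** (`buildStromalModel()`): Gaussian-smooth the matrix
   channel, threshold it (strict `>`), take the mask's border, and derive
   signed distances (negative inside stroma).
2. **Cells** (`ingestLabels()` / `segmentNucleiBuiltin()`,
   `expandCells()`, `filterByArea()`): nuclei from an external segmenter
   or the built-in blob segmenter, expanded radially by 5 µm into
   non-overlapping whole-cell regions, filtered to the 5th–99th
   percentile of nuclear area.
3. **Features** (`measureCells()`): mean, median, min, max and SD of
   every channel over nucleus, cytoplasm and whole-cell pixel sets, in
   raw grey levels, with QuPath-compatible column names.
4. **Threshold calibration** (`fitBestDistribution()`,
   `propagateThresholds()`): model each image's intensity sample with the
   best-fitting positive continuous distribution and translate an expert
   threshold across images by percentile preservation.
5. **Classification** (`classifyByThreshold()`, `trainRF()`,
   `agreement()`): marker-positive/negative and cancer/non-cancer labels
   by translated thresholds or a seeded random forest; agreement between
   routes as a confusion matrix with percent agreement.
6. **Spatial summaries** (`distanceProfile()`, `profileDifference()`,
   `runSensitivityGrid()`): distance-binned intensity profiles with
   bootstrap SEMs, error-propagated group differences, and a smoothing ×
   threshold sensitivity grid over the Pearson correlation between
   intensity and distance.

`runPipeline()` chains all stages under a single declarative
configuration and writes a checksummed manifest, so a rerun with the same
inputs reproduces identical artifacts.

## The statistical core: percentile-preserving threshold propagation

Fluorescence intensity is only comparable within an image; between images
the same biological state can map to quite different grey levels. An
expert threshold $t_{\mathrm{ref}}$ chosen on a reference image therefore
does not transfer directly. The package's calibration:

1. Fit each image's per-cell intensity sample $x_1,\dots,x_n$ by maximum
   likelihood under each candidate family (log-normal, gamma, Weibull,
   exponential by default).
2. Score each fitted density $f_\theta$ against the normalized intensity
   histogram at bin centers $c_j$ by the least-squares error
   $\sum_j (h_j - f_\theta(c_j))^2$, and keep the family minimizing it.
   Fluorescence histograms are right-skewed with a pronounced left elbow,
   and the log-normal family wins essentially always on such data.
3. Map the expert threshold to its percentile under the *reference*
   image's fit, $p = F_{\mathrm{ref}}(t_{\mathrm{ref}})$, and translate it
   to every other image as that image's fitted quantile,
   $t_i = F_i^{-1}(p)$.

A consistent fraction $1 - p$ of cells is classified positive in every
image, whatever its staining scale. Two properties are worth stating
precisely, and both are enforced by tests:

* **Percentile preservation.** $F_i(t_i) = p$ to within $10^{-9}$ for
  every image.
* **Scale equivariance.** If a target image's intensities are exactly a
  positive multiple $c$ of the reference's, the translated threshold is
  $c\,t_{\mathrm{ref}}$ (the log-normal family is closed under scaling
  and maximum-likelihood estimation is equivariant, so this holds to
  numerical precision, not just approximately).

Parameters are estimated by maximum likelihood rather than by
least-squares against the histogram; the histogram score is used only for
family selection. Histogram-based estimation would make the fitted
parameters depend on an arbitrary bin width, whereas the likelihood does
not; the bin width (Freedman–Diaconis by default) then only influences
which family is selected, a far less sensitive decision. One caveat of
least-squares selection is nesting: gamma and Weibull contain the
exponential at shape 1, so on exponential data the richer family wins on
histogram noise about half the time. Identification trials are therefore
meaningful for non-nested pairs (log-normal vs gamma) only. Values at or
below zero are excluded from fitting (all candidate families have
positive support) with a logged count; classification still applies the
threshold to every cell.

## Geometry: border, signed distance, bins

The stromal mask is `smooth > threshold` with a strict inequality. The
border is the set of mask pixels with at least one non-mask 4-neighbor;
pixels on the image edge are *not* border (an out-of-image neighbor
counts as stroma), so cells near the frame measure their distance to real
tissue borders only. Signed distance to a query point (a nuclear
centroid, in µm) is the exact minimum Euclidean distance to any border
pixel center, negative if and only if the point's containing pixel is
inside the mask. Per-cell distances are computed by an exact vectorized
nearest-border search; the per-pixel distance map uses an exact Euclidean
distance transform, and the two routes agree to within one pixel diagonal
everywhere (exactly, at pixel centers).

Distance bins are half-open intervals $[k w, (k+1)w)$ with $w = 10$ µm by
default — roughly one cell diameter — aligned so that 0 (the border) is
always an edge; $d = 0$ falls in $[0, 10)$, $d = -0.1$ in $[-10, 0)$. The
default profile range is $[-100, 300)$ µm. Per bin, the profile reports
the cell count, the mean of the chosen intensity column, the within-bin
sample SD, and a bootstrap SEM (500 within-bin resamples by default,
seeded). The bin-wise difference between two populations propagates error
as
$$\mathrm{SEM} = \sqrt{\sigma_a^2/n_a + \sigma_b^2/n_b},$$
with $\sigma$ the within-bin sample SDs. A single-cell bin has a
bootstrap SEM of exactly 0 (every resample is the same value), which is a
faithful description of the bootstrap, not a claim of certainty; read
singleton bins with corresponding care.

## Sensitivity analysis

Two parameters shape the stromal model: the smoothing sigma and the
intensity threshold. `runSensitivityGrid()` rebuilds the model over a
grid of both (3 × 3 around the configured operating point by default),
recomputes every cell's signed distance, and summarizes each grid point
by the Pearson correlation between marker intensity and distance,
separately for cells inside ($d < 0$) and outside ($d \ge 0$) the stroma
— border-bin cells count as outside. The correlation is evaluated
directly from its definition over the per-cell values. Inside/outside
correlations from the same image under the same parameters are paired;
their difference is tested with a two-sided Wilcoxon signed-rank test.
Zero differences are dropped, tied absolute differences receive average
ranks, and for up to 25 retained pairs the two-sided p-value is exact:
the null distribution of the positive-rank sum is computed by the
generating-function recursion on doubled ranks, which reproduces full
$2^n$ sign enumeration at a cost linear in $n \sum r$. Above 25 pairs a
normal approximation with tie correction is used. The pairing unit
("grid": every image × parameter combination; "images": per-image medians
across the grid) is an explicit argument, since either convention is
defensible. Mean correlations per side carry bootstrap standard errors
obtained by resampling *images* with replacement; with fewer than three
images the SE is withheld with a warning rather than reported from a
vacuous resample.

## The synthetic-tissue generator

Because real whole-slide images of this kind are not redistributable,
validation rests on `generateTissue()`, which emulates the structure of
multiplexed xenograft fields with complete ground truth: nucleus label
image, centroids, stromal mask, per-cell signed distance, per-cell
noiseless channel means, and binary cancer/marker classes.

The generative model, and why each choice was made:

* **Field geometry.** Default 512 × 512 px at 1 µm/px — a whole-slide
  field downsampled to desk scale. At this size a field spans 512 µm, so
  the default profile range, a 50 µm marker decay length and 5–15 µm
  smoothing kernels all fit inside it with the same scale separation
  (structure ≫ kernel) that full-resolution slides have. Native 20×
  scan resolution (0.3215 µm/px) is available as a parameter, but at 512
  px such a field spans only 165 µm and the largest smoothing kernel
  becomes a third of the field — a regime no real analysis operates in.
* **Stromal compartment.** Low-frequency value noise (a coarse 4 × 4
  uniform grid, bilinearly upscaled and lightly smoothed) thresholded at
  the $(1-\mathrm{fraction})$ quantile, then cleaned of sub-1% specks:
  one to a few large contiguous curvy regions whose areal fraction
  matches the target essentially exactly, resembling desmoplastic ECM
  deposits. A `half_plane` mode exists for analytic distance ground
  truth.
* **Cells.** Disk nuclei with Gaussian DAPI profiles, radius ~N(3, 0.4²)
  µm, rejection-sampled without overlap; candidates inside the stroma
  are thinned to 30% relative density, since desmoplastic stroma is
  mostly acellular matrix and real per-bin cell counts are far lower
  inside it. Cancer (KER-high) cells exist only outside the stromal
  mask; 2% of the outside compartment is non-cancer (KER-low), giving
  the classifiers genuine errors to make.
* **Marker law.** Every cell's noiseless marker mean follows the
  configured distance law — for exponential decay,
  $\mu(d) = \mathrm{baseline} + \mathrm{amplitude}\,
  e^{-\max(d,0)/L}$ — evaluated at its true signed distance. Per-cell
  intensities are drawn log-normally around these means (so pooled
  histograms are right-skewed and the log-normal family wins model
  selection, as on real data), painted over the cell area, and finally
  transformed by an affine batch shift that emulates between-image
  staining variation. The rank order of per-cell intensities is
  invariant under the shift, which is exactly the property percentile
  propagation exploits.
* **Dispersion.** The log-normal shape defaults to 0.1. The rationale
  for this choice is statistical, not biological: at a few hundred cells
  per field, a handful of cells fall in each 10 µm bin, and adjacent-bin
  mean differences of the decay law are resolvable only when per-cell
  draw noise is small relative to the gradient. Whole-slide images
  resolve the same structure through sheer cell numbers. Raising the
  dispersion (0.3 is a realistic biological value) stress-tests the
  classifiers but blurs desk-scale spatial ordering.
* **Determinism.** All randomness flows through one seeded local
  generator; the caller's RNG stream is untouched, and identical specs
  produce bit-identical output.

What the generator does *not* emulate — and hence what passing tests do
not show about real tissue: nuclei are convex disks, not crowded
irregular nuclei, so segmentation accuracy claims do not transfer;
staining artifacts (folds, debris, illumination gradients) are absent;
the marker law is exactly the configured one, so tests demonstrate
*recovery* of a known law, not discovery; and optical spillover is
modeled only as disk overlap between neighboring cells.

## Numerical conventions

* Percentiles interpolate linearly between order statistics throughout
  (area filter, display clipping); values exactly at a percentile are
  kept by the area filter (strict inequalities discard).
* The per-cell SD uses the population formula (divide by $n$) in the
  feature table; within-bin profile SDs use the sample formula
  ($n - 1$), feeding the error-propagation SEM.
* Median of an even-sized pixel set is the mean of the two central order
  statistics.
* Classification is strictly `>`: a value exactly at the threshold is
  negative.
* Cell expansion assigns contested pixels to the nearest nucleus by
  exact squared pixel-center distance (integers, so ties are exact), and
  ties go to the lower label id.
* Coordinates: pixel centers sit on a 0-based integer grid scaled by the
  pixel size, x along columns, y increasing downward; a continuous point
  belongs to the pixel whose center is nearest.
* Degenerate inputs fail loudly: empty masks yield an `Inf` distance map
  and `signedDistance()` refuses to guess; all-equal intensity samples
  refuse to fit; an all-zero-difference Wilcoxon refuses to test.

## Known limitations

Border localization is resolution-limited: the smoothed, thresholded
border can sit a pixel or two away from the "true" interface, so cells
hugging the border may land on either side of 0 and in either adjacent
bin. At whole-slide cell counts this is invisible; at a few hundred
cells a single such cell can visibly perturb a singleton bin of a
profile. Distance is 2D; sections project 3D structure, and a cell
touching stroma above or below its plane measures as distant. Stromal
delineation is intensity-based; texture- or learning-based segmentation
would be less sensitive to staining variability but is out of scope.
Threshold propagation assumes the chosen family fits every image in the
batch; images whose staining failed outright violate that silently, so
inspect per-image `sse` values in the `ThresholdMap` before trusting the
translation.

## Reference operating point

Defaults mirror a standard operating point for decay-type markers:
5 µm expansion, 5th/99th area percentiles, smoothing sigma 15 µm
(10 µm suits sharper nuclear-foci markers), 10 µm bins over
$[-100, 300)$ µm, 500 bootstrap iterations, random forest with 100
trees. Validation workloads in the test suite use 512 × 512 px fields
with ~300 cells (and up to 800 × 800 px with 2,000 cells where a null
correlation needs tight sampling error), which keeps the complete suite
in the low minutes on a single core.
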