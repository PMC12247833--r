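# stromaSpatial

Quantifies the spatial distribution of cell markers relative to a stromal
border in multi-channel immunofluorescence tissue images.

Stroma-rich tumors (pancreatic ductal adenocarcinoma being the archetype)
embed cancer-cell nests in a dense, largely acellular matrix compartment.
Where a cell sits relative to that compartment shapes its matrix-sensing
signaling, drug exposure and proliferation, so a recurring analysis task
is: *model the stromal compartment from a matrix-protein channel, measure
each cell's signed distance to its border, and profile marker expression
against that distance — consistently across image batches whose staining
intensity varies.* This package implements that analysis for
image-analysis practitioners and computational biologists working with
multiplexed IF panels (e.g. DAPI / pan-cytokeratin / fibronectin / one or
more analysis markers).

## What it computes

Given channels and a physical pixel size, the pipeline:

1. models the stroma: mask = Gaussian-smoothed matrix channel `>`
   threshold; its border (mask pixels with a non-mask 4-neighbor; the
   image edge never counts) is the spatial reference;
2. obtains cells: an external nuclei label mask or the built-in blob
   segmenter, radial 5 µm expansion partitioned between neighbors by
   nearest nucleus, 5th–99th nuclear-area percentile filter;
3. measures per-cell compartment statistics (mean/median/min/max/SD per
   channel over nucleus, cytoplasm, whole cell) in raw grey levels with
   QuPath-compatible column names;
4. harmonizes expert thresholds across images by **percentile
   propagation**: each image's intensity sample is fitted by maximum
   likelihood under candidate positive distributions (log-normal, gamma,
   Weibull, exponential), the family with the least squared error
   against the normalized histogram is kept, the expert threshold
   `t_ref` maps to its percentile `p = F_ref(t_ref)` under the reference
   fit, and every image gets `t_i = F_i^{-1}(p)` — so the same top
   fraction of cells is called positive in every image;
5. classifies cells by translated thresholds (strict `>`) and/or a
   seeded random forest on intensity features, with confusion-matrix
   agreement between the routes;
6. computes each cell's signed Euclidean distance to the border
   (negative inside stroma; exact nearest-border-pixel search), bins
   cells in half-open 10 µm intervals aligned on the border, and reports
   per-bin mean intensity with bootstrap SEM, error-propagated group
   differences `SEM = sqrt(sd_a²/n_a + sd_b²/n_b)`, and a smoothing ×
   threshold sensitivity grid over the Pearson correlation between
   intensity and distance, with an exact paired Wilcoxon signed-rank
   test comparing inside vs outside.

A synthetic-tissue generator with complete ground truth (nuclei labels,
stromal mask, per-cell distances, classes, noiseless intensity laws)
backs the test suite and lets every stage be validated without external
data.

## Worked example

```r
library(stromaSpatial)

tis   <- generateTissue(tissueSpec(n_cells = 300, seed = 1))
stack <- tis$stack
stack
#> ChannelStack: 512 x 512 px @ 1 um/px
#>   channels: DAPI, KER, FN, MARKER

ps    <- pixelSize(stack)
nuc   <- segmentNucleiBuiltin(getChannel(stack, "DAPI"), ps)
cells <- expandCells(nuc, 5, ps)
geoms <- filterByArea(cellGeometries(nuc, cells, ps))$kept
tab   <- measureCells(stack, geoms, image_id = "field1")   # 290 cells

fit <- fitBestDistribution(tab[["Cell: MARKER max"]])
fit
#> FittedDistribution: lnorm ( meanlog=4.121, sdlog=0.4871 ) sse = 9.61e-05 n = 290

fn    <- getChannel(stack, "FN")
model <- buildStromalModel(fn, sigma_um = 15, threshold = 65.64,
                           pixel_size_um = ps)
model
#> StromalModel: 512 x 512 px, sigma = 15 um, threshold = 65.6408
#>   stromal fraction: 0.3 | border pixels: 1000

tab$signed_distance_um <- signedDistance(
  model, tab[, c("centroid_x_um", "centroid_y_um")])

mthr <- percentileToThreshold(fit, 0.9)       # top 10% are "positive"
tab  <- classifyByThreshold(tab, mthr, marker = "Cell: MARKER max",
                            label_column = "marker_class")   # 42 positive

prof <- distanceProfile(tab, "Cell: MARKER max",
                        subset = tab$marker_class == "positive",
                        range_um = c(-50, 150), seed = 1,
                        population_label = "marker-positive")
head(as.data.frame(prof), 5)
#>   bin_left bin_right n  mean     sd   sem
#> 1      -50       -40 2 132.7  9.760 4.865
#> 2      -40       -30 3 134.0  6.822 3.163
#> 3      -30       -20 5 132.8 17.522 7.335
#> 4      -20       -10 4 125.9  9.421 4.493
#> 5      -10         0 4 152.4  6.979 2.873

sens <- runSensitivityGrid(stack, tab, c(10, 15, 20), 65.64 * c(0.8, 1, 1.2),
                           "Cell: MARKER max", seed = 1)
sens
#> SensitivityResult: 3 sigmas x 3 thresholds x 1 images
#>   r_inside mean: 0.2762  r_outside mean: -0.8845
#>   paired Wilcoxon (grid): p = 0.003906
```

Reading the output: the generator planted an exponentially decaying
marker (length scale 50 µm) outside a stromal compartment covering 30%
of the field. The fitted stromal mask reproduces that fraction; the
marker column is best fit by a log-normal distribution, as fluorescence
intensities generally are; the translated 90th-percentile threshold
marks 42 of 290 cells positive; and the sensitivity grid shows a
strongly negative intensity–distance correlation outside the stroma
(mean r = −0.88) that is stable across all nine smoothing/threshold
combinations, while inside-stroma correlations are far weaker and of
opposite sign — the decaying gradient exists only on the outside, which
is exactly the planted truth. The Wilcoxon p (0.0039 = 2/2⁹, the exact two-sided
minimum for 9 paired grid points) confirms the inside/outside contrast.

`plotProfile(prof)` draws the Figure-style profile: mean intensity per
bin with a shaded SEM band, a dashed line at the border, and per-bin
cell counts on a secondary axis.

For multi-image batches, `runPipeline()` executes everything
(segmentation → measurement → calibration → classification → stroma →
profile → sensitivity) from one `pipelineConfig()` and writes tables,
masks, the threshold map, profiles and a checksummed run manifest. A
command-line front end ships in `inst/exec/stroma-spatial` with
subcommands `simulate`, `segment`, `measure`, `calibrate`, `classify`,
`stroma`, `profile`, `sensitivity`, `run`.

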