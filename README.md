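# bretr — ratiometric BRET image analysis

`bretr` turns two-channel bioluminescence resonance energy transfer (BRET)
time-lapse recordings into quantitative ratio measurements. BRET imaging
records the light of a luciferase **donor** (D) and of a fluorophore
**acceptor** (A) excited by non-radiative transfer when the two tagged
proteins sit within a few nanometers; the pixel-wise ratio

&nbsp;&nbsp;&nbsp;&nbsp;R(x, y, t) = A(x, y, t) / D(x, y, t)

reports molecular proximity independently of local protein amount. The
catch: wherever D approaches the noise floor, R blows up, so the donor must
be masked frame by frame before dividing — and the donor signal decays with
time while a neuron's soma is orders of magnitude brighter than its thin
neurites and spines, so no single global threshold works across space or
time.

The package implements the full pipeline for people doing live-cell
ratiometric imaging (BRET, and by extension similar two-channel ratio
assays):

1. **clean** — 3×3 median filter; per-frame median background subtraction;
   translation-only subpixel registration (estimated on D, applied to both
   channels);
2. **threshold** — per-frame donor masks: `constant`, `median_roi`, `otsu`,
   `phansalkar`, or the **composite** method
   `[Li(D − G(D, σ_low)) AND Li(D − G(D, σ_high))] OR Otsu(D)`
   built for specimens with heterogeneous subcellular volumes;
3. **divide** — masked pixel-wise A/D, 0 reserved as the background
   sentinel;
4. **render** — bounded 16-color cold-to-hot pseudocolor scale with a
   nearest-rank 5th–995th permille range suggestion, optional donor-weighted
   brightness;
5. **measure** — per-ROI, per-frame mean and sample SD of the nonzero ratio
   pixels (zero pixels are excluded automatically, so ROIs need not trace
   the specimen outline).

A deterministic neuron-like phantom generator with full ground truth
(`default_neuron_phantom()`) backs the test suite; no external data are
needed. The package reads/writes uncompressed multi-page TIFF with its own
minimal codec, JSON region sidecars, and CSV measurement tables. See the
vignette (`vignettes/ratiometric-pipeline.Rmd`) for the model, parameter
meanings and design decisions.

## Worked example

```r
library(bretr)

ph <- default_neuron_phantom(seed = 1)   # donor, acceptor, regions, truth
ph$donor
#> ImageStack: 10 frame(s) of 256 x 256 (y, x), dtype_in = uint16
#>   value range [76, 1116]

res <- run_pipeline(pipeline_config(ph$donor, ph$acceptor, ph$regions,
                                    out_dir = "bret_out"))
cat(sprintf("display range: [%.3f, %.3f]\n", res$range$low, res$range$high))
#> display range: [0.343, 0.679]

head(res$measurements[res$measurements$roi_name == "soma", ], 4)
#>   roi_name frame_index mean_ratio    sd_ratio n_pixels
#> 1     soma           1  0.4999659 0.002249797      400
#> 2     soma           2  0.5001131 0.002460822      400
#> 3     soma           3  0.5008008 0.002268722      400
#> 4     soma           4  0.4993137 0.002659605      400
```

The soma's true ratio in the phantom is 0.50: the pipeline recovers it
within 0.2% in every frame even though the donor decays threefold across
the series and the field drifts — the per-frame composite threshold and the
registration absorb both. The small spine ROIs (true ratio 0.65) are noisier
because only a handful of pixels survive masking:

```r
subset(res$measurements, frame_index == 1 & grepl("spine", roi_name))
#>    roi_name frame_index mean_ratio   sd_ratio n_pixels
#> 21  spine_1           1  0.6802853 0.05405277        3
#> 31  spine_2           1  0.6364469 0.02729218        7
#> 41  spine_3           1  0.6061404 0.03016192        6
#> 51  spine_4           1  0.6512105 0.10187549        9
#> 61  spine_5           1  0.6434197 0.03371188        6

round(res$manifest$log$alignment$shifts[8:10, ], 2)  # true drift: (0.3,-0.2)/frame
#>        dx    dy
#> [1,] 2.09 -1.40
#> [2,] 2.39 -1.60
#> [3,] 2.71 -1.81
```

`bret_out/` now contains `donor_clean.tif`, `acceptor_clean.tif`,
`mask.tif` (8-bit 0/255), `ratio.tif` (32-bit float),
`render_pseudocolor.tif` (8-bit RGB), `measures.csv` and `manifest.json`
(config, version and per-stage log — background medians, shifts, thresholds
— sufficient to re-run bit-identically).

## Command line

Every stage is also a subcommand of the bundled CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "bretr.R", package = "bretr"))')
Rscript $CLI simulate --preset neuron --seed 1 --out-dir phantom/
Rscript $CLI run --donor phantom/D.tif --acceptor phantom/A.tif \
                 --regions phantom/regions.json --out-dir out/
# or stage by stage: clean, threshold, divide, measure, compare-thresholds
```

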