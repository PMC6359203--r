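# phytocloud

Non-destructive plant monitoring from colored 3D point clouds.

Close-range structure-from-motion (SfM) photogrammetry turns a few dozen
handheld photos of a potted plant into a dense colored point cloud. From
that single data product, phytocloud estimates three per-point fields and
tracks them through time:

* **Chlorophyll content**, from the normalized Red value
  `r_n = R / (R + G + B)` of each point's color. Chlorophyll absorbs red
  light, so `r_n` rises as chlorophyll falls; a linear calibration
  `chl = a·r_n + b`, fitted against wet-chemistry measurements of punched
  leaf discs (Porra-equation spectrophotometry), maps color to areal
  chlorophyll in µg/mm² across the whole cloud.
* **Leaf inclination (zenith) angle** — the angle between the local
  surface normal and the vertical — and the **azimuthal angle** of that
  normal, estimated per point by orthogonal least-squares plane fitting
  over the points inside a 0.5 cm cube centered on each target point.
* **Day-by-day aggregates**: per-leaf histograms, per-region time series
  (leaf centroid, left edge, right edge) and between-day Kruskal–Wallis
  tests, the combination that makes developing water stress visible as
  falling chlorophyll, steepening blades and twisting azimuths.

Metric scale and the gravity-aligned frame come from a reference box of
known dimensions (default 13 cm × 12 cm × 9 cm) photographed next to the
plant. A synthetic-canopy generator with analytic ground truth (leaf
patches of known orientation, chlorophyll fields inverted into 8-bit
color, multi-day stress trajectories) backs the entire validation suite —
no downloads needed.

The package is aimed at plant-phenotyping researchers who already have
SfM reconstructions (PLY with per-vertex RGB) and want calibrated,
per-point physiology and structure instead of whole-plant indices.

## Worked example

Simulate a five-day water-stress series (one leaf, day-1/3/5 target
means: chlorophyll 12.9/11.7/7.0, zenith 23.7/33.1/33.9°, azimuth
88.6/119.3/156.9°), then run the full pipeline on the generated files:

```r
library(phytocloud)

simulate_to_dir("sim", seed = 42)          # day1..5.ply, samples, labels
res <- run_pipeline(pipeline_config(),
                    sprintf("sim/day%d.ply", 1:5),
                    "sim/calibration_samples.csv",
                    labels_path = "sim/labels.json",
                    out_dir = "sim/out")
#> calibrate: slope=-42.74 intercept=20.36 R2=0.787 cv_mae=1.09 (n=30)
#> angles: day 1, 2513 points
#> ...
#> done in 5.8 s

subset(res$series, quantity == "chlorophyll" & region == "centroid")
#>  day leaf   region    quantity      mean         sd   n
#>    1    1 centroid chlorophyll 12.752518 0.07128482  80
#>    2    1 centroid chlorophyll 12.134903 0.06781756  68
#>    3    1 centroid chlorophyll 11.472387 0.07812263  83
#>    4    1 centroid chlorophyll  9.000967 0.07100149  63
#>    5    1 centroid chlorophyll  6.474455 0.07292329 103

res$tests
#>     quantity day_a day_b statistic df p_value  method
#>  chlorophyll     1     5  3768.753  1       0 kruskal
#>       zenith     1     5  3768.750  1       0 kruskal
#>      azimuth     1     5  3768.750  1       0 kruskal
```

The fitted calibration (R² 0.787 from 30 noisy samples of a slope −40
line) recovers the generating curve; the centroid-region chlorophyll
means fall from ≈12.8 to ≈6.5 as programmed; and day 1 vs day 5 separates
decisively for all three quantities (P < 0.05). `sim/out/` holds the
annotated per-day PLYs, `curve.json`, `series.csv`, `histograms.csv`,
`tests.csv` and a `manifest.json` that fully determines the run.

The same workflow is scriptable from a shell via the thin CLI:

```sh
Rscript inst/cli/phytocloud.R simulate --scenario water-stress --seed 42 --outdir sim
Rscript inst/cli/phytocloud.R run --clouds sim/day1.ply,...,sim/day5.ply \
    --samples sim/calibration_samples.csv --labels sim/labels.json \
    --outdir sim/out
```

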