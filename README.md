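# bspim

Label-free detection of living nematodes in transparent soil by **biospeckle
light-sheet imaging** — simulated end to end, analysed with the
generalized-differences activity index, and counted automatically in 3D.

## The problem

Free-living nematodes (FLN) are microscopic soil worms, 40 µm–1.5 mm long,
nearly transparent, effectively unstainable, and highly mobile. Some species
damage crops by feeding on roots and vectoring viruses; most are beneficial.
Screening their activity in soil-like conditions needs a fast, label-free way
to find live animals in several millilitres of substrate. Biospeckle
selective plane illumination microscopy (BSPIM) does this with physics
instead of stains: under a coherent light sheet, every optical section
produces a laser speckle pattern; static material freezes it, while a moving
animal decorrelates it frame to frame. Scanning the sheet through the sample
and integrating the temporal variation of each pixel yields a 3D activity
volume in which live nematodes light up — and heat-killed ones do not.

`bspim` is aimed at people developing or validating such detection
pipelines: it bundles a seeded, physics-based simulator of BSPIM
acquisitions (temporally decorrelating complex speckle fields, static
granular clutter, saturated roots, read noise) together with the analysis
chain used on the real instrument.

## The method

For each stage position, 64 frames are recorded at 10 fps and collapsed to a
**generalized differences** (GD) activity image,

```
GD = sum_i sum_j | I_(i+j) - I_i |
```

the all-pairs sum of absolute intensity differences at each pixel — zero for
static pixels, large where speckle decorrelates. GD images from successive
positions (1 mm sheet, 125 µm steps, so each animal spans ~8 overlapping
sections) are stacked into a volume and segmented with the published
pipeline: global 8-bit conversion, 2 mm boxcar background subtraction, 80 µm
3D Gaussian smoothing, then 3D connected-component counting above brightness
threshold 40 with a 50-voxel size filter. Image contrast is quantified by
the transect signal-to-noise ratio `SN = (I_s - <I>) / sd` along a line
profile through the object.

## Worked example

```r
library(bspim)

# a 2 x 2 mm, 3 mm deep synthetic microcosm with three live nematodes
scene <- make_scene(n_nematodes = 3, grid_shape = c(128, 128, 24), seed = 7)
acq   <- acquisition_config(n_positions = 24)
scan  <- simulate_scan(scene, acq)
det   <- detect_nematodes(scan)
tidy(det)
#> # A tibble: 3 × 6
#>   label  x_um  y_um  z_um voxels peak_activity
#>   <int> <dbl> <dbl> <dbl>  <int>         <dbl>
#> 1     1  757. 1678.  620.   1494          72.2
#> 2     2 1399.  521. 1323.   2820          74.0
#> 3     3 1536. 1688. 1621.   2227          73.2
```

All three animals are recovered as single 3D objects (their ~8 overlapping
sheet sections merge under 26-connectivity), with centroids in micrometres
and smoothed peak activity well above the detection threshold of 40.

A miniature count-recovery sweep and its regression:

```r
tab <- run_recovery_experiment(counts = c(0, 3, 6, 9), replicates = 2,
                               seed = 11,
                               acq = acquisition_config(n_positions = 32),
                               scene_args = list(grid_shape = c(192, 192, 32)))
summarize_recovery(tab)
#> <recovery fit> R^2 = 1.0000, slope = 1.000, intercept = -0.000
#>   Spearman rho = 1.000 (p = 0.0833), n = 4 (mean)
autoplot(tab)   # detected vs inserted, mean ± SD, fitted line
```

Every simulated animal was counted exactly once, so the regression of
detected on inserted counts is the identity. A brightfield-versus-GD
contrast comparison on single-animal scenes under static clutter:

```r
sn <- run_sn_experiment(n_scenes = 6, seed = 3, image_px = 512)
sn_fold_change(sn)
#> <S/N fold change> n = 4 (2 excluded): mean 17.8 (SE 5.4), max 31.4
```

Two scenes had non-positive brightfield SN (the animal is essentially
invisible in brightfield there) and are excluded; among the rest, GD
imaging improved the transect S/N up to ~31-fold in this small batch —
larger batches with stronger clutter reach far higher maxima.

A command-line wrapper with `simulate`, `gd`, `detect`, `recover` and `sn`
subcommands lives at `inst/cli/bspim`:

```sh
Rscript inst/cli/bspim detect --scan scandir --out results
```

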