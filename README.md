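# lungcontour

Training-data engineering for robust lung parenchyma segmentation on 2D
coronal MR-like images, built around three ingredients:

* **Balanced augmentation** — slices are grouped into four
  sequence/position categories (`FLASH`, `AP_FLASH`, `bSSFP`,
  `AP_bSSFP`; anterior/posterior means ≥ 17 mm from the central slice)
  and each category *c* is replicated by an integer factor
  `round(target / count_c)`, so all categories contribute near-equal
  image numbers to training.
* **Artificially-generated consolidations** — a model-based synthesis
  of solid parenchymal lesions: a randomly grown region inside one lung
  is filled with Uniform(min, max) noise spanning that lung's intensity
  range, a 10×10 median filter is applied to the whole image, the
  filtered result is composited back inside the lung only, and a 5×5
  Gaussian blur blends the region border. Ground-truth labels are left
  untouched, teaching the network to keep consolidations *inside* the
  lung.
* **Contour-class ground truth** — the network predicts the closed
  6-pixel lung contour (mask minus the mask eroded six times with the
  3×3 box) rather than the filled mask; postprocessing thresholds the
  probability map, closes gaps, flood-fills from the image border and
  keeps the two largest components.

Segmentations are scored with the Sørensen-Dice coefficient
`SDC(X,Y) = 2|X∩Y| / (|X|+|Y|)` and the symmetric boundary Hausdorff
distance `HD(A,B) = max{ sup_a inf_b d(a,b), sup_b inf_a d(a,b) }`
in mm; training strategies are compared with Welch's t-test
`t = (x̄−ȳ)/√(s₁²/n₁+s₂²/n₂)` at a Bonferroni-corrected level
(0.05 over 3 comparisons → 0.016).

Because clinical MR data cannot ship with the method, the package
includes a phantom generator producing coronal lung-MR-like slices
(two dark lung fields in a brighter thorax, slice-position-dependent
lung size, FLASH/bSSFP contrast profiles) with exact ground-truth
masks, plus a compact, dependency-free U-Net backend (RcppArmadillo),
so the full pipeline — phantoms → labels → consolidations → balancing →
training → postprocessing → statistics — runs and is tested end to end
on one CPU. See `vignettes/lung-contour-methods.Rmd` for the design
rationale of every stage.

## Worked example

```r
library(lungcontour)

# a phantom slice with ground truth, its contour label, a consolidation
ph  <- generate_phantom(phantom_spec(seed = 1))
lab <- make_contour_label(ph$mask)
reg <- sample_region(ph$mask, consolidation_params(), seed = 2)
img <- insert_consolidation(ph$image, ph$mask, reg, seed = 3)

ph$image
#> <Image2D 64 x 64, spacing 7.81 x 7.81 mm, range [0.000, 0.633]>
lab
#> <ContourLabel 64 x 64, width 6 px, 750 foreground px>
sum(reg)                       # consolidation area in pixels
#> 102

# balanced augmentation arithmetic for a four-category training table
plan <- compute_balancing_factors(
  c(FLASH = 1371, AP_FLASH = 21, bSSFP = 256, AP_bSSFP = 18),
  target = 4330)
plan
#>  category count factor resulting percent
#>     FLASH  1371      3      4113   24.0%
#>  AP_FLASH    21    206      4326   25.3%
#>     bSSFP   256     17      4352   25.4%
#>  AP_bSSFP    18    241      4338   25.3%
#> Total: 1666 images before, 17129 after augmentation

# the corrected level for the three pairwise arm comparisons
bonferroni(0.05, 3)
#> [1] 0.016
#> attr(,"exact")
#> [1] 0.01666667
```

A small two-arm experiment (balanced augmentation with and without
consolidations, shared test cohorts) runs in a few minutes:

```r
cfg <- experiment_config(
  n_train = 40, n_test_nocons = 8, n_test_cons = 6,
  arms = c("Bal_NoCons", "Bal_Cons"),
  train = unet_config(input_size = 64, depth = 3, base_channels = 8,
                      batch_size = 16, max_epochs = 8,
                      early_stop_patience = 4),
  seed = 11)
res <- run_experiment(cfg)
res$report$summary[, c("cohort", "arm", "sdc_mean_pct", "hd_mean_mm")]
```

At the package's default desk scale (200 training phantoms, 15-epoch
training) the same two-arm contrast gives, for master seed 1:

```
        cohort        arm  n sdc_mean_pct hd_mean_mm
1 without_cons Bal_NoCons 30         99.1        7.8
2 without_cons   Bal_Cons 30         95.9       15.1
3    with_cons Bal_NoCons 10         94.5       24.0
4    with_cons   Bal_Cons 10         98.6        7.8
```

— on the consolidation cohort, the consolidation-trained arm keeps the
lesions inside the segmentation (mean SDC 98.6% vs 94.5%), the
direction of effect the training strategy is designed to produce.

There is also a command-line wrapper over the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "lungcontour.R", package = "lungcontour"))') \
  plan-augmentation --counts 1371,21,256,18 --target 4330
```

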