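# breastskin

Automated removal of the surface skin from breast DCE-MRI slice stacks,
so that vessels, mammary glands and tumors become visible in 3-D maximum
intensity projections (MIPs).

## The problem and who this is for

Dynamic contrast-enhanced breast MRI renders the skin as a thin bright
band that dominates the MIP and hides the anatomy beneath it.
Radiologists remove it by hand, slice by slice — hours per case — and
naive automation fails in characteristic ways: the skin's position and
thickness vary across slices; small vessels and glands adhere to the
skin's inner surface at nearly the skin's intensity, so intensity-based
methods delete them along with the skin; and bright chest-wall organs
break global thresholds.

The package is aimed at medical-image-analysis researchers who want a
complete, testable reference implementation of a skin-removal pipeline
(and its evaluation protocol) that runs without clinical data: a
synthetic phantom generator with exact ground-truth labels stands in for
patient images.

## Method in brief

1. **Pre-processing** — exact median filter, Otsu binarization,
   morphological opening/closing with a Euclidean disk; the skin's upper
   boundary is the per-column first foreground row. Chest-wall organs
   are cut away below the parabola `y = -c (x - x_h)^2 + y_h`, with
   vertex at the organ mass's highest point `B` and curvature fixed by
   its lowest left point `A`.
2. **Active contour (snake)** — an open curve with fixed endpoints
   minimizes `∫ ½(α|v′|² + β|v″|²) + E_ext(v) ds`, where
   `E_ext = w_line·I − w_edge·|∇I|² + w_term·E_term` and `E_term` is the
   level-line curvature of a smoothed copy of the image. The
   semi-implicit (pentadiagonal) update runs under a monotone step
   control, so the energy trace never increases. The converged contour
   bounds the *rough* skin band — which deliberately over-segments
   adherent vessels, as intensity-based contours do.
3. **Skin-thickness continuity** — thickness is measured from each
   boundary point along the inward normal through the rough mask.
   Genuine skin thickens and thins gradually, so samples exceeding
   `k` times the running median (a discontinuous jump = an adherent
   vessel or gland) are replaced by the median. The corrected band is
   swept back along the normals, removed from the image, and the stack
   is rendered by MIP.
4. **Evaluation** — Dice volume overlap against ground truth, GLCM
   texture features (ASM, entropy, contrast, correlation) of the tumor
   region with and without skin, and paired t-tests across cases.

The methods vignette (`vignettes/breastskin-methods.Rmd`) derives the
models, documents every tunable parameter with its default and
rationale, and states what the phantom does and does not emulate.

## Worked example

```r
library(breastskin)

spec <- phantom_spec(n_slices = 8, seed = 42)   # 256x256, skin 3-9 px,
ph   <- generate_case(spec)                     # 3 adherent vessels, tumor
ph$case
#> <case_stack> 'phantom-seed42': 8 slices of 256 x 256 px

seg <- segment_case(ph$case)                    # full pipeline
gt  <- simplify2array(lapply(ph$labels, function(l) l == 1L))

dice(simplify2array(seg$skin_masks), gt)        # corrected skin mask
#> [1] 0.962
rough <- simplify2array(lapply(seg$results, `[[`, "rough_mask"))
dice(rough, gt)                                 # snake alone
#> [1] 0.932
```

The corrected mask (Dice 0.962) beats the rough active-contour band
(0.932) because the continuity correction returns the adherent vessels
to the image instead of removing them with the skin. `seg$mip` holds
the skin-removed projection; `segment_case(..., output_dir = "out/")`
additionally writes PNG slices, masks, the MIP and a JSON run log.

The benchmark study reports the same quantities over many seeded cases:

```r
phantom_study(n_cases = 3, seed = 7)
#>    seed n_slices n_vessels dice_full dice_acm vessel_retention
#> 1 22629       11         2     0.959    0.929            0.963
#> 2 30548       10         2     0.960    0.934            0.936
#> 3 38467        9         5     0.934    0.868            0.900
```

Per row: the case seed and size, 3-D Dice of the final and ACM-only
masks against ground truth, and the fraction of vessel pixels the
pipeline preserved.

A command-line driver for shell use ships in
`inst/scripts/breastskin.R` (subcommands `phantom`, `segment`, `mip`,
`evaluate`):

```sh
script=$(Rscript -e 'cat(system.file("scripts/breastskin.R", package="breastskin"))')
Rscript "$script" phantom --out case0 --slices 16 --seed 0
Rscript "$script" segment --in case0/slices --out case0_out
```

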