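# hyperskin

Automatic reflectance calibration and spectral segmentation of line-scan
(push-broom) hyperspectral skin images, for quantitative dermatological
image analysis.

A push-broom VNIR camera records, per acquisition, a cube *L(m, n, k)* of
up to 899 × 1312 pixels × ~800 bands over 397–1030 nm. Raw counts mix the
tissue signal with the lamp spectrum, per-column sensitivity and lighting
falloff, and clinical use needs operator-independent delineation of tissue
classes. `hyperskin` implements the full processing chain:

1. **ENVI I/O** — header + binary payload (BIL/BSQ/BIP, 16-bit raw or
   32-bit float), with single-band and single-pixel-spectrum views.
2. **Median pre-filtering** — per-band 3 × 3 median, sized for impulse
   clusters of at most 2 pixels.
3. **White-stripe calibration** — a diffuse white stripe imaged at the top
   of every frame is found automatically (per-column row-gradient
   binarized at an Otsu threshold, lower boundary within 80 ± 5 rows);
   each pixel is divided by the per-column, per-band stripe mean
   *L_w(n, k)* and clipped, giving reflectance *L_K ∈ [0, 1]*:

       L_K(m, n, k) = min(1, L_M(m, n, k) / L_w(n, k))

4. **Sequence normalization** — the cube is divided by its ROI band-mean
   curve and rescaled to a fixed mid-scale level, so acquisitions
   differing by a global gain normalize identically.
5. **Distance segmentation** — per-pixel mean absolute spectral deviation
   from a class reference spectrum *L_zw(k)* (ROI mean or literature
   table),

       L_D(m, n) = (1/K) Σ_k |L_O(m, n, k) − L_zw(k)|,

   binarized at a tolerance *p_w* selected manually, by Otsu, or
   automatically as the midpoint of the longest plateau of the
   area-versus-threshold curve *A(p_w)*; multi-class labels by nearest
   admissible reference.
6. **Conditional morphology** — erosion/dilation with a 13-pixel 5 × 5
   disk applied only where the local mean of the deviation map satisfies
   `s_re·(1 − p_we) > p_mn` (erosion) or `s_rd·(1 + p_wd) > p_mn`
   (dilation), iterated five times per class; refined label maps contain
   zero unclassified pixels.
7. **Error accounting** — per-class surface-area error
   `δ_w = 100·|A − A_Z|/A_Z` against expert masks, report tables and
   series summaries.
8. **Synthetic phantom** — a seeded generator of study-geometry cubes
   (stripe, lighting falloff, skin/tattoo/background spectra, impulse
   noise) with exact ground truth, used for end-to-end validation.

## Worked example

The desk-scale phantom mirrors the study geometry at one-fifth linear
scale (180 × 260 × 64, stripe 16 ± 2 rows, 20 % lighting tilt, σ = 0.01
noise):

```r
library(hyperskin)
spec <- default_study_phantom(seed = 1)
res <- run_pipeline(list(phantom = spec, roi = "phantom",
                         references = "phantom"))
writeLines(res$log)
#> input: phantom 180 x 260 x 64, seed 1
#> median filter: 3 x 3, edges reflect
#> stripe contour: rows 14..17, p_r = 0.1661, 0 column(s) filled in
#> ROI: 59 x 59 at (43, 42)
#> normalization: target 0.50, ROI grand mean 0.6448
#> references: pattern, background, skin, tattoo
#> threshold: policy flat_region on 'skin' -> p_w = 0.1050
#> morphology: p_we = 0.50, p_wd = 0.50, p_mn = 0.1050, 5 iteration(s), sequential order
#> max per-class delta_w vs truth: 0.2%

class_report(res$labels, res$truth)
#>          class algorithm_px expert_px algorithm_pct expert_pct delta_w_pct
#> 1      pattern         4145      4148           8.9        8.9         0.1
#> 2   background        19418     19411          41.5       41.5         0.0
#> 3         skin        21191     21191          45.3       45.3         0.0
#> 4       tattoo         2046      2050           4.4        4.4         0.2
#> 5 unclassified            0         0           0.0        0.0          NA
```

Reading the log: the jittered stripe edge was found between rows 14 and
17, the flat-region policy picked the deviation tolerance `p_w = 0.105`
from the plateau of the area curve, and after conditional refinement every
class is within 0.2 % of the ground-truth area. Before refinement the
tattoo's partial-volume boundary ring (178 pixels) is unclassified —
`label_counts(res$labels_raw)` shows the raw tattoo count at 1868 of 2050
(an 8.9 % deficit) — and the refinement recovers it.

A thin CLI over the same functions is installed with the package
(`inst/cli/hyperskin.R`) with subcommands `phantom`, `segment` (YAML
config) and `report`.

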