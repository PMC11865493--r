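# mitorestore

Restoration of mitochondrial cristae in low-resolution fluorescence
microscopy images, for microscopists and image analysts who have (or can
synthesize) paired high/low-resolution data. Cristae — inner-membrane
folds 30–50 nm wide — are resolved by STED nanoscopy (~25 nm/px) but not
by fast, gentle live imaging; `mitorestore` trains a residual U-Net to
restore them and ships every stage of that workflow as composable R
functions: paired-data synthesis, mitochondria-focused patch sampling,
the region-prioritized training loss, training and inference, masked
evaluation metrics, FWHM resolution measurement, and a synthetic phantom
generator so the entire pipeline runs and tests without external data.

## The method in brief

Training minimizes a structural-dissimilarity loss that prioritizes
mitochondria:

    L(y, ŷ) = (1/N²) Σᵢⱼ ((1 − SSIMᵐᵃᵖ(i,j)) / 2)^γᵢⱼ ,   γᵢⱼ = 1 on
    mitochondria pixels, 4 elsewhere

Since the per-pixel dissimilarity lies in [0, 1], the exponent 4 shrinks
background terms, concentrating learning on mitochondria. Training pairs
are built by degrading HR images (Gaussian blur σ_blur = 3.25 px, then
Poisson–Gaussian noise with σ_noise = 4.0) and sampling 128 × 128
patches centered on mitochondria found by Anscombe transform → robust
MAD noise estimate → Z-score threshold (start 30, step 5, ≥ 10 % of
pixels) → median cleanup, with ROI centers ≥ 60 px apart and ≥ 64 px
from the borders. Evaluation restricts NRMSE/PSNR/SSIM to mitochondria
or cristae masks, and cristae widths are measured as Gaussian-fit FWHM
(2√(2 ln 2)·σ·pixel size) on line profiles.

## Worked example

```r
library(mitorestore)

# a synthetic STED-like field with exact masks
cfg <- phantom_config(image_size = c(256, 192), n_tubes = 3, seed = 42)
sample <- generate_phantom(cfg)
mean(sample$mito_mask)                     # fraction of mitochondria pixels

# degrade it to a low-resolution input and locate mitochondria
lr <- degrade(sample$hr_image, degradation_params(seed = 7))
mask <- mito_mask_from_image(lr)

# the prioritized loss at its worked 4-pixel value
scop_from_ssim_map(matrix(0, 2, 2), matrix(c(1, 1, 4, 4), 2))

# measure a crista-scale structure width
x <- seq(0, 40, by = 0.25)
profile <- data.frame(position_px = x,
                      intensity = 2 * exp(-(x - 20)^2 / (2 * 2^2)) + 0.5)
fwhm_width(profile, pixel_size = 25)$fwhm_nm

# crista-to-crista intervals along a tube centerline (in nm)
head(peak_to_peak_intervals(centerline_profile(sample), prominence = 0.1))
```

```
[1] 0.3517456      # ~35% of the frame is mitochondrial
[1] 0.28125        # the documented 4-pixel loss value
[1] 117.741        # FWHM of a sigma = 2 px Gaussian at 25 nm/px
[1] 121.875 100.000 103.125 121.875 103.125 121.875   # intervals in nm
```

The mitochondrial coverage is realistic for a STED field, the loss value
matches the hand computation ((0.5 + 0.5 + 0.0625 + 0.0625)/4), the FWHM
equals the closed form 2√(2 ln 2)·2·25 nm, and the peak intervals (mean
109.7 nm over this tube's 94 ridge gaps) recover the spacing this tube was
drawn with (4.44 px = 110.9 nm; per-tube spacings are sampled from
N(5 px, 1 px²)).

Training end to end on phantoms (a few minutes on one core):

```r
study <- phantom_restoration_study(seed = 1, verbose = TRUE)
study$record            # per-epoch train/validation loss
study$psnr_cristae_gain_db
```

A full configurable pipeline (`run_pipeline()`, YAML configs via
`read_run_config()`) and a command-line surface
(`inst/scripts/mitorestore-cli.R`) wrap the same functions.

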