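---
title: "Restoring mitochondrial cristae: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoring mitochondrial cristae: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cristae — the folds of the inner mitochondrial membrane, 30–50 nm wide —
sit below the resolution of routine live fluorescence microscopy. STED
nanoscopy resolves them (at roughly 25 nm/px) but is slow and
phototoxic for long live imaging. `mitorestore` implements a restoration
approach: a convolutional network is trained on pairs of high-resolution
(HR) STED-like images and synthetically degraded low-resolution (LR)
copies, and then applied frame by frame to real LR acquisitions. The
package provides every stage — paired-data synthesis, mitochondria-focused
patch sampling, the region-prioritized training loss, the residual U-Net,
masked evaluation metrics, and a synthetic phantom generator that makes
the whole pipeline testable without any external data.

## The training loss

Pixel losses spread their attention uniformly over the frame, but most of
a fluorescence image is dark background. The training loss here instead
averages per-pixel structural dissimilarity raised to a region-dependent
exponent:

$$L(y, \hat y) = \frac{1}{N^2} \sum_{i,j}
  \left(\frac{1 - \mathrm{SSIM}^{map}_{y,\hat y}(i,j)}{2}\right)^{\gamma_{ij}},$$

with $\gamma_{ij} = 1$ on mitochondria pixels and $4$ elsewhere. The
dissimilarity $D = (1-\mathrm{SSIM})/2$ lies in $[0,1]$, so $D^4 \le D$
pointwise: background terms can only shrink, which concentrates the
gradient signal on mitochondria while still penalizing badly restored
background. The loss is 0 exactly when the SSIM map is 1 everywhere and
never exceeds 1.

The SSIM map uses the standard parameterization — 11×11 Gaussian window
(sd 1.5 px), $C_1 = (0.01R)^2$, $C_2 = (0.03R)^2$ with data range $R = 1$
after normalization — because the loss definition leaves the window
unspecified; all of it is exposed through `scop_params()`. Window
statistics are computed with zero padding, which keeps the windowed
operator self-adjoint so the analytic gradient (`scop_loss_grad()`) is a
plain convolution chain; it agrees with finite differences to ~1e-7.

## Data synthesis and normalization

LR inputs are synthesized from HR images by a Gaussian blur of sd
3.25 px (approximating the PSF) followed by Poisson–Gaussian noise with
Gaussian sd 4.0, chosen for data whose foreground maxima span 56–356
intensity units. The Poisson stage interprets blurred intensities
directly as expected counts (gain 1, no clipping), so flat regions obey
Var ≈ mean + σ²_noise — the same model the Anscombe step later assumes.
Setting `sigma_noise = 0` disables the stochastic stage entirely: the
parameter is the single noise knob, and a zero value means a noise-free,
deterministic degradation.

Every image (training and inference alike) is normalized by
$(I - p_2)/(p_{99.8} - p_2)$ using its own 2nd and 99.8th percentiles.
Values outside $[0,1]$ are kept: clipping would destroy outlier
statistics. The map is affine-invariant and idempotent on its own
output.

Training targets can be sharpened with Richardson–Lucy deconvolution
(`richardson_lucy_enhance()`, Gaussian PSF). The iteration count and PSF
width are not pinned by the method description, so both are exposed with
defaults psf sd 1.5 px and 10 iterations. For the *synthetic phantom
studies in this package the enhancement is disabled* (`rl_psf_sigma = 0`,
the delta-PSF fixed point): deconvolution corrects PSF blur in measured
targets, but a phantom ground truth is exact — deconvolving it
over-sharpens the ridges and moves the target away from the image the
metrics are computed against. A perfect network trained on 10-iteration
RL targets scores *worse* on cristae PSNR against the true phantom than
the degraded input does, which says nothing about restoration and
everything about the target mismatch.

## Patch sampling

Random patch positions would land mostly on background, so sampling is
driven by a mitochondria mask built in four steps on the raw (count
scale) LR image: (1) the Anscombe transform $2\sqrt{3/8 + I}$
approximately converts Poisson–Gaussian noise to unit-variance Gaussian
noise (negative pixels, possible after the additive Gaussian stage, are
clamped to zero first); (2) the noise mean is estimated as the image
median and the noise sd robustly as $1.4826\,\mathrm{median}(|r|)$ over
pseudo-residuals $r = (2I_{i,j} - I_{i+1,j} - I_{i,j+1})/\sqrt 6$;
(3) the Z-score map $(I - \hat\mu)/\hat\sigma$ is thresholded starting at
$c = 30$, decrementing by 5 while the mask holds less than 10 % of the
pixels — if the next decrement would reach zero the loop stops at the
last positive threshold with a warning (the adaptive loop needs a floor
to terminate on pathological inputs); (4) a single-pass 3×3 binary
median filter removes salt noise — the smallest kernel that does so
without eroding thin tubes. The loop controls the fraction *above the
threshold*; the cleanup can only remove pixels, so the cleaned mask may
sit marginally below the minimum on salt-like inputs (both quantities
are returned as mask attributes).

ROI centers are then drawn uniformly at random from mask pixels at least
N/2 = 64 px from every edge (so patches never need padding), rejecting
candidates closer than 60 px to an accepted center, up to the per-image
budget $N_I = \lfloor W/128\rfloor \lfloor L/128 \rfloor$; uniform draws
over mask pixels make mitochondria-rich regions proportionally more
likely. Augmentation quadruples the image pairs by 90°/180°/270°
rotations, and a random 25 % of the augmented set additionally receives a
shrink (0.75 downscale, reflect-padded back — the factor is unspecified
in the method description and config-exposed) followed by horizontal and
vertical flips. The pooled patches are split 80/20 into training and
validation sets at the patch level with no overlap; an image-level split
can be emulated by building the two sets from disjoint image lists.

The per-patch exponent maps $\gamma$ are cut from the image-level mask —
loss weights must depend only on targets, never on predictions — and a
user-supplied segmentation can replace the automatic mask.

## Network and training

The model is a residual U-Net: `depth` (default 3) contracting blocks of
two 3×3 convolutions + ReLU followed by 2×2 max pooling, a bottleneck,
and mirrored expansive blocks of 2×2 nearest-neighbour upsampling,
concatenation with the skip-connected encoder features and two 3×3
convolutions; a final 1×1 convolution maps back to one channel and is
*added to the network input*. The final convolution is zero-initialized,
so an untrained model is exactly the identity — the network learns a
correction, which keeps early training stable. At inference, frames of
any size are reflect-padded to multiples of $2^{depth}$ and cropped back;
stacks are restored plane by plane.

Optimization is Adam on the prioritized loss, seeded and fully
reproducible (identical seeds give identical loss curves); the
best-validation checkpoint is returned with early stopping (patience 10
by default). The original schedule is not part of the method contract,
so epochs, batch size and learning rate are plain configuration. The
convolution kernels run batched as nine shifted GEMMs over a zero-padded
buffer and use single precision internally — on a single core the tap
GEMMs are memory-bandwidth-bound, and halving the element width roughly
doubles throughput; losses, metrics and parameters stay double.

## Evaluation

Whole-frame NRMSE/PSNR/SSIM are dominated by background, so every metric
is also computed restricted to the mitochondria mask and to the cristae
mask. NRMSE is normalized by the *masked dynamic range* of the target
(mean normalization is available behind a flag, since the original
normalization constant is not fully specified); PSNR uses the same
masked range and returns an `Inf` sentinel on perfect matches, which the
aggregator excludes from means with a warning; masked SSIM computes the
local map on the full frame first and then averages over the mask,
preserving window context at mask borders.

Cristae widths are measured by fitting
$a\,e^{-(x-c)^2/2\sigma^2} + b$ to line profiles and reporting
FWHM $= 2\sqrt{2\ln 2}\,\sigma \cdot$ pixel size in nm; profiles without
a measurable peak raise an error so unmeasurable cristae are dropped
explicitly, mirroring how out-of-scale measurements are excluded in
practice. Crista-to-crista intervals are distances between consecutive
intensity peaks with topographic prominence of at least 10 % of the
profile's dynamic range (the prominence criterion is a package choice;
none is stated in the source method). Profiles are sampled bilinearly at
0.25 px steps along user-given segments. For inference on other
modalities, inputs are first resampled so the mean mitochondrial width
matches the training width of 15.64 px (391 nm at 25 nm/px) —
`rescale_to_width()` returns the factor for traceability.

## The phantom generator

`generate_phantom()` draws `n_tubes` smooth centerlines (cubic splines
through 4 uniformly placed control points), dilates each to a width drawn
from N(15.64, 4.04²) px truncated above the crista width, and modulates
the intensity along the tube with transverse raised-cosine ridges of
width 3.5 px at a per-tube spacing drawn from N(5, 1²) px; per-tube peak
intensities are uniform in 56–356 over a background of 5. Rendering is
at 2× supersampling with box downsampling for anti-aliasing. The
mitochondria mask is the exact dilated-centerline support, and the
cristae mask is the set of tube pixels where the ridge modulation
reaches half its maximum — a crisp, testable stand-in for the manual
annotation that real data requires; it is a definition, not a
reproduction of any annotation protocol. Three tubes on a 256×256 frame
give 20–35 % mitochondrial coverage, typical of a STED field.

What the phantoms deliberately do not emulate: PSF anisotropy and
depletion physics, out-of-focus light, motion between frames, intensity
falloff along tubes, and annotation ambiguity. Tests passing on phantoms
therefore validate the pipeline's *mechanics and statistics* (noise
models, sampler contracts, loss behavior, metric definitions), not
biological performance on real STED data.

## The scaled-down study

`phantom_restoration_study()` runs the pipeline end to end at desk scale:
24 training phantoms and 4 held-out phantoms of 256×192 px with 3 tubes
each, degradation at the training conditions (σ_blur 3.25 px,
σ_noise 4.0), ~190 patch pairs after ×4 augmentation (two ROI centers
per frame), and a depth-3, 16-filter network trained for 10 epochs with
Adam at 1e-3 and batch 16 — a short schedule chosen for a ~100-step run,
against the 1e-4 default intended for full-length training. The study
reports the validation-loss trajectory, the cristae-masked PSNR of
restorations against the true phantoms relative to the degraded inputs,
and the same comparison for a background-exponent-1 model trained on the
identical patches (the loss ablation).

One caveat the study itself quantifies: at σ_blur = 3.25 px the ridge
pattern (period ≈ 5 px) is attenuated by a factor
$e^{-2\pi^2\sigma^2/T^2} \approx 4\cdot10^{-4}$ — far below the noise
floor — so the *true* crista phase is unrecoverable from a single frame
and restoration gains at this scale come from denoising, deblurring of
the tube body, and intensity calibration rather than genuine ridge
recovery. Full-scale training on real data learns strong shape priors
that desk-scale phantom runs cannot.

## Numerical choices and degenerate inputs

* Percentiles use R's default (type-7) quantiles; the normalizer rejects
  constant images.
* The pseudo-residual grid is (W−1)×(L−1): forward offsets beyond the
  frame are skipped.
* Gaussian blur uses a radius-⌈4σ⌉ sampled kernel, normalized, with
  reflective padding (avoids dark halos at frame edges in patches).
* Richardson–Lucy guards divisions with 1e-12 and preserves
  non-negativity; a zero-sum image is an error.
* Coordinates are 0-based (row, col) with pixel centers at integers;
  ROI center distances are Euclidean.
* Intensity resampling is Catmull–Rom cubic (smooth at the rescaling
  factors used, no ringing); masks resample nearest-neighbour.
* Float TIFFs outside [0,1] are stored affinely mapped with the mapping
  recorded in a JSON sidecar, because the TIFF writer clamps to [0,1];
  reads invert the mapping.
* All randomness flows from one root seed through named sub-streams
  (phantom, degrade, sample, train, split, augment, predict), so each
  stage is individually reproducible.

## Known limitations

* The trained desk-scale models are demonstrations; real use requires
  full-scale training on real STED pairs.
* The cristae mask definition (ridge modulation ≥ ½ max) is specific to
  the phantom; real data needs manual or external segmentation.
* Only 2D (or plane-by-plane) restoration is implemented; there are no
  3D convolutions.
* The comparison-method zoo (CARE, RCAN, Wiener, ...) and Fourier Ring
  Correlation are out of scope.
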