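---
title: "quickdwi: models, simulation choices, and numerical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quickdwi: models, simulation choices, and numerical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Whole-body diffusion-weighted MRI (WBDWI) trades scan time for
signal-to-noise ratio: the clinical-standard image is an average of many
repeated acquisitions (NOA~N~, "number of acquisitions = N"), which takes
20--30 minutes per study. A fast protocol acquires each b-value image once
(NOA~1~) in a few minutes but is visibly noisy, and the apparent diffusion
coefficient (ADC) maps computed from it inherit that noise. `quickdwi`
implements the full chain needed to study a learned remedy on synthetic
data: a denoising image filter (DNIF) -- a U-Net-style convolutional
regression network -- is trained to map a normalized NOA~1~ image to the
corresponding clinical-standard averaged image, and the package measures
both image quality (MSE, SSIM, PSNR) and downstream ADC fidelity (ROI mean,
coefficient of variation, relative difference of means, mean absolute
voxel-wise difference).

## Signal model and the averaging chain

Each voxel follows monoexponential decay over the diffusion weighting $b$
(s/mm^2^):

$$ S_d(b) = S_0 \exp(-b \cdot \mathrm{ADC}_d), $$

with an optional per-direction ADC 3-vector for anisotropic voxels. The
scanner model acquires each (b, direction) image repeatedly with Rician
noise: the magnitude $\sqrt{(S+n_1)^2 + n_2^2}$, $n_i \sim N(0,\sigma^2)$,
clipped to the integer intensity ceiling (4095 whole-body, 939 lung). Rician
noise is not named by most clinical protocols but is the standard
single-coil magnitude-MRI model and produces the familiar positive noise
floor where $S \approx 0$ (mean $\sigma\sqrt{\pi/2}$, which averaging does
not remove). Values are clipped, not rounded: the $\sigma \to 0$ limit of
the simulator must reproduce the noiseless signal exactly.

The clinical averaging chain is fixed as *directions first, acquisitions
second*: the trace-weighted image is the voxel-wise geometric mean over the
three orthogonal encoding directions (computed as an exact product root;
zero voxels give zero), and the clinical-standard image is the arithmetic
mean of the trace-weighted images over acquisitions. Three directions times
three acquisitions give the NOA~9~ training target. The reverse order is
mathematically different and is deliberately not offered.

## Phantoms: what the generator emulates and what it does not

Phantoms are 2-D sections: a large healthy-tissue ellipse
(ADC 1.2--1.6 x 10^-3^ mm^2^/s), one focal lesion with lower ADC
(0.6--1.0 x 10^-3^ mm^2^/s, the cellular-tumour range) and higher S0
(restricted diffusion lesions are bright at high b), and zero-signal
background (air). Background ADC defaults to 2.0 x 10^-3^ mm^2^/s
(free-water-like) and is configurable. Shapes are rasterized by
center-of-pixel inclusion with no anti-aliasing so ROI masks are exactly
reproducible. The generator emulates the *statistical* structure of DWI
(decay over b, direction averaging, Rician floor, intensity ranges); it does
not emulate anatomy, partial volume, motion, EPI distortion, or coil
profiles. A green training test therefore establishes that the network
denoises this noise model on piecewise-smooth images -- not that it would
match radiologist ratings on patients.

The desk-profile noise level is $\sigma = 300$ (signal units against a
ceiling of 4095). This was calibrated once so that the noisy NOA~1~ input
measures ~25 dB PSNR against the clinical-standard reference, the stated
operating point of the scaled-down training experiment (an a-priori estimate
$\sigma = 4095 \cdot 10^{-25/20} \approx 230$ measured 27.3 dB because
background pixels contribute less error than foreground ones).

## The denoising network

The architecture is a canonical U-Net adapted to regression: per level two
3x3 convolutions (ReLU) then 2x2 max pooling; a two-convolution bottleneck;
per decoder level a learned 2x2 transposed convolution, concatenation with
the encoder skip, and two 3x3 convolutions; and a final *linear* 1x1
convolution to one channel. Weights use He-normal initialization, and the
incoming-weight vector of every hidden filter is constrained to L2 norm
<= 3, re-projected after every optimizer update. Training uses Adam
(learning rate 0.001, batch 36, 15 epochs in the `"paper"` profile) on
images normalized to [0, 1], pooling all b-values and directions into one
dataset -- one network serves every b-value.

Three losses are available: MSE, MAE (the default cost), and the combined
loss $\alpha\,\mathrm{MAE} + (1-\alpha)(1-\mathrm{SSIM})$ with
$\alpha = 0.7$. The SSIM term enters as a dissimilarity because a loss must
decrease as similarity increases; its analytic gradient is implemented and
verified against finite differences in the test-suite. Since no deep
learning framework exists in the supported R stack, the convolution
primitives, backpropagation, Adam, and the constraint are implemented in
this package (C++ im2col convolutions via RcppArmadillo); a full-network
finite-difference gradient check is part of development history and the
training determinism contract (bit-identical loss history under a fixed
seed) is tested.

Exact channel counts are not pinned by the published description; the
defaults are depth 4 with 16 base channels doubling per level. The CPU
`"desk"` profile uses depth 3 with 8 base channels, batch 8, 5 epochs on
64x64 phantoms -- chosen once for single-CPU feasibility (a full desk run,
30 training + 20 validation phantoms, takes under two minutes) and frozen
before the acceptance assertions were written. Inputs whose sides are not
divisible by $2^{\mathrm{depth}-1}$ are reflect-padded symmetrically and
cropped on output.

### Numerical notes

* SSIM uses an 11x11 Gaussian window ($\sigma = 1.5$, $K_1 = 0.01$,
  $K_2 = 0.03$, data range 1), averaged over fully interior windows
  (borders cropped); this matches the scikit-image
  `gaussian_weights=True, use_sample_covariance=False` convention exactly
  (verified to 12 decimal digits during development). For images smaller
  than 11 pixels the window shrinks to the largest odd size that fits.
* Plain fixed-learning-rate Adam on the MAE cost has a step-size floor:
  training loss plateaus near 2.5 x 10^-3^ on toy identity tasks regardless
  of epochs, and descends further only under learning-rate annealing. The
  identity-task unit test therefore asserts the empirically verified bound
  (final MAE < 5 x 10^-3^ and below the initial loss) rather than an
  arbitrary tighter figure.
* The ADC fit is unweighted ordinary least squares of $\ln S$ on $b$;
  "least squares" is the plain reading, and a weighted option exists but is
  off by default. Voxels with any non-positive signal across b-values
  cannot be log-transformed: their ADC is set to 0 and flagged in a
  validity mask. Negative ADCs from noise (signal increasing with b) are
  preserved -- they carry information about the noise distribution.
* ROI statistics use the population standard deviation (divisor $n$) for
  the coefficient of variation, fixed for test stability. RDM is reported
  as an absolute percentage.
* Wilcoxon signed-rank comparisons drop zero differences, use full
  enumeration of sign assignments (exact even under tied ranks) for up to
  15 pairs, the exact signed-rank distribution for up to 25 untied pairs,
  and the normal approximation with continuity correction beyond;
  Benjamini-Hochberg adjustment is applied across all comparisons of one
  invocation.

## Known limitations and an honest red result

In the desk-scale world the denoiser cleanly wins on image quality (PSNR
+4 to +6 dB; lower MSE and higher SSIM on every held-out image) and its ADC
coefficient of variation tracks the clinical protocol far better than the
noisy NOA~1~ maps. One directional claim does **not** reproduce: the ROI
*mean* ADC from noisy NOA~1~ images is already nearly unbiased relative to
the clinical protocol (both share the Rician floor, and random error
averages out over the ROI), so its relative difference of means (~3%) is
*smaller* than that of the denoised maps (~4%), where edge smoothing on
small (5--9 pixel radius) lesions introduces a small systematic bias. The
corresponding acceptance assertion is kept as specified and left failing;
the source study's own lung cohort shows the same direction (noisy RDM 2.0%
vs denoised 3.7--4.0%), so this appears to be a genuine property of
ROI-mean ADC under denoising rather than an implementation defect.

Other non-goals: k-space artifacts, motion, 3-D tensors beyond a diagonal
3-vector, DICOM, GPU training, perceptual/GAN losses, and human-reader
studies.

## Reproducibility

Every stochastic stage derives its seed from the pipeline `global_seed` by
a fixed offset and logs it; identical configuration and seed reproduce the
simulation and quantification artifacts checksum-for-checksum, and training
is bit-deterministic on a fixed platform. Configurations serialize to JSON
(no YAML parser exists in the supported stack); images serialize to
NIfTI-1 via the package's own minimal float32 reader/writer, since no NIfTI
package is available in the supported R stack.
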