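---
title: "MR-based attenuation correction for brain PET: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MR-based attenuation correction for brain PET: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Quantitative PET requires correcting each line of response for the
attenuation of 511 keV annihilation photons. On PET/MR systems no
transmission or CT scan is available, so the attenuation map (a volume of
linear attenuation coefficients, cm^-1) must be derived from MRI.
Conventional MR sequences cannot distinguish bone from air — both are
dark — yet bone is the strongest attenuator in the head. Zero-echo-time
(ZTE) sequences retain signal from short-T2 species, making bone visible
as an intermediate-intensity tissue between air (dark) and soft tissue
(bright), which enables two families of methods implemented here:

1. **Segmentation-based ZTE AC** (`zte_pseudoct()`): normalize the ZTE
   intensity so soft tissue sits at 1, classify air / soft tissue / bone
   by intensity banding, detect interior air pockets (paranasal-sinus and
   mastoid analogues), and assign Hounsfield units with a continuous
   bone-density model,
   \[ \mathrm{HU}_{bone} = 42 + 2400\,(1 - I_{ZTE}), \]
   so that denser bone (darker on ZTE) maps to higher HU. Soft tissue is
   assigned 42 HU, making the model continuous at \(I_{ZTE} = 1\); air is
   -1000 HU.
2. **Learned pseudo-CT regression** (`build_model()`, `train()`,
   `predict_volume()`): a patch-based 3D U-net maps standardized ZTE
   intensity patches directly to CT values, trained with mean squared
   error and Adam on randomly sampled 3D patches; whole volumes are
   predicted by sliding-window tiling with overlapping predictions
   averaged uniformly.

Either pseudo-CT is then converted to 511 keV attenuation coefficients by
a bilinear transform and smoothed (`hu_to_mu()`, `smooth_ac()`), and the
downstream effect on PET quantification is measured by simulating
emission data with the ground-truth attenuation and reconstructing with
each candidate map (`simulate_counts()`, `osem()`), exactly as one would
compare MR-based AC maps against a reference CT-based reconstruction.

## Synthetic head phantoms

Clinical paired ZTE/CT data cannot be shipped with a package, so
`generate_phantom()` builds synthetic heads on which every claim the test
suite makes can be verified against a known ground truth. The phantom is
an ellipsoidal head: a soft-tissue scalp layer (6 mm), a skull shell
between two ellipsoids whose bone density follows a smooth
distance-weighted profile spanning 200–2000 HU (peaking mid-shell),
nested grey/white-matter ellipsoids with a 4:1 grey:white activity
ratio — a typical FDG contrast — and spherical interior air pockets
standing in for the paranasal sinuses and mastoid cells. The default grid
is 96 x 96 x 48 voxels at 2.4 mm isotropic, matching a typical ZTE voxel
size while remaining desk-scale.

The ZTE volume is constructed as the exact inverse of the bone-density
model: soft tissue at a raw level of 100 a.u. (the normalization step
must rediscover this level rather than assume it), bone at
\(100\,(1 - (\mathrm{HU} - 42)/2400)\), air at zero. A smooth
multiplicative bias field (three low-order cosine modes with seeded
random phases) and additive Gaussian noise are then applied to the ZTE
only. Consequently, on a noiseless phantom a perfect segmentation
pipeline reproduces the CT *exactly* on bone and air voxels — the test
suite asserts this to machine precision — while noise and bias exercise
the robustness of the normalization and banding.

`phantom_cohort()` jitters the ellipsoid semi-axes and cavity radii by up
to ±8% per subject so that train/held-out splits for the network are not
degenerate copies of one anatomy.

What the phantom deliberately does **not** model: partial-volume mixing
at tissue interfaces (labels are assigned by voxel-centre membership), MR
physics (no T2* decay, no coil profiles beyond the smooth bias field),
anatomical complexity (no trabecular structure, no vertebrae, no
heterotopic calcifications), and scanner hardware attenuation. Passing
tests on these phantoms therefore demonstrate correctness of the
algorithms and the stated orderings under controlled conditions, not
clinical performance.

## Segmentation pipeline choices

* **Head mask**: the above-Otsu-threshold mask is morphologically closed
  (6-connected, radius 2) *before* taking the largest connected
  component. Closing first matters: the densest part of the skull can
  fall below an air/tissue threshold, and closing bridges that dark core
  so scalp, skull and brain form one component.
* **Normalizer**: the histogram mode (128 bins) of in-mask intensities,
  refined as the mean of the values in the fullest bin. The refinement
  makes the normalizer exact when soft tissue is a single repeated value
  and is scale-invariant because the bins span the data range.
* **Bone band**: normalized intensities in [0.1, 0.85] (closed interval)
  are bone; above is soft tissue, below is air. The band is exposed as a
  parameter. With the phantom's 200–2000 HU bone range, surface bone
  below ~400 HU maps above 0.85 and is missed by design — this is the
  intensity-overlap failure mode that motivates the learned method.
* **Speckle removal**: the bone class is opened (radius 1). On thin
  voxelized shells opening is not the identity, so the exact-recovery
  tests disable it (`open_radius = 0`) and the default is covered by
  near-exact (Dice) assertions.
* **Interior air**: air components not 6-connected to the image border
  are interior; bone blobs smaller than 1 cm^3 entirely enclosed by
  interior air are relabelled as air. The 1 cm^3 bound and the
  morphological radii are package conventions — the clinical
  sinus-edge-correction algorithms they stand in for are not public.

## Network design

The architecture follows the stated encoder plan of four stages of
batch-normalized 3x3x3 convolutions with ELU activations and
[8, 32, 32, 8] filters connected by max-pooling, with a mirrored decoder
(nearest-neighbour upsampling then convolution, skip concatenations) and
a linear 1x1x1 head. Open details were resolved as follows:

* **Pooling on the thin axis**: patches are 64 x 64 x 16; the 16-voxel
  axis cannot survive four 2x poolings, so pooling factors are
  (2,2,2), (2,2,2), (2,2,1), (2,2,1) and the thin axis never drops
  below 4.
* **Upsampling**: nearest-neighbour followed by convolution rather than
  transposed convolution, avoiding checkerboard artifacts and keeping
  the default parameter count at 144,129 — within the ±20% window around
  the published total that encodes the remaining wiring uncertainty.
* **Targets**: CT values divided by 1000 (`hu_scale`), keeping the MSE
  targets O(1).
* **Inference**: batch-normalization statistics are frozen (eval mode),
  making `predict_volume()` deterministic; overlapping windows are
  averaged with uniform weights — the simplest contract, stated
  explicitly rather than tapered.
* **Tail weight averaging**: the returned weights are the average of the
  last 100 Adam iterates (`average_last`). The final iterate of a noisy
  stochastic trajectory is an arbitrary sample around the optimum;
  averaging the tail damps that jitter and reduces run-to-run variance
  of the trained model.
* **Batch-norm re-estimation**: after optimization the normalization
  statistics are re-estimated as the average batch statistics over 50
  freshly drawn batches (`bn_recal_batches`). Patch batches are highly
  heterogeneous (some are all air, some cross the skull), so the
  exponential running average tracked during training depends on the
  accidental content of the last few hundred batches and can sit far
  from the statistics of typical inputs; for some training realizations
  this degraded frozen-statistics inference badly while train-mode loss
  was unaffected. Averaging over fixed batches with the final weights
  removes that dependence and keeps training fully deterministic (the
  re-estimation continues the same seeded RNG stream).

### Desk-scale training protocol

The published training regime (50,000 iterations of batch 100 on a GPU)
is far beyond a CPU test environment. The package's evaluation protocol
(`tests/testthat/test-acceptance.R`, `scripts/acceptance.R`) instead
trains a reduced model — patches 16 x 16 x 8, filters [6, 12, 12, 6],
2,000 Adam iterations of batch 8 at learning rate 2e-3, 60 patches from
each of 15 noisy training phantoms, sliding-window inference at 50%
overlap — and evaluates bone Dice at the 200 HU threshold on 5 held-out
subjects, both noiseless and at the noisy study condition
(`zte_noise_sd = 0.05`). These sizes were chosen once as
the smallest configuration whose training is stable and converged; the
qualitative claims checked (held-out Dice >= 0.80; learned regression at
or above the segmentation method on noisy data) are orderings, not the
clinical coefficients. One model is trained on the noisy condition and
evaluated on both conditions: training with noise is the harder task, so
the noiseless held-out evaluation bounds the noiseless-capacity claim
from below.

## Attenuation map and PET simulation

* **Bilinear HU-to-mu**: water at 0.096 cm^-1, breakpoint 0 HU, bone
  slope 5.1e-5 cm^-1/HU — conventional 511 keV conversion values for
  ~120 kVp CT, exposed in `bilinear_params()` since the exact published
  coefficients of vendor pipelines are not public. The transform is
  continuous and monotone; air (-1000 HU) maps to exactly 0.
* **Smoothing**: separable Gaussian, sigma = FWHM / (2 sqrt(2 ln 2)) per
  axis in voxel units, reflective boundaries (totals preserved up to
  boundary effects); default FWHM 10 mm.
* **Projector**: exact ray-grid intersection lengths (Siddon-style
  traversal), 2D parallel-beam per axial slice. TOF, PSF and scatter are
  deliberately absent: the simulator isolates the attenuation mechanism.
  Attenuation enters as survival weights 1/ACF with
  ACF = exp(0.1 * line integral of mu) (mm-to-cm conversion in one
  place).
* **OSEM**: multiplicative EM over angle-interleaved subsets
  (angle i -> subset i mod S, fixed order for reproducibility),
  non-negativity by construction, zero-sensitivity voxels excluded and
  reported. The desk default of 4 iterations x 8 subsets scales the
  clinical 8 x 28 schedule down in proportion to the smaller problem.
  With one subset the updates are plain MLEM and the test suite checks
  the Poisson log-likelihood is non-decreasing.

A consequence asserted end-to-end: reconstructing with the true mu-map
recovers the whole-brain mean activity within 1% on noiseless data,
while reconstructing with a bone-free mu-map biases the whole-brain mean
*downward* — the direction of the global underestimation expected when an
AC method misses bone.

## Evaluation suite conventions

* Dice 2|A∩B|/(|A|+|B|) and Jaccard |A∩B|/|A∪B| on bone masks
  thresholded at >= 200 HU (closed comparison); two empty masks give 1,
  flagged.
* Relative PET error ΔSUV = 100 (PET_test - PET_ref)/PET_ref per voxel
  inside a brain mask; reference voxels <= 0 are dropped and counted.
* Summaries are median and IQR = IQ75 - IQ25 with type-7
  (linear-interpolation) quantiles — pinned so test values are exact.
* Joint-histogram R^2 is computed **against the identity line**
  (1 - SS_res/SS_tot with the reference as prediction), not a fitted
  regression, because the comparison of interest is agreement with the
  reference reconstruction; RMSE is in native intensity units.
* The repeated-measures ANOVA is a two-way within-subject decomposition
  (method, region, interaction) with Greenhouse-Geisser epsilon computed
  from normalized orthogonal contrasts; with two levels epsilon is
  exactly 1. Post-hoc paired t-tests use Bonferroni correction
  (p * m, capped at 1), with stated conventions for zero-variance
  differences. The variance-homogeneity check is the median-centred
  (Brown-Forsythe) Levene variant, which is mildly conservative at
  moderate sample sizes; the centring choice is recorded in its output.
* Sample standard deviations use the n-1 denominator throughout.

## Known limitations

* The phantom world has no partial-volume effect, which flatters
  intensity-banding methods; orderings measured here need not transfer
  to clinical data. In particular, because the phantom ZTE is the exact
  inverse of the bone-density model, bone the segmentation method *does*
  detect receives exactly the generating HU, so its downstream ΔSUV can
  be smaller than the network's even where the network's bone mask
  overlaps the true bone better — the acceptance script reports both
  quantities side by side rather than asserting a ΔSUV ordering.
* The 2D parallel-beam slice geometry cannot represent oblique lines of
  response; axial smoothing effects of 3D reconstruction are absent.
* The sinus-edge handling is a stand-in rule (border-connectivity plus
  an enclosed-volume bound), not a reimplementation of the vendor
  algorithm.
* Atlas-based AC, scanner-hardware templates, scatter/randoms modelling
  and DICOM I/O are out of scope.
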