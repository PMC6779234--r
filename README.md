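# zteac

Attenuation correction (AC) is the step that makes brain PET
quantitative: every line of response must be compensated for the loss of
511 keV annihilation photons, and on PET/MR scanners the attenuation map
has to be derived from MRI rather than CT. Bone — the strongest
attenuator in the head — is invisible on conventional MR sequences but
visible on zero-echo-time (ZTE) images, where it sits between air (dark)
and soft tissue (bright). `zteac` implements, end to end and on synthetic
ground truth, the two MR-based AC strategies built on that observation,
plus everything needed to measure what an AC map error does to the
reconstructed PET image.

**Who it is for:** researchers studying MR-based AC methods and their
downstream quantification errors who need a self-contained, reproducible
desk-scale testbed rather than scanner data.

## What is inside

* **Segmentation-based ZTE AC** (`zte_pseudoct()`): normalize ZTE
  intensity so the soft-tissue mode is 1 (I<sub>ZTE</sub>), classify
  air / soft / bone by intensity banding, detect interior air pockets
  (paranasal-sinus analogues) by connectivity, and assign Hounsfield
  units with the continuous bone-density model

  HU<sub>bone</sub> = 42 + 2400 (1 − I<sub>ZTE</sub>),

  soft tissue = 42 HU, air = −1000 HU.
* **Patch-based 3D U-net pseudo-CT** (`build_model()`, `train()`,
  `predict_volume()`): four batch-normalized ELU convolution stages
  (8, 32, 32, 8 filters of 3³ kernels) with max-pooling, a mirrored
  decoder with skip concatenations, trained with MSE/Adam on random
  64×64×16 ZTE patches (~144k parameters under the default
  architecture); whole-volume inference by overlapped sliding windows
  with uniform averaging.
* **Attenuation maps** (`hu_to_mu()`, `smooth_ac()`, `bone_mask()`):
  bilinear HU→μ conversion at 511 keV (water 0.096 cm⁻¹, bone slope
  5.1×10⁻⁵ cm⁻¹/HU), Gaussian smoothing (default FWHM 10 mm), bone
  thresholding at ≥ 200 HU.
* **PET simulator** (`project()`, `attenuation_factors()`,
  `simulate_counts()`, `osem()`): exact Siddon-style parallel-beam
  projector per axial slice, ACF = exp(∫μ dl), Poisson count simulation,
  and OSEM/MLEM reconstruction with attenuation folded into the system
  model as survival weights.
* **Synthetic head phantoms** (`generate_phantom()`,
  `phantom_cohort()`): paired ZTE/CT/activity/label volumes with skull
  shell (200–2000 HU density profile), scalp, grey/white matter (4:1
  activity), and air cavities; the ZTE is the exact inverse of the bone
  model so noiseless pipelines can be verified to machine precision.
* **Evaluation suite** (`dice()`, `jaccard()`, `delta_suv()`,
  `summarize_errors()`, `joint_histogram()`, `voi_errors()`,
  `rm_anova()`, `posthoc_paired_t()`, `levene()`): bone-overlap
  coefficients, relative PET error ΔSUV = 100 (PET<sub>test</sub> −
  PET<sub>ref</sub>)/PET<sub>ref</sub>, median/IQR summaries, identity-line
  R²/RMSE, per-VOI tables, and a repeated-measures ANOVA stack with
  Greenhouse–Geisser correction, Bonferroni post-hocs and a
  median-centred Levene test.

See `vignettes/zteac-methods.Rmd` for the full model description,
parameter choices and limitations.

## Worked example

Generate a small noisy cohort, build AC maps by ZTE segmentation,
reconstruct PET with each map (reference: the ground-truth CT map), and
summarize the errors:

```r
library(zteac)
cfg <- run_config(
  n_subjects  = 2, methods = "zte",
  phantom_args = list(grid_shape = c(48L, 48L, 24L), spacing_mm = 4.8,
                      zte_noise_sd = 0.02),
  recon = recon_config(iterations = 2, subsets = 4), seed = 3)
report <- run_pipeline(cfg)
report
```

```
<eval_report>
  bone overlap (vs CT, 200 HU threshold):
    zte   Dice 0.127  Jaccard 0.068
  zte   whole-brain dSUV median -10.69%, IQR 3.75%
  ct    whole-brain dSUV median +0.00%, IQR 0.00%
```

Reading this: at this deliberately coarse 4.8 mm demonstration
resolution the thin skull shell is barely more than one voxel thick, so
the segmentation method recovers almost no bone (Dice 0.13) — and the
missing bone biases the reconstructed whole-brain uptake *down* by about
−10.7% relative to CT-based AC, the direction and rough magnitude
expected when an AC map misses the skull. The reference method compared
against itself is exactly zero everywhere, as it must be. At the default
2.4 mm phantom resolution the segmentation method reaches bone
Dice ≈ 0.94 and the trained network ≈ 0.97 (see the acceptance outputs
below).

The same steps are scriptable from a shell via the thin CLI installed
with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/zteac", package = "zteac"))') \
  phantom --out scratch/ph --seed 1 --noise-sd 0.05
```

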