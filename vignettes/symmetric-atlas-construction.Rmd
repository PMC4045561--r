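---
title: "Building symmetric newborn brain atlases with symatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building symmetric newborn brain atlases with symatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Brain atlases built by plain averaging of normalized images inherit the
anatomical left-right asymmetries of the cohort and of the chosen reference
subject. When such an atlas is then used to spatially normalize images for
an *asymmetry study* — for example of the early structural lateralization
(planum temporale, superior temporal sulcus) thought to accompany language
development — the atlas's own asymmetry biases the very quantity under
study. A symmetric atlas, one that is exactly invariant under mirroring
across the midsagittal plane, removes that bias. `symatlas` builds such an
atlas, consisting of an intensity template plus probabilistic brain and CSF
models, from a cohort of T1-weighted newborn head volumes.

## The procedure

Write $I_i$, $i = 1 \dots N$ for the AC-PC-aligned, isotropically resliced,
bias-reduced input images with binary brain masks $B_i$, CSF masks $C_i$
and intracranial masks $IC_i = B_i \cup C_i$. Each image and every mask is
flipped across $x = 0$ to give $2N$ inputs. A reference subject $I_R$ with
little global head deformation is chosen (explicitly, or automatically as
the subject with the smallest mean pairwise $\sum|\log s| + \sum|h|$ affine
distance). Then, for each of the $2N$ inputs:

1. **Affine normalization.** A 12-parameter transform $A_i$ (translation,
   rotation, scale, shear) minimizes the intracranially weighted SSD
   $\sum_x w(x)\,\bigl(I_R(x) - g\,I_i(A_i x)\bigr)^2$, with $w$ the
   (lightly smoothed) IC mask of the reference and $g$ a per-evaluation
   least-squares intensity gain that absorbs global scanner-gain
   differences. The parameters are applied to the image and all masks:
   $I_i' = A(I_i)$, etc.
2. **Nonlinear normalization.** A low-frequency displacement field
   $u_i(x) = \sum_{klm} c_{klm}\,b_k(x_1)b_l(x_2)b_m(x_3)$ over the lowest
   $k^3$ 3D cosine basis functions minimizes the same weighted SSD plus a
   bending-energy penalty $\lambda \int \|\nabla^2 u\|^2$, giving
   $I_i'' = D(I_i')$ and the warped masks.
3. **Unbiased average deformation.** The reverse map $T_i$ (reference to
   affine-normalized subject) is obtained by numerically inverting $D_i$,
   and the average $\bar T = \tfrac{1}{2N}\sum_i T_i$ is applied to every
   normalized image and mask, so the atlas geometry is the cohort mean
   rather than the reference's shape.
4. **Averaging.** The template is the voxelwise mean of the $2N$ corrected
   images; the brain and CSF probability maps are the means of the
   continuously warped masks.

This yields the *first-pass* atlas. The whole procedure is repeated with
the first-pass template (and the 0.5-thresholded support of its combined
probability maps, lightly smoothed, as weighting mask) in place of the
reference subject, because the reference itself carries asymmetry. Finally
the second-pass atlas is averaged with its own sagittal flip. Because
flipping is implemented as a pure index reversal on a grid whose x voxel
centres are symmetric about $x = 0$, the flip-average is *bit-exactly*
flip-invariant: `max(abs(template - flip(template)))` is exactly 0, not
merely small. The asymmetric control atlas runs the identical pipeline on
the $N$ originals with no flips and no final flip-averaging.

## Symmetry evaluation

The voxelwise asymmetry index of any atlas component $V$ is
$\mathrm{AI} = 2\,(V - \bar V)/(V + \bar V)$ with $\bar V$ the mirrored
image; voxels with $V + \bar V = 0$ (symmetric air background) are assigned
0 rather than NaN. The signed difference image $V - \bar V$ and a
hemispheric volume report (left %, right %, and their difference in
percentage points per structure, with midline voxel columns split half to
each side) complete the evaluation. Both a 0.5-thresholded and a
continuous-probability-mass volume row are reported, since either
definition of an atlas "volume" is defensible.

## A worked example

```{r example, eval = FALSE}
library(symatlas)

# a synthetic cohort of 4 newborn heads, left hemisphere enlarged by 5%
cohort <- generate_cohort(4, phantom_spec(left_scale = 1.05, seed = 7),
                          seed = 7)
cohort <- bias_correct_cohort(cohort)

atlas <- build_symmetric_atlas(cohort, reference_id = "S01")
max(abs(atlas$template$data - flip_sagittal(atlas$template)$data))  # 0

control <- build_asymmetric_atlas(cohort, reference_id = "S01")
max(abs(difference_image(control$template)$data))                   # > 0

hemisphere_volume_report(atlas$brain_prob, atlas$csf_prob)
```

## The phantom module

Real newborn MR cohorts cannot be redistributed, so every stage is
exercised against an analytic head phantom: nested ellipsoids (scalp, CSF
shell, brain) voxelized with 2x2x2 supersampling so compartment boundaries
carry realistic partial-volume intensities, an optional left-hemisphere
enlargement (`left_scale`; the left/total brain volume ratio is
$s/(1+s)$ by construction) and torque, a multiplicative bias field built
from one low-frequency cosine per axis, and additive Gaussian noise.
Cohorts add per-subject rigid offsets, anisotropic scale, shear and a
smooth low-order warp, with the ground-truth transforms recorded, so
registration accuracy can be measured against known answers. Per-subject
random streams are derived from one seed by counter, making any subject
reproducible independently of cohort size.

Default study conditions: head semi-axes 40 x 50 x 35 mm, brain fraction
0.75, 4 mm CSF shell, class intensities 0/40/100/70
(background/CSF/brain/scalp — newborn T1 contrast with unmyelinated
parenchyma brighter than CSF and scalp in between), bias amplitude 0.15,
noise SD 3 (3% of brain intensity), jitter of ±3 mm, ±4°, ±4% scale,
±0.02 shear and 1.5 mm warp, at 1 mm resolution (0.5 mm is the target
resolution for real data; phantom defaults trade resolution for tractable
cohort experiments). What the phantom does *not* emulate — cortical
folding, gestational-age contrast changes, true scanner noise correlation —
limits what passing tests show about real data: they validate the
*geometry* and the *symmetry bookkeeping* of the pipeline, not clinical
segmentation or registration accuracy.

## Numerical choices

* **Grid-exact flipping.** All pipeline grids keep x voxel centres
  symmetric about $x = 0$ (reslicing and AC-PC reorientation construct
  them so). Flipping therefore needs no interpolation, which is the only
  way the final atlas can be *exactly* symmetric.
* **Interpolation.** Trilinear everywhere; out-of-field values are 0
  (air). Masks are warped continuously and only binarized on request —
  the probabilistic models average the continuous values directly.
* **Affine optimizer.** Multi-resolution (4, 2, 1 mm) BFGS with the exact
  analytic gradient of the trilinearly interpolated objective; the
  intensity gain is profiled out in closed form each evaluation. The
  objective is normalized by the weighted reference variance, so traces
  are comparable across levels and images. Deterministic; no seeds.
* **Nonlinear fit.** Cosine basis order 8 per axis by default (the paper's
  software used the same family; the order is not published). Pyramid 4
  and 2 mm — the basis carries no detail below ~10 mm wavelength, so a
  finer level adds cost, not accuracy. Bending-energy weight
  `lambda = 1` in normalized-objective units: on phantom cohorts this is
  the magnitude that keeps fitted warps diffeomorphic (folding-free);
  much smaller values let flipped-versus-original fits fold, which the
  inversion step rejects by design.
* **Inversion of $D_i$.** Fixed-point iteration $v \leftarrow -u(x + v)$
  on a 25-per-axis lattice, then least-squares re-projection onto the same
  cosine basis; the composition residual is attached to the result. A
  field with nonpositive Jacobian anywhere on the lattice is refused. The
  reverse-direction map could instead be fitted by a second registration;
  inversion is cheaper, deterministic and is the package default.
* **Bias reduction.** Iterative fit of a separable two-harmonic Fourier
  (cosine + sine) log-field over the mask's bounding box — the scale of
  scanner coil nonuniformity, too smooth to absorb anatomy — referenced to
  robust (median) 3-class intensity levels with 3-MAD trimming of
  partial-volume outliers. Whether the intensities genuinely carry tissue
  classes is decided by model comparison: the class reference is used only
  when the quantization explains the log-intensities clearly better than
  the smooth field model alone, so a smooth field over a homogeneous
  region is removed directly instead of being mistaken for anatomy. The
  globally evaluated field is clamped to its in-mask range, so basis
  extrapolation cannot distort the background. A plain Gaussian low-pass
  of log-intensity was rejected: it leaks tissue contrast into the field
  and cannot remove FOV-scale components near the support boundary.
* **Segmentation stand-in.** The published framework delegates tissue
  segmentation to an external method; here a documented simple pipeline
  (Otsu background split, cavity filling, largest component, 3-class
  1D k-means, component-adjacency CSF cleanup) is provided, and externally
  computed masks are accepted everywhere. The brain/CSF intensity order is
  a switch (`csf_bright`).
* **Order invariance.** Records are sorted by subject id before
  registration and averaging, so `run_pass` output is bit-identical under
  input reordering.
* **Ties.** Automatic reference selection breaks ties on the lowest
  subject id. Midline voxel columns are split 50/50 between hemispheres,
  keeping mirrored inputs at exactly 50.00/50.00.

## Known limitations

* Weighted SSD assumes consistent tissue contrast after bias reduction and
  global gain scaling; inter-sequence registration is out of scope.
* On nearly rotationally symmetric heads (the phantom is one) the rotation
  component of the affine fit is weakly determined; translation and scale
  recovery are the tested guarantees. Real heads are less ambiguous.
* Uncorrected strong bias fields can masquerade as geometry and derail the
  nonlinear fit; bias reduction before atlas construction is part of the
  pipeline contract, not an optional nicety.
* The automatic reference selection runs $N(N-1)$ coarse registrations;
  for large cohorts pass an explicit `reference_id`.
* Exact flip symmetry is a property of the final atlas by construction; it
  does not certify that individual registrations found globally optimal
  alignments.

## Problem sizes used in the tests

Unit tests run on 2-3 mm phantoms with reduced basis order and pyramid
levels; the end-to-end symmetry and control-contrast checks and the
known-transform recovery trials run at the phantom default of 1 mm with
default registration settings; these sizes are the package's chosen
standard verification conditions.
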