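---
title: "Groupwise alignment by alternating least squares on Self Quotient Images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Groupwise alignment by alternating least squares on Self Quotient Images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(congealsqi)
```

## The model

An ensemble of N grayscale images of common size is assumed to consist of
geometrically distorted views of a common underlying scene. Each image's
distortion is modeled as an affine warp with parameter vector
$p \in \mathbb{R}^6$, acting on pixel coordinates centered at the image
midpoint through the matrix

$$\begin{pmatrix} 1+p_1 & p_3 & p_5 \\ p_2 & 1+p_4 & p_6 \end{pmatrix},$$

so $p = 0$ is the identity and $(p_5, p_6)$ is a translation in pixels.
Centering the coordinates keeps the translation and linear columns of the
normal equations on comparable scales, which conditions the Gauss--Newton
solve. Warping is implemented as inverse resampling with bilinear
interpolation: the output pixel at $x$ takes the source value at
$w(x; p)$. Samples that fall outside the source rectangle are masked out
of all alignment sums rather than zero-filled, so frame borders never act
as outliers (an `"edge"` fill mode produces full frames by edge
replication where a frame-filling output is needed, e.g. whole-frame
quality metrics).

Alignment minimizes the mean misalignment cost — the mean over images of
the squared residual to a mean image — by alternating:

1. the closed-form mean update, a per-pixel average of the currently
   warped images over their in-support contributions, which minimizes the
   cost for fixed warps;
2. a per-image Gauss--Newton update
   $\Delta p = (G^\top G)^{-1} G^\top r$, where $G$ is the Jacobian of the
   warped image in $p$ (spatial central-difference gradients times the
   affine basis) and $r$ the residual to the current mean, followed by the
   additive rule $p \leftarrow p + \Delta p$.

Each iteration therefore solves exactly N six-parameter least-squares
problems — linear in the ensemble size — in contrast to the quadratic
all-pairs misalignment (available as the diagnostic `compute_csme()` but
never used by the loop).

## Self Quotient Images

When the ensemble mixes illumination conditions, occlusions or imaging
contrasts, raw intensities are not comparable across images. The Self
Quotient Image $Q = I / I_\sigma$ (the image divided by its Gaussian
smoothing, default $\sigma = 2$ px) is exactly invariant to global
intensity scaling and approximately invariant to any multiplicative
shading that is smooth at the kernel scale; what survives is local edge
structure, whose width grows with $\sigma$. A small constant
($10^{-3} \times$ the image maximum) guards the denominator in dark
regions. Hard thresholding then suppresses quotient deviations within
$\mu$ standard deviations of the mean (default $\mu = 0.5$), zeroing
noise and residual shading while keeping strong edges; the output is
centered, which also removes the DC offset that would otherwise dominate
the least-squares cost. Alignment runs on these thresholded quotients; the
recovered warps apply unchanged to the original intensities, and both the
SQI mean and the original-intensity mean are reported.

The signed thresholded quotient assumes that corresponding edges have the
same contrast polarity across the ensemble. Under a contrast inversion
(bright-to-dark versus dark-to-bright, as between T1- and T2-weighted
MRI) the quotient's deviations flip sign and the dominant overshoot ridge
moves to the opposite side of each edge, so signed maps anti-correlate
and even their magnitudes carry a systematic sub-kernel-width bias. For
such ensembles `sqi_edge = "magnitude"` aligns instead on the hard-
thresholded gradient magnitude of the lightly smoothed quotient, which
peaks at the edge crossing regardless of polarity.

## Numerical safeguards

* **Stopping.** Iteration ends at `kmax` (default 200) or when the cost
  decrease between successive iterations falls below `emax` (default
  $10^{-8}$) relative to the stage's initial cost; relative change makes
  the rule scale-free. An exactly aligned ensemble stops after one
  iteration with zero cost.
* **Drift control.** The mean-image formulation fixes no absolute frame:
  the whole ensemble could translate, shrink or shear without changing
  the cost. After every iteration all warps are composed with the inverse
  of their average affine matrix, making the average warp exactly the
  identity (toggle `drift_correction`). Because the correction is a right
  multiplication, the normalized average is the identity exactly, not
  approximately.
* **Coarse-to-fine.** By default the alternation runs in three stages on
  working images blurred with Gaussian $\sigma = 4$, then $2$, then
  unblurred, splitting the iteration budget 1:1:2. Thresholded SQI maps
  are sparse and thin; without the widened basin they can lock onto
  aliased correspondences (e.g. a ventricle edge onto a skull edge) a
  ring-spacing away. `coarse_to_fine = FALSE` restores the literal
  single-scale alternation.
* **Damping.** During the blurred stages the normal equations are
  Levenberg--Marquardt damped ($G^\top G + 0.01\,\mathrm{diag}(G^\top G)$)
  to hold the weakly constrained shear/scale directions of sparse edge
  maps; the full-resolution stage always runs the plain pseudo-inverse
  update, so the final refinement is the unmodified Gauss--Newton step.
* **Degeneracy.** Warps whose linear part is (near-)singular are rejected
  before resampling; per-image updates with normal-equation condition
  number above $10^{10}$, or with fewer than six in-support pixels, are
  skipped for that iteration — the image keeps its parameters and the
  event is logged — while the rest of the ensemble proceeds.
* **Prescaling.** Stack intensities are divided by their global maximum
  (shifted first only if negatives are present), mapping into $[0, 1]$ so
  that `emax` and the SQI epsilon are scale-free. The zero point is
  deliberately preserved: shifting the darkest pixel to exactly zero
  would manufacture near-zero quotient denominators whose amplified noise
  drowns the edge maps.

## Quality metrics

Per-image PSNR is $10 \log_{10}(\max(\bar i)^2 / \mathrm{MSE})$ with the
MSE taken over all pixels of the vectorized images, and the global SSIM
statistic uses whole-image means, variances and covariance with
stabilization constants $c_1 = 0.01\max(\bar i)$ and
$c_2 = 0.03\max(\bar i)$ — both constants linear in the intensity
maximum, and the covariance term entering as $2\sigma_{0n} + c_2$. This
deviates from the common windowed SSIM convention (squared constants,
local windows); it is kept as the package's reporting convention, with
`windowed = TRUE` available for comparison against mainstream
implementations. mPSNR/mSSIM are arithmetic means over the ensemble;
images identical to the mean (infinite PSNR) are excluded from mPSNR with
a warning. For these whole-frame metrics the warped images are resampled
with edge replication, so the score reflects residual misalignment rather
than the sliver of frame lost to resampling.

## The synthetic-data generator

`make_ensemble()` emulates the experimental conditions the method is
meant for, with full ground truth:

* **Geometry.** Each image's warp is drawn by perturbing three corners of
  the image rectangle with i.i.d. Gaussian displacements of variance
  $\sigma^2$ (in squared pixels) and solving exactly for the affine map —
  distortion strength is monotone in $\sigma^2$, with $\sigma^2 = 1$ mild
  (corner spread about 1.2 px RMS) and $\sigma^2 = 10$ strong. The
  convention ties corner-RMSE numbers to this artifact; they are not
  comparable to other corner-perturbation schemes.
* **Support.** The base is reflect-padded before warping and the result
  cropped, so every distorted image fills its frame the way real
  photographs and MRI crops do. Zero-filled borders would inject strong
  artificial frame edges that dominate the quotient images.
* **Photometry.** Multiplicative shading is either a linear ramp from 0.2
  to 1.0 in a random direction per image (strong, directional — the hard
  case for raw least squares) or a smooth random field in $[0.4, 1.2]$.
* **Modality.** Pseudo-modality maps are gamma remaps with
  $\gamma \in \{0.5, 2\}$ and a random monotone *decreasing* 5-knot
  piecewise-linear remap — a contrast inversion, chosen to destroy the
  intensity correspondence raw least squares needs while preserving edge
  positions, as between MRI weightings. `"mixed"` cycles
  identity/gamma/inversion across the ensemble.
* **Occlusion.** A chosen fraction of images receives one opaque
  rectangle of a chosen area fraction at a random position with a random
  constant intensity, pasted after everything else.

Base images are a band-limited texture, a face-like blob arrangement, or
a brain-like phantom of nested ellipses with asymmetric focal structures
and interior texture (amplitude 0.12) — the asymmetry and texture keep
the alignment normal equations well conditioned in every affine
direction, which concentric rings alone would not.

What the generator does *not* emulate: sensor noise, non-affine
(elastic) anatomy differences between subjects, partial-volume effects,
resolution anisotropy, or the statistics of real face databases. Passing
tests on these ensembles therefore demonstrate the optimization and the
invariances they construct — not performance on any particular real
dataset.

## Problem sizes and experiment design

The packaged experiments use desk-scale ensembles chosen to exercise the
study conditions while staying quick to re-run: warp recovery uses N = 20
images of 100×100 at $\sigma^2 = 2$; the shading, multimodal and
occlusion experiments use N = 9–10 images of 80×80 at $\sigma^2 = 2$,
with up to 150–200 iterations. Shading robustness is scored as the
fraction of the initial corner-RMSE removed, compared with the unshaded
baseline's fraction: the unshaded baseline converges one to two orders of
magnitude below the bilinear-interpolation noise floor, so a ratio of
final RMSE values would compare noise floors rather than alignment
quality.

## Known limitations

* Affine warps only; no homographies or elastic deformation.
* The magnitude edge map trades some precision for polarity invariance:
  on mixed-contrast phantoms the residual corner spread is typically a
  few tenths of a pixel, versus a few hundredths within a single
  modality.
* The alternation is not guaranteed monotone — Gauss--Newton steps can
  overshoot — though in practice the cost trace is non-increasing after
  the first few iterations up to numerical jitter.
* 2-D only: NIfTI volumes are sliced, never congealed volumetrically.
* Global (non-windowed) SSIM as reported here saturates near 1 for
  well-aligned ensembles and is less discriminative than windowed SSIM.
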