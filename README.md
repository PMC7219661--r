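# congealsqi

Least-squares groupwise image alignment ("congealing") with Self Quotient
Image preprocessing, for ensembles of 2-D grayscale images: photometrically
distorted photographs, partially occluded faces, and unimodal or multimodal
MRI slices (T1/T2/PD-style contrasts). The package is aimed at anyone who
needs to jointly align N images to each other without electing one of them
as a biased reference — e.g. to build an unbiased mean image or to remove
acquisition jitter before downstream analysis.

## The method

Given N vectorized images `i_n` deformed by affine warps `w(.; p_n)` with
parameters `p_n ∈ R^6`, congealing minimizes the mean misalignment cost

    C0(P_N; i*) = (1/N) Σ_n || i* − i_w(p_n) ||²

where `i*` is the (unknown) mean image. Instead of the expensive joint
minimization over warps and mean, the package alternates two cheap steps:

1. **Mean update** — for fixed warps the minimizer is the per-pixel average
   of the currently warped ensemble, `i(k) = (1/N) Σ_n i_w(p_n(k−1))`.
2. **Warp update** — each image receives one Gauss–Newton (Lucas–Kanade)
   perturbation `Δp_n = (GᵀG)⁻¹ Gᵀ (i(k) − i_w(p_n))`, with `G` the
   Jacobian of the warped image with respect to `p`, and the additive rule
   `p_n ← p_n + Δp_n`.

The cost per iteration is `O(N · NxNy · Np)` — linear in the ensemble
size, unlike the `O(N²)` all-pairs formulations (kept here only as the
`compute_csme()` diagnostic).

Raw intensities are a poor alignment currency when the ensemble mixes
illumination conditions, occlusions, or MRI contrasts. The **Self Quotient
Image** `Q = I / I_σ` (the image over its Gaussian-smoothed self) cancels
smooth multiplicative shading and strips intensity distributions down to
edge structure; a hard threshold `T_μ = μ·σ_Q` (default `μ = 0.5`)
suppresses sub-threshold quotient fluctuations as denoising. Alignment
then runs on the thresholded SQIs and the recovered warps are applied to
the original intensities. For ensembles mixing *inverted* contrasts the
signed quotient anti-correlates; `sqi_edge = "magnitude"` instead aligns a
polarity-insensitive edge-strength map derived from the quotient.

Quality is reported as mPSNR and mSSIM — the ensemble means of each
image's PSNR and (global, single-statistic) SSIM against the final mean
image. Defaults follow `kmax = 200` iterations and a relative
cost-decrease stopping tolerance `emax = 1e-8`.

## Worked example

```r
library(congealsqi)

base <- make_base_image("texture", c(100, 100), seed = 11)
ens  <- make_ensemble(base, N = 20, distortion_spec(sigma2 = 2, seed = 12))
st   <- congeal(ens$stack, congeal_config())
rep  <- ensemble_metrics(st, ens$stack)

cat(sprintf("corner RMSE: %.3f px -> %.4f px in %d iterations\n",
            corner_rmse(ens), corner_rmse(ens, st$params), st$iteration))
print(rep)
```

```
corner RMSE: 1.741 px -> 0.0040 px in 133 iterations
ensemble metrics over 20 images:
  mPSNR = 44.435 dB
  mSSIM = 0.9982
```

The 20 synthetic images start with a root-mean-square corner misalignment
of 1.74 px (corner-perturbation strength `sigma2 = 2`); after congealing
the residual spread of the ensemble's corner positions is 0.004 px, and
each aligned image matches the final mean image at 44 dB PSNR.

For a multimodal ensemble (one brain-like phantom seen through identity,
gamma and contrast-inverting intensity maps), add SQI preprocessing:

```r
ph <- make_base_image("phantom", c(80, 80), seed = 31)
mm <- make_ensemble(ph, 9, distortion_spec(sigma2 = 2, modality = "mixed", seed = 32))
st <- congeal(mm$stack, congeal_config(use_sqi = TRUE, sqi_edge = "magnitude"))
```

## Command line

A thin wrapper over the same functions lives in `inst/cli/congealsqi.R`:

```sh
Rscript inst/cli/congealsqi.R simulate --base texture --n 20 --sigma2 2 --seed 3 --out sim/
Rscript inst/cli/congealsqi.R align --input sim/ --sqi --out results/
Rscript inst/cli/congealsqi.R evaluate --aligned results/ --truth sim/ground_truth.json
```

`align` accepts directories of PNG/TIFF images or a NIfTI volume
(`--nifti-slice`), and writes aligned 16-bit TIFFs, mean images before and
after, the warp parameters as JSON, and per-image metrics as CSV/JSON.

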