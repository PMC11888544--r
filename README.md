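# elitedce

Reconstruction and analysis toolbox for dynamic contrast-enhanced (DCE) MRI
acquired with golden-angle radial sampling, written for researchers working
on accelerated breast DCE protocols who need high spatial resolution *and*
second-scale temporal resolution from the same acquisition.

## The problem and the method

A golden-angle radial acquisition samples k-space along spokes rotated by
111.246° per shot, so any contiguous group of spokes can be binned into a
frame: 288 spokes become 36 frames at 8 spokes/frame (4.2 s/frame) or 144
frames at 2 spokes/frame (1 s/frame). Few spokes per frame means heavy
undersampling, and a plain gridding reconstruction (NUFFT) is dominated by
streak artifacts.

GRASP compressed sensing recovers the dynamic series `M` by solving

    argmin_M  1/2 || y − E M ||²  +  λ || S M ||₁

where `E = √w Φ F C` is the multi-coil radial encoding operator (coil maps
`C`, NUFFT `F`, per-frame spoke selection `Φ`, ramp density weights `w`) and
`S` is the temporal finite-difference transform (total variation in time).

The subspace extension constrains each image region to a low-dimensional
temporal subspace. From a low-resolution GRASP reconstruction (the radial
center is densely sampled), each region's Casorati matrix (time × voxels) is
decomposed by PCA, keeping the `K` dominant temporal basis vectors `Uᵢ`
(`T × K`). The high-resolution series is then reconstructed over the
coefficients only:

    argmin_V  1/2 || y − E Σᵢ Uᵢ Vᵢ ||²  +  λ || S Σᵢ Uᵢ Vᵢ ||₁

Regions can be the whole image (globally low-rank, GLR), overlapping blocks
(locally low-rank, LLR), or tissue segments — the ELITE variant — with the
background confined to a single principal component, which is what removes
most background streaks and noise. Defaults follow the published protocol:
`λ = 0.01`, 7 conjugate-gradient iterations repeated 3 times, `K = 6` per
tissue, `K = 1` for background.

For 1-second imaging (2 spokes/frame) the low-resolution frames are too
streaked for reliable basis estimation, so a residual convolutional network
(ten 3×3 convolution layers by default, L2 loss, Adam) trained on synthetic
phantom pairs denoises them first.

Pharmacokinetic analysis uses the two-compartment exchange model

    Ct = vp·Cp + ve·Ce
    vp dCp/dt = Fp·Ca + PS·Ce − (Fp + PS)·Cp
    ve dCe/dt = PS·(Cp − Ce)
    Ktrans = Fp (1 − exp(−PS/Fp))

with a population arterial input function and bootstrap fitting (average 10%
of the voxels, fit, repeat 100 times).

Everything runs end-to-end on a synthetic breast digital reference object
(six tissue classes, tissue-specific rise times, smooth complex coil maps),
so no external data are required.

## Worked example

```r
library(elitedce)

# synthetic acquisition: 160x160 slice, 8 coils, 144 spokes at 8/frame
bm <- run_benchmark(list(n_spokes = 144L, seed = 1L))
print(bm$folds)
```

```
  method       cnr    noise_sd  cnr_fold noise_reduction_fold
1  nufft  1.667273 0.150549313  1.000000             1.000000
2  grasp  3.708721 0.050568467  2.224423             2.977138
3  elite 86.304270 0.002760855 51.763732            54.529965
```

`cnr` is the contrast-to-noise ratio between the lesion and fibroglandular
ROIs at the peak-enhancement frame; `noise_sd` is the background noise
estimated from consecutive-frame subtraction in six background ROIs. The
tissue-segment reconstruction (ELITE) raises CNR and suppresses background
noise by an order of magnitude relative to GRASP, and both improve on the
NUFFT baseline — the qualitative ordering the method is designed to deliver.

Pharmacokinetic fitting on a known curve:

```r
af <- model_aif(seq(0, 300, by = 2), onset = 30)
truth <- pkm_params(ve = 0.35, vp = 0.05, Fp = 0.8, PS = 0.3)
fit <- fit_pkm(tcxm_forward(truth, af), af)
coef(fit)
#>      ve      vp      Fp      PS  Ktrans
#>  0.3500  0.0500  0.8000  0.3000  0.2497
```

A command-line front end (`inst/cli/elite.R`) exposes `simulate`, `recon`,
`pkm`, `metrics` and `benchmark` subcommands over the same functions.

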