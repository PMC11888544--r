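---
title: "Tissue-segment subspace reconstruction for radial DCE-MRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-segment subspace reconstruction for radial DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(elitedce)
```

This vignette is the package's account of the science it implements: the
reconstruction models and their assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic phantom does and does
not emulate, and the numerical choices that were genuinely open.

## Acquisition model

Golden-angle radial sampling acquires k-space spokes through the centre,
each rotated by 111.246° from the last, so that any contiguous window of
spokes covers k-space near-uniformly. Spokes are binned sequentially into
frames; with 288 spokes over a 150 s scan, 8 spokes/frame gives 36 frames at
4.2 s/frame and 2 spokes/frame gives 144 frames at 1 s/frame. Trailing
spokes that do not fill a frame are discarded, which is what makes the
288-spoke, 2-spokes-per-frame count come out at exactly 144.

Coordinates are normalized frequencies in cycles/FOV on $[-0.5, 0.5)$, with
the image DC at the centre pixel (0-based $N/2$). Readouts are sampled at
twice the image bandwidth ($2N$ samples per spoke): image corners lie at
radius $\approx 0.7N$ pixels, beyond the radial Nyquist rate of an
unoversampled readout, and without the oversampling the density-compensated
adjoint shows a several-percent halo that no spoke count removes.

## The encoding operator

$E = \sqrt{w}\,\Phi F C$ combines coil sensitivity weighting $C$, a gridding
non-uniform FFT $F$ (Kaiser–Bessel kernel, width 4, oversampling 2, Beatty
$\beta$; interpolation stored as a sparse matrix per frame and reused across
coils and iterations), per-frame spoke selection $\Phi$, and the square root
of the ramp density weights. Applying $\sqrt{w}$ symmetrically in $E$ and
$E^H$ keeps the pair an exact algebraic transpose —
$\langle Ex, y\rangle = \langle x, E^H y\rangle$ holds to machine precision
in the tests — while still preconditioning the normal operator by the
sampling density.

Two details of the ramp weights matter numerically:

* every spoke passes through $k = 0$, so the DC cell (a disk of radius half
  the radial cell) is *shared* by all $S$ spokes; each centre sample gets
  $1/S$ of the disk area (the ramp value at a quarter cell). Giving each
  centre sample the half-cell value instead over-counts DC $S$-fold and adds
  a constant offset to every reconstruction.
* the ramp measure $r\,\Delta r\,\pi/S$ is defined for the full spoke set;
  a frame containing only $S_f$ spokes integrates the same disk with
  $\Delta\theta = \pi/S_f$, so the per-frame adjoint is rescaled by $S/S_f$.
  Without this the gridding baseline is scaled down by the undersampling
  factor and every absolute metric (noise, curve amplitude) is wrong.

`lowres_subset` keeps the readout samples with $|k| \le L/2N$ — the densely
sampled centre — rescales the trajectory to the $L$-grid and multiplies the
samples by $(L/N)^2$, the voxel-volume factor that makes the cropped data
consistent with the forward model of the Fourier-downsampled object.

## GRASP and the subspace reconstructions

`grasp_recon` solves
$\min_M \tfrac12\|y - EM\|^2 + \lambda\|SM\|_1$
with $S$ the forward temporal difference. The solver is nonlinear conjugate
gradient (Fletcher–Reeves) with a backtracking line search (factor 0.5, up
to 20 steps, Armijo constant $10^{-4}$), run for `n_iter = 7` iterations and
restarted `n_repeat = 3` times, initialized at the density-compensated
adjoint. Because both $E$ and $S$ are linear, each iteration needs exactly
one forward and one adjoint application; the line search reuses the
precomputed directional images. The $\ell_1$ term uses the smooth surrogate
$\sqrt{|x|^2 + \epsilon^2}$ per complex element with
$\epsilon = 10^{-6} \times$ the peak of the initial image, and $\lambda$ is
likewise scaled by that peak, so `lambda = 0.01` means one percent of the
image scale regardless of units. Accepted objective values are
non-increasing by construction and the trace is stored on the result.

`estimate_basis` performs PCA per region as a plain SVD of the Casorati
matrix (time × voxels) **without mean-centering** — the subspace model
$M = UV$ has no intercept, so centering would misplace the baseline signal.
Basis vectors are phase-fixed so their largest-magnitude entry is positive
real, making stored bases reproducible. `K = 6` components per tissue region
follows the published protocol; the background region gets a single
component (`K_background = 1`), which is the step that collapses background
streaks. Regions with fewer pixels than `K` have `K` reduced with a warning.

`subspace_recon` optimizes the same objective over the coefficients $V_i$
with the bases fixed, initialized at the compression of the adjoint image.
One whole-image region reproduces the globally low-rank reconstruction
(verified to $10^{-8}$), overlapping blocks give the locally low-rank one,
and a tissue label map with single-component background gives the
tissue-segment variant. Block mode defaults to a 10×10 grid with 50%
overlap per side and uniform averaging on reassembly; the overlap amount is
a package choice (the protocol states overlap was used but not how much),
and the published block-size figures are mutually inconsistent with the
stated grid sizes, so the grid is configurable. With overlapping blocks the
expand map divides by the coverage count, and its adjoint — not plain
compression — is used in the gradient.

## The synthetic phantom

The digital reference object is a stylized 2D axial breast slice with six
tissue classes: background, an ellipsoidal lesion embedded in the
fibroglandular interior, the fibroglandular tissue, a posterior pectoral
muscle band, a thin skin rim, and a small heart disc. Geometry constants are
fixed fractions of the grid; the seed jitters the lesion position. Tissue
dynamics are two-compartment exchange curves scaled to unit peak, entered as
`baseline × (1 + amplitude × curve)`; the per-tissue rise time drawn from
the dictionary (lesion 15–40 s, fibroglandular 40–90 s, muscle and skin
60–120 s, heart 5–15 s — a plausible ordering with the blood-pool heart
fastest, chosen once as package defaults) sets the plasma flow through the
transit-time relation $(v_p + v_e)/F_p = \tau$. A multiplicative Gaussian
field on the amplitude (SD 0.05) gives each region Casorati rank above one,
so multi-component subspaces are meaningful; with it switched off every
region is exactly rank 1, which the tests exploit. Coil maps are smooth
Gaussian lobes with gentle linear phase on a circle around the FOV.

K-space noise in the simulation driver is complex white Gaussian with SD
specified relative to the RMS magnitude of the noiseless data (2% by
default) — scaling to the DC peak instead makes the noise astronomically
large relative to everything but the centre sample.

What the phantom does *not* emulate: 3D anatomy, fat signal, $B_0/B_1$
effects, motion, and the diversity of real lesion morphology. Passing the
benchmark therefore shows that the algorithms behave as designed under the
stated model — correct operators, correct subspace algebra, the expected
CNR/noise ordering — not that clinical image quality is reproduced.

## Benchmark conditions

The fixed-seed benchmark uses a 160×160 grid, 8 coils, 144 spokes binned 8
per frame (18 frames at 4.2 s), contrast arrival 30 s into the scan and 2%
RMS k-space noise. 144 spokes rather than the protocol's 288 keeps the
three-reconstruction comparison within a few minutes on one CPU; the
orderings it asserts (CNR: tissue-segment > GRASP > NUFFT; background
noise reversed) are direction-only claims and hold across seeds. The
denoiser runs at desk scale — 16 frame pairs at 32×32 for the training
contract, 48×48 for the temporal-fidelity check — reproducing the structure
of the published 900-dataset training, not its scale.

## Pharmacokinetics

`tcxm_forward` integrates the two-compartment exchange ODEs with `lsoda`
(relative tolerance $10^{-8}$; the system is stiff for small $v_p$), taking
the arterial input as a piecewise-linear interpolant on its native grid.
Limiting cases are handled explicitly: $PS = 0$ decouples the EES, $v_p = 0$
uses a quasi-steady plasma compartment, $F_p = 0$ returns zeros. The
independent check in the tests convolves the model's closed-form
biexponential impulse response at a 2 ms step and agrees to well under 0.1%.

Fitting is bounded Levenberg–Marquardt over $(v_e, v_p, F_p, PS)$ with
bounds $[10^{-4}, 1]$ on the fractions and $[10^{-4}, 10]\ \mathrm{min}^{-1}$
on the rates, five multi-starts with fixed seeds, and — importantly — a
finite-difference step (`epsfcn = 1e-8`) much larger than the ODE solver's
noise floor; with the default machine-precision step the Jacobian is garbage
and the optimizer stalls after two iterations. $K^{trans}$ is derived from
the fit via $F_p(1 - e^{-PS/F_p})$.

Signal-to-concentration conversion inverts the spoiled gradient-echo
steady-state equation with baseline-estimated $M_0$, tissue $T_{10}$ (1.5 /
1.4 / 1.3 s for malignant / benign / fibroglandular) and relaxivity
$r_1 = 4.5\ \mathrm{L\,mmol^{-1}s^{-1}}$ (gadobutrol-class); the conversion
model and relaxivity are package assumptions. Samples implying $R_1$ below
the pre-contrast rate are clipped to zero concentration and counted. The
population AIF averages onset-aligned curves (onset = first sample above 10%
of peak, a threshold robust to baseline noise) and is shifted to each case's
detected onset when applied. Bootstrap fitting averages a random 10% of the
voxels per replicate, 100 replicates, without replacement within a
replicate.

The analytic population AIF used to drive simulations is the standard
two-Gaussian-plus-sigmoidal-washout parameterization for a gadolinium
bolus, shifted to the injection time (30 s into the scan by default).

## The residual denoiser

The streak suppressor for 2-spokes-per-frame imaging is a residual network:
`n_conv_layers` 3×3 convolutions (default 10, with 64 channels) with ReLU
between them and output = input + correction, trained with Adam on an L2
loss between streaked 2-spoke reconstructions and fully sampled references,
on magnitude images normalized to the reference peak. Convolutions are
evaluated as im2col + BLAS products with hand-written backpropagation, so
training is deterministic under the spec seed. With all correction weights
zero the network is exactly the identity — the safe starting point the
residual design buys. In the full pipeline the denoiser is applied to the
low-resolution 2-spoke series *before* basis estimation, not to the final
high-resolution images: its job is to make the PCA bases trustworthy, and
any residual bias it introduces cannot leave the estimated subspace.

In simulation the fully sampled reference frame is the rendered object
itself, which is exact; `make_training_pairs(reference = "nyquist")`
instead reconstructs a Nyquist-rate spoke set, reproducing the structure of
a measured reference at the cost of adding the gridding operator's own
discretization noise to the targets. The network input is a single frame by
default; rise-time augmentation regenerates each training case's kinetics
from the dictionary, which is how 18 cases × 50 augmentations yield 900
training datasets.

## Known limitations

* 2D slices only; the 3D stack-of-stars geometry, partial Fourier and
  fat-saturation physics of the clinical protocol are out of scope.
* Coil maps are assumed known (simulation provides them); a sum-of-squares
  estimate from data is not implemented.
* The phantom's enhancement model shares its functional family with the
  fitted pharmacokinetic model, so parameter-recovery results exercise the
  fitting machinery, not model misspecification.
* Desk-scale denoiser training means the published fold-change magnitudes
  (which come from 55-patient clinical data) are not reproduced — only the
  directional claims are.
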