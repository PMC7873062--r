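---
title: "Diffusion kurtosis micro-imaging: models, pipeline and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion kurtosis micro-imaging: models, pipeline and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdki)
```

## The measurement and its models

A pulsed-gradient spin-echo (PGSE) experiment sensitises the MR signal to
water displacement. With gradient amplitude $G$, pulse duration $\delta$ and
pulse separation $\Delta$, the normalised signal under the narrow-pulse
approximation is the characteristic function of the ensemble average
propagator $P(R)$:

$$\frac{S(q)}{S(0)} = \int P(R)\, e^{2\pi i q R}\, dR,
  \qquad q = \frac{\gamma G \delta}{2\pi}.$$

Expanding $\ln S$ in cumulants of $P(R)$ and truncating after the fourth
cumulant gives the quadratic-exponential kurtosis model along one direction:

$$\ln\frac{S(b)}{S(0)} \approx -\,b\,D_{app}
  + \tfrac{1}{6}\,b^2 D_{app}^2 K_{app},$$

with $b = \gamma^2 G^2 \delta^2 \tau$ and the effective diffusion time
$\tau = \Delta - \delta/3$ (used because micro-imaging pulses are not
narrow: here $\delta/\Delta = 3.1/8.502$ ms). $K_{app}$ is the excess
kurtosis $\mu_4/\mu_2^2 - 3$ of the displacement distribution; for free
Gaussian diffusion it is zero and the model reduces to the mono-exponential
DTI form. Over a voxel, directional dependence is carried by the symmetric
diffusion tensor $D$ (6 unique elements) and the fully symmetric
fourth-order kurtosis tensor $W$ (15 unique elements):

$$D_{app}(n) = n^{T} D\, n, \qquad
  K_{app}(n) = \frac{MD^2}{D_{app}(n)^2}\sum_{ijkl} W_{ijkl}\, n_i n_j n_k n_l.$$

Two independent routes to kurtosis anchor the implementation. The *cumulant
route* (`excess_kurtosis_from_samples()`, `signal_from_propagator()`)
estimates $K$ directly from displacement samples or from the Monte-Carlo
characteristic function; for a scale mixture of Gaussians it has the closed
form $3\,\mathrm{Var}(D)/\bar D^2$. The *signal route* fits the
quadratic-exponential model to decay curves. The test suite requires the two
routes to agree — but only inside the expansion's radius of validity.
Numerically, for the 50/50 mixture of $0.5$ and $1.5\times10^{-3}$ mm$^2$/s
the truncated fit recovers the closed-form $K = 0.75$ to under 5% only while
$b\,\bar D\,K \lesssim 0.6$ (about $b \le 800$ s/mm$^2$ here); over the full
three-shell range the omitted higher cumulants bias $K_{app}$ low by roughly
a quarter. This is the same physics that makes a mono-exponential fit over an
extended b-range underestimate diffusivity, and both signs are asserted as
invariants rather than hidden.

### Fitting

`fit_dki_volume()` solves, per voxel, a linear least-squares problem in 22
parameters ($\ln S_0$, 6 elements of $D$, 15 elements of $MD^2 W$) with a
second pass weighted by the squared first-pass signal predictions — the
standard heteroscedasticity correction for log-linearised fits. $W$ is
recovered by dividing by $MD^2$ from the same fit (one iteration).
Constraints are post-hoc projections, never constrained optimisation, so
fitting stays linear and deterministic: directional $K_{app}$ is clamped to
$[0, 10]$ where evaluated, negative diffusion-tensor eigenvalues are clamped
to zero at the scalar-map stage, and both events are counted and reported.
Voxels with any nonpositive signal are excluded from fitting and flagged.

### Scalar maps

FA, MD, AD and RD come from the eigenvalues of $D$ (sorted descending,
negatives clamped first). MK is the arithmetic mean of $K_{app}(n)$ over a
deterministic spherical Fibonacci lattice (724 points by default; the
724/248-point pair agrees to better than 0.5% on every phantom voxel, which
the suite asserts), and KA is the population standard deviation of the same
directional samples. A variant normalised by MK exists behind
`ka_normalized = TRUE` but is not the default. MD/AD/RD maps carry a
conventional display window of $[0, 3\times10^{-3}]$ mm$^2$/s.

## The digital phantom

Real micro-dMRI data of this kind are not publicly deposited, so every stage
is validated against a synthetic phantom whose ground truth is known
exactly. The phantom emulates the acquisition geometry (96×128 in-plane
matrix at 78.125 µm, 0.781 mm slices, three shells at $b = 800/1800/2500$
s/mm$^2$ with 6/8/12 evenly spread directions and one b0 per shell) and the
anatomy schematically: concentric anisotropic shells for the optic-lobe
neuropils (retina, lamina, medulla, lobula), a chiasm slab of two fibre
populations interleaved voxel-by-voxel (checkerboard — deliberately *not*
intra-voxel crossing, which deterministic tensor tracking cannot resolve), a
central isotropic low-kurtosis blob, small mid-anisotropy blobs, a straight
tract bar for tracking geometry tests, and zero-signal air tubes standing in
for trachea.

Signals are generated from the truncated kurtosis model itself, so noiseless
fitting must return every parameter to numerical precision — this
round-trip is the pipeline's primary oracle, and the acceptance checks hold
it to $10^{-8}$ relative. A separate bi-exponential generator exists solely
so that the cumulant oracle can validate the fitters against signals *not*
produced by the fitted model. Region kurtosis levels are kept inside the
monotone-decay regime $b\,D_{app}K_{app} < 3$ at $b = 2500$, pairing high
kurtosis with low diffusivity as real neuropil does.

Design choices worth stating explicitly:

* **S0 texture.** The b0 signal carries a smooth multiplicative texture
  (±15%, fixed seed), as real tissue does through proton density and coil
  sensitivity. Texture is part of the ground truth — fits recover it
  exactly — and it gives rigid registration the irregular structure that
  purely geometric ring phantoms lack.
* **Trachea.** Air gives no MR signal, so tracheal tubes are zero-signal.
  The physical air region is one voxel wider than the *labelled* tube: the
  outermost air voxels are a partial-volume shell. Any interpolated FA gate
  lets a streamline take one step into the first zero-FA boundary voxel
  before terminating; only the labelled core is therefore asserted to
  contain no streamline points.
* **Noise.** Rician magnitude noise $\sqrt{(S+g_1)^2+g_2^2}$ with
  $g_i \sim N(0, \sigma^2)$. No SNR is printed for the emulated acquisition;
  the default $\sigma = 0.05\,S_0$ (b0 SNR ≈ 20) is an assumption,
  config-exposed. Artefact order follows acquisition physics: k-space
  truncation (Gibbs) first, then per-volume rigid misalignment, then
  magnitude noise.
* **Grid.** Default 96×128×35 matching the emulated scan; a 32×32×8 small
  mode is used throughout the tests and the acceptance script so the whole
  suite runs in minutes on one core. The small mode preserves voxel size,
  region topology and volume count.

What passing on this phantom does *not* show: robustness to susceptibility
distortion, exchange and restriction biophysics beyond the cumulant level,
intra-voxel fibre crossings, or anatomical realism of region shapes. Claims
about real tissue should be read with those limits in mind.

## Preprocessing

The chain runs denoise → unring → eddy, each stage disableable; with all
three off the data pass through bit-identically.

**Rician noise estimation.** With a background mask,
$\hat\sigma = \text{mean(background)}/\sqrt{\pi/2}$ (Rayleigh mean);
without one, the median local 3×3×3 standard deviation over low-signal
voxels, corrected by $\sqrt{(4-\pi)/2}$.

**Non-local means.** Patch-similarity weights
$\exp(-\max(d^2 - 2\sigma^2, 0)/h^2)$ with patch radius 1, search radius 3,
$h = \sigma$ by default (the cited method's parameters are not printed;
these are conventional). Averaging runs over squared magnitudes and the
Rician bias is removed as $\sqrt{\max(0, \mathrm{NL}(x^2) - 2\sigma^2)}$.
At $\sigma = 10\%$ of signal this reduces RMSE to truth by well over the 40%
the acceptance check requires. Reapplying the filter requires re-estimating
the (now much smaller) residual $\sigma$; reusing the original $\sigma$
over-subtracts the bias term.

**Gibbs unringing.** The local subvoxel-shift method: each 1-D line is
resampled at 64 candidate shifts in $(-0.5, 0.5)$ voxels via Fourier phase
ramps; per voxel the shift minimising total variation in a ±3-voxel window
is selected and the value linearly interpolated back to the grid. Applied
along both in-plane axes and averaged.

**Eddy / misalignment correction.** Registering diffusion-weighted volumes
to a b0 reference with normalized cross-correlation is unreliable on this
kind of data: tissue contrast inverts with diffusion direction, and
interpolation blur from candidate rotations systematically *raises* NCC by
suppressing unshared high-frequency content. The corrector is therefore
model-based, in the spirit of modern eddy tools: each volume is registered
to a leave-one-out model prediction of itself (mono-exponential in the
detection pass — low-order, so a grossly misaligned volume cannot corrupt
the predictions of the others; quadratic-exponential in refinement passes,
which adds the kurtosis curvature to the target's contrast). Leave-one-out
matters: a prediction fitted *with* the volume absorbs part of its own
misalignment and the recovered transform shrinks towards zero. The metric
resamples both images by half the candidate transform (cubic interpolation)
so resampling blur is symmetric; the optimiser is an exhaustive coarse
translation grid on a smoothed, downsampled pair followed by coordinate-wise
quadratic refinement — fully deterministic. Corrections below a deadband of
0.25 voxel / 0.75° are not applied: they sit at the registration noise
floor, add interpolation blur, and — because a reference-free volume set
has an unconstrained collective-motion mode — iterating them lets the whole
set drift. Corrected volumes are always resampled once from the original
data under the accumulated transform, and b-vectors are rotated by the
recovered rotation (the source protocol does not state whether its
b-vectors were rotated; rotating them is the defensible choice and is
flagged as an assumption).

Known limitation: a volume whose diffusion contrast is nearly azimuthally
symmetric about an axis carries no rotational information about that axis;
the estimator can then report a spurious rotation of a few degrees for that
volume. Injected misalignments are still recovered within 0.1 voxel and
0.3°, and aligned volumes' translations within 0.05 voxel, which the
acceptance suite asserts.

## Tractography

Deterministic Euler integration over the principal-eigenvector field with
the protocol's exact gates: FA threshold 0.15, turning angle ≤ 45° per step,
step 0.05 mm, kept length in [0.31, 50] mm, 5000 streamlines, cubic
interpolation. The alternative minimum length of 0.18 mm that the same
protocol lists in a neighbouring sentence ships as a preset
(`tracking_params(min_length_mm = 0.18)`); the discrepancy is recorded, not
resolved. Seeds are drawn uniformly at random from the FA-passing voxels
under a fixed RNG seed (the seeding policy is not printed; uniform random
within the mask emulates the common default), each seed grows
bidirectionally, and the angle gate applies to each consecutive segment
pair, not cumulatively. Interpolation sign-aligns each neighbouring
eigenvector with the incoming direction before blending, so antipodally
stored vectors never average towards zero; interpolation at exact voxel
centres reproduces stored vectors (Keys cubic convolution, not a smoothing
B-spline, precisely for this property). FA is gated at step points with the
same interpolator. Tracking runs on the kurtosis-fit-derived FA (whether the
original protocol tracked on a DTI sub-fit is unstated). Streamlines are
exchanged in the TrackVis `.trk` binary dialect (version 2, 1000-byte
header, voxel-mm coordinates); round-trips are exact to float32.

## ROI reporting

Medians of FA, MD, MK and KA are taken per ROI over voxels inside both the
ROI mask and the fit mask — voxels where the model could not be fitted are
excluded rather than counted as zeros, which would bias medians downward.
Medians use the even-count convention (mean of the central pair) and are
computed over the full 3-D mask, not slice-wise. The report renders with
ROIs as columns in the canonical order AL, CC, Rt, Me, MB, La, MN, Lox,
Ax_tk, and MD in $\times 10^{-3}$ mm$^2$/s notation. On the noisy phantom
the rank order of median FA matches the ground-truth order for every pair of
regions separated by more than 0.02 in true FA (the retina and chiasm differ
by less than 0.01 by construction and are allowed to tie).

## Reproducibility machinery

One pipeline seed fans out to per-stage seeds by a stable hash of the stage
name, so any stage can be reproduced in isolation. Identical configs hash
identically (`run_pipeline()` stamps the hash into its run log), reruns are
bit-identical, and every warning-worthy event — eigenvalue clamps, masked
voxels, empty tractograms — is counted in the log rather than silently
passed. Problem sizes in the tests and the acceptance script (32×32×8 grid,
248-point direction sets, 2×10^6 Monte-Carlo samples, 400–5000 streamlines)
were chosen as the smallest sizes at which the checked quantities are stable
to well within their tolerances.
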