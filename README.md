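# microdki

Diffusion kurtosis analysis for multi-shell micro-MRI of small brains, with
a ground-truth digital phantom.

Micro diffusion MRI can resolve the neuropil architecture of an insect
brain — retina, lamina, medulla, lobula complex, mushroom body, central
complex — at tens of micrometres, and infer the large axonal tracts that
connect them. Doing that quantitatively needs a full pipeline: gradient-table
handling and b-value arithmetic for a pulsed-gradient spin-echo (PGSE)
acquisition, denoising that respects Rician magnitude statistics,
Gibbs-ringing removal, eddy-current/misalignment correction, a diffusion
kurtosis fit, scalar maps, deterministic tractography and ROI reporting.
`microdki` implements that pipeline in R, end to end, and ships a synthetic
phantom with exactly known tensors so that every stage is testable without
access to scanner data.

## The model

Along a gradient direction $n$ with diffusion weighting
$b = \gamma^2 G^2 \delta^2 \tau$ (effective diffusion time
$\tau = \Delta - \delta/3$), the signal follows the quadratic-exponential
kurtosis model

$$\ln\frac{S(b)}{S(0)} \approx -\,b\,D_{app} + \tfrac16\, b^2 D_{app}^2 K_{app},$$

where $D_{app} = n^T D n$ is the apparent diffusivity and $K_{app}$ the
apparent excess kurtosis ($\mu_4/\mu_2^2 - 3$ of the displacement
distribution; 0 for free Gaussian diffusion). Voxelwise, the package fits
the diffusion tensor $D$ (6 parameters) and kurtosis tensor $W$
(15 parameters) by two-pass weighted linear least squares over all shells,
then derives FA, MD, AD, RD from the eigenvalues of $D$ and MK, KA as the
mean and standard deviation of $K_{app}$ over a dense direction set.
Streamline tracking integrates the principal eigenvector field with Euler
steps, gated by FA, turning angle and length.

## Worked example

Simulate the emulated three-shell acquisition (b = 800/1800/2500 s/mm²,
6/8/12 directions + 3 b0) on the small phantom with 2% Rician noise,
denoise, fit, derive maps, track, and extract ROI medians:

```r
library(microdki)
cfg <- pipeline_config(small = TRUE, sigma = 0.02, seed = 7L,
                       n_tracts_target = 500L, n_dir = 248L,
                       unring = FALSE, eddy = FALSE)
res <- run_pipeline(cfg)
#> phantom: 32x32x8 grid, 29 volumes
#> preprocess: denoise=TRUE unring=FALSE eddy=FALSE sigma=18.26
#> fit: 5728/8192 voxels (2464 masked, 1323 negative-eigenvalue)
#> maps: 2164 eigenvalue clamps
#> track: 500 streamlines kept
#> report: 36 cells

print(res$maps)
#> scalar_maps: 32 x 32 x 8; 5728 voxels in mask; 2164 eigenvalues clamped
#>   FA median 0.7383 range [0, 1]
#>   MD median 0.0007204 range [0, 0.001716]
#>   AD median 0.001446 range [0, 0.00377]
#>   RD median 0.0003351 range [0, 0.0009083]
#>   MK median 1.183 range [0, 7.626]
#>   KA median 0.9866 range [0, 4.82]

writeLines(render_report(res$report, "markdown"))
#> | sample | metric | AL | CC | Rt | Me | MB | La | MN | Lox | Ax_tk |
#> | --- | --- | --- | --- | --- | --- | --- | --- | --- | --- | --- |
#> | phantom | FA | 0.35 | 0.13 | 0.76 | 0.56 | 0.43 | 0.72 | 0.27 | 0.49 | 0.76 |
#> | phantom | MD | 0.55 x 10^-3 | 0.74 x 10^-3 | 0.79 x 10^-3 | ...
#> | phantom | MK | 1.46 | 0.45 | 1.14 | 1.72 | 1.33 | 1.12 | 1.54 | 2.13 | 1.14 |
#> | phantom | KA | 0.29 | 0.22 | 1.05 | 1.01 | 0.63 | 0.93 | 0.31 | 1.11 | 1.07 |
```

The masked voxels are background and air (no signal after Rician-bias
removal); negative-eigenvalue counts and clamps are reported rather than
silently fixed. The ROI medians reproduce the phantom's built-in ordering:
the highly directional retina (Rt), lamina (La) and axonal-tract chiasm
(Ax_tk) carry the highest FA, the isotropic central-complex-like region (CC)
the lowest — the qualitative fingerprint this kind of ex-vivo insect imaging
reports. Per-voxel results are available tidily:

```r
tidy(res$fit)       # one row per voxel: S0, 6 D elements, 15 W elements
glance(res$fit)     # one-row fit summary
tidy(res$tract)     # one row per streamline: points, length, seed
autoplot(res$maps, metric = "FA")   # slice raster
autoplot(res$tract)                 # streamline projection
write_trk(res$tract, "tracts.trk")  # TrackVis export
```

A thin command-line wrapper lives at `inst/cli/microdki.R`
(`Rscript microdki.R run --out outdir --sigma 0.02`).

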