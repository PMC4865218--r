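# prismct

Simulation and reconstruction toolkit for **hybrid spectral CT**: a scanner
whose detector array is mostly conventional energy-integrating elements
(EIDs) with a narrow **photon-counting** module (PCD) in the center. The PCD
rays resolve the X-ray spectrum into energy bins but cover only a central
*spectral field of view*; the EID rays cover the whole object but collapse
the spectrum into one grayscale reading. `prismct` reconstructs the full
multi-energy image from both, for researchers studying spectral CT
architectures, interior/exterior tomography and K-edge contrast imaging.

## The method

Let $X = [\mu_1, \dots, \mu_M]$ be the $N \times M$ matrix of per-bin
attenuation maps. PCD counts give per-bin line integrals on the central
rays, $A_c \mu_k = Y_{c,k}$ with $Y_{c,k} = -\ln(I_k / S_k)$. Each
polychromatic EID reading
$I_g = \sum_k S_k \exp(-[A_g \mu_k]_i)$ is linearized by a first-order
Taylor expansion around a current estimate $\tilde X$, producing one linear
equation per ray that couples all bins:

$$\sum_k \tilde I_i(E_k)\,[A_g \mu_k]_i = Y_{g,i}, \qquad
\tilde I_i(E_k) = S_k\,e^{-[A_g \tilde\mu_k]_i}.$$

Both data sets are fit jointly under the PRISM prior (prior rank, intensity
and sparsity model), $X = X_L + X_S$ with a nuclear-norm penalty
$\lambda_1\|X_L\|_*$ exploiting inter-bin correlation and an
$\ell_1$ penalty $\lambda_2\|X_S\|_1$ for sparse (e.g. K-edge contrast)
structure, solved by an extended ADMM whose inner cycle alternates a
conjugate-gradient data-fit solve, singular value thresholding, soft
thresholding and a multiplier update, and whose outer loop re-linearizes
around the improving estimate. The Taylor center is initialized by a
physics-based estimate: the photoelectric + Compton decomposition reduces
each EID reading to a monotone equation in the effective electron-density
path integral, which is inverted by bisection, reconstructed by CGLS and
expanded to all bins. See the vignette
(`vignettes/hybrid-spectral-ct.Rmd`) for the model, assumptions and all
numerical choices.

## Worked example

Simulate a hybrid scan of a synthetic abdomen phantom (water + bone, 8
energy bins over 30-120 keV), reconstruct, and score against the ground
truth:

```r
library(prismct)
geometry <- fanbeam_geometry(detector_count = 128, view_count = 60,
                             grid_n = 64, fov = 32)
spectrum <- make_spectrum(total_photons = 1e7)
maps     <- make_abdomen_phantom(64, seed = 1)
X_true   <- compose_spectral_images(maps, spectrum)
layout   <- hybrid_layout(geometry, peer = 1)   # half the array is PCD
proj     <- simulate_hybrid_scan(X_true, spectrum, geometry, layout)
init     <- initial_estimate(proj, geometry)
fit      <- run_algorithm1(proj, geometry, layout, init$X,
                           prism_params(outer_iterations = 200))
print(fit)
#> <prism_fit> 200 outer iterations; final max quadratic Taylor error
#> 7.43e-09 (worst bin), 1.64e-09 (median bin)
round(quality_report(fit$X, X_true), 4)
#>   bin psnr_db   ssim
#> 1   1 46.2446 0.9797
#> 2   2 55.3956 0.9975
#> 3   3 71.0540 1.0000
#> 4   4 65.3989 0.9996
#> 5   5 60.9742 0.9990
#> 6   6 59.1893 0.9985
#> 7   7 58.2708 0.9982
#> 8   8 57.7368 0.9980
```

The per-bin PSNR/SSIM compare each reconstructed mono-energy image with the
phantom truth over the whole image (not just the spectral FOV): quality
peaks in the middle bins where the tube spectrum concentrates its photons,
and the final quadratic Taylor errors certify that the linearization of the
grayscale data has converged. With `peer = 1` the spectral FOV covers only
the central ~9 cm of the 32 cm field, so most of what is scored here is
*exterior* spectral reconstruction carried by the EID data and the
low-rank + sparsity prior.

`run_experiment()` drives the study protocols (PEER sweep, Poisson-noise
study, gadolinium spot/strip position sweeps), and
`inst/cli/prismct.R` exposes `simulate`, `init-estimate`, `reconstruct`
and `evaluate` subcommands for shell use, reading a plain key-value config
and writing TIFF stacks, CSV diagnostics and JSON manifests.

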