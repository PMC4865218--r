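---
title: "Hybrid spectral CT: model, solver and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid spectral CT: model, solver and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The imaging problem

Photon-counting detectors (PCDs) resolve the energy of individual X-ray
photons and so deliver one sinogram per energy bin, but they are expensive
and count-rate limited. Energy-integrating detectors (EIDs) are cheap and
fast but collapse the whole spectrum into a single grayscale reading.
`prismct` models a pragmatic hybrid: a conventional full EID array with a
narrow PCD module in its center. The PCD rays cover only a central disc of
the object — the *spectral field of view* (FOV) — while the EID covers
everything. The reconstruction task is to recover the full multi-energy
image $X = [\mu_1, \dots, \mu_M]$ (one attenuation map per bin, stacked as
an $N\,\text{pixels} \times M\,\text{bins}$ matrix) from

* per-bin PCD counts on the central rays, and
* polychromatic EID intensities on all rays.

The PCD-to-EID extent ratio (`peer` in `hybrid_layout()`) fixes the module
width: the PCD occupies a fraction $\mathrm{PEER}/(1+\mathrm{PEER})$ of the
array. The ratio is defined as PCD length over EID length with the two
detector types partitioning the array, so `peer = 1` means half the array
is photon-counting; the `"full"` sentinel (complete PCD coverage) exists
for oracle tests. EID readings are available on *all* elements of every
view, as in a dual-source implementation where a conventional scan
accompanies the hybrid one.

## Forward model

Within each narrow bin the beam is treated as monochromatic at the bin
center $E_k$, so a PCD ray obeys Beer-Lambert per bin,
$I_k = S_k \exp(-[A x_k]_i)$, with $S_k$ the effective per-bin fluence
(tube spectrum times detector response, folded into one number) and $A$ the
fan-beam system matrix of intersection lengths. The EID reading is the sum
over bins:
$$I_{g,i} = \sum_{k=1}^M S_k \exp\!\big(-[A x_k]_i\big), \qquad
I = \sum_k S_k \;\text{(blank scan)}.$$

The simulator (`simulate_hybrid_scan()`) evaluates exactly this model, so
the noise-free EID reading equals the bin-sum of the noise-free PCD
intensities on every PCD ray to machine precision — a conservation identity
the tests pin down. Poisson noise, when requested, is drawn per bin and per
ray and summed for the EID; this matches the unweighted count-integration
form of the model above rather than an energy-weighted integrator, and
keeps the EID and PCD models consistent with each other.

## Taylor-linearized grayscale data

The EID equation is nonlinear in $X$. Around a current estimate
$\tilde X$ the model is expanded to first order, which yields one *linear*
constraint per ray coupling all bins:
$$\sum_k \tilde I_i(E_k)\, [A x_k]_i = Y_{g,i}, \qquad
\tilde I_i(E_k) = S_k e^{-[A \tilde x_k]_i},$$
$$Y_{g,i} = \sum_k \tilde I_i(E_k)\big(1 + [A \tilde x_k]_i\big) - I_{g,i}.$$

Two properties matter and are tested:

* **Exactness at the center.** If the data are noise-free and
  $X = \tilde X$ equals the generating image, the residual is identically
  zero (no linearization error at the expansion point).
* **Quadratic remainder.** Moving $X$ away from $\tilde X$ grows the
  residual quadratically (log-log slope 2), which is why the solver
  re-linearizes as it converges and why the per-bin maximum quadratic error
  $\max_i ([A(\tilde x_k - x_k)]_i)^2$ is the convergence diagnostic.

## PRISM regularization and the nested solver

Energy channels of the same object are strongly correlated — with two
basis materials the noiseless $X$ has rank two — while K-edge contrast
features are spatially sparse. The prior rank, intensity and sparsity model
(PRISM) splits $X = X_L + X_S$ and solves

$$\min_{X, X_L, X_S} \|A_c X - Y_c\|_F^2 + \|\mathcal B X - Y_g\|^2
+ \lambda_1 \|X_L\|_* + \lambda_2 \|X_S\|_1
\quad \text{s.t. } X_L + X_S = X,$$

with $A_c$ the PCD-ray projector applied per bin, $\mathcal B$ the
weighted bin-coupling grayscale operator above, and $Y_c$ the per-bin log
transform of the PCD counts. `run_algorithm1()` implements the nested
scheme: each outer iteration re-linearizes ($\tilde X \leftarrow X$,
update $\tilde I$ and $Y_g$), resets the multiplier
$D = X_L + X_S - X$, then runs five inner ADMM cycles of

1. data-fit solve for $X$ (augmented with $\lambda\|X_L+X_S-X+D\|_F^2$),
2. $X_L \leftarrow \mathrm{SVT}(-X_S + X - D,\ \lambda_1/2\lambda)$,
3. $X_S \leftarrow \mathrm{Soft}(-X_L + X - D,\ \lambda_2/2\lambda)$,
4. $D \leftarrow D + X_L + X_S - X$.

The returned image is $X_L + X_S$. Resetting $D$ every outer iteration
follows the nested scheme literally; because the linearization (and hence
the inner problem) changes at every outer step, the stale multiplier is
discarded by default, and `reset_multiplier = FALSE` preserves it for
comparison.

### Numerical choices

* **Inner solver.** The data-fit subproblem is solved inexactly by 10
  conjugate-gradient steps on the normal equations, warm-started at the
  previous iterate. Because the PCD rays are a subset of the EID rays, one
  forward and one adjoint projector application serve both data terms in
  each CG step. The quadratic objective is non-increasing along CG
  iterates, which the tests verify.
* **Grayscale conditioning.** The intensities $\tilde I$ are of order
  $10^6$ photons while the log-domain PCD residuals are of order one. By
  default the grayscale equation (weights and target alike) is scaled by
  $1/I$, which brings both residuals to comparable magnitude so the
  default weights $\lambda = 1$, $\lambda_1 = \lambda_2 = 0.01$ act at a
  sensible scale; `prism_params(grayscale_weight =)` overrides it. Scaling
  both sides of a least-squares row rescales that term's relative weight
  only, not its solution set.
* **Proximal maps.** `svt()` uses the thin SVD of the $N \times M$ matrix
  ($M = 8$, so this costs little); both proximal operators are verified
  against brute-force minimization of their defining objectives.
* **Stopping.** Fixed outer count (1000 by default; 200 in the scaled-down
  study profile) plus an early exit when the data-fit residual changes by
  less than `tol` (default $10^{-8}$) between outer iterations.
* **No positivity constraint.** Attenuation is physically nonnegative, but
  the solver does not clip inside ADMM (the sparse part is signed by
  design); clipping is left to post-processing if desired.
* **Count floor.** Zero PCD counts would make the log transform infinite;
  counts are floored at 0.5 photons — half the smallest observable count —
  before the log.

## Physics-based initial estimation

A good Taylor center accelerates and stabilizes the outer loop. The
attenuation is decomposed into photoelectric and Compton parts,
$$\mu(r, E) = \mu_\mathrm{eff}(r)\,\Big(c_\mathrm{ph}\,
Z_\mathrm{eff}^3\, \epsilon^{-3.5} + N_A f_\mathrm{kn}(\epsilon)\Big),
\qquad \mu_\mathrm{eff} = \rho Z / A,$$
with $\epsilon = E/511\,\mathrm{keV}$ and $f_\mathrm{kn}$ the
Klein-Nishina function. With $Z_\mathrm{eff}$ fixed to water (7.42), each
EID reading becomes a strictly decreasing function of the single unknown
$t = \int \mu_\mathrm{eff}\,dl$, inverted by safeguarded bisection (the
monotonicity asserted on a grid before each solve, the bracket grown
geometrically). The $t$ sinogram is inverted by 50 CGLS iterations (a
least-squares solve avoids committing to any fan-beam filtered
backprojection convention), and the per-bin images follow by the rank-one
expansion above. The estimate is deliberately biased wherever the material
is not water-like — worst in the lowest-energy bins, where the
photoelectric term dominates — and that bias is precisely what the PRISM
iterations correct.

Two conventions are worth flagging. The photoelectric cross section is
implemented with an overall $Z^4$ per atom (hence $Z_\mathrm{eff}^3$ after
one factor of $Z$ is absorbed into $\mu_\mathrm{eff}$). The standard
Sauter-Heitler Born result scales as $Z^5$ per atom; the $Z^4$ convention
is used consistently in both the material model and the initial
estimation, so the simulation/estimation roundtrip is self-consistent
regardless, and swapping the exponent would only rescale the (already
approximate) effective-Z model. The classical electron radius is taken as
$2.818 \times 10^{-13}$ cm. For $\epsilon < 10^{-4}$ the Klein-Nishina
formula is evaluated by its low-energy series to avoid catastrophic
cancellation (the closed form loses about four digits at
$\epsilon = 10^{-6}$ in double precision).

## The synthetic phantom and what it does (not) show

The study phantom is generated, not measured: an elliptical water body
(semi-axes 12.8 cm by 9.6 cm) with smooth random soft-tissue texture, a
spine-plus-ribs set of bone ellipses (2-4 bone features, fractions up to
0.95), and optional gadolinium contrast (K-edge 50.207 keV, jump factor 5,
density 0.005 g/cm^3 — a dilute contrast agent giving unit-fraction pixels
a few times 0.01 cm^-1) as four spots and one strip, all deterministic
given a seed. It emulates the *structure* of an abdominal dual-energy
study: two-material composition (so the noiseless multi-energy image has
rank two, rank three with gadolinium), realistic attenuation magnitudes
(water-like tissue about 0.19 cm^-1 at 60 keV), and beam hardening through
20-30 cm of tissue.

It does **not** emulate anatomical detail, partial-volume mixtures beyond
two materials per pixel, scatter, detector cross-talk, charge sharing or
pulse pile-up. Passing tests therefore demonstrate the correctness and
self-consistency of the simulation-reconstruction chain and the behavior
of the algorithm under its stated model — not clinical image quality.

The tube spectrum is a built-in filtered Kramers shape,
$w(E) \propto (E_\mathrm{tube} - E)/E \cdot \exp(-(E_f/E)^3)$ with
$E_\mathrm{tube} = 120$ keV and filtration scale $E_f = 55$ keV,
integrated over 8 bins spanning 30-120 keV and normalized to $10^7$
photons per ray. The filtration term plays the role of beam-shaping
hardware and places the fluence maximum in the 3rd-5th bins, as in a
filtered 120 kVp spectrum; a `table` model accepts measured per-bin
weights (CSV import/export via `read_spectrum_csv()`).

## Geometry

Fan beam, source 50 cm from the iso-center, flat equi-spaced detector
50 cm on the other side, 512 elements over 70 cm, 180 views uniform over
360 degrees (opposing rays are kept, not deduplicated). The system matrix
is materialized sparsely by Siddon ray tracing, making the back projector
the exact adjoint (dot-product identity to $10^{-10}$). With this
geometry the scan FOV has radius $50 \sin(\arctan(35/100)) \approx 16.5$
cm, so the default image square is 32 cm wide — the largest inscribed in
the scan FOV; the geometry constructor rejects image fields that are not
fully covered by every view.

## Study profiles and problem sizes

The package's quantitative study profile (`experiment_config()`) uses a
64 x 64 grid, 60 views, 128 detectors, 8 bins, noise-free data, PEER = 1
and 200 outer iterations — the scale at which the headline figures
(per-bin PSNR above 45 dB mid-spectrum and on average; SSIM at or above
0.98 in at least six of eight bins; final maximum quadratic Taylor errors
below $10^{-3}$ and below their initial values) are reproduced by
`scripts/acceptance.R` and the test suite. Qualitative-trend experiments
(PEER sweep, exterior-error growth with distance from the spectral FOV,
strip-versus-spot contrast diffusion) run on a 48 x 48 grid with 48 views,
96 detectors and 60 outer iterations. Exterior error is summarized over
body pixels in 2.5 cm radial shells spanning 7.5 cm beyond the spectral
FOV boundary — beyond that the shells leave the body and contain mostly
air. Gadolinium feature error is the mean squared error over the feature's
own support, and image-wide PSNR/SSIM are computed over the entire image,
not only the spectral FOV.

```{r example}
library(prismct)
geometry <- fanbeam_geometry(detector_count = 128, view_count = 60,
                             grid_n = 64, fov = 32)
spectrum <- make_spectrum(total_photons = 1e7)
maps     <- make_abdomen_phantom(64, seed = 1)
X_true   <- compose_spectral_images(maps, spectrum)
layout   <- hybrid_layout(geometry, peer = 1)
proj     <- simulate_hybrid_scan(X_true, spectrum, geometry, layout)
init     <- initial_estimate(proj, geometry)
fit      <- run_algorithm1(proj, geometry, layout, init$X,
                           prism_params(outer_iterations = 200))
quality_report(fit$X, X_true)
```

## Known limitations

* 2D fan beam only; no cone beam, no detector blur, no scatter.
* The effective-Z initial model ignores K-edges entirely, so contrast
  agents start from a poor estimate; exterior gadolinium recovery relies
  wholly on the low-rank/sparse prior and degrades with distance from the
  spectral FOV.
* The data terms are unweighted least squares (no Poisson likelihood), so
  very low-count bins are treated the same as high-count ones apart from
  the $\tilde I$ weighting inherent in the linearized model.
* The sparse system matrix is kept in memory; at 256 x 256 with the full
  512-detector, 180-view geometry it occupies a few hundred MB. Larger
  problems call for a matrix-free projector, which this package does not
  provide.
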