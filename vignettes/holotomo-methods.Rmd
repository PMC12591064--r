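---
title: "Models and methods in holotomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in holotomo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holotomo)
```

## The physical model

Propagation-based phase-contrast imaging records the free-space
self-interference of a coherent X-ray wavefront downstream of a weakly
absorbing sample. The sample multiplies the incident wave by a transmission
function; under the homogeneous-object assumption (a single material, so
absorption tracks phase) this is

$$T(x) = \exp\bigl((B + i)\,\varphi(x)\bigr), \qquad B = \beta/\delta \ge 0,$$

with the sign convention that matter denser than the reference medium
retards the wave: $\varphi \le 0$. After propagation over a distance $z$ the
detector sees $I = |\mathcal{D}_F(T)|^2$, a *hologram*, normalized to mean
level 1 by empty-beam division.

All propagation in the package happens in pixel units, governed entirely by
the dimensionless **Fresnel number** per pixel and per axis,
$F = \Delta x^2 / (z \lambda)$. The discrete propagator is the unitary
Fourier multiplier

$$H(\nu) = \exp(-i \chi(\nu)), \qquad
  \chi(\nu) = \pi\left(\frac{\nu_x^2}{f_x} + \frac{\nu_y^2}{f_y}\right),$$

with frequencies in cycles/pixel and per-axis Fresnel numbers $f_x, f_y$
(astigmatism, e.g. from anisotropic magnification, is just $f_x \neq f_y$).
The sign of the kernel exponent is a convention; every retrieval formula in
the package is written against this choice and the pair is locked together
by a linearization-consistency test: for $|\varphi| \le 10^{-3}$ the
simulated contrast $I - 1$ must match the linear model
$2(\sin\chi + B\cos\chi)\hat\varphi$ to 1% — with the wrong relative sign
this fails catastrophically, so a sign regression cannot pass the suite.

Cone-beam acquisitions at source-sample distance $z_{01}$ and
source-detector distance $z_{02}$ map onto this parallel-beam picture by the
Fresnel scaling theorem: magnification $M = z_{02}/z_{01}$, effective pixel
$\Delta x / M$ and effective distance $z_{12}/M$. `coneBeamGeometry()`
stores SI units internally and accepts the beamline's customary mm / µm /
keV; the conversion constant is fixed at $hc = 12.3984193$ keV·Å. Printed
magnifications are rounded half-away-from-zero.

## Phase retrieval

Two regimes call for different algorithms.

**Direct contrast** ($F \approx 1$, edge enhancement): single-distance
Fourier filters. `paganin()` inverts the transport-of-intensity model for a
homogeneous object, $\varphi = \ln \mathcal{F}^{-1}[\hat I /(1 +
\chi/B)]/(2B)$. `generalizedPaganin()` replaces $\chi$ by its discrete
Laplacian counterpart $(1 - \cos 2\pi\nu)/(2\pi f)$ per axis — the constant
is fixed by requiring the small-$\nu$ Taylor limit to reproduce $\chi$
exactly, which the tests verify; near Nyquist the discrete form damps
strictly less, reducing over-smoothing on the pixel grid.
`modifiedBronnikov()` inverts the weak pure-phase limit $2\sin\chi \approx
2\chi$ with a constant regularizer $\alpha$ (default $10^{-3}$, dimensionless
on the $\chi$ scale) filling the DC singularity; since a pure phase object
conserves flux, the retrieved mean is undetermined and comparisons are made
up to a constant offset. `bronnikovAidedCorrection()` uses that estimate to
divide out the phase-contrast factor and return an attenuation-only image;
the correction denominator is clipped at 0.1 to avoid division blow-ups.

**Holographic regime** ($F \ll 1$, many fringes): multi-distance methods on
a common pixel grid (rescale with `rescaleFresnel()` first; there is no
in-retrieval registration).

* `ctfRetrieve()` solves the weak-object normal equations in closed form,
  $\hat\varphi = \sum_d s_d \hat g_d / (2\sum_d s_d^2 + \alpha(\nu))$ with
  $s_d = \sin\chi_d + B\cos\chi_d$ and $g_d = I_d - 1$. The two-level
  regularization $\alpha(\nu)$ interpolates between `alphaLow` (default
  $2\times10^{-5}$) below the first CTF maximum and `alphaHigh` (default
  $3\times10^{-5}$) above it, through an erf crossover of width 0.5 centred
  at $\chi = \pi/2$. Writing the crossover as a function of $\chi$ rather
  than $|\nu|$ keeps it consistent under astigmatism. The denominator
  normalization (the factor 2) is chosen so these weights are meaningful
  relative to $s^2 \in [0, 1 + B^2]$.
* `ctfConstrained()` splits the same quadratic from the constraint
  projection and runs accelerated ADMM with restart ($\eta = 0.999$,
  $\rho = 1$); the returned phase is the final projection iterate, so
  non-positivity and support hold *exactly*. With no active constraint the
  closed-form solution is returned directly, since a scalar-$\rho$ ADMM
  converges arbitrarily slowly at frequencies where the data weight
  vanishes. Pixel-wise priors carry real information exactly where the data
  are weak — single-distance acquisitions (unfilled CTF zeros), low photon
  counts, missing low frequencies. On noiseless two-distance data the
  unconstrained solution is already essentially optimal and projection bias
  can slightly *increase* the L2 error; the test-suite asserts the benefit
  in the underdetermined setting where the method is actually used.
* `tikhonovRetrieve()` minimizes the full nonlinear objective
  $\sum_d \tfrac12 \| |\mathcal{D}_{f_d}(e^{(B+i)\varphi})| - \sqrt{I_d}
  \|^2 + \tfrac1{2N}\|\sqrt{\alpha}\hat\varphi\|^2$ with the adaptive
  proximal gradient method, warm-started from the projected CTF solution.
  The amplitude (not intensity) residual is a deliberate convention: its
  gradients are better conditioned at low counts. Gradients are hand-derived
  (Wirtinger calculus) and validated against central finite differences at
  $10^{-5}$ relative tolerance. In the weak-object limit this objective
  linearizes exactly to the CTF normal equations with the same $\alpha$, so
  the two methods are mutually consistent.
* `tikhonovTV()` adds the smoothed total-variation penalty
  $\tau \sum \sqrt{|\nabla\varphi|^2 + \epsilon^2}$ (forward differences,
  periodic boundaries, default $\epsilon = 10^{-2}$); $\tau = 0$ reduces
  bit-for-bit to the plain solver.
* `alternatingProjections()` is the classic error-reduction loop between
  the per-distance modulus constraints and the homogeneous-object set,
  with a log-space least-squares object step
  $\varphi = (B \ln|T| + \arg T)/(B^2 + 1)$ and uniform averaging over
  distances.

## First-order solvers

`pgmAdaptive()` implements a proximal gradient method with
Barzilai-Borwein spectral steps and a nonmonotone (window 10) backtracking
line search using the quadratic upper-bound acceptance test; a pure
sufficient-decrease test was tried and rejected because it collapses the
step near nonsmooth optima. `fista()` adds Nesterov momentum with
gradient-based adaptive restart. `admmAccel()` is the accelerated ADMM with
restart parameter $\eta = 0.999$ and optional residual balancing. Defaults:
tolerance $10^{-6}$ relative iterate change, 100 iterations. The solvers
only see callables (value, gradient, prox / closed-form x-update), so any
model modification plugs in without touching them; `checkGradient()`
provides the finite-difference check used throughout the tests.

## Tomography and alignment

The parallel-beam projector is ray-driven (bilinear interpolation, step 0.5
pixel, sampling grid symmetric about the rotation centre so conjugate rays
agree), with the rotation axis at detector column $(N-1)/2 +$ `corOffset`
and per-projection detector shifts applied as cyclic Fourier shifts. Two
backprojectors coexist, as in mainstream tomography toolboxes: the exact
scatter adjoint (for SIRT and for the $\langle Av, p\rangle = \langle v,
A^{\mathsf T}p\rangle$ property, which holds to floating precision) and a
smoother pixel-driven gather used by `fbp()`. FBP uses the standard
band-limited discrete ramp kernel with optional Shepp-Logan or Hann
apodization and weight $\pi/N_{\mathrm{angles}}$; a full-turn angle list
averages conjugate rays automatically through the same weighting. Cone-beam
data are handled in the effective parallel geometry throughout — at
magnifications of several hundred the cone angle is far below a detector
pixel per row, which is the same approximation the phase-retrieval chain
already makes.

The centre of rotation comes from `findCorOpposing()` (mirror one of two
opposing projections about the pixel-centre axis and register; the offset is
half the detected shift, a relation made exact by mirroring about
$(N-1)/2$) or, more robustly, from `findCorSinogram()`, which registers two
half rotations of a sinogram en bloc and thereby averages over all angles;
repeated over detector rows it also yields the axis tilt (reported as a
diagnostic, not compensated by the projectors). `reprojectionAlign()`
iterates reconstruct - reproject - register with block-mean binning and a
Gaussian band-pass before registration. The band-pass matters: a pure
high-pass leaves the reconstruction's streak noise dominating the
correlation peak and stalls the alignment around 0.7 px residual, while
subtracting a wide blur (default $40/\mathrm{binning}$) *and* applying a
narrow one (default 1 binned pixel) reaches about 0.2 px on the same data.
Updates are damped by `damping` (default 1; the detected shift is applied in
full) and iteration stops when the largest update falls below 0.1 px.
Recovered shift trajectories are only determined up to a global offset plus
an in-plane object translation (a $\cos\theta$ / $\sin\theta$ component of
the horizontal shifts), so residuals are quoted after projecting out that
gauge.

Ring artifacts: `removeRingsAdditive()` subtracts the deviation of sinogram
column means from a running-median smooth — the median, unlike a moving
average, removes an isolated stripe column exactly instead of leaking a
1/width fraction of it into the reference. `removeRingsWavelet()` performs
an $l$-level Daubechies decomposition (own periodic filter-bank
implementation, perfect reconstruction tested to $10^{-10}$; db5 by
default), damps the angle-constant content of each level's stripe band
(lowpass along angle, highpass along detector) with
$1 - e^{-k^2/(2\sigma^2)}$ in band-index units, and reconstructs. Defaults
$l = 4$, $\sigma = 1$.

## The simulator and what passing tests mean

`simulateHolograms()` closes the loop: project a phantom (shared code path
with the reconstruction projector, deliberately, so projector defects
surface in two independent test families), scale to a peak phase
`phiMax`, apply the homogeneous-object transmission, propagate per
distance, square, add Poisson noise at `photonCount`, and optionally shift
each projection by uniform per-projection jitter. Defaults are a deeply
holographic two-distance scan: Fresnel numbers $2.44\times10^{-4}$ and
$1.98\times10^{-4}$ (the second distance already rescaled to the common
pixel grid), $B = 0.035$, regularization weights $2\times10^{-5}$ /
$3\times10^{-5}$, `phiMax` 0.3 rad (moderate phase: inside the nonlinear
methods' domain, at the edge of CTF linearity) and $10^4$ counts/pixel, a
typical synchrotron exposure.

The simulator emulates coherent propagation, photon statistics and rigid
trajectory errors. It does **not** emulate partial coherence or source
blur, detector point-spread and nonlinearity, beam-hardening-like spectral
effects, or non-rigid sample dynamics — passing tests therefore demonstrate
algorithmic correctness and self-consistency, not robustness to every
artifact of real beamline data.

Digital phantoms are evaluated on a binary voxel grid. The discrete Radon
and Fresnel oracles presume band-limited inputs, so accuracy benchmarks
(filtered back-projection error, grid-refinement consistency, the
end-to-end correlation) band-limit the phantom with a one-pixel Gaussian
first; on the raw binary phantom the voxelization itself already costs
about 4.5% RMSE in a projector-independent way (an external reference
implementation reproduces the same number to three digits).

## Problem sizes and numerical choices

The validation suite runs at sizes a laptop handles in minutes:
$256^2$ images for the retrieval benchmarks (weak-object CTF error < 2%,
strong-phase Tikhonov strictly better than CTF), $256^2$ / 400 angles for
the FBP oracle, $128^3$ / 180-201 angles for alignment (±10 px jitter
recovered to < 0.5 px RMS at binning 4) and for the full pipeline, which
chains simulation (photon noise $10^4$, jitter ±10 px), per-projection
nonlinear Tikhonov retrieval (20 iterations, CTF-initialized), reprojection
alignment, wavelet ring filtering and ramp-filtered FBP to a phantom
correlation above 0.95. The nonlinear retrieval is used there because at
`phiMax` 0.3 the CTF linearization bias alone caps the correlation at about
0.945 — the nonlinear refinement is precisely what removes that bias.

Degenerate inputs are defined, not rejected: flat holograms retrieve zero
phase; an empty constraint set short-circuits to the closed form; a zero
sinogram reconstructs to zero; the empty background mask degrades to
division by the smoothed hologram. Faulty-pixel repair never flags the
outermost border row/column (the clamped 3×3 window biases the median
there) and is idempotent on its own output. The biharmonic background
solver runs conjugate gradients to $10^{-8}$ relative residual with a
symmetric-boundary (mirror-padded) Gaussian of width 5 px pinning the
background outside the support.

## Known limitations

Single-threaded CPU implementation; no GPU path. No cone-beam (FDK)
reconstruction — high-magnification data are treated in the effective
parallel geometry. No phase unwrapping, no simultaneous two-parameter
(phase and attenuation) retrieval without the homogeneity assumption, no
non-translational per-projection registration, and the tilt estimated from
multi-row sinograms is reported but not compensated. Stack I/O is
uncompressed float32 TIFF only.
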