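---
title: "Models and methods behind bioconvect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bioconvect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioconvect)
```

# The system

Suspensions of swimming microalgae such as *Chlamydomonas reinhardtii* are
denser than their medium and swim, on average, against gravity (negative
gravitaxis). In a closed, shallow compartment the up-swimming flux balances
diffusion and the cells pile up beneath the top wall in an *inverse
sedimentation profile*, an exponential with decay length $D/v$ where $v$ is
the mean swimming speed and $D$ the effective translational diffusion
constant of the cells. The stratification is top-heavy: when buoyancy
overcomes viscous and diffusive dissipation the layer overturns into
*bioconvection* — stationary convective plumes into which gyrotaxis (the
balance between the gravitational righting torque and the viscous torque of
the local vorticity) focuses the cells.

What makes the photoactive system special is the control knob: under
anaerobic conditions the single-cell motility depends on the incident light
intensity, so the suspension can be switched between a stable inverted
profile and a convecting state purely by light. `bioconvect` implements both
sides of the quantitative analysis: stochastic single-cell simulators and a
transmitted-light image synthesizer on the generation side; spectral
pattern quantification, densitometry, tracking/motility statistics and PIV
on the analysis side; and the continuum stability theory that connects them.

# Single-cell model

Cells follow overdamped Langevin dynamics in a 2D plane (the horizontal
plane of a shallow chamber, or the vertical mid-plane of a thin side-view
cell). With heading $\mathbf{p} = (\sin\theta, \cos\theta)$ ($\theta$ =
tilt from vertical):

* position: $\dot{\mathbf r} = u\,\mathbf p + \mathbf u_f +
  \mathbf v_{\rm sed}$,
* orientation: $\dot\theta = -\sin\theta/(2B) + \omega/2 + \xi$, with
  $\langle\xi(t)\xi(t')\rangle = 2 D_r\,\delta(t-t')$,
* run-and-tumble: Poisson-timed complete reorientations at the tumble rate
  (the new heading is uniform on the circle; published turn-angle
  distributions are not available for this organism under these conditions,
  so full randomization is the least-informative choice).

In 2D the orientation is a single angle, so integrating $\theta$ directly
is exactly equivalent to the vector Euler–Maruyama update with per-step
renormalization and preserves $|\mathbf p| = 1$ to machine precision; the
package uses the angle form. The equilibrium of the deterministic
orientation equation under uniform vorticity is $\sin\theta = B\omega$, the
classic gyrotactic balance, and is recovered by the simulator to five
decimal places (see the test suite).

Walls reflect positions and leave the heading unchanged; a reflected swimmer
re-enters the bulk when its heading turns. Optional short-range steric
repulsion (a truncated-parabola force within one cell diameter) is provided
but off by default; hydrodynamic cell–cell interactions are out of scope.

Two consequences worth knowing:

* A pure run-and-tumble swimmer has $C_v(t) = v^2 e^{-t/\tau_c}$ *exactly*
  in this discretization, with $1/\tau_c = \lambda_{\rm tumble} + D_r$, so
  the velocity-autocorrelation machinery can be validated against programmed
  truth.
* For motility assays the domain default should be generous (the examples
  use 20 mm boxes) because wall reflections add a velocity-decorrelation
  channel at rate $\approx v P/(\pi A)$ that real assays do not have — in
  experiments cells are tracked in a central field of view far from walls,
  with tracks simply ending at the FOV edge. A 3 mm reflective box would
  bias $\tau_c$ downward by roughly 20%.

# Image formation and densitometry

Transmitted-light frames are rendered with the Beer–Lambert law: with $k$
cells in a pixel column, $I_T = I_0\,e^{-\alpha' k}$ with a single lumped
per-cell attenuation $\alpha'$ (the true attenuation coefficient and path
length are never separable in these data), followed by Gaussian PSF blur,
optional Gaussian or Poisson (shot) noise, and quantization to the camera
bit depth.

The inverse map needs neither $I_0$ nor $\alpha'$: the relative density

$$\frac{n - n_0}{\alpha} = \langle \log I_T \rangle - \log I_T$$

cancels the incident intensity inside the averaging mask, is exactly
zero-mean over the mask, and is invariant under global intensity rescaling
(both are enforced as exact tests). Natural logarithms are used; the base
only rescales the unknown $\alpha$. Pixels quantized to zero are clipped to
half a count before the log (with a warning) instead of being discarded.
No scattering correction is applied; in dense regions the method
underestimates the density, a known property of optical-density proxies.

Vertical profiles are row means of these maps; the sedimentation length is
a three-parameter fit $a\,e^{z/L} + b$ by Levenberg–Marquardt, since the
map is affine in the unknown density. Flat profiles return an
infinite-length marker rather than failing. Fits are most reliable when the
column spans at least ~3 decay lengths; the tests use such geometries.

# Spectral pattern quantification

Each frame $J$ is multiplied by a 2D Hamming window $H$ to limit spectral
leakage and Fourier transformed; the spectrum is $|\mathcal F[J\,H]|$
normalized by the scalar window gain $\sum H$. A pointwise division by
$|\mathcal F[H]|$ would divide by near-zeros everywhere off DC, so the
scalar gain is used; it preserves peak locations and relative amplitudes.
The frame mean is subtracted before windowing so a constant image has an
identically zero spectrum (otherwise the window smears DC into low-$q$
bins). Top-view stacks are azimuthally averaged into annuli one fundamental
wide; side-view stacks are column-averaged to a 1D signal first.
Wavenumbers are in cycles per length, so the pattern wavelength is simply
$\lambda = 1/q_{\max}$.

Dynamics come from $S_{\max}(t)$, the in-band spectral maximum: the onset
$t_{\rm on}$ is the first time $S_{\max}$ exceeds the baseline mean plus
$k$ baseline SDs for $m$ consecutive frames ($k = m = 5$ by default — no
published rule exists, and these values make the detection robust against
single-frame noise while costing at most a couple of frames of latency);
the growth rate $\omega$ is the least-squares slope of $\log S_{\max}$
between onset and the first crossing of half the final plateau, beyond
which nonlinear saturation bends the curve. Because the spectrum is a
magnitude (not a squared power), $S_{\max}$ is proportional to the pattern
amplitude and the fitted slope estimates the amplitude growth rate
directly. The peak search band excludes $q < 2/(\text{image width})$
(window leakage) and the upper half of the resolved band.

The synthetic `generate_growing_pattern()` fixture emulates exactly this
model — uniform frames, then a sinusoid whose amplitude grows exponentially
from onset and saturates — with defaults at the observed scales (wavelength
1.7 mm, growth rate 0.04 1/s, onset 220 s, 3 fps). What it does *not*
emulate: pattern drift, coarsening, defects and the spatial inhomogeneity
of real onsets, so round-trip tests demonstrate estimator correctness, not
robustness to those effects.

# Tracking and motility statistics

Detection is a gradient-direction circular Hough transform: edge pixels
vote along $\pm$ their gradient direction at each candidate radius
(2.6–5.5 µm by default, the accepted size range for *C. reinhardtii*), the
blurred accumulator is normalized by the expected perimeter count and
maximized over radii, and non-maximum suppression enforces a minimum
separation. Direction voting suppresses the tangency artifacts that plain
ring-kernel convolution produces between neighbouring cells.

Linking minimizes total frame-to-frame displacement under a hard gate (no
link longer than 7 µm between consecutive frames at 30 fps, the standard
setting for this assay). The gate decomposes each frame pair into small
connected components, each solved exactly by a Jonker–Volgenant
shortest-augmenting-path assignment with a non-assignment cost equal to the
gate, so feasible links are always preferred and fragmentation is an
outcome, not an error. The solver is verified against brute-force
permutation enumeration.

The velocity autocorrelation uses frame-to-frame displacement velocities,
averaged over all cells and, assuming stationarity, over all time origins
within each track (FFT-based, sample-weighted; pooling origins only reduces
variance relative to the fixed-origin definition). The motility fit
$C_v = v^2 e^{-t/\tau_c}$ runs over lags up to three times a 1/e-crossing
initial estimate. The diffusion constant is reported twice — the closed
form $v^2\tau_c/d$ with $d = 2$, and the Green–Kubo trapezoidal integral of
the measured $C_v$ — and a >10% discrepancy is flagged; the integral is
truncated at the largest measured lag, so it needs several $\tau_c$ of lags
to agree with the closed form.

# PIV

Frames are preprocessed with CLAHE (tile size 1.5 mm by default; fewer than
2×2 tiles fall back to a global clipped equalization). The flow field comes
from multipass FFT cross-correlation with progressive window refinement
(0.24, 0.19, 0.15 mm windows; 0.12, 0.10, 0.07 mm steps — the third step
read as 0.07 mm, since a step larger than its window is not meaningful),
discrete window offsetting between passes in place of full image-warping
window deformation (a documented simplification that preserves accuracy on
smooth fields), and 3-point Gaussian subpixel peak interpolation.

Two numerical details matter for accuracy on the broad correlation peaks
this data produces: windows are zero-padded to twice their size (killing
circular wraparound) and the correlation map is divided by the exact pixel
overlap count, which removes the triangular weighting that otherwise biases
broad peaks toward zero displacement — without it, half-pixel displacements
are systematically underestimated by ~0.1–0.2 px. The search is restricted
to a quarter window (the standard one-quarter rule); vectors with a low
first-to-second peak ratio are replaced by the local median and flagged,
and final-pass displacements beyond half a window are marked invalid. On
dense speckle fixtures the recovered uniform shifts are accurate to well
under 0.1 px in the mean.

The velocity–density coupling curve pools co-located (vertical velocity,
relative density) samples and bins by density. The reporting convention of
0.5 density units per bin is kept as the default even though it is coarse
against the typical observed range (±0.4); pass `bin_width = 0.05` for a
resolved curve. In gyrotactic plumes the curve slopes downward: cells
accumulate where the flow descends.

# Continuum theory

The dimensionless numbers are
$R = g\,\phi\,(\Delta\rho/\rho)\,h^3/(\nu D)$ (bioconvective Rayleigh
number), $w = v h/D$ (scaled swimming speed), $G = B D/h^2$ (gyrotaxis
number) and $Sc = \nu/D$ (Schmidt number). With the reference parameters of
the 3D experiments ($\phi = 0.021$, $\Delta\rho/\rho = 0.05$, $h = 1$ mm,
$\nu = 10^{-6}\,\mathrm{m^2/s}$, $D = 1.6\times10^4\,\mathrm{\mu m^2/s}$)
the package computes $R \approx 640$. $D$ itself comes from the measured
motility, $D = v^2\tau_c/2$ in 2D, and is essentially light-independent
($46^2\cdot15/2 \approx 92^2\cdot 2.4/2 \approx 1.6\times10^4$), so light
moves only $w$ (5.75 at the anaerobic plateau to 11.5 at high light for the
2 mm compartment — the 2 mm height reproduces the reported speed values exactly
and is used here; the reorientation time $B$ is unknown for this organism,
and 3 s is used as a working default wherever gyrotaxis must be
quantified).

Nondimensionalizing lengths by $h$, time by $h^2/D$ and density by its
column mean, the model solved here is

$$\frac{1}{Sc}\frac{D\mathbf u}{Dt} = -\nabla p + \nabla^2\mathbf u -
R\,n\,\hat z, \qquad
\frac{\partial n}{\partial t} = -\nabla\cdot\left(n\mathbf u + w\,n\,
\mathbf p - \nabla n\right),$$

with the quasi-static orientation closure $p_x = G\,\omega$ (clamped at
$|p_x| = 1$), $p_z = \sqrt{1 - p_x^2}$ — valid when $B$ is small against
the flow time scale, which holds throughout the regime studied. The
momentum equation is the standard Boussinesq form with cells denser than
the medium (buoyancy $-R\,n\,\hat z$); the pressure is eliminated by the
stream-function–vorticity formulation.

## Linear stability

The base state is the exponential inverse-sedimentation profile,
$n_s \propto e^{w z}$ normalized to unit column mean. Normal modes
$e^{iqx + \sigma t}$ reduce the linearized system to a generalized
eigenvalue problem in the vertical velocity amplitude $W(z)$ (clamped,
no-slip: $W = W' = 0$) and density amplitude $N(z)$ (no-flux:
$N' = w N$), discretized with second-order central differences (fourth
derivative via clamp ghosts). `linear_growth_rate()` returns the eigenvalue
of largest real part; `critical_rayleigh()` brackets and bisects the $R$
where it crosses zero at each $q$ and minimizes over a log-spaced $q$ grid
with local refinement (default search band 0.1–20 cycles/mm).

The solver has a sharp independent check: as $w \to 0$ the problem reduces
to Rayleigh–Bénard convection between rigid walls with *insulating*
(fixed-flux) boundaries, whose critical Rayleigh number is 720 with
$q_c \to 0$ — and the solver converges to $R_c\,w \to \approx 730$,
$q_c \to$ the bottom of the scan band (the residual 1–2% is the finite
scan floor and grid). The fixed-temperature value 1708 is *not* the right
limit here because cell number, unlike temperature, cannot be clamped at a
wall.

At the study conditions ($B = 3$ s, $h = 2$ mm) the solver gives
$R_c(w = 5.75) \approx 490$ and $R_c(w = 11.5) \approx 1.76\times10^3$:
the measured $R = 640$ falls *between* them, so the same suspension is
convectively unstable at the low-light plateau and stable at high light —
the light-switchable instability, reproduced from first principles. At the
3D-compartment conditions ($R = 640$, $h = 1$ mm) the fastest-growing mode
has a wavelength of about 1.2 mm, the observed millimetre scale.

Two published asymptotic statements are *not* reproduced by this model and
are left as red acceptance checks rather than absorbed: the quartic scaling
$R_c \propto w^4$ (the solver measures $R_c(11.5)/R_c(5.75) \approx 3.6$,
consistent with the boundary-layer estimate "sub-layer Rayleigh number
$R/w^2 \approx$ const", and the result is grid-converged), and the near-$w$
independence of the fastest mode at fixed $R$ (the fastest mode tracks the
sub-layer scale $\propto 1/w$ here). Both cited statements likely rest on a
different Rayleigh-number or length convention for the deep-layer
sub-problem; with $B$ unknown the absolute $R_c$ cannot be pinned down
experimentally either. The qualitative mechanism — $R_c$ grows with $w$, so
lowering the light (hence $v$ and $w$) drops $R_c$ below the fixed $R$ — is
exactly what the solver shows.

## Nonlinear solver

`simulate_bioconvection_2d()` integrates the same model in a periodic
lateral strip with rigid top and bottom. Per lateral Fourier mode, the
Poisson solve for $\psi$, the implicit (backward-Euler) diffusion of
$\omega$ and $n$, and the Thom wall-vorticity coupling are assembled into
small dense per-mode matrices factorized once per time step size — making
the stiff viscous dynamics ($Sc = 62.5$) unconditionally stable — while
advection, swimming and buoyancy are explicit donor-cell upwind fluxes
under a CFL cap (the step halves and the operators refactor if the cap is
hit). The flux form with zero wall faces conserves the total cell number to
machine precision (the acceptance suite demands 1e-6 over 1000+ steps) and
upwinding keeps $n \ge 0$. The run starts from the *discrete* steady
profile of the upwind operator (so growth/decay measurements are not
contaminated by initial adjustment) plus either seeded broadband noise or a
single lateral mode; the per-step mode amplitude is logged, which is how
the sign of the linear growth rate is cross-checked against this
independent discretization on multiple $(R, q)$ pairs. Default grids of
$48^2$–$64^2$ resolve the supercritical plumes used in the tests; the
boundary-layer scale $1/w$ sets the resolution requirement at larger $w$.

# Pipeline

`run_pipeline()` executes configured stages (simulate → render → spectrum /
density / motility / PIV → theory) with per-stage seeds derived from one
global seed by a fixed counter scheme, writes standard-format artifacts
(trajectory CSV, multi-page TIFF with JSON sidecars, CSV tables, JSON
reports) and a manifest with parameter hashes; identical configs give
identical manifests (timestamps aside), and `resume = TRUE` reuses cached
stages whose hashes match. `validate_against_theory()` injects measured
motility into the suspension parameters and compares $R$ against the
critical value. A thin command-line wrapper lives in
`inst/scripts/bioconvect-pipeline.R`.

# Problem sizes used in the checks

The shipped tests and the acceptance script are sized to what the analyses
need, not more: motility recovery uses 300–1500 cells for 60 s at 30 fps
(the recovered $v$ is within ~1% and $\tau_c$ within ~4% of programmed
truth at 1500 cells); the spectral round trip uses the full 900 s recording
at 3 fps and 256×256 px frames; stability scans use 48–96 vertical grid
points (the $R_c$ values above change by <0.5% from 64 to 128 points); the
nonlinear solver runs on $32^2$–$48^2$ grids. The inverse-sedimentation
check uses a weak-bias gyrotactic swimmer engineered for a 20 µm/s drift
and $D \approx 1.6\times10^4\,\mathrm{\mu m^2/s}$, i.e. a decay length of
800 µm in a 2 mm column, fitted away from one persistence length of each
wall.

# Known limitations

* Hydrodynamic cell–cell interactions (declared but unspecified in the
  underlying model) are not implemented; steric repulsion is optional and
  crude.
* The quasi-static orientation closure drops $\partial_t \mathbf p$; for
  large $B$ or fast flows a dynamic orientation field would be needed.
* Beer–Lambert densitometry saturates in dense plumes (no scattering
  model), so plume cores are underestimated.
* The PIV measures *cell* flow (swimming plus advection), not fluid flow;
  the two are not decomposed.
* Absolute densities are never calibrated: all densitometry is relative to
  the compartment mean, in units of the unknown attenuation scale.
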