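---
title: "Anisotropic Womersley flow: model, numerics and design choices"
author: "awflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anisotropic Womersley flow: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awflow)
```

## The model

Classical Womersley flow is the exact solution for fully developed
pulsatile flow of a Newtonian fluid in a rigid, straight circular tube:
a time-periodic axial pressure gradient drives a purely axial velocity
field $u_z(r,t)$, and the azimuthal velocity is identically zero. Blood,
however, is a dense suspension whose red cells deform and align under
arterial shear, which gives the bulk stress tensor off-diagonal
components that a scalar viscosity cannot represent. `awflow` implements
the minimal extension that captures this: the two relevant shear
stresses are tied to the two strain rates through a $2\times 2$
kinematic-viscosity matrix,

$$
\begin{pmatrix}\tau_{zr}\\ \tau_{\theta r}\end{pmatrix}
= \rho
\begin{pmatrix}\nu_{zz} & \nu_{z\theta}\\
               \nu_{\theta z} & \nu_{\theta\theta}\end{pmatrix}
\begin{pmatrix}\partial_r u_z\\
               \partial_r u_\theta - u_\theta/r\end{pmatrix},
$$

with the dimensionless ratios $\beta = \nu_{z\theta}/\nu_{zz}$,
$\gamma = \nu_{\theta z}/\nu_{zz}$, $\delta =
\nu_{\theta\theta}/\nu_{zz}$. The isotropic limit is $\beta=\gamma=0$,
$\delta=1$. The flow remains axisymmetric and fully developed
($u_r = 0$, $\partial_\theta = 0$, rigid wall), so geometry cannot
generate secondary motion: any swirl is produced by the constitutive
coupling alone.

Per pressure harmonic $h$ (frequency $h\,\omega_0$), the dimensionless
momentum equations for the complex amplitudes are

$$
i h \alpha^2 \hat U_z = a_h + L_0 \hat U_z + \beta L_1 \hat U_\theta,
\qquad
i h \alpha^2 \hat U_\theta = \gamma L_0 \hat U_z
  + \delta L_1 \hat U_\theta,
$$

with $L_0 f = f'' + f'/r$, $L_1 f = f'' + f'/r - f/r^2$, Womersley
number $\alpha = R\sqrt{\omega_0/\nu_{zz}}$, velocity scale
$U_0 = |G_0| R^2/(\rho\,\nu_{zz})$ built from the steady pressure
gradient, and $a_h$ the harmonic gradient amplitudes (so $a_0 = 1$ for
the bundled physiological records). The model is linear per harmonic;
the nonlinearity re-enters only in the quadratic post-processing
(Lamb vector, forces), which is therefore always evaluated on the
synthesized real-valued time-domain fields.

Key derived fields: vorticity $\omega_\theta = -\partial_r u_z$,
$\omega_z = (1/r)\,\partial_r(r u_\theta)$; the reduced radial Lamb
component $\ell_r = u_\theta \omega_z - u_z \omega_\theta$ (the whole
velocity–vorticity coupling of this geometry); the transverse force
density $f_r = \rho\,\ell_r\,U_0^2/R$; and the pillbox-integrated
endothelial load $F_{EC}(t) = A_{EC}\int_{R-\delta_{EC}}^{R}
|f_r|\,dr$.

## Numerical method

**Discretization.** The radial interval $[0,1]$ carries
Chebyshev–Gauss–Lobatto nodes stored in ascending order (centerline
first, wall last), so that the near-wall pillbox is a contiguous slice
at the end of the node vector. The derivative matrix uses the
trigonometric CGL formula with the negative-sum trick for the diagonal;
both choices keep rounding noise small at the production order
$N = 150$. $L_0$ and $L_1$ are assembled directly from $D$ and $D^2$;
their singular centerline rows are populated with the regular symmetric
limits ($2f''(0)$ and $\tfrac32 f''(0)$), a choice that is inert in the
solver because those rows are always replaced by boundary conditions.

**Harmonic solve.** Each harmonic is an independent dense complex
$2(N{+}1)\times 2(N{+}1)$ block system solved by LU factorization, with
four rows replaced: no-slip at the wall for both components,
$d\hat U_z/dr(0)=0$ (symmetry) and $\hat U_\theta(0)=0$ (regularity) at
the centerline. A reciprocal-condition check guards against singular
assemblies. The steady anisotropic problem has the closed form
$\hat U_\theta = (c/3)(r^2 - r)$ with
$c = (\gamma a/\delta)/(1 - \beta\gamma/\delta)$, which the test suite
uses as a hand-derived oracle, alongside an independent second-order
finite-difference discretization of the same equations.

**Validation branch.** The isotropic benchmark is the Bessel-form
solution $\hat U_z \propto 1 - J_0(\lambda r)/J_0(\lambda)$. Consistency
with the $e^{+i\omega t}$ convention of the solver requires
$\lambda^2 = -i h \alpha^2$, i.e. the branch
$\lambda = i^{3/2}\sqrt{h}\,\alpha$; the $e^{i\pi/4}$ branch solves the
complex-conjugate (time-reversed) problem and matches only at $t = 0$.
$J_0$ at complex argument is evaluated by power series, which is
accurate to ~$10^{-13}$ relative for $|z| \le 25$ (the series is
capped at $|z| = 40$, where cancellation has cost about seven digits);
a quadrature of the integral representation serves as its independent
oracle in the tests. At $N = 150$ the solver matches the closed form to
better than $10^{-13}$ in $L^\infty$ over $\alpha \in [3, 20]$.

**Quadratures.** The pillbox integral interpolates $\ell_r$
barycentrically onto a uniform subgrid of at least 64 points inside
$[R-\delta_{EC}, R]$ and applies the composite trapezoid rule; the bulk
velocity uses the same interpolate-then-trapezoid approach on 2001
points over the full radius. Both agree with adaptive quadrature of the
interpolant to $10^{-6}$ relative or better in the tests.

**Precision floor.** Successive grid refinement on a six-harmonic
physiological case (thoracic aorta, $\beta=\gamma=0.1$, evaluated at
peak phase $t^*=0.25$) drives the pointwise residual against an
$N = 180$ reference to its double-precision floor by about $N = 100$.
That floor is a few times $10^{-13}$, not smaller: the assembled
harmonic systems have condition numbers of order $10^3$ after row
scaling, so the LU forward error is bounded below by roughly
$\mathrm{cond}\times\varepsilon\,\|u\| \approx 10^{-13}$. Sin-form
differentiation matrices, equilibration and iterative refinement were
all evaluated and do not move this floor materially; claims of
residuals below $10^{-14}$ are not reproducible in double precision
for this system.

## Parameters and defaults

| Parameter | Default | Units | Meaning / why |
|---|---|---|---|
| `N` | 150 | – | collocation order; grid-independent from ~100 |
| `Nt` | 256 | phases | resolves 6 harmonics and their quadratic products with margin |
| `beta`, `gamma` | 0.1 | – | upper end of the plausible cross-coupling range $[-0.1, 0.1]$ |
| `delta` | 1 | – | azimuthal/axial viscosity ratio, range $[0.9, 1.1]$ |
| `rho` | 1050 | kg/m³ | blood density |
| `omega0` | $2\pi\cdot 1.2$ | rad/s | fundamental cardiac frequency (~72 bpm) |
| `nu_zz` | 3.4955e-6 | m²/s | calibrated: see below |
| `G0` | 1 | Pa/m | free scale; see below |
| `A_EC` | 1e-10 | m² | endothelial footprint, 100 µm² |
| `V_EC` | 1e-16 | m³ | endothelial volume, 100 µm³ ($\delta_{EC}$ = 1 µm) |

**Calibrated viscosity.** The six bundled arterial records fix pairs
$(R, \alpha)$; with $\omega_0 = 2\pi\cdot1.2$ rad/s, the single value
$\nu_{zz} = \omega_0 (R/\alpha)^2 = 3.4955\times10^{-6}\,$m²/s
reproduces all six Womersley numbers from the radii to two decimals
(e.g. aortic root: $7.5398\times(0.015/22.03)^2 = 3.496\times10^{-6}$).
It is a back-derived effective value, about 10–20% above typical
whole-blood kinematic viscosity, and is flagged as such; all entries
are overridable through the `scales:` configuration block.

**The pressure-gradient scale is free.** Dimensionless solutions never
read the physical scales. Dimensional forces scale as $G_0^2$ (through
$U_0^2$), and $G_0$ is not constrained by the bundled records, so
absolute picoNewton magnitudes are configuration-dependent. The package
therefore treats orderings, distributions, ratios and spectra of the
forces as the meaningful outputs, and the test suite asserts exactly
the $G_0^2$ scaling rather than any absolute value.

## Design choices where the design was open

* **Dissipativity of a non-symmetric tensor.** Positive-definiteness is
  imposed on the symmetric part (equivalently $\delta > 0$ and
  $\delta > (\beta+\gamma)^2/4$ after normalization), because that is
  the condition guaranteeing non-negative dissipation
  $s^\top S s > 0$ for every strain state $s$.
* **Harmonic indexing.** The six amplitudes of each arterial record are
  read as $h = 0..5$. Every record starts with exactly 1.00, which is
  forced by the normalization $a_0 = 1$ when $U_0$ is built from the
  steady gradient; under an $h = 1..6$ reading the universal leading
  1.00 would be an unexplained coincidence and $U_0$ would lose its
  definition.
* **Phase convention.** Record amplitudes are real cosine coefficients;
  a negative entry flips the phase by $\pi$.
* **Single-ratio sweeps.** Sweeps and physiological runs parameterized
  by one "anisotropy ratio" use $\beta = \gamma$ with $\delta = 1$.
  Swirl is generated only through $\gamma$ (it enters the azimuthal
  equation as $\gamma L_0 \hat U_z$), so a sweep in which swirl vanishes
  at the zero of the swept parameter forces $\gamma$ to vary with it;
  tying $\beta$ to it keeps the tensor symmetric.
* **Mono-harmonic convention.** Single-frequency runs use $h = 1$,
  $a_1 = 1$, all other amplitudes zero.
* **Bulk velocity for the geometric bound.** The curvature-driven
  transverse force bound $f_{r,c} = \rho u^2 (1+\kappa)/R$ uses the
  instantaneous area-averaged axial velocity
  $2\int_0^1 u_z\,r\,dr$ (not the centerline value), including its
  steady component. A mean-subtracted variant
  (`subtract_mean_bulk = TRUE`) is provided because the outcome of the
  dominance comparison is strongly sensitive to this convention — see
  the limitations below.
* **Steady component of dominance spectra.** The $1/h$ inertial filter
  is undefined at $h = 0$, so dominance spectra report harmonics
  $h \ge 1$ of the (full) force signals.
* **Stokes-layer prefactor.** $\delta_{W,h} = \sqrt2/(\sqrt h\,\alpha)$
  uses the classical Stokes-layer $\sqrt2$; the prefactor is a reporting
  convention only and never enters the solver.
* **Minimum grid order.** `cgl_grid()` accepts $N \ge 2$; $N = 2$ gives
  the textbook three-node grid $\{0, \tfrac12, 1\}$, useful only for
  inspection.

## What the bundled conditions emulate — and what they do not

The six-record registry spans viscous-dominated (brachial,
$\alpha = 2.94$) to inertia-dominated (aortic root, $\alpha = 22.03$)
regimes with six-harmonic pressure-gradient waveforms; this is the
study-condition set used by all physiological protocols, at
$\beta = \gamma = 0.1$, $\delta = 1$. The model is rigid-walled,
straight, axisymmetric and linear per harmonic, with constant
coefficients: it does not represent wall compliance, curvature- or
branching-induced secondary flow (curvature appears only as the scaling
bound above), shear-thinning, viscoelastic memory, yield stress, or the
cell-free layer resolved as a structure. Passing tests therefore
establish correctness of this constitutive mechanism in its idealized
setting, not a quantitative prediction for any real artery.

## Observed behavior of the solution family

Two structural facts about the model, established by the package's own
sweeps and worth stating because they shape expectations:

* Under fixed dimensionless forcing ($a = 1$, $h = 1$), the peak swirl
  amplitude $\max_r|\hat U_\theta|$ is a monotone decreasing function
  of $\alpha$: it is largest in the quasi-steady limit (where it
  approaches the closed form, $\approx 0.0084$ at $\beta=\gamma=0.1$)
  and decays like $\alpha^{-2}$ once the oscillatory layer forms. The
  peak axial vorticity behaves the same way. Re-scalings of the
  velocity normalization shift the curves but do not create an interior
  maximum in $\alpha$ for these observables; the swirl peak *location*,
  by contrast, moves from $r/R = 0.5$ (quasi-steady) toward the wall
  ($r/R \approx 0.94$ at $\alpha = 25$) and is nearly independent of
  $\beta$.
* In the thin pillbox the near-wall expansion gives
  $\ell_r \approx d\,[s_z(t)^2 + s_\theta(t)^2]$ with $d$ the distance
  from the wall and $s_j$ the wall strains — a sign-definite quantity.
  Consequently $F_{EC}(t)$ of an $H$-harmonic waveform is band-limited
  to $2H$: the quadratic structure doubles the forcing band (the
  "frequency-doubling cascade"), and the rectification adds nothing
  beyond it.

## Known limitations

* The grid-refinement residual floor is $\mathcal{O}(10^{-13})$ in
  double precision (see above); tighter agreement would need extended
  precision or a better-conditioned formulation.
* The dominance comparison between the anisotropic force and the
  curvature bound depends strongly on the bulk-velocity convention:
  with the steady component included, the geometric bound's spectrum is
  dominated by steady–oscillatory cross-terms and exceeds the
  anisotropic amplitudes at all harmonics for the default
  configuration; with the mean removed the two mechanisms are within a
  factor ~2 of each other across harmonics. The package reports both;
  neither convention is privileged by the model itself.
* Absolute force magnitudes in newtons require a physically measured
  $G_0$, $A_{EC}$ and $V_{EC}$; the defaults are order-of-magnitude
  placeholders and results should be read comparatively.
* `bessel_J0c()` is a series implementation restricted to
  $|z| \le 40$; it is an oracle for validation, not a general
  special-function library.

## Problem sizes used by the automated checks

The test suite solves at $N = 150$ for the production-resolution
checks (validation over $\alpha = 3..20$, the $\alpha$-sweep at steps
of 0.25, six-artery forces at $N_t = 256$) and at $N = 24..100$ for
unit-level oracles; the full suite completes in well under a minute on
one CPU. These sizes are the package's production defaults, chosen so
that every reported quantity sits on its numerical plateau.
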