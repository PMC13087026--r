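# awflow — anisotropic Womersley flow and near-wall transverse forces

Pulsatile blood flow in a straight, rigid artery is classically
described by Womersley's solution, in which the velocity field is purely
axial and the only wall load is the axial shear traction. Real blood is
a dense red-cell suspension whose stress response is direction
dependent. `awflow` solves the minimal extension of the Womersley
problem that admits this: a 2×2 tensorial kinematic viscosity

    [ tau_zr     ]         [ nu_zz      nu_ztheta     ] [ du_z/dr            ]
    [ tau_thetar ] = rho * [ nu_thetaz  nu_thetatheta ] [ du_th/dr - u_th/r  ]

couples axial and azimuthal shear, so a purely axial pulsatile pressure
gradient generates swirl `u_theta`, axial vorticity `omega_z`, and a
radial inertial force given by the reduced Lamb vector

    ell_r = u_theta * omega_z - u_z * omega_theta,     f_r = rho * ell_r,

all of which vanish identically in the isotropic limit
(`beta = gamma = 0`, `delta = 1`, with `beta = nu_ztheta/nu_zz`,
`gamma = nu_thetaz/nu_zz`, `delta = nu_thetatheta/nu_zz`).

Per pressure harmonic `h` the dimensionless equations

    i*h*alpha^2 * Uz = a_h + L0 Uz + beta  * L1 Ut
    i*h*alpha^2 * Ut =       gamma * L0 Uz + delta * L1 Ut

(`L0 f = f'' + f'/r`, `L1 f = f'' + f'/r - f/r^2`, Womersley number
`alpha = R*sqrt(omega0/nu_zz)`) are discretized by Chebyshev–Gauss–
Lobatto collocation and solved by direct LU with boundary conditions
imposed by row replacement (no-slip at the wall; symmetry and
regularity at the centerline). Post-processing reconstructs real
time-domain fields by Fourier synthesis, integrates `|f_r|` over an
endothelial-scale near-wall "pillbox" control volume to get the
transverse load `F_EC(t)`, computes wall traction, force ratio/angle
diagnostics, harmonic force spectra, Kruskal–Wallis statistics across a
bundled registry of six physiological arterial waveforms, and compares
the constitutive force spectrum against a curvature-driven geometric
bound under a 1/h inertial low-pass filter.

The intended audience is researchers in cardiovascular biomechanics and
hemodynamic modelling who need a controlled, geometry-free baseline for
how constitutive anisotropy — as opposed to vessel curvature — shapes
multidirectional near-wall forcing.

## Worked example

```r
library(awflow)

## solve one mono-harmonic case at alpha = 8, anisotropy 0.1
g      <- cgl_grid(150)
ratios <- anisotropy_ratios(beta = 0.1, gamma = 0.1, delta = 1)
sol    <- solve_harmonic(g, alpha = 8, h = 1, ratios, a_h = 1)
max(Mod(sol$Utheta))          # 0.000450766  (peak swirl, units of U0)
peak_swirl_location(8, 0.1)   # 0.803053     (r/R of the swirl maximum)

## a physiological artery: carotid waveform, six harmonics
case <- solve_artery("Carotid", beta = 0.1, N = 150, Nt = 256)
f    <- ec_force(case$field, case$scales)
f
#> Endothelial force series: Nt = 256, mean F_EC = 1.259e-08 pN, max = 2.212e-08 pN

## validation against the Bessel-form classical solution
run_validation(alpha_list = c(3, 10, 20), N = 150)
#>   alpha   linf_error
#> 1     3 4.644896e-14
#> 2    10 1.043436e-15
#> 3    20 1.166602e-16
```

The swirl amplitude is in units of the velocity scale
`U0 = |G0| R^2/(rho*nu_zz)`; the absolute force in pN scales with the
square of the configurable pressure-gradient scale `G0` (default
1 Pa/m), so force values are meaningful comparatively — across
arteries, harmonics and parameter settings — rather than absolutely.

The command-line front end exposes the same protocols:

```sh
Rscript inst/cli/awflow.R validate --N 150 --out out/
Rscript inst/cli/awflow.R forces --artery Carotid --beta 0.1 --out out/
Rscript inst/cli/awflow.R reproduce-all --out out/
```

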