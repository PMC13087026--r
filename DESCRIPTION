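Package: awflow
Title: Anisotropic Womersley Flow and Near-Wall Transverse Force Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spectral solver for pulsatile flow of an anisotropic Newtonian
    fluid in a rigid straight circular vessel (an anisotropic extension of
    classical Womersley flow). A tensorial viscosity couples axial and
    azimuthal shear, so that a pulsatile axial pressure gradient generates
    swirl, axial vorticity and a radial Lamb-vector inertial force that are
    identically zero in the isotropic solution. The coupled harmonic
    equations are discretized by Chebyshev-Gauss-Lobatto collocation and
    solved harmonic by harmonic with boundary conditions imposed by row
    replacement. Post-processing tools reconstruct time-domain fields by
    Fourier synthesis, compute vorticity and the reduced Lamb vector,
    integrate the transverse force density over an endothelial-scale
    near-wall control volume, and compare the constitutive force spectrum
    against a curvature-driven geometric bound under inertial low-pass
    filtering. A registry of six physiological arterial pressure-gradient
    waveforms, validation against the classical Bessel-function Womersley
    solution, parameter sweeps, grid-independence assessment and
    rank-based statistics complete the analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
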