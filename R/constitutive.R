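#' Anisotropy ratios of the viscosity tensor
#'
#' The 2x2 viscosity tensor of the anisotropic constitutive law is
#' parameterized by three dimensionless ratios relative to the axial
#' viscosity \eqn{\nu_{zz}}:
#' \deqn{\beta = \nu_{z\theta}/\nu_{zz}, \quad
#'       \gamma = \nu_{\theta z}/\nu_{zz}, \quad
#'       \delta = \nu_{\theta\theta}/\nu_{zz}.}
#' The isotropic limit is `beta = gamma = 0`, `delta = 1`. Physiologically
#' plausible ranges for blood are `beta, gamma` in \[-0.1, 0.1\] and
#' `delta` in \[0.9, 1.1\].
#'
#' Dissipativity requires the symmetric part of the normalized tensor
#' \eqn{[[1, \beta], [\gamma, \delta]]} to be positive-definite, i.e.
#' \eqn{\delta > 0} and \eqn{\delta > (\beta+\gamma)^2/4}.
#'
#' @param beta dimensionless ratio \eqn{\nu_{z\theta}/\nu_{zz}}.
#' @param gamma dimensionless ratio \eqn{\nu_{\theta z}/\nu_{zz}}.
#' @param delta dimensionless ratio \eqn{\nu_{\theta\theta}/\nu_{zz}}; must
#'   be positive.
#' @return An object of class `"anisotropy_ratios"`: a list with elements
#'   `beta`, `gamma`, `delta`.
#' @examples
#' anisotropy_ratios()              # isotropic
#' anisotropy_ratios(0.1, 0.1, 1)   # symmetric cross-coupling
#' @export
anisotropy_ratios <- function(beta = 0, gamma = 0, delta = 1) {
  stopifnot(is.numeric(beta), is.numeric(gamma), is.numeric(delta),
            length(beta) == 1L, length(gamma) == 1L, length(delta) == 1L,
            is.finite(beta), is.finite(gamma), is.finite(delta))
  if (delta <= 0)
    stop("delta (nu_thetatheta/nu_zz) must be positive, got ", delta)
  if (delta <= (beta + gamma)^2 / 4)
    stop("dissipativity violation: symmetric part of the normalized ",
         "viscosity tensor has a non-positive eigenvalue ",
         "(requires delta > (beta+gamma)^2/4; here delta = ", delta,
         ", (beta+gamma)^2/4 = ", (beta + gamma)^2 / 4, ")")
  structure(list(beta = beta, gamma = gamma, delta = delta),
            class = "anisotropy_ratios")
}

#' @export
print.anisotropy_ratios <- function(x, ...) {
  cat("Anisotropy ratios: beta =", x$beta, " gamma =", x$gamma,
      " delta =", x$delta, "\n")
  invisible(x)
}

#' Anisotropic viscosity tensor
#'
#' The constitutive law of the flow model relates the two relevant shear
#' stresses to the two strain rates through a 2x2 kinematic-viscosity
#' matrix:
#' \deqn{\begin{pmatrix}\tau_{zr}\\ \tau_{\theta r}\end{pmatrix} = \rho
#'   \begin{pmatrix}\nu_{zz} & \nu_{z\theta}\\ \nu_{\theta z} &
#'   \nu_{\theta\theta}\end{pmatrix}
#'   \begin{pmatrix}\partial_r u_z\\ \partial_r u_\theta -
#'   u_\theta/r\end{pmatrix}.}
#' The symmetric part of the matrix must be positive-definite so that the
#' mechanical dissipation is non-negative for every strain state.
#'
#' @param nu_zz axial kinematic viscosity (m^2/s), positive.
#' @param nu_ztheta cross viscosity coupling azimuthal strain into axial
#'   stress (m^2/s).
#' @param nu_thetaz cross viscosity coupling axial strain into azimuthal
#'   stress (m^2/s).
#' @param nu_thetatheta azimuthal kinematic viscosity (m^2/s), positive.
#' @return An object of class `"viscosity_tensor"`.
#' @export
viscosity_tensor <- function(nu_zz, nu_ztheta = 0, nu_thetaz = 0,
                             nu_thetatheta = nu_zz) {
  stopifnot(is.numeric(nu_zz), length(nu_zz) == 1L, is.finite(nu_zz),
            is.finite(nu_ztheta), is.finite(nu_thetaz),
            is.finite(nu_thetatheta))
  if (nu_zz <= 0) stop("nu_zz must be positive")
  if (nu_thetatheta <= 0) stop("nu_thetatheta must be positive")
  M <- matrix(c(nu_zz, nu_thetaz, nu_ztheta, nu_thetatheta), 2, 2)
  S <- (M + t(M)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("dissipativity violation: symmetric part of the viscosity tensor ",
         "has eigenvalue ", format(min(ev)), " <= 0")
  structure(list(nu_zz = nu_zz, nu_ztheta = nu_ztheta,
                 nu_thetaz = nu_thetaz, nu_thetatheta = nu_thetatheta),
            class = "viscosity_tensor")
}

#' @export
print.viscosity_tensor <- function(x, ...) {
  cat("Viscosity tensor (m^2/s):\n")
  print(matrix(c(x$nu_zz, x$nu_thetaz, x$nu_ztheta, x$nu_thetatheta), 2, 2,
               dimnames = list(c("z", "theta"), c("z", "theta"))))
  invisible(x)
}

#' Build a viscosity tensor from anisotropy ratios
#'
#' @param nu_zz axial kinematic viscosity (m^2/s), positive.
#' @param ratios an [anisotropy_ratios()] object.
#' @return A [viscosity_tensor()] with `nu_ztheta = beta*nu_zz`,
#'   `nu_thetaz = gamma*nu_zz`, `nu_thetatheta = delta*nu_zz`.
#' @examples
#' tensor_from_ratios(3.5e-6, anisotropy_ratios(0.1, 0.1, 1))
#' @export
tensor_from_ratios <- function(nu_zz, ratios) {
  stopifnot(inherits(ratios, "anisotropy_ratios"))
  if (!is.numeric(nu_zz) || length(nu_zz) != 1L || nu_zz <= 0)
    stop("nu_zz must be a positive scalar")
  viscosity_tensor(nu_zz,
                   nu_ztheta = ratios$beta * nu_zz,
                   nu_thetaz = ratios$gamma * nu_zz,
                   nu_thetatheta = ratios$delta * nu_zz)
}

#' Extract anisotropy ratios from a viscosity tensor
#'
#' Inverse of [tensor_from_ratios()].
#'
#' @param tensor a [viscosity_tensor()].
#' @return An [anisotropy_ratios()] object.
#' @export
ratios_from_tensor <- function(tensor) {
  stopifnot(inherits(tensor, "viscosity_tensor"))
  anisotropy_ratios(beta = tensor$nu_ztheta / tensor$nu_zz,
                    gamma = tensor$nu_thetaz / tensor$nu_zz,
                    delta = tensor$nu_thetatheta / tensor$nu_zz)
}

#' Shear stresses from strain rates
#'
#' Evaluates the constitutive law: the stress pair is the density times the
#' viscosity matrix applied to the strain pair. The azimuthal strain input
#' is the quantity \eqn{\partial_r u_\theta - u_\theta/r}.
#'
#' @param tensor a [viscosity_tensor()].
#' @param rho fluid density (kg/m^3).
#' @param axial_strain axial strain rate \eqn{\partial_r u_z} (1/s);
#'   vectorized.
#' @param azimuthal_strain azimuthal strain rate (1/s); same length as
#'   `axial_strain`.
#' @return A list with elements `tau_zr` and `tau_thetar` (Pa).
#' @examples
#' tn <- viscosity_tensor(3.5e-6)
#' shear_stress(tn, 1050, 1, 0)   # isotropic: (rho*nu, 0)
#' @export
shear_stress <- function(tensor, rho, axial_strain, azimuthal_strain) {
  stopifnot(inherits(tensor, "viscosity_tensor"),
            is.numeric(rho), rho > 0,
            length(axial_strain) == length(azimuthal_strain),
            all(is.finite(axial_strain)), all(is.finite(azimuthal_strain)))
  list(tau_zr = rho * (tensor$nu_zz * axial_strain +
                         tensor$nu_ztheta * azimuthal_strain),
       tau_thetar = rho * (tensor$nu_thetaz * axial_strain +
                             tensor$nu_thetatheta * azimuthal_strain))
}

# Default physical constants. The fundamental cardiac frequency is ~1.2 Hz;
# nu_zz is back-derived so that alpha = R*sqrt(omega0/nu_zz) reproduces the
# Womersley numbers of all six bundled arterial records from their radii to
# two decimals (see the methods vignette for the derivation). G0 is a free
# pressure-gradient scale: dimensionless results do not depend on it, while
# dimensional force magnitudes scale with G0^2.
.awflow_defaults <- list(
  rho = 1050,              # kg/m^3
  nu_zz = 3.4955e-6,       # m^2/s
  omega0 = 2 * pi * 1.2,   # rad/s
  G0 = 1                   # Pa/m
)

#' Physical scales of a pulsatile-flow configuration
#'
#' Collects the dimensional parameters and derives the characteristic
#' velocity scale \eqn{U_0 = |G_0| R^2 / (\rho \nu_{zz})} and the Womersley
#' number \eqn{\alpha = R \sqrt{\omega_0/\nu_{zz}}}. All dimensionless
#' computations in the solver are independent of these scales; they enter
#' only when fields and forces are dimensionalized.
#'
#' @param R vessel radius (m), positive.
#' @param rho fluid density (kg/m^3), positive.
#' @param nu_zz axial kinematic viscosity (m^2/s), positive.
#' @param omega0 fundamental angular frequency (rad/s), positive.
#' @param G0 pressure-gradient amplitude scale (Pa/m), nonzero.
#' @return An object of class `"physical_scales"` with fields `rho`,
#'   `nu_zz`, `R`, `omega0`, `G0`, and derived `U0` (m/s) and `alpha`.
#' @examples
#' sc <- physical_scales(R = 0.015)
#' sc$alpha   # about 22.03 for the default constants
#' @export
physical_scales <- function(R,
                            rho = .awflow_defaults$rho,
                            nu_zz = .awflow_defaults$nu_zz,
                            omega0 = .awflow_defaults$omega0,
                            G0 = .awflow_defaults$G0) {
  vals <- c(R = R, rho = rho, nu_zz = nu_zz, omega0 = omega0)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("R, rho, nu_zz and omega0 must all be positive and finite")
  if (!is.finite(G0) || G0 == 0) stop("G0 must be nonzero and finite")
  structure(list(rho = rho, nu_zz = nu_zz, R = R, omega0 = omega0, G0 = G0,
                 U0 = abs(G0) * R^2 / (rho * nu_zz),
                 alpha = R * sqrt(omega0 / nu_zz)),
            class = "physical_scales")
}

#' @export
print.physical_scales <- function(x, ...) {
  cat(sprintf(paste0("Physical scales: R = %g m, rho = %g kg/m^3, ",
                     "nu_zz = %g m^2/s,\n  omega0 = %g rad/s, G0 = %g Pa/m",
                     " -> U0 = %g m/s, alpha = %.2f\n"),
              x$R, x$rho, x$nu_zz, x$omega0, x$G0, x$U0, x$alpha))
  invisible(x)
}
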