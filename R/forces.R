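#' Fourier synthesis of the time-domain flow field
#'
#' Reconstructs the real velocity fields from the per-harmonic complex
#' amplitudes on a uniform grid of `Nt` phases covering one cycle:
#' \deqn{u_j(r, t^*) = \mathrm{Re}\sum_h \hat U_{j,h}(r)\,
#'   e^{2\pi i h t^*}, \qquad j \in \{z, \theta\}.}
#' The nonlinear Lamb-vector products must be formed from these real
#' fields (not in the complex plane) so that all cross-harmonic
#' interactions are captured.
#'
#' @param solutions list of [solve_harmonic()] results sharing one grid
#'   and one Womersley number.
#' @param Nt number of uniform phases per cycle (default 256).
#' @return An object of class `"flow_field"`: list with `grid`, `alpha`,
#'   `times` (length `Nt`, in \[0, 1)), and `(N+1) x Nt` real matrices
#'   `uz` and `utheta`.
#' @export
synthesize <- function(solutions, Nt = 256) {
  stopifnot(is.list(solutions), length(solutions) >= 1L,
            all(vapply(solutions, inherits, TRUE, "harmonic_solution")),
            Nt >= 4, Nt == round(Nt))
  g <- solutions[[1]]$grid
  alpha <- solutions[[1]]$alpha
  for (s in solutions) {
    if (!identical(s$grid$N, g$N) || max(abs(s$grid$nodes - g$nodes)) > 0)
      stop("all harmonic solutions must share one grid")
    if (s$alpha != alpha)
      stop("all harmonic solutions must share one Womersley number")
  }
  times <- (0:(Nt - 1)) / Nt
  n <- g$N + 1L
  uz <- matrix(0, n, Nt)
  ut <- matrix(0, n, Nt)
  for (s in solutions) {
    ph <- exp(2i * pi * s$h * times)
    uz <- uz + Re(outer(s$Uz, ph))
    ut <- ut + Re(outer(s$Utheta, ph))
  }
  structure(list(grid = g, alpha = alpha, times = times,
                 uz = uz, utheta = ut),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(paste0("Flow field: N = %d, Nt = %d, alpha = %g, ",
                     "max|u_z| = %.4g, max|u_theta| = %.4g\n"),
              x$grid$N, length(x$times), x$alpha,
              max(abs(x$uz)), max(abs(x$utheta))))
  invisible(x)
}

#' Vorticity components of an axisymmetric field
#'
#' For the axisymmetric two-component field the nonzero vorticity
#' components are
#' \deqn{\omega_\theta = -\partial_r u_z, \qquad
#'       \omega_z = \frac{1}{r}\partial_r (r u_\theta),}
#' with the regular centerline limit \eqn{\omega_z(0) = 2\,
#' \partial_r u_\theta(0)}.
#'
#' @param field a [synthesize()] result.
#' @return List with matrices `omega_theta` and `omega_z` matching the
#'   field dimensions.
#' @export
vorticity <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  g <- field$grid
  dut <- g$D %*% field$utheta
  rinv <- c(0, 1 / g$nodes[-1])
  omega_z <- dut + rinv * field$utheta
  omega_z[1, ] <- 2 * dut[1, ]
  list(omega_theta = -(g$D %*% field$uz), omega_z = omega_z)
}

#' Radial component of the Lamb vector
#'
#' Under axisymmetry with no radial velocity the Lamb vector
#' \eqn{\ell = u \times \omega} reduces to its radial component
#' \deqn{\ell_r = u_\theta\,\frac{1}{r}\partial_r(r u_\theta) +
#'       u_z\,\partial_r u_z = u_\theta \omega_z - u_z \omega_\theta.}
#' In the isotropic limit \eqn{u_\theta \equiv 0} this collapses to the
#' centripetal term \eqn{u_z \partial_r u_z}. The centerline value is zero
#' analytically (by symmetry \eqn{u_\theta(0) = 0} and
#' \eqn{\partial_r u_z(0) = 0}); numerically it is left as computed, so the
#' identity \eqn{\ell_r = u_\theta\omega_z - u_z\omega_\theta} holds
#' exactly at every node.
#'
#' @param field a [synthesize()] result.
#' @return Matrix of dimensionless \eqn{\ell_r} values matching the field.
#' @export
lamb_radial <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  w <- vorticity(field)
  field$utheta * w$omega_z - field$uz * w$omega_theta
}

#' Endothelial control-volume geometry
#'
#' A thin near-wall "pillbox" of thickness `delta_EC = V_EC / A_EC`
#' adjacent to the wall, where `A_EC` is the endothelial cell footprint
#' area and `V_EC` the cell volume. Defaults are a 100 um^2 footprint and
#' a 100 um^3 volume, i.e. a 1 um thick pillbox; both are configurable
#' because neither is tightly constrained by measurement.
#'
#' @param A_EC footprint area (m^2), default `1e-10` (100 um^2).
#' @param V_EC cell volume (m^3), default `1e-16` (100 um^3).
#' @return Object of class `"ec_geometry"` with `A_EC`, `V_EC`,
#'   `delta_EC` (m).
#' @export
ec_geometry <- function(A_EC = 1e-10, V_EC = 1e-16) {
  stopifnot(is.numeric(A_EC), A_EC > 0, is.numeric(V_EC), V_EC > 0)
  structure(list(A_EC = A_EC, V_EC = V_EC, delta_EC = V_EC / A_EC),
            class = "ec_geometry")
}

#' @export
print.ec_geometry <- function(x, ...) {
  cat(sprintf(paste0("Endothelial pillbox: A_EC = %g m^2, V_EC = %g m^3, ",
                     "delta_EC = %g m\n"), x$A_EC, x$V_EC, x$delta_EC))
  invisible(x)
}

#' Integrated endothelial transverse force
#'
#' Dimensionalizes the transverse inertial force density
#' \eqn{f_r = \rho\,\ell_r\,U_0^2/R} (N/m^3) and integrates its magnitude
#' over the near-wall pillbox:
#' \deqn{F_{EC}(t) = A_{EC}\int_{R-\delta_{EC}}^{R} |f_r(r,t)|\,dr.}
#' The integrand is evaluated by barycentric interpolation of the
#' dimensionless \eqn{\ell_r} onto a fine uniform subgrid inside the
#' pillbox and integrated with the composite trapezoid rule.
#'
#' @param field a [synthesize()] result.
#' @param scales a [physical_scales()] object.
#' @param ec an [ec_geometry()]; `delta_EC` must satisfy
#'   `R * 1e-6 <= delta_EC < R`.
#' @param n_sub number of subgrid points in the pillbox (>= 64).
#' @return Object of class `"ec_force_series"`: list with `times`, `F_EC`
#'   (N), `F_EC_pN` (pN), and the inputs.
#' @export
ec_force <- function(field, scales, ec = ec_geometry(), n_sub = 64) {
  stopifnot(inherits(field, "flow_field"),
            inherits(scales, "physical_scales"),
            inherits(ec, "ec_geometry"), n_sub >= 64)
  if (ec$delta_EC >= scales$R)
    stop("pillbox thickness delta_EC must be smaller than the radius R")
  if (ec$delta_EC < scales$R * 1e-6)
    stop("pillbox thinner than resolvable: delta_EC < R * 1e-6")
  eps <- ec$delta_EC / scales$R
  rs <- seq(1 - eps, 1, length.out = n_sub)
  P <- interp_matrix(field$grid, rs)
  ell_sub <- abs(P %*% lamb_radial(field))       # n_sub x Nt, dimensionless
  drs <- rs[2] - rs[1]
  integral <- (colSums(ell_sub) - (ell_sub[1, ] + ell_sub[n_sub, ]) / 2) * drs
  # dr (dimensional) = R dr*; rho * U0^2 / R * R = rho * U0^2
  F_EC <- ec$A_EC * scales$rho * scales$U0^2 * integral
  structure(list(times = field$times, F_EC = F_EC, F_EC_pN = F_EC * 1e12,
                 scales = scales, ec = ec),
            class = "ec_force_series")
}

#' @export
print.ec_force_series <- function(x, ...) {
  cat(sprintf(paste0("Endothelial force series: Nt = %d, mean F_EC = %.4g",
                     " pN, max = %.4g pN\n"),
              length(x$times), mean(x$F_EC_pN), max(x$F_EC_pN)))
  invisible(x)
}

#' Wall shear traction from the full constitutive law
#'
#' Evaluates the axial shear stress at the wall,
#' \eqn{\tau_w(t) = \tau_{zr}(R, t)}, including the anisotropic coupling
#' term: \eqn{\tau_{zr} = \rho[\nu_{zz}\partial_r u_z +
#' \nu_{z\theta}(\partial_r u_\theta - u_\theta/r)]}. The dimensionless
#' strains carry the factor \eqn{\rho \nu_{zz} U_0 / R}.
#'
#' @param field a [synthesize()] result.
#' @param tensor a [viscosity_tensor()].
#' @param scales a [physical_scales()].
#' @return Numeric vector `tau_w(t)` in Pa, one value per phase.
#' @export
wall_traction <- function(field, tensor, scales) {
  stopifnot(inherits(field, "flow_field"),
            inherits(tensor, "viscosity_tensor"),
            inherits(scales, "physical_scales"))
  g <- field$grid
  n <- g$N + 1L
  duz <- (g$D %*% field$uz)[n, ]
  dut <- (g$D %*% field$utheta)[n, ]
  strain_t <- dut - field$utheta[n, ] / g$nodes[n]
  dim_fac <- scales$rho * scales$U0 / scales$R
  dim_fac * (tensor$nu_zz * duz + tensor$nu_ztheta * strain_t)
}

#' Near-wall radial force proxy
#'
#' Pointwise proxy for the transverse wall load used in the ratio/angle
#' diagnostics: the dimensional force density \eqn{\rho \ell_r U_0^2/R}
#' at the collocation point nearest the wall, times a reference area and
#' the pillbox thickness.
#'
#' @param field a [synthesize()] result.
#' @param scales a [physical_scales()].
#' @param ec an [ec_geometry()].
#' @param A_ref reference area (m^2), default `1e-10` (100 um^2).
#' @return Numeric vector `F_r_wall(t)` in N.
#' @export
near_wall_force_proxy <- function(field, scales, ec = ec_geometry(),
                                  A_ref = 1e-10) {
  stopifnot(inherits(field, "flow_field"),
            inherits(scales, "physical_scales"))
  n <- field$grid$N + 1L
  ell <- lamb_radial(field)[n - 1L, ]           # nearest-wall node
  scales$rho * ell * scales$U0^2 / scales$R * A_ref * ec$delta_EC
}

#' Transverse-to-axial force ratio and angle
#'
#' Instantaneous magnitude ratio \eqn{\chi(t) = |F_r|/|F_z|} and vector
#' angle \eqn{\varphi(t) = \tan^{-1}(F_r/F_z)} of the near-wall force
#' pair. Where \eqn{|F_z|} falls below `eps`, `chi` is reported as `Inf`
#' and `phi` as \eqn{\pm\pi/2} with the sign of `F_r`.
#'
#' @param F_r radial force series (N).
#' @param F_z axial force series (N); same length as `F_r`.
#' @param eps threshold below which `F_z` counts as vanishing.
#' @return List with numeric vectors `chi` (dimensionless) and `phi`
#'   (rad).
#' @examples
#' force_ratio_angle(1, 1)$phi   # pi/4
#' @export
force_ratio_angle <- function(F_r, F_z, eps = .Machine$double.xmin * 1e10) {
  if (length(F_r) != length(F_z))
    stop("F_r and F_z must have the same length")
  small <- abs(F_z) < eps
  chi <- abs(F_r) / abs(F_z)
  phi <- atan(F_r / F_z)
  chi[small] <- ifelse(F_r[small] == 0, 0, Inf)
  phi[small] <- ifelse(F_r[small] == 0, 0, sign(F_r[small]) * pi / 2)
  list(chi = chi, phi = phi)
}
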