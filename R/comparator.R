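#' Curvature specification for the geometric transverse-force bound
#'
#' Curvature enters only as the dimensionless ratio
#' \eqn{\kappa = R/\mathcal{R}} of vessel radius to radius of curvature.
#' The secondary-flow velocity scale follows the inertial balance
#' \eqn{u_s \sim u_z \sqrt{\kappa}}.
#'
#' @param kappa curvature ratio, `0 <= kappa < 1`.
#' @param R vessel radius (m), optional; if given, the radius of curvature
#'   `Rcurv = R/kappa` is derived (for `kappa > 0`).
#' @return Object of class `"curvature_spec"`.
#' @export
curvature_spec <- function(kappa, R = NULL) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, is.finite(kappa),
            kappa >= 0, kappa < 1)
  Rcurv <- if (!is.null(R) && kappa > 0) R / kappa else NA_real_
  structure(list(kappa = kappa, Rcurv = Rcurv,
                 u_s_scale = "u_s ~ u_z * sqrt(kappa)"),
            class = "curvature_spec")
}

#' Curvature-driven transverse force density bound
#'
#' Conservative estimate of the geometric (curvature-driven) transverse
#' inertial force density. In the default `"bound"` mode it is the
#' near-wall upper bound
#' \deqn{f_{r,c}(t) = \rho\,u_z(t)^2\,(1+\kappa)/R,}
#' obtained from the centrifugal scale plus the secondary-flow correction
#' evaluated at `r = R`. The `"scaling"` mode evaluates the alternative
#' form \eqn{\rho\,u^2(\kappa/R + 1/r)} at a caller-specified radius.
#'
#' @param uz_bulk bulk axial velocity series (m/s).
#' @param spec a [curvature_spec()].
#' @param rho fluid density (kg/m^3).
#' @param R vessel radius (m).
#' @param mode `"bound"` (default) or `"scaling"`.
#' @param r evaluation radius (m) for the `"scaling"` mode; defaults to
#'   `R`.
#' @return Numeric vector `f_rc(t)` in N/m^3.
#' @examples
#' sp <- curvature_spec(0.35)
#' curvature_bound(0.5, sp, 1050, 0.015)   # 23625 N/m^3
#' @export
curvature_bound <- function(uz_bulk, spec, rho, R,
                            mode = c("bound", "scaling"), r = R) {
  stopifnot(inherits(spec, "curvature_spec"), is.numeric(uz_bulk),
            rho > 0, R > 0, r > 0)
  mode <- match.arg(mode)
  if (mode == "bound") {
    rho * uz_bulk^2 * (1 + spec$kappa) / R
  } else {
    rho * uz_bulk^2 * (spec$kappa / R + 1 / r)
  }
}

#' Inertial low-pass filter on a harmonic spectrum
#'
#' The bulk curvature-driven cross-stream response to forcing at harmonic
#' `h` is first-order inertial, \eqn{\hat u_{s,h} = O(\hat f_h /
#' (\rho\,\omega_h))}, so its transfer magnitude carries a `1/h`
#' attenuation. The steady component has no defined filter value and is
#' excluded.
#'
#' @param amplitudes numeric amplitudes indexed by harmonic.
#' @param h integer harmonic indices (all >= 1) matching `amplitudes`.
#' @return `amplitudes / h`.
#' @examples
#' inertial_filter(c(1, 1, 1, 1), 1:4)   # 1, 1/2, 1/3, 1/4
#' @export
inertial_filter <- function(amplitudes, h = seq_along(amplitudes)) {
  stopifnot(length(amplitudes) == length(h), all(h == round(h)))
  if (any(h < 1))
    stop("the inertial filter is defined only for harmonics h >= 1 ",
         "(the steady component is excluded)")
  amplitudes / h
}

#' Oscillatory boundary-layer thickness of harmonic h
#'
#' The harmonic Womersley number is \eqn{\alpha_h = \sqrt{h}\,\alpha}, so
#' the Stokes-layer thickness, as a fraction of the radius, is
#' \deqn{\delta_{W,h} = \sqrt{2}/(\sqrt{h}\,\alpha).}
#' The \eqn{\sqrt 2} prefactor is the classical Stokes-layer convention
#' and is used only for reporting, never inside the solver.
#'
#' @param alpha Womersley number (> 0).
#' @param h harmonic index (>= 1); vectorized.
#' @return Dimensionless thickness (fraction of `R`).
#' @examples
#' boundary_layer_thickness(20, 1)   # sqrt(2)/20
#' @export
boundary_layer_thickness <- function(alpha, h) {
  stopifnot(alpha > 0, all(h == round(h)))
  if (any(h < 1)) stop("h must be >= 1")
  sqrt(2) / (sqrt(h) * alpha)
}

#' Instantaneous bulk (area-averaged) axial velocity
#'
#' Dimensionless cross-sectional average \eqn{2\int_0^1 u_z\,r\,dr} on the
#' unit disk, evaluated per phase by interpolating onto a fine uniform
#' radial grid and applying the composite trapezoid rule.
#'
#' @param field a [synthesize()] result.
#' @param n_fine number of radial quadrature points.
#' @param subtract_mean if `TRUE`, the cycle mean is removed (pulsatile
#'   content only). Default `FALSE`: the instantaneous average including
#'   the steady component.
#' @return Numeric vector, one dimensionless bulk velocity per phase.
#' @export
bulk_velocity <- function(field, n_fine = 2001, subtract_mean = FALSE) {
  stopifnot(inherits(field, "flow_field"), n_fine >= 101)
  rs <- seq(0, 1, length.out = n_fine)
  P <- interp_matrix(field$grid, rs)
  integrand <- (P %*% field$uz) * rs               # n_fine x Nt
  dr <- rs[2] - rs[1]
  ub <- 2 * (colSums(integrand) -
               (integrand[1, ] + integrand[n_fine, ]) / 2) * dr
  if (subtract_mean) ub <- ub - mean(ub)
  ub
}

#' Harmonic amplitudes of a periodic series
#'
#' One-sided amplitude spectrum over exactly one cycle: `a_0` is the mean
#' and `a_h = 2|X_h|/Nt` for `h >= 1`, where `X` is the discrete Fourier
#' transform.
#'
#' @param x real series sampled on uniform phases over one cycle.
#' @param H highest harmonic to report.
#' @return Numeric vector of amplitudes for `h = 0..H`.
#' @keywords internal
harmonic_amplitudes <- function(x, H) {
  Nt <- length(x)
  if (H >= Nt / 2) stop("H must be below the Nyquist harmonic")
  X <- stats::fft(x)
  c(Mod(X[1]) / Nt, 2 * Mod(X[2:(H + 1)]) / Nt)
}

#' Constitutive versus geometric dominance spectrum
#'
#' Compares the pillbox-integrated anisotropic Lamb-vector force
#' \eqn{F_{a,EC}(t)} against the curvature-driven geometric bound
#' \eqn{F_{c,EC}(t)} harmonic by harmonic. Both force series are built
#' from the same time-domain field: the anisotropic side integrates
#' \eqn{|\rho\,\ell_r\,U_0^2/R|} over the pillbox; the geometric side
#' applies [curvature_bound()] to the dimensional bulk velocity (constant
#' across the pillbox, so its integral is `delta_EC` times the density)
#' at the two ends of the curvature band. Each series is decomposed into
#' harmonic amplitudes by discrete Fourier transform over one cycle and
#' the geometric amplitudes are attenuated by the `1/h` inertial filter.
#'
#' @param field a [synthesize()] result (multi-harmonic physiological
#'   solve).
#' @param scales a [physical_scales()].
#' @param ec an [ec_geometry()].
#' @param kappa_low,kappa_high ends of the curvature band.
#' @param H highest harmonic reported; defaults to 5 (the bundled
#'   waveforms carry harmonics 0..5).
#' @param mode passed to [curvature_bound()].
#' @param subtract_mean_bulk passed to [bulk_velocity()]; the default
#'   `FALSE` uses the instantaneous area average including the steady
#'   component.
#' @return A data.frame with columns `h`, `F_c_low`, `F_c_high` (filtered
#'   geometric amplitudes, N), `F_a` (anisotropic amplitude, N), and
#'   `delta_W` (dimensionless layer thickness).
#' @export
dominance_spectrum <- function(field, scales, ec = ec_geometry(),
                               kappa_low = 0.35, kappa_high = 0.70,
                               H = 5, mode = c("bound", "scaling"),
                               subtract_mean_bulk = FALSE) {
  stopifnot(inherits(field, "flow_field"),
            inherits(scales, "physical_scales"))
  mode <- match.arg(mode)
  Fa <- ec_force(field, scales, ec)$F_EC
  ub_dim <- scales$U0 * bulk_velocity(field,
                                      subtract_mean = subtract_mean_bulk)
  Fa_amp <- harmonic_amplitudes(Fa, H)[-1]
  one_kappa <- function(kap) {
    frc <- curvature_bound(ub_dim, curvature_spec(kap), scales$rho,
                           scales$R, mode = mode)
    Fc <- ec$A_EC * abs(frc) * ec$delta_EC
    inertial_filter(harmonic_amplitudes(Fc, H)[-1], 1:H)
  }
  data.frame(h = 1:H,
             F_c_low = one_kappa(kappa_low),
             F_c_high = one_kappa(kappa_high),
             F_a = Fa_amp,
             delta_W = boundary_layer_thickness(field$alpha, 1:H))
}
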