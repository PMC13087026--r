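#' Registry of physiological arterial waveforms
#'
#' Six representative human arterial segments with vessel radius,
#' Womersley number and the first six real harmonic amplitudes
#' (h = 0..5) of the driving pressure-gradient waveform, spanning
#' viscous-dominated (brachial, alpha ~ 2.9) to inertia-dominated
#' (aortic root, alpha ~ 22) regimes. Amplitudes are normalized so the
#' steady component is 1.
#'
#' @return A data.frame with columns `name`, `radius` (m), `alpha`, and
#'   amplitude columns `a0`..`a5`.
#' @examples
#' artery_registry()
#' @export
artery_registry <- function() {
  amp <- rbind(
    c(1.00, 0.82, 0.54, 0.33, 0.24, 0.17),
    c(1.00, 0.76, 0.45, 0.28, 0.20, 0.12),
    c(1.00, 0.58, 0.10, -0.17, 0.05, 0.04),
    c(1.00, 0.63, 0.31, 0.15, 0.10, 0.06),
    c(1.00, 0.51, 0.12, -0.11, 0.05, 0.03),
    c(1.00, 0.49, 0.16, -0.05, 0.02, 0.01))
  colnames(amp) <- paste0("a", 0:5)
  data.frame(name = c("Aortic Root", "Thoracic Aorta", "Femoral",
                      "Carotid", "Iliac", "Brachial"),
             radius = c(0.015, 0.012, 0.004, 0.0035, 0.0045, 0.002),
             alpha = c(22.03, 17.62, 5.87, 5.14, 6.61, 2.94),
             amp)
}

#' Fetch one arterial record
#'
#' @param name artery name as listed by [artery_registry()]
#'   (case-insensitive).
#' @return A list with `name`, `R` (m), `alpha`, `amplitudes` (h = 0..5)
#'   and a ready-made [waveform()].
#' @export
artery_record <- function(name) {
  reg <- artery_registry()
  i <- match(tolower(name), tolower(reg$name))
  if (is.na(i))
    stop("unknown artery '", name, "'; available: ",
         paste(reg$name, collapse = ", "))
  amps <- as.numeric(reg[i, paste0("a", 0:5)])
  list(name = reg$name[i], R = reg$radius[i], alpha = reg$alpha[i],
       amplitudes = amps, waveform = waveform(amps, reg$name[i]))
}

#' Solve a physiological artery case end to end
#'
#' Convenience wrapper: solves all six harmonics of a registry waveform
#' at the artery's own Womersley number and synthesizes the time-domain
#' field. The anisotropy convention for the physiological runs is
#' `beta = gamma`, `delta = 1`.
#'
#' @param name artery name.
#' @param beta anisotropy ratio (`gamma` defaults to the same value).
#' @param gamma azimuthal-from-axial coupling ratio.
#' @param delta azimuthal viscosity ratio.
#' @param N collocation order.
#' @param Nt phases per cycle.
#' @param scales optional [physical_scales()]; defaults to the calibrated
#'   constants with the artery's radius.
#' @return A list with `record`, `scales`, `solutions`, `field`.
#' @export
solve_artery <- function(name, beta = 0.1, gamma = beta, delta = 1,
                         N = 150, Nt = 256, scales = NULL) {
  rec <- artery_record(name)
  if (is.null(scales)) scales <- physical_scales(R = rec$R)
  ratios <- anisotropy_ratios(beta, gamma, delta)
  sols <- solve_waveform(cgl_grid(N), rec$alpha, ratios, rec$waveform)
  list(record = rec, scales = scales, solutions = sols,
       field = synthesize(sols, Nt))
}

#' Mono-harmonic parameter sweep
#'
#' Solves the mono-harmonic problem (`h = 1`, `a = 1`) over a grid of
#' Womersley numbers and anisotropy ratios (convention `beta = gamma`,
#' `delta = 1`) and records, per cell, the peak swirl amplitude
#' `max_r |U_theta|`, the peak axial-vorticity amplitude
#' `max_r |omega_z|`, the radial location of the swirl peak (refined on
#' the spectral interpolant), and the near-wall transverse force
#' amplitude `max_t |ell_r|` at the collocation point nearest the wall
#' (dimensionless).
#'
#' @param alpha_grid Womersley numbers (within \[1, 25\] by default use).
#' @param beta_grid anisotropy ratios (within \[0, 0.1\]).
#' @param N collocation order.
#' @param Nt phases used for the near-wall force observable.
#' @return A data.frame with one row per `(alpha, beta)` cell and columns
#'   `alpha`, `beta`, `swirl_max`, `vortz_max`, `peak_loc`, `wall_force`.
#' @export
sweep_mono <- function(alpha_grid = seq(1, 25, by = 0.5),
                       beta_grid = seq(0, 0.1, by = 0.0125),
                       N = 150, Nt = 64) {
  stopifnot(length(alpha_grid) >= 1L, length(beta_grid) >= 1L,
            all(alpha_grid > 0), all(beta_grid >= 0))
  g <- cgl_grid(N)
  n <- g$N + 1L
  rows <- vector("list", length(alpha_grid) * length(beta_grid))
  k <- 0L
  for (alpha in alpha_grid) for (beta in beta_grid) {
    k <- k + 1L
    sol <- solve_harmonic(g, alpha, 1, anisotropy_ratios(beta, beta, 1), 1)
    swirl <- Mod(sol$Utheta)
    vz <- g$D %*% sol$Utheta + c(0, 1 / g$nodes[-1]) * sol$Utheta
    vz[1] <- 2 * (g$D %*% sol$Utheta)[1]
    peak <- if (max(swirl) > 0)
      .refine_peak(g, sol$Utheta) else NA_real_
    fld <- synthesize(list(sol), Nt)
    wall_force <- max(abs(lamb_radial(fld)[n - 1L, ]))
    rows[[k]] <- data.frame(alpha = alpha, beta = beta,
                            swirl_max = max(swirl),
                            vortz_max = max(Mod(vz)),
                            peak_loc = peak,
                            wall_force = wall_force)
  }
  do.call(rbind, rows)
}

# locate the maximum of |interpolant| of a complex nodal profile to 1e-4
# resolution: coarse scan then golden-section refinement
.refine_peak <- function(grid, profile, resolution = 1e-4) {
  obj <- function(r) -abs(barycentric_eval(grid, profile, r))
  rs <- seq(0, 1, by = 1e-3)
  vals <- abs(drop(interp_matrix(grid, rs) %*% profile))
  i <- which.max(vals)
  lo <- rs[max(i - 1L, 1L)]
  hi <- rs[min(i + 1L, length(rs))]
  opt <- stats::optimize(obj, c(lo, hi), tol = resolution / 10)
  opt$minimum
}

#' Radial location of the peak swirl velocity
#'
#' Solves one mono-harmonic cell and returns the radius (fraction of R)
#' maximizing `|U_theta(r)|`, refined on the barycentric interpolant to
#' 1e-4 resolution. The steady problem (`h = 0`) has the closed-form
#' swirl profile proportional to `r^2 - r` and yields exactly 0.5.
#'
#' @param alpha Womersley number.
#' @param beta anisotropy ratio (`gamma = beta`, `delta = 1` convention).
#' @param N collocation order.
#' @param h harmonic index (default 1, the mono-harmonic convention).
#' @return Peak radius in (0, 1).
#' @export
peak_swirl_location <- function(alpha, beta, N = 150, h = 1) {
  if (beta == 0)
    stop("swirl profile is identically zero at beta = 0; ",
         "the peak location is undefined")
  g <- cgl_grid(N)
  sol <- solve_harmonic(g, alpha, h, anisotropy_ratios(beta, beta, 1), 1)
  if (max(Mod(sol$Utheta)) < 1e-300)
    stop("swirl profile is numerically zero; peak location undefined")
  .refine_peak(g, sol$Utheta)
}

#' Grid-independence assessment
#'
#' Solves one physiological waveform on successively refined CGL grids,
#' reconstructs the axial velocity at one phase, and reports the maximum
#' pointwise residual against the reference-order solution, with the
#' coarse solution evaluated at the reference nodes by barycentric
#' interpolation.
#'
#' @param artery artery name (default thoracic aorta).
#' @param beta anisotropy ratio (`gamma = beta`, `delta = 1`).
#' @param N_list grid orders to test.
#' @param N_ref reference order (> max(N_list)).
#' @param tstar evaluation phase (cycle fraction), default peak phase
#'   0.25.
#' @return A data.frame with columns `N` and `residual`.
#' @export
grid_independence <- function(artery = "Thoracic Aorta", beta = 0.1,
                              N_list = c(60, 80, 100, 120, 140, 160),
                              N_ref = 180, tstar = 0.25) {
  stopifnot(all(N_list < N_ref))
  rec <- artery_record(artery)
  ratios <- anisotropy_ratios(beta, beta, 1)
  profile_at <- function(N) {
    g <- cgl_grid(N)
    sols <- solve_waveform(g, rec$alpha, ratios, rec$waveform)
    uz <- 0
    for (s in sols) uz <- uz + Re(s$Uz * exp(2i * pi * s$h * tstar))
    list(grid = g, uz = uz)
  }
  ref <- profile_at(N_ref)
  res <- vapply(N_list, function(N) {
    coarse <- profile_at(N)
    max(abs(barycentric_eval(coarse$grid, coarse$uz, ref$grid$nodes) -
              ref$uz))
  }, numeric(1))
  data.frame(N = N_list, residual = res)
}

#' Harmonic spectrum of an endothelial force series
#'
#' Discrete Fourier transform of `F_EC(t)` over exactly one cycle.
#' Amplitudes are one-sided (`a_0` = mean, `a_h = 2|X_h|/Nt`); powers are
#' Parseval-consistent, i.e. they sum to the mean square of the signal.
#'
#' @param series an [ec_force()] result, or a numeric vector sampled on
#'   uniform phases over one cycle.
#' @param H_report highest harmonic to report (below Nyquist).
#' @return A data.frame with columns `h`, `amplitude` (N), `power`
#'   (N^2).
#' @export
force_spectrum <- function(series, H_report = 6) {
  x <- if (inherits(series, "ec_force_series")) series$F_EC
       else as.numeric(series)
  if (anyNA(x)) stop("series contains missing values")
  amps <- harmonic_amplitudes(x, H_report)
  pow <- c(amps[1]^2, amps[-1]^2 / 2)
  data.frame(h = 0:H_report, amplitude = amps, power = pow)
}

#' Kruskal-Wallis rank test across groups
#'
#' Non-parametric H-test that the groups share one distribution, with tie
#' correction and the chi-square upper-tail p-value on k - 1 degrees of
#' freedom (delegated to [stats::kruskal.test()]). The degenerate case of
#' all values identical across all groups returns `H = 0`, `p = 1`.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @return List with `H`, `p`, `df`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))   # H = 3.857...
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, 1L) >= 2L),
            all(vapply(groups, is.numeric, TRUE)))
  vals <- unlist(groups)
  if (length(unique(vals)) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Root-mean-square truncation error of a Fourier reconstruction
#'
#' Measures how well a uniformly sampled single-period waveform is
#' represented by its order-`H` Fourier truncation: the rms of the
#' reconstruction residual, normalized by the rms of the waveform. Used
#' to choose the number of harmonics for user-supplied waveforms (the
#' selection rule keeps the relative rms below 1e-3).
#'
#' @param samples numeric samples covering exactly one period.
#' @param H truncation order (below Nyquist).
#' @return Relative rms reconstruction error (dimensionless).
#' @export
truncation_rms <- function(samples, H) {
  stopifnot(is.numeric(samples), length(samples) >= 4L,
            H == round(H), H >= 0)
  Nt <- length(samples)
  if (H >= Nt / 2) stop("H must be below the Nyquist harmonic Nt/2")
  X <- stats::fft(samples)
  keep <- rep(FALSE, Nt)
  keep[1] <- TRUE
  if (H >= 1) {
    keep[2:(H + 1)] <- TRUE
    keep[Nt - (1:H) + 1] <- TRUE
  }
  recon <- Re(stats::fft(X * keep, inverse = TRUE)) / Nt
  sqrt(mean((samples - recon)^2)) / sqrt(mean(samples^2))
}
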