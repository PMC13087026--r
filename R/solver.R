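#' Pressure-gradient waveform
#'
#' A periodic axial pressure gradient represented by real harmonic
#' amplitudes `a_h`, `h = 0..H`, under the cosine-phase convention: the
#' dimensionless forcing is \eqn{\mathrm{Re}\,\sum_h a_h e^{2\pi i h t^*}}.
#' Amplitudes may be negative (sign flips the phase). The bundled
#' physiological records are normalized so that `a_0 = 1`, which follows
#' from building the velocity scale `U0` from the steady gradient.
#'
#' @param amplitudes numeric vector of harmonic amplitudes, index `h = 0`
#'   first.
#' @param label free-text name.
#' @return An object of class `"waveform"` with fields `amplitudes`, `H`,
#'   `label`.
#' @examples
#' waveform(c(1, 0.5), "steady + fundamental")
#' @export
waveform <- function(amplitudes, label = "") {
  stopifnot(is.numeric(amplitudes), length(amplitudes) >= 1L,
            all(is.finite(amplitudes)))
  structure(list(amplitudes = as.numeric(amplitudes),
                 H = length(amplitudes) - 1L, label = as.character(label)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat("Waveform", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      "with harmonics h = 0..", x$H, ":\n  ", sep = "")
  cat(paste(format(x$amplitudes), collapse = ", "), "\n")
  invisible(x)
}

#' Assemble the coupled harmonic system
#'
#' For one harmonic `h`, the dimensionless momentum equations
#' \deqn{i h \alpha^2 \hat U_z = a_h + L_0 \hat U_z + \beta L_1 \hat U_\theta,}
#' \deqn{i h \alpha^2 \hat U_\theta = \gamma L_0 \hat U_z +
#'       \delta L_1 \hat U_\theta}
#' are discretized as a dense complex `2(N+1) x 2(N+1)` block system
#' `A u = b` with `u = (Uz, Utheta)`. Four rows are then replaced by
#' boundary conditions: no-slip at the wall for both components,
#' `dUz/dr = 0` (symmetry) and `Utheta = 0` (regularity) at the
#' centerline.
#'
#' @param grid a [cgl_grid()].
#' @param alpha Womersley number (> 0).
#' @param h harmonic index (integer >= 0).
#' @param ratios an [anisotropy_ratios()] object.
#' @param a_h real or complex pressure-gradient amplitude of harmonic `h`.
#' @return A list with the system matrix `A`, right-hand side `b`, and the
#'   index bookkeeping (`n`, node indices of the replaced rows).
#' @export
assemble_system <- function(grid, alpha, h, ratios, a_h) {
  stopifnot(inherits(grid, "cgl_grid"), inherits(ratios, "anisotropy_ratios"),
            is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            length(h) == 1L, h == round(h), h >= 0, length(a_h) == 1L)
  inert <- h * alpha^2
  if (!is.finite(inert)) stop("h * alpha^2 overflows")
  n <- grid$N + 1L
  I <- diag(n)
  A <- rbind(cbind(grid$L0 - 1i * inert * I, ratios$beta * grid$L1),
             cbind(ratios$gamma * grid$L0,
                   ratios$delta * grid$L1 - 1i * inert * I))
  b <- c(rep(-a_h + 0i, n), rep(0i, n))
  ctr <- 1L; wall <- n
  # wall rows: value rows (no-slip), zero right-hand side
  A[wall, ] <- 0; A[wall, wall] <- 1; b[wall] <- 0
  A[n + wall, ] <- 0; A[n + wall, n + wall] <- 1; b[n + wall] <- 0
  # centerline rows: axial symmetry (derivative row), azimuthal regularity
  A[ctr, ] <- 0; A[ctr, seq_len(n)] <- grid$D[ctr, ]; b[ctr] <- 0
  A[n + ctr, ] <- 0; A[n + ctr, n + ctr] <- 1; b[n + ctr] <- 0
  list(A = A, b = b, n = n, centerline = ctr, wall = wall)
}

#' Solve one harmonic of the anisotropic Womersley problem
#'
#' Direct dense LU solve of the assembled block system. The returned
#' complex nodal amplitudes satisfy no-slip at the wall, symmetry and
#' regularity at the centerline; for `beta = gamma = 0` the azimuthal
#' component vanishes to solver precision.
#'
#' @inheritParams assemble_system
#' @return An object of class `"harmonic_solution"`: list with `h`,
#'   `alpha`, `a_h`, `ratios`, complex vectors `Uz` and `Utheta` at the
#'   grid nodes, and the `grid`.
#' @examples
#' g <- cgl_grid(24)
#' s <- solve_harmonic(g, 10, 0, anisotropy_ratios(), 1)
#' max(abs(s$Uz - (1 - g$nodes^2) / 4))   # steady Poiseuille
#' @export
solve_harmonic <- function(grid, alpha, h, ratios, a_h) {
  sys <- assemble_system(grid, alpha, h, ratios, a_h)
  rc <- rcond(sys$A)
  if (!is.finite(rc) || rc < 1e-15)
    stop("harmonic system is numerically singular ",
         "(reciprocal condition estimate ", format(rc), ")")
  u <- solve(sys$A, sys$b)
  n <- sys$n
  structure(list(h = as.integer(h), f_h = as.integer(h), alpha = alpha,
                 a_h = a_h, ratios = ratios,
                 Uz = u[seq_len(n)], Utheta = u[n + seq_len(n)],
                 grid = grid),
            class = "harmonic_solution")
}

#' @export
print.harmonic_solution <- function(x, ...) {
  cat(sprintf(paste0("Harmonic solution h = %d, alpha = %g: max|Uz| = %.4g,",
                     " max|Utheta| = %.4g\n"),
              x$h, x$alpha, max(Mod(x$Uz)), max(Mod(x$Utheta))))
  invisible(x)
}

#' Solve every harmonic of a waveform
#'
#' The harmonics are independent (the equations are linear), so each is
#' solved separately on the shared grid.
#'
#' @param grid a [cgl_grid()].
#' @param alpha Womersley number.
#' @param ratios an [anisotropy_ratios()] object.
#' @param wf a [waveform()].
#' @return A list of [solve_harmonic()] results for `h = 0..H`.
#' @export
solve_waveform <- function(grid, alpha, ratios, wf) {
  stopifnot(inherits(wf, "waveform"))
  lapply(0:wf$H, function(h)
    solve_harmonic(grid, alpha, h, ratios, wf$amplitudes[h + 1]))
}

#' Interior residual of a harmonic solution
#'
#' Substitutes the computed amplitudes back into the un-replaced interior
#' equations and returns the maximum residual magnitude, normalized by the
#' natural row scale of the operator (the infinity norm of the interior
#' operator rows times the solution magnitude, plus the forcing), so that
#' a backward-stable solve yields a value near machine epsilon
#' independently of the grid order.
#'
#' @param sol a [solve_harmonic()] result.
#' @return Maximum relative interior residual (dimensionless).
#' @export
interior_residual <- function(sol) {
  stopifnot(inherits(sol, "harmonic_solution"))
  g <- sol$grid
  n <- g$N + 1L
  inert <- 1i * sol$h * sol$alpha^2
  rz <- (g$L0 %*% sol$Uz - inert * sol$Uz +
           sol$ratios$beta * g$L1 %*% sol$Utheta) + sol$a_h
  rt <- (sol$ratios$gamma * g$L0 %*% sol$Uz +
           sol$ratios$delta * g$L1 %*% sol$Utheta - inert * sol$Utheta)
  interior <- 2:(n - 1)
  opscale <- max(rowSums(abs(g$L0)) + rowSums(abs(g$L1)) + Mod(inert))
  umax <- max(Mod(sol$Uz), Mod(sol$Utheta))
  max(Mod(rz[interior]), Mod(rt[interior])) /
    (opscale * umax + abs(sol$a_h))
}
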