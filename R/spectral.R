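#' Chebyshev-Gauss-Lobatto collocation grid on \[0, 1\]
#'
#' Builds the CGL nodes mapped to the unit radial interval, the spectral
#' first-derivative matrix `D`, and the cylindrical operators
#' \deqn{L_0 f = f'' + f'/r, \qquad L_1 f = f'' + f'/r - f/r^2}
#' as dense collocation matrices. Nodes are stored in ascending order, so
#' the first node is the centerline (r = 0) and the last is the wall
#' (r = 1); node clustering at both ends gives fine near-wall resolution.
#'
#' The derivative matrix uses the trigonometric CGL formula with the
#' negative-sum trick for the diagonal, which keeps rounding errors small
#' at high order. The singular centerline rows of `L0`/`L1` are populated
#' by the regular symmetric limits (`lim f'/r = f''(0)`, giving `2 f''(0)`
#' for `L0` and `3/2 f''(0)` for `L1`); the harmonic solver always
#' overwrites these rows with boundary conditions, so the choice is inert
#' there.
#'
#' @param N polynomial order (integer >= 2); the grid has `N + 1` nodes.
#' @return An object of class `"cgl_grid"`: list with `N`, `nodes`
#'   (length `N + 1`, ascending, exactly containing 0 and 1), `D`, `D2`,
#'   `L0`, `L1` (dense `(N+1) x (N+1)` matrices), and barycentric weights
#'   `bary_w`.
#' @examples
#' g <- cgl_grid(8)
#' range(g$D %*% g$nodes^2 - 2 * g$nodes)  # exact on polynomials
#' @export
cgl_grid <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || N != round(N) || N < 2)
    stop("N must be an integer >= 2")
  N <- as.integer(N)
  k <- 0:N
  theta <- pi * k / N
  # standard ordering x = cos(theta) descends; reverse to ascending r
  cc <- c(2, rep(1, max(N - 1, 0)), 2) * (-1)^k
  D <- matrix(0, N + 1, N + 1)
  for (i in seq_len(N + 1)) {
    js <- setdiff(seq_len(N + 1), i)
    D[i, js] <- (cc[i] / cc[js]) /
      (-2 * sin((theta[i] + theta[js]) / 2) * sin((theta[i] - theta[js]) / 2))
  }
  diag(D) <- -rowSums(D)
  idx <- (N + 1):1
  r <- (1 + cos(theta[idx])) / 2       # ascending: r[1] = 0, r[N+1] = 1
  r[1] <- 0; r[N + 1] <- 1
  D <- 2 * D[idx, idx]                 # chain rule for x = 2 r - 1
  D2 <- D %*% D
  rinv <- c(0, 1 / r[-1])
  L0 <- D2 + rinv * D
  L1 <- L0 - rinv^2 * diag(N + 1)
  L0[1, ] <- 2 * D2[1, ]               # lim_{r->0} (f'' + f'/r) = 2 f''(0)
  L1[1, ] <- 1.5 * D2[1, ]             # odd-function limit: (3/2) f''(0)
  w <- (-1)^(0:N)
  w[1] <- w[1] / 2
  w[N + 1] <- w[N + 1] / 2
  structure(list(N = N, nodes = r, D = D, D2 = D2, L0 = L0, L1 = L1,
                 bary_w = w),
            class = "cgl_grid")
}

#' @export
print.cgl_grid <- function(x, ...) {
  cat("Chebyshev-Gauss-Lobatto grid on [0,1]: order N =", x$N,
      "(", x$N + 1, "nodes, ascending)\n")
  invisible(x)
}

.check_sampled <- function(grid, f) {
  stopifnot(inherits(grid, "cgl_grid"))
  if (length(f) != grid$N + 1)
    stop("sampled function has length ", length(f),
         " but the grid has ", grid$N + 1, " nodes")
  invisible(TRUE)
}

#' Apply the axial cylindrical operator L0
#'
#' Returns \eqn{f'' + f'/r} of a function sampled at the grid nodes,
#' to spectral accuracy away from the centerline (where the regularized
#' symmetric limit is used).
#'
#' @param grid a [cgl_grid()].
#' @param f numeric or complex vector sampled at `grid$nodes`.
#' @return Vector of the same length as `f`.
#' @export
apply_L0 <- function(grid, f) {
  .check_sampled(grid, f)
  drop(grid$L0 %*% f)
}

#' Apply the azimuthal cylindrical operator L1
#'
#' Returns \eqn{f'' + f'/r - f/r^2} of a function sampled at the grid
#' nodes, to spectral accuracy away from the centerline.
#'
#' @inheritParams apply_L0
#' @return Vector of the same length as `f`.
#' @export
apply_L1 <- function(grid, f) {
  .check_sampled(grid, f)
  drop(grid$L1 %*% f)
}

#' Barycentric interpolation matrix for CGL data
#'
#' Builds the matrix `P` such that `P %*% f` evaluates the degree-`N`
#' polynomial interpolant of nodal values `f` at the target radii. Exact
#' at the nodes and for any polynomial of degree at most `N`.
#'
#' @param grid a [cgl_grid()].
#' @param targets radii in \[0, 1\].
#' @return A `length(targets) x (N+1)` matrix.
#' @export
interp_matrix <- function(grid, targets) {
  stopifnot(inherits(grid, "cgl_grid"), is.numeric(targets))
  if (any(!is.finite(targets)) || any(targets < 0) || any(targets > 1))
    stop("interpolation targets must lie in [0, 1]")
  r <- grid$nodes
  w <- grid$bary_w
  P <- matrix(0, length(targets), length(r))
  for (i in seq_along(targets)) {
    d <- targets[i] - r
    hit <- which(d == 0)
    if (length(hit)) {
      P[i, hit[1]] <- 1
    } else {
      q <- w / d
      P[i, ] <- q / sum(q)
    }
  }
  P
}

#' Evaluate the spectral interpolant at arbitrary radii
#'
#' @param grid a [cgl_grid()].
#' @param f numeric or complex vector sampled at `grid$nodes`.
#' @param targets radii in \[0, 1\].
#' @return Interpolated values at `targets`.
#' @examples
#' g <- cgl_grid(5)
#' barycentric_eval(g, g$nodes^3, 0.3)   # exactly 0.027
#' @export
barycentric_eval <- function(grid, f, targets) {
  .check_sampled(grid, f)
  drop(interp_matrix(grid, targets) %*% f)
}
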