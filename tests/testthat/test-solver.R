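test_that("steady solves match the hand-derived closed forms", {
  g <- grid40
  # isotropic steady: Poiseuille
  s <- solve_harmonic(g, 10, 0, iso, 1)
  expect_equal(Re(s$Uz), (1 - g$nodes^2) / 4, tolerance = 1e-12)
  expect_lt(max(Mod(s$Utheta)), 1e-12)
  # anisotropic steady swirl: (c/3)(r^2 - r) with c = 0.101010...
  s <- solve_harmonic(g, 10, 0, aniso11, 1)
  expect_equal(Re(s$Utheta),
               steady_swirl_exact(g$nodes, 0.1, 0.1, 1),
               tolerance = 1e-12)
  expect_equal(Re(barycentric_eval(g, s$Utheta, 0.5)),
               -(0.1 / 0.99) / 3 * 0.25, tolerance = 1e-10)
})

test_that("assembly decouples in the isotropic limit and replaces BC rows", {
  g <- cgl_grid(10)
  n <- g$N + 1
  sys <- assemble_system(g, 5, 2, iso, 1)
  expect_true(all(sys$A[seq_len(n), n + seq_len(n)] == 0))
  expect_true(all(sys$A[n + seq_len(n), seq_len(n)] == 0))
  # wall row of the axial block is the unit selector of the wall node
  ewall <- rep(0, 2 * n); ewall[n] <- 1
  expect_equal(as.vector(sys$A[n, ]), as.complex(ewall))
  expect_equal(sys$b[n], 0 + 0i)
  # steady assembly has no imaginary inertial term on the diagonal
  sys0 <- assemble_system(g, 5, 0, iso, 1)
  expect_true(all(Im(diag(sys0$A)[2:(n - 1)]) == 0))
})

test_that("boundary and symmetry invariants hold for oscillatory solves", {
  g <- grid40
  for (alpha in c(3, 12)) for (h in c(1, 3)) {
    s <- solve_harmonic(g, alpha, h, aniso11, 0.8)
    expect_lt(Mod(s$Uz[g$N + 1]), 1e-12)        # no-slip
    expect_lt(Mod(s$Utheta[g$N + 1]), 1e-12)
    expect_lt(Mod(s$Utheta[1]), 1e-12)          # centerline regularity
    expect_lt(Mod((g$D %*% s$Uz)[1]), 1e-10)    # centerline symmetry
    expect_lt(interior_residual(s), 1e-12)
  }
})

test_that("isotropic oscillatory solves generate no spurious swirl", {
  g <- grid40
  for (alpha in c(3, 8, 22)) {
    s <- solve_harmonic(g, alpha, 1, iso, 1)
    expect_lt(max(Mod(s$Utheta)), 1e-12)
  }
})

test_that("solutions are linear in the forcing and in gamma", {
  g <- grid40
  s1 <- solve_harmonic(g, 8, 1, aniso11, 1)
  s2 <- solve_harmonic(g, 8, 1, aniso11, 2)
  expect_equal(s2$Uz, 2 * s1$Uz, tolerance = 1e-12)
  expect_equal(s2$Utheta, 2 * s1$Utheta, tolerance = 1e-12)
  # swirl is exactly linear in gamma when the beta-feedback is absent
  # (the coupling enters Utheta only through gamma * L0 Uz)
  a <- solve_harmonic(g, 8, 1, anisotropy_ratios(0, 0.02, 1), 1)
  b <- solve_harmonic(g, 8, 1, anisotropy_ratios(0, 0.08, 1), 1)
  expect_equal(max(Mod(b$Utheta)) / max(Mod(a$Utheta)), 4,
               tolerance = 1e-12)
  # with beta-feedback the deviation from linearity is O(beta*gamma)
  af <- solve_harmonic(g, 8, 1, anisotropy_ratios(0.05, 0.02, 1), 1)
  bf <- solve_harmonic(g, 8, 1, anisotropy_ratios(0.05, 0.08, 1), 1)
  expect_equal(max(Mod(bf$Utheta)) / max(Mod(af$Utheta)), 4,
               tolerance = 0.01)
})

test_that("waveform solves return one independent solution per harmonic", {
  g <- grid24
  wf <- waveform(c(1, 0.5, -0.2), "demo")
  sols <- solve_waveform(g, 6, aniso11, wf)
  expect_length(sols, 3)
  expect_equal(vapply(sols, function(s) s$h, 1L), 0:2)
  single <- solve_harmonic(g, 6, 1, aniso11, 0.5)
  expect_equal(sols[[2]]$Uz, single$Uz)
  # Table-1 thoracic record gives six solutions at h = 0..5
  rec <- artery_record("Thoracic Aorta")
  sols <- solve_waveform(g, rec$alpha, aniso11, rec$waveform)
  expect_length(sols, 6)
})

test_that("an independent finite-difference discretization converges to the
           spectral solution", {
  # second-order FD on a uniform grid, assembled from the same equations
  fd_solve <- function(M, alpha, h, beta, gamma, delta, a) {
    r <- seq(0, 1, length.out = M + 1); dr <- r[2] - r[1]; n <- M + 1
    D1 <- matrix(0, n, n); D2 <- matrix(0, n, n)
    for (i in 2:M) {
      D1[i, i - 1] <- -1 / (2 * dr); D1[i, i + 1] <- 1 / (2 * dr)
      D2[i, i - 1] <- 1 / dr^2; D2[i, i] <- -2 / dr^2
      D2[i, i + 1] <- 1 / dr^2
    }
    rin <- c(0, 1 / r[-1])
    L0 <- D2 + rin * D1
    L1 <- L0 - rin^2 * diag(n)
    A <- rbind(cbind(L0 - 1i * h * alpha^2 * diag(n), beta * L1),
               cbind(gamma * L0, delta * L1 - 1i * h * alpha^2 * diag(n)))
    b <- c(rep(-a + 0i, n), rep(0i, n))
    A[1, ] <- 0; A[1, 1:3] <- c(-3, 4, -1) / (2 * dr); b[1] <- 0
    A[n, ] <- 0; A[n, n] <- 1; b[n] <- 0
    A[n + 1, ] <- 0; A[n + 1, n + 1] <- 1; b[n + 1] <- 0
    A[2 * n, ] <- 0; A[2 * n, 2 * n] <- 1; b[2 * n] <- 0
    u <- solve(A, b)
    list(r = r, Uz = u[1:n], Utheta = u[(n + 1):(2 * n)])
  }
  g <- grid40
  s <- solve_harmonic(g, 3, 1, aniso11, 1)
  errs <- vapply(c(250, 1000), function(M) {
    fd <- fd_solve(M, 3, 1, 0.1, 0.1, 1, 1)
    max(Mod(barycentric_eval(g, s$Uz, fd$r) - fd$Uz),
        Mod(barycentric_eval(g, s$Utheta, fd$r) - fd$Utheta)) /
      max(Mod(fd$Uz))
  }, numeric(1))
  expect_lt(errs[2], 1e-4)
  expect_lt(errs[2], errs[1] / 10)   # second-order refinement
})
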