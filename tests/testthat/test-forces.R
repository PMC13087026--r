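test_that("Fourier synthesis reproduces amplitudes, periodicity and means", {
  g <- grid24
  s1 <- solve_harmonic(g, 6, 1, aniso11, 1)
  fld <- synthesize(list(s1), 64)
  # t* = 0: field equals the real part of the amplitude
  expect_equal(fld$uz[, 1], Re(s1$Uz))
  expect_equal(fld$utheta[, 1], Re(s1$Utheta))
  # periodic: synthesis at t* = 1 equals t* = 0
  expect_equal(Re(s1$Uz * exp(2i * pi * 1)), fld$uz[, 1], tolerance = 1e-14)
  # wall row vanishes (no-slip)
  expect_lt(max(abs(fld$uz[g$N + 1, ])), 1e-10)
  # cycle mean equals the steady harmonic amplitude
  rec <- artery_record("Carotid")
  sols <- solve_waveform(g, rec$alpha, aniso11, rec$waveform)
  fld <- synthesize(sols, 128)
  expect_equal(rowMeans(fld$uz), Re(sols[[1]]$Uz), tolerance = 1e-12)
  # mixed grids rejected
  s2 <- solve_harmonic(grid40, 6, 1, aniso11, 1)
  expect_error(synthesize(list(s1, s2), 64), "share one grid")
})

test_that("vorticity matches closed forms including the centerline limit", {
  g <- grid40
  Nt <- 8
  mk <- function(uz, ut) {
    f <- mono_field(5, iso, N = 40, Nt = Nt)
    f$uz <- matrix(uz, g$N + 1, Nt)
    f$utheta <- matrix(ut, g$N + 1, Nt)
    f
  }
  r <- g$nodes
  w <- vorticity(mk(0 * r, r))               # solid-body swirl
  expect_equal(w$omega_z[, 1], rep(2, g$N + 1), tolerance = 1e-10)
  w <- vorticity(mk(1 - r^2, 0 * r))         # Poiseuille
  expect_equal(w$omega_theta[, 1], 2 * r, tolerance = 1e-10)
  w <- vorticity(mk(0 * r, r^2 - r))
  expect_equal(w$omega_z[, 1], 3 * r - 2, tolerance = 1e-10)
})

test_that("the radial Lamb component has the centripetal structure", {
  g <- grid40
  r <- g$nodes
  f <- mono_field(5, iso, N = 40, Nt = 8)
  f$uz <- matrix(1 - r^2, g$N + 1, 8)
  f$utheta <- matrix(0, g$N + 1, 8)
  ell <- lamb_radial(f)
  expect_equal(ell[, 1], -2 * r * (1 - r^2), tolerance = 1e-9)
  # u_z >= 0 and decreasing: inward (non-positive) force everywhere
  expect_true(all(ell <= 1e-12))
  f$uz <- matrix(0, g$N + 1, 8)
  expect_equal(lamb_radial(f), matrix(0, g$N + 1, 8))
  # isotropic solver output: collapses to u_z d(u_z)/dr
  fld <- mono_field(8, iso, N = 40, Nt = 16)
  ell <- lamb_radial(fld)
  expect_lt(max(abs(ell - fld$uz * (g$D %*% fld$uz))), 1e-12)
})

test_that("a mono-harmonic Lamb field carries only DC and twice the driving
           frequency", {
  fld <- mono_field(8, aniso11, N = 40, Nt = 64)
  ell <- lamb_radial(fld)
  x <- ell[30, ]                     # fixed interior radius
  a <- Mod(stats::fft(x)) / length(x)
  present <- a[c(1, 3)]              # h = 0 and h = 2
  absent <- a[c(2, 4, 5, 6)]         # h = 1, 3, 4, 5
  expect_gt(min(present), 1e3 * max(absent))
})

test_that("pillbox integration is exact for constants and stable in Nt", {
  sc <- physical_scales(R = 0.012)
  ecg <- ec_geometry()
  g <- grid40
  fld <- mono_field(5, iso, N = 40, Nt = 32)
  fld$uz <- matrix(0, g$N + 1, 32)
  fld$utheta <- matrix(0, g$N + 1, 32)
  expect_equal(ec_force(fld, sc, ecg)$F_EC, rep(0, 32))
  # constant ell_r = f0 inside the pillbox: F = A * delta * rho U0^2/R * f0
  # (dimensionless ell integrates to f0 * delta/R over the pillbox)
  fld$uz <- matrix(g$nodes, g$N + 1, 32)     # uz = r -> ell_r = r
  F <- ec_force(fld, sc, ecg)$F_EC
  eps <- ecg$delta_EC / sc$R
  exact <- ecg$A_EC * sc$rho * sc$U0^2 * (1 - eps / 2) * eps
  expect_equal(F, rep(exact, 32), tolerance = 1e-10)
  # refinement stability: physiological case, Nt 256 vs 512 within 0.1%
  case <- solve_artery("Carotid", N = 60, Nt = 256)
  f1 <- mean(ec_force(case$field, case$scales)$F_EC)
  fld2 <- synthesize(case$solutions, 512)
  f2 <- mean(ec_force(fld2, case$scales)$F_EC)
  expect_lt(abs(f1 - f2) / f2, 1e-3)
  expect_error(ec_force(case$field, case$scales,
                        ec_geometry(A_EC = 1e-10, V_EC = 1e-26)),
               "thinner than resolvable")
})

test_that("pillbox quadrature agrees with adaptive quadrature of the
           interpolant", {
  case <- solve_artery("Femoral", N = 60, Nt = 32)
  sc <- case$scales
  ecg <- ec_geometry()
  ell <- lamb_radial(case$field)
  j <- 7                              # one representative phase
  eps <- ecg$delta_EC / sc$R
  oracle <- stats::integrate(function(r)
    abs(barycentric_eval(case$field$grid, ell[, j], r)),
    1 - eps, 1, rel.tol = 1e-10)$value
  got <- ec_force(case$field, sc, ecg, n_sub = 256)$F_EC[j]
  expect_equal(got, ecg$A_EC * sc$rho * sc$U0^2 * oracle,
               tolerance = 1e-6)
})

test_that("wall traction follows the full constitutive law", {
  g <- grid40
  sc <- physical_scales(R = 0.012)
  Nt <- 8
  fld <- mono_field(5, iso, N = 40, Nt = Nt)
  fld$uz <- matrix((1 - g$nodes^2) / 4, g$N + 1, Nt)
  fld$utheta <- matrix(0, g$N + 1, Nt)
  tn_iso <- tensor_from_ratios(sc$nu_zz, iso)
  tau <- wall_traction(fld, tn_iso, sc)
  expect_equal(tau, rep(-sc$rho * sc$nu_zz * sc$U0 / (2 * sc$R), Nt),
               tolerance = 1e-10)
  expect_equal(wall_traction(fld, tn_iso, sc) * 0,
               wall_traction({fld$uz[] <- 0; fld}, tn_iso, sc))
  # anisotropic excess is exactly nu_ztheta times the azimuthal wall strain
  case <- solve_artery("Iliac", N = 60, Nt = Nt)
  tn_an <- tensor_from_ratios(sc$nu_zz, aniso11)
  dstrain <- (g2 <- case$field$grid)$D %*% case$field$utheta
  strain_t <- dstrain[g2$N + 1, ] - case$field$utheta[g2$N + 1, ] / 1
  excess <- wall_traction(case$field, tn_an, case$scales) -
    wall_traction(case$field, tensor_from_ratios(sc$nu_zz, iso),
                  case$scales)
  expect_equal(excess,
               case$scales$rho * case$scales$U0 / case$scales$R *
                 tn_an$nu_ztheta * strain_t,
               tolerance = 1e-12)
})

test_that("force ratio and angle behave at the axes and the 100 pN scale", {
  ra <- force_ratio_angle(0, 5)
  expect_equal(ra$chi, 0); expect_equal(ra$phi, 0)
  ra <- force_ratio_angle(3, 3)
  expect_equal(ra$phi, pi / 4)
  ra <- force_ratio_angle(c(1, -1), c(0, 0))
  expect_equal(ra$chi, c(Inf, Inf))
  expect_equal(ra$phi, c(pi / 2, -pi / 2))
  # tau_w = 1 Pa over A_ref = 100 um^2 is exactly 100 pN
  expect_equal(1 * 1e-10 * 1e12, 100)
  expect_error(force_ratio_angle(1:3, 1:2), "same length")
})
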