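# shared fixtures: small grids and canned solves, built once per run
grid24 <- cgl_grid(24)
grid40 <- cgl_grid(40)
iso <- anisotropy_ratios()
aniso11 <- anisotropy_ratios(0.1, 0.1, 1)

# steady anisotropic closed form: Utheta = (c/3)(r^2 - r),
# c = (gamma a / delta) / (1 - beta gamma / delta); derived by eliminating
# L0 Uz between the two steady equations and integrating L1 Utheta = c
steady_swirl_exact <- function(r, beta, gamma, delta, a = 1) {
  cc <- (gamma * a / delta) / (1 - beta * gamma / delta)
  (cc / 3) * (r^2 - r)
}

mono_field <- function(alpha, ratios, N = 40, Nt = 64, h = 1, a = 1) {
  g <- cgl_grid(N)
  synthesize(list(solve_harmonic(g, alpha, h, ratios, a)), Nt)
}
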