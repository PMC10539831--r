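test_that("diffusion eigen-times and parameter round trips are exact", {
  # isotropic degeneracy
  d_iso <- diffusion_model(D_par = 1e8, D_perp = 1e8)
  expect_equal(tau_eigenvalues(d_iso), rep(1 / 6e8, 3))
  # anisotropy 2.5 at tau_eff = 1 ns
  d <- diffusion_model(tau_eff = 1e-9, anisotropy = 2.5)
  expect_equal(tau_eigenvalues(d) * 1e9, ORACLE$tau_ns_a2.5, tolerance = 1e-12)
  # scale-free ratio at anisotropy 1.5: tau0/tau2 = (6 + 4*(1.5-1))/6 = 8/6
  for (te in c(1e-9, 7e-9)) {
    tk <- tau_eigenvalues(diffusion_model(tau_eff = te, anisotropy = 1.5))
    expect_equal(tk[1] / tk[3], 8 / 6, tolerance = 1e-12)
    expect_true(all(diff(tk) < 0))  # tau0 > tau1 > tau2 for prolate tensors
  }
  # (tau_eff, anisotropy) <-> (D_par, D_perp) round trip
  for (rho in c(0.5, 1, 1.5, 2.5)) for (te in c(1e-10, 1e-9, 2.5e-9)) {
    d <- diffusion_model(tau_eff = te, anisotropy = rho)
    expect_equal(d$tau_eff, te, tolerance = 1e-12)
    expect_equal(d$anisotropy, rho, tolerance = 1e-12)
  }
  expect_error(diffusion_model(D_par = 1e8), "either")
  expect_error(diffusion_model(tau_eff = -1, anisotropy = 1), "positive")
})

test_that("Woessner amplitudes satisfy the closure identity", {
  expect_equal(woessner_amplitudes(0, 0), c(A0 = 1, A1 = 0, A2 = 0))
  expect_equal(woessner_amplitudes(90, 90), c(A0 = 0.25, A1 = 0, A2 = 0.75),
               tolerance = 1e-12)
  expect_equal(sum(woessner_amplitudes(0, 90)), -0.5, tolerance = 1e-12)
  # sum rule: A0 + A1 + A2 = P2(cos(theta_u - theta_v)) for any signed angles
  set.seed(11)
  for (i in 1:50) {
    tu <- runif(1, -180, 180); tv <- runif(1, -180, 180)
    expect_equal(sum(woessner_amplitudes(tu, tv)),
                 p2(cos((tu - tv) * pi / 180)), tolerance = 1e-12)
  }
})

test_that("multi-Lorentzian J behaves analytically", {
  s <- lorentzian_spectrum(1, 2e-9)
  expect_equal(j_lorentzian(s, 0), 2e-9)
  expect_equal(j_lorentzian(s, 1 / 2e-9), 1e-9)  # half-height point
  # strictly decreasing in omega for all-positive amplitudes
  s2 <- lorentzian_spectrum(c(0.5, 0.3), c(2e-9, 5e-10))
  js <- j_lorentzian(s2, seq(0, 2e9, length.out = 40))
  expect_true(all(diff(js) < 0))
  expect_error(lorentzian_spectrum(c(1, 0.5), c(1e-9, 1e-9)), "amplitudes")
  expect_error(lorentzian_spectrum(1, -1e-9), "positive")
})

test_that("the model-free spectrum respects its limiting cases", {
  d <- diffusion_model(tau_eff = 1e-9, anisotropy = 2.5, beta = 30)
  # rigid limit: three Woessner terms, amplitudes sum to the P2 projection
  s1 <- build_spectrum(57, 37, d, motion_model(S2 = 1))
  expect_length(s1$a, 3)
  expect_equal(sum(s1$a), p2(cos(20 * pi / 180)), tolerance = 1e-12)
  # fully mobile limit: single isotropic term with tau3
  s0 <- build_spectrum(45, 45, d, motion_model(S2 = 0, tau_int = 1e-10))
  expect_length(s0$a, 1)
  expect_equal(s0$a, 1)
  expect_equal(s0$tau, 1 / (1 / 1e-10 + 1 / 1e-9), tolerance = 1e-12)
  # intermediate: internal-term amplitude (1 - S2) P2(cos angle)
  sh <- build_spectrum(0, 90, d, motion_model(S2 = 0.5, tau_int = 1e-10))
  expect_equal(sh$a[length(sh$a)], 0.5 * -0.5, tolerance = 1e-12)
  # normalization bound holds for random orientation pairs and S2
  set.seed(7)
  for (i in 1:40) {
    s <- build_spectrum(runif(1, -180, 180), runif(1, -180, 180), d,
                        motion_model(S2 = runif(1), tau_int = 1e-10))
    expect_gte(sum(s$a), -0.5 - 1e-9)
    expect_lte(sum(s$a), 1 + 1e-9)
  }
})

test_that("numeric cosine-transform quadrature matches closed forms to 0.1%", {
  g <- exp_tcf_grid(1e-9)
  expect_equal(numeric_j(g$t, g$c, 0), 1e-9, tolerance = 1e-3)
  expect_equal(numeric_j(g$t, g$c, 1e9), 0.5e-9, tolerance = 1e-3)
  expect_error(numeric_j(rev(g$t), g$c), "increasing")

  # four-term model-free spectrum: quadrature of the reconstructed TCF agrees
  # with the Lorentzian sum at 0 and at both Larmor frequencies
  d <- diffusion_model(tau_eff = 2.5e-9, anisotropy = 2.5, beta = 20)
  m <- motion_model(S2 = 0.6, tau_int = 1e-10)
  spec <- build_spectrum(57, 37, d, m)
  t <- seq(0, 12 * max(spec$tau), length.out = 6000)
  ct <- tcf_eval(spec, t)
  const <- physical_constants()
  for (w in c(0, abs(const$gamma_n) * const$B0, const$gamma_c * const$B0))
    expect_equal(numeric_j(t, ct, w), j_lorentzian(spec, w), tolerance = 1e-3)
})

test_that("the J(0) ratio collapses to the geometric limit without anisotropy", {
  expect_equal(iso_ratio_limit(10, 10, 50, 50), 1)
  expect_equal(iso_ratio_limit(0, 90, 20, 20), -0.5)
  expect_error(iso_ratio_limit(0, 0, 0, acos(1 / sqrt(3)) * 180 / pi),
               "magic")
  # S2 = 0: the ratio equals the limit exactly for any diffusion tensor
  d <- diffusion_model(tau_eff = 1e-9, anisotropy = 2.5, beta = 77)
  m0 <- motion_model(S2 = 0, tau_int = 2e-10)
  r <- j_lorentzian(build_spectrum(57, 37, d, m0), 0) /
       j_lorentzian(build_spectrum(0, -29, d, m0), 0)
  expect_equal(r, iso_ratio_limit(57, 37, 0, -29), tolerance = 1e-12)
  # anisotropy -> 1 at S2 = 1: same collapse
  d1 <- diffusion_model(tau_eff = 1e-9, anisotropy = 1, beta = 77)
  r1 <- j_lorentzian(build_spectrum(57, 37, d1), 0) /
        j_lorentzian(build_spectrum(0, -29, d1), 0)
  expect_equal(r1, iso_ratio_limit(57, 37, 0, -29), tolerance = 1e-9)
})
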