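# Stochastic-oracle checks. Trajectories use dt = 1e-11 s (well inside the
# dt <= 0.02/max(6 D) stability bound for ~ns tumbling) and 2e6 steps, i.e.
# 20 us of rotational diffusion -- enough to estimate P2 TCFs to well under
# a percent on their natural O(1) scale. All seeds fixed.

test_that("the step-size stability bound is enforced", {
  d <- diffusion_model(tau_eff = 1e-9, anisotropy = 2.5)
  expect_error(simulate_rotor(d, dt = 1e-10, n_steps = 100), "stability")
})

test_that("trajectories are reproducible and orientations stay normalized", {
  d <- diffusion_model(tau_eff = 1e-9, anisotropy = 2.5)
  a <- simulate_rotor(d, dt = 1e-12, n_steps = 5e4, seed = 8, stride = 10)
  b <- simulate_rotor(d, dt = 1e-12, n_steps = 5e4, seed = 8, stride = 10)
  expect_identical(a$R, b$R)
  # row norms of the rotation matrices stay unit to tight tolerance
  n1 <- sqrt(a$R[, 1]^2 + a$R[, 2]^2 + a$R[, 3]^2)
  expect_lt(max(abs(n1 - 1)), 1e-9)
})

test_that("a near-frozen rotor keeps its orientational memory", {
  # orientational decay over the longest lag ~ 6 D t = 6e-6
  d <- diffusion_model(D_par = 0.01, D_perp = 0.01)
  tr <- simulate_rotor(d, dt = 1e-7, n_steps = 1e4, seed = 2, stride = 100)
  tc <- tcf_from_trajectory(tr, 45, 45, max_lag = 10, n_lags = 11)
  expect_gt(min(tc$C), 1 - 1e-4)
})

test_that("lag-zero TCF values equal the geometric projections exactly", {
  d <- diffusion_model(tau_eff = 1e-9, anisotropy = 2.5)
  tr <- simulate_rotor(d, dt = 1e-11, n_steps = 2e4, seed = 3, stride = 2)
  expect_equal(tcf_from_trajectory(tr, 30, 30, max_lag = 1)$C[1], 1,
               tolerance = 1e-9)
  # rigid body preserves relative angles: C(0) = P2(cos 90) at every frame
  expect_equal(tcf_from_trajectory(tr, 0, 90, max_lag = 1)$C[1], -0.5,
               tolerance = 1e-9)
})

test_that("isotropic tumbling reproduces the 1/(6D) correlation time", {
  tau <- 1e-9
  d <- diffusion_model(D_par = 1 / (6 * tau), D_perp = 1 / (6 * tau))
  tr <- simulate_rotor(d, dt = 1e-11, n_steps = 2e6, seed = 1, stride = 2)
  tc <- tcf_from_trajectory(tr, 20, 20, max_lag = 250, n_lags = 120)
  fit <- stats::lm(log(C) ~ t, data = tc[tc$C > 0.2, ])
  tau_hat <- -1 / stats::coef(fit)[2]
  expect_equal(unname(tau_hat), tau, tolerance = 0.05)
})

test_that("anisotropic cross-TCFs match the Woessner closed form", {
  d <- diffusion_model(tau_eff = 1e-9, anisotropy = 2.5)
  tk <- tau_eigenvalues(d)
  tr <- simulate_rotor(d, dt = 1e-11, n_steps = 2e6, seed = 1, stride = 2)
  tc <- tcf_from_trajectory(tr, 20, 0, max_lag = 100, n_lags = 101)
  i <- which.min(abs(tc$t - tk[2]))  # evaluate near t = tau_1
  ana <- tcf_eval(build_spectrum(20, 0, d), tc$t[i])
  expect_lt(abs(tc$C[i] - ana), 0.03)
})

test_that("simulated TCFs validate against the spectral-density module", {
  pairs <- list(c(57, 37), c(0, -29), c(0, 61))
  # isotropic: tight 2% agreement
  d1 <- diffusion_model(tau_eff = 1e-9, anisotropy = 1)
  v1 <- validate_against_analytic(d1, pairs, tol = 0.02, dt = 1e-11,
                                  n_steps = 2e6, stride = 2, seed = 1)
  expect_true(all(v1$pass))
  # anisotropy 2.5 with a rotated main axis: 5%
  d2 <- diffusion_model(tau_eff = 1e-9, anisotropy = 2.5, beta = 30)
  v2 <- validate_against_analytic(d2, pairs, tol = 0.05, dt = 1e-11,
                                  n_steps = 2e6, stride = 2, seed = 1)
  expect_true(all(v2$pass))
  # negative control: comparing against the wrong main-axis orientation fails
  d_wrong <- diffusion_model(tau_eff = 1e-9, anisotropy = 2.5, beta = 30)
  traj <- simulate_rotor(d_wrong, dt = 1e-11, n_steps = 5e5, seed = 1,
                         stride = 2)
  sim <- tcf_from_trajectory(traj, 57 - 30, 37 - 30, max_lag = 500,
                             n_lags = 100)
  wrong_spec <- build_spectrum(57, 37,
                               diffusion_model(tau_eff = 1e-9,
                                               anisotropy = 2.5, beta = 120))
  rmsd_wrong <- sqrt(mean((sim$C - tcf_eval(wrong_spec, sim$t))^2))
  expect_gt(rmsd_wrong, 0.05)
})

test_that("the simulated J(0) ratio of the two channels converges to Q", {
  pl <- build_peptide_plane()
  pars <- pl$params
  o <- pl$orientations
  const <- physical_constants()
  d <- diffusion_model(tau_eff = 1e-9, anisotropy = 2.5)
  tr <- simulate_rotor(d, dt = 1e-11, n_steps = 2e6, seed = 1, stride = 2)
  n <- nrow(tr$R)
  nblk <- 8
  edges <- floor(seq(1, n + 1, length.out = nblk + 1))
  tau0 <- max(tau_eigenvalues(d))
  kn <- k_prefactor(spin_pair("N_NH", const, pars), const)
  kc <- k_prefactor(spin_pair("C_CCa", const, pars), const)
  q_of <- function(j_nh, j_xx, j_yy)
    (kc * ((pars$sigma_xx_c - pars$sigma_zz_c) * j_xx +
           (pars$sigma_yy_c - pars$sigma_zz_c) * j_yy)) /
    (kn * pars$delta_n * j_nh)
  max_lag <- ceiling(10 * tau0 / tr$dt_save)
  qs <- sapply(seq_len(nblk), function(b) {
    blk <- slice_trajectory(tr, edges[b], edges[b + 1] - 1)
    j0 <- function(u, v) {
      tc <- tcf_from_trajectory(blk, u, v, max_lag = max_lag, n_lags = 120)
      numeric_j(tc$t, tc$C, 0)
    }
    q_of(j0(o["nh"], o["n_csa"]), j0(o["c_ca"], o["c_xx"]),
         j0(o["c_ca"], o["c_yy"]))
  })
  # analytic Q with the same truncation window, for a like-for-like target
  t_grid <- seq(0, max_lag * tr$dt_save, length.out = 2000)
  jana <- function(u, v)
    numeric_j(t_grid, tcf_eval(build_spectrum(u, v, d), t_grid), 0)
  q_ana <- q_of(jana(o["nh"], o["n_csa"]), jana(o["c_ca"], o["c_xx"]),
                jana(o["c_ca"], o["c_yy"]))
  se <- stats::sd(qs) / sqrt(nblk)
  expect_lt(abs(mean(qs) - q_ana), 3 * se + 0.01)
  # and the windowed analytic target itself is close to the model Q
  expect_equal(q_ana, ccr_model(tau_eff = 1e-9, anisotropy = 2.5, S2 = 1)$Q,
               tolerance = 0.02)
})
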