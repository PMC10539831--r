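# Values frozen from independent hand/numeric oracles (plain trigonometry and
# CODATA arithmetic, worked out separately from the package code paths).

ORACLE <- list(
  q_iso = 0.3097549,        # (kC/kN) * (161.5*P2(cos29) + 103.2*P2(cos61)) / (170*P2(cos20))
  k_ratio = 0.4859612,      # gc^3 r_NH^3 / (gn^2 gh r_CCa^3)
  caca_angle = 157.8022,    # atan2 of Ca(i)->Ca(i+1) in the canonical frame
  tau_ns_a2.5 = c(1.5, 1.2, 0.75),  # anisotropy 2.5, tau_eff 1 ns
  beta_min_a2.5 = 75,       # argmin/argmax of Q over 1-deg grid, S2 = 1
  beta_max_a2.5 = 162
)

dist2 <- function(a, b) sqrt(sum((a - b)^2))

# unit-amplitude exponential TCF sampled densely enough for 0.1 % quadrature
exp_tcf_grid <- function(tau, n_per_tau = 200, n_tau = 12) {
  t <- seq(0, n_tau * tau, length.out = n_per_tau * n_tau + 1)
  list(t = t, c = exp(-t / tau))
}

# view on a contiguous frame range of a rotor trajectory (for block averaging)
slice_trajectory <- function(traj, from, to) {
  structure(list(R = traj$R[from:to, , drop = FALSE],
                 dt_save = traj$dt_save, dt = traj$dt,
                 n_steps = (to - from) * traj$stride, stride = traj$stride,
                 d = traj$d),
            class = "rotor_trajectory")
}
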