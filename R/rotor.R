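#' Brownian rotational-diffusion trajectory
#'
#' Simulates rigid-body rotational diffusion of an axially symmetric top
#' carrying the peptide plane: at every step, small Gaussian random rotations
#' about the three body axes (variances `2 D_perp dt` about the two
#' perpendicular axes, `2 D_par dt` about the unique z axis) are composed in
#' random order and applied in the body frame. This is the stochastic oracle
#' against which the closed-form Woessner spectral densities are validated.
#' The orientation matrix is re-orthonormalized every 1000 steps (drift well
#' below 1e-9). Trajectories are reproducible under [set.seed()].
#'
#' @param d a [diffusion_model()].
#' @param dt time step, seconds; must satisfy the stability bound
#'   `dt <= 0.02 / max(6 D_par, 6 D_perp)`.
#' @param n_steps number of steps.
#' @param seed optional RNG seed ([set.seed()] is called when given).
#' @param stride save every `stride`-th frame.
#' @return object of class `rotor_trajectory`: `R` (n_save x 9 matrix of
#'   row-major body-to-lab rotation matrices), `dt_save` (seconds between
#'   saved frames), `dt`, `n_steps`, `stride`, `d`.
#' @export
#' @examples
#' d <- diffusion_model(tau_eff = 1e-9, anisotropy = 1)
#' tr <- simulate_rotor(d, dt = 1e-12, n_steps = 1000, seed = 1)
simulate_rotor <- function(d, dt, n_steps, seed = NULL, stride = 1L) {
  stopifnot(inherits(d, "diffusion_model"))
  bound <- 0.02 / max(6 * d$D_par, 6 * d$D_perp)
  if (dt > bound)
    stop(sprintf(
      "dt = %.3g s exceeds the stability bound 0.02 / max(6 D_par, 6 D_perp) = %.3g s",
      dt, bound))
  n_steps <- as.integer(n_steps)
  stride <- as.integer(stride)
  if (n_steps < 1L || stride < 1L) stop("n_steps and stride must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  R <- rotor_trajectory_cpp(d$D_par, d$D_perp, dt, n_steps, stride)
  structure(list(R = R, dt_save = dt * stride, dt = dt,
                 n_steps = n_steps, stride = stride, d = d),
            class = "rotor_trajectory")
}

#' @export
print.rotor_trajectory <- function(x, ...) {
  cat(sprintf(
    "Brownian rotor trajectory: %d steps of %.3g s (%d frames saved)\n",
    x$n_steps, x$dt, nrow(x$R)))
  print(x$d)
  invisible(x)
}

# lab-frame series of a body-fixed unit vector at angle theta (deg) from the
# unique axis, in the body xz plane (all peptide-plane vectors are coplanar
# with the main axis)
lab_vectors <- function(traj, theta) {
  u <- c(sin(theta * pi / 180), 0, cos(theta * pi / 180))
  R <- traj$R
  cbind(R[, 1] * u[1] + R[, 2] * u[2] + R[, 3] * u[3],
        R[, 4] * u[1] + R[, 5] * u[2] + R[, 6] * u[3],
        R[, 7] * u[1] + R[, 8] * u[2] + R[, 9] * u[3])
}

#' Orientational correlation function from a trajectory
#'
#' Lag-averaged estimate of `C(t) = < P2(u(0) . v(t)) >` (symmetrized over
#' the order of `u` and `v`) for two body-fixed vectors given as angles from
#' the diffusion main axis.
#'
#' @param traj a [simulate_rotor()] trajectory.
#' @param u,v signed angles of the body-fixed vectors from the unique axis,
#'   degrees.
#' @param max_lag largest lag, in saved frames; must not exceed a tenth of
#'   the saved trajectory length (defaults to that bound).
#' @param n_lags number of lag values (spread evenly from 0 to `max_lag`).
#' @return data frame with columns `t` (seconds) and `C`.
#' @export
tcf_from_trajectory <- function(traj, u, v = u,
                                max_lag = nrow(traj$R) %/% 10,
                                n_lags = 200) {
  stopifnot(inherits(traj, "rotor_trajectory"))
  n <- nrow(traj$R)
  if (max_lag > n %/% 10)
    stop("max_lag must not exceed a tenth of the saved trajectory length")
  lags <- unique(round(seq(0, max_lag, length.out = min(n_lags, max_lag + 1))))
  U <- lab_vectors(traj, u)
  V <- if (identical(u, v)) U else lab_vectors(traj, v)
  data.frame(t = lags * traj$dt_save,
             C = tcf_lags_cpp(U, V, as.integer(lags)))
}

#' Validate closed-form spectral densities against the Brownian rotor
#'
#' For each vector pair, simulates a rigid-body trajectory with the given
#' diffusion tensor, estimates the orientational cross-correlation function,
#' and compares it with the analytic three-Lorentzian form (rigid limit,
#' `S2 = 1`). The pass/fail measure is the root-mean-square deviation of the
#' TCF over lags up to ten times the slowest correlation time; TCF amplitudes
#' are O(1), so this is on the natural scale of the curve. The deviation of
#' the windowed zero-frequency integral `int_0^t_max C dt` is also reported,
#' normalized by the corresponding integral of a unit-amplitude decay at the
#' slowest correlation time (normalizing by the pair's own J(0) would blow up
#' for cross pairs near the magic angle, where J(0) itself is near zero).
#'
#' @param d a [diffusion_model()] (its `beta` is part of the test: vector
#'   angles are interpreted relative to the C'->Ca axis, so the angle to the
#'   main axis is `angle - beta`).
#' @param pairs list of length-2 numeric vectors: in-plane orientations
#'   (degrees from C'->Ca) of each vector pair.
#' @param tol pass tolerance on the TCF root-mean-square deviation.
#' @param dt,n_steps,stride,seed simulation controls (see [simulate_rotor()]).
#' @return data frame with one row per pair: `u`, `v`, `rmsd`, `j0_dev`
#'   (scaled as described above), `pass`.
#' @export
validate_against_analytic <- function(d, pairs, tol = 0.05,
                                      dt = 1e-12, n_steps = 2e6,
                                      stride = 10L, seed = NULL) {
  stopifnot(inherits(d, "diffusion_model"))
  traj <- simulate_rotor(d, dt = dt, n_steps = n_steps, seed = seed,
                         stride = stride)
  tau0 <- max(tau_eigenvalues(d))
  max_lag <- min(nrow(traj$R) %/% 10, ceiling(10 * tau0 / traj$dt_save))
  rows <- lapply(pairs, function(pr) {
    theta <- pr - d$beta
    sim <- tcf_from_trajectory(traj, theta[1], theta[2], max_lag = max_lag)
    spec <- build_spectrum(pr[1], pr[2], d, motion_model(S2 = 1))
    ana <- tcf_eval(spec, sim$t)
    j0_sim <- numeric_j(sim$t, sim$C, 0)
    j0_ana <- numeric_j(sim$t, ana, 0)
    rmsd <- sqrt(mean((sim$C - ana)^2))
    t_max <- max(sim$t)
    j0_scale <- tau0 * (1 - exp(-t_max / tau0))  # unit-amplitude reference
    data.frame(u = pr[1], v = pr[2], rmsd = rmsd,
               j0_dev = abs(j0_sim - j0_ana) / j0_scale,
               pass = rmsd <= tol)
  })
  do.call(rbind, rows)
}
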