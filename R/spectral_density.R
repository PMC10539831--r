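#' Axially symmetric rotational diffusion model
#'
#' Defines the rotational diffusion tensor either by its principal rates
#' (`D_par`, `D_perp`) or by the effective tumbling time and anisotropy,
#' related through `tau_eff = 1 / (4 D_perp + 2 D_par)` and
#' `anisotropy = D_par / D_perp`. `beta` is the in-plane orientation of the
#' unique (main) diffusion axis, in degrees from the C'->Ca reference axis,
#' rotating towards the N-HN vector.
#'
#' @param D_par,D_perp diffusion rates about and perpendicular to the unique
#'   axis, 1/s; both positive.
#' @param tau_eff effective tumbling time in seconds (alternative input).
#' @param anisotropy `D_par / D_perp`, dimensionless (alternative input).
#' @param beta main-axis in-plane orientation, degrees.
#' @return object of class `diffusion_model` with fields `D_par`, `D_perp`,
#'   `tau_eff`, `anisotropy`, `beta`.
#' @export
#' @examples
#' d <- diffusion_model(tau_eff = 1e-9, anisotropy = 2.5)
#' d$D_perp * d$tau_eff * (4 + 2 * 2.5)  # 1: exact round trip
diffusion_model <- function(D_par = NULL, D_perp = NULL,
                            tau_eff = NULL, anisotropy = NULL, beta = 0) {
  from_rates <- !is.null(D_par) && !is.null(D_perp)
  from_tau <- !is.null(tau_eff) && !is.null(anisotropy)
  if (from_rates == from_tau)
    stop("give either (D_par, D_perp) or (tau_eff, anisotropy)")
  if (from_tau) {
    if (tau_eff <= 0 || anisotropy <= 0)
      stop("tau_eff and anisotropy must be positive")
    D_perp <- 1 / (tau_eff * (4 + 2 * anisotropy))
    D_par <- anisotropy * D_perp
  }
  if (D_par <= 0 || D_perp <= 0) stop("diffusion rates must be positive")
  structure(list(D_par = D_par, D_perp = D_perp,
                 tau_eff = 1 / (4 * D_perp + 2 * D_par),
                 anisotropy = D_par / D_perp,
                 beta = beta),
            class = "diffusion_model")
}

#' @export
print.diffusion_model <- function(x, ...) {
  cat(sprintf(
    "Axially symmetric diffusion: D_par = %.4g /s, D_perp = %.4g /s\n",
    x$D_par, x$D_perp))
  cat(sprintf("  tau_eff = %.4g s, anisotropy = %.4g, beta = %g deg\n",
              x$tau_eff, x$anisotropy, x$beta))
  invisible(x)
}

#' Model-free internal motion
#'
#' Fast isotropic internal motion superimposed on the overall tumbling: a
#' generalized order parameter `S2` weights the slow anisotropic contribution
#' against a single fast isotropic decay with correlation time `tau_int`.
#'
#' @param S2 order parameter in `[0, 1]`.
#' @param tau_int internal correlation time, seconds, positive.
#' @return object of class `motion_model`.
#' @export
motion_model <- function(S2 = 1, tau_int = 1e-10) {
  if (S2 < 0 || S2 > 1) stop("S2 must lie in [0, 1]")
  if (tau_int <= 0) stop("tau_int must be positive")
  structure(list(S2 = S2, tau_int = tau_int), class = "motion_model")
}

#' Correlation times of the axially symmetric diffusion tensor
#'
#' The three rank-2 decay times `tau_k = 1 / (6 D_perp + k^2 (D_par - D_perp))`
#' for `k = 0, 1, 2`, i.e. the inverted eigenvalues of the rotational
#' diffusion operator of a symmetric top.
#'
#' @param d a [diffusion_model()].
#' @return numeric vector `c(tau0, tau1, tau2)` in seconds.
#' @export
#' @examples
#' tau_eigenvalues(diffusion_model(tau_eff = 1e-9, anisotropy = 2.5)) * 1e9
#' # 1.5 1.2 0.75 ns
tau_eigenvalues <- function(d) {
  stopifnot(inherits(d, "diffusion_model"))
  k <- 0:2
  1 / (6 * d$D_perp + k^2 * (d$D_par - d$D_perp))
}

#' Woessner amplitudes for coplanar vectors
#'
#' Amplitudes of the three Lorentzian components of the cross time-correlation
#' function of two vectors rigidly attached to a symmetric top, specialized to
#' vectors coplanar with the unique axis. `theta_u` and `theta_v` are signed
#' in-plane angles from the unique axis; the signs absorb the azimuthal phase
#' (phi_u - phi_v is 0 or 180 degrees for coplanar vectors).
#'
#' @param theta_u,theta_v signed angles from the main axis, degrees.
#' @return numeric vector `c(A0, A1, A2)`; the amplitudes always sum to
#'   `p2(cos(theta_u - theta_v))`.
#' @export
#' @examples
#' woessner_amplitudes(90, 90)  # c(0.25, 0, 0.75)
woessner_amplitudes <- function(theta_u, theta_v) {
  tu <- theta_u * pi / 180
  tv <- theta_v * pi / 180
  c(A0 = p2(cos(tu)) * p2(cos(tv)),
    A1 = 0.75 * sin(2 * tu) * sin(2 * tv),
    A2 = 0.75 * sin(tu)^2 * sin(tv)^2)
}

#' Multi-Lorentzian spectrum
#'
#' A spectral density represented as a list of `(amplitude, correlation time)`
#' pairs, `J(omega) = sum_k a_k tau_k / (1 + (omega tau_k)^2)`. The amplitudes
#' must sum to a value in `[-0.5, 1]` (the value of the time-correlation
#' function at t = 0, a second-rank Legendre average).
#'
#' @param a amplitudes, dimensionless.
#' @param tau correlation times, seconds, all positive.
#' @return object of class `lorentzian_spectrum` with fields `a` and `tau`.
#' @export
lorentzian_spectrum <- function(a, tau) {
  if (length(a) != length(tau)) stop("a and tau must have equal length")
  if (any(tau <= 0)) stop("all correlation times must be positive")
  s <- sum(a)
  if (s < -0.5 - 1e-9 || s > 1 + 1e-9)
    stop("sum of amplitudes (", format(s), ") outside [-0.5, 1]")
  structure(list(a = as.numeric(a), tau = as.numeric(tau)),
            class = "lorentzian_spectrum")
}

#' @export
print.lorentzian_spectrum <- function(x, ...) {
  cat("Lorentzian spectrum:\n")
  print(data.frame(a = x$a, tau_s = x$tau))
  invisible(x)
}

#' Evaluate a multi-Lorentzian spectral density
#'
#' @param spec a [lorentzian_spectrum()].
#' @param omega angular frequency (rad/s), non-negative; vectorized.
#' @return `J(omega)` in seconds.
#' @export
j_lorentzian <- function(spec, omega = 0) {
  stopifnot(inherits(spec, "lorentzian_spectrum"))
  if (any(omega < 0)) stop("omega must be non-negative")
  vapply(omega,
         function(w) sum(spec$a * spec$tau / (1 + (w * spec$tau)^2)),
         numeric(1))
}

#' Reconstruct the time-correlation function of a spectrum
#'
#' `C(t) = sum_k a_k exp(-t / tau_k)`, the inverse of the Lorentzian
#' decomposition. Used mainly to cross-validate [j_lorentzian()] against
#' numerical quadrature and the Brownian rotor simulator.
#'
#' @param spec a [lorentzian_spectrum()].
#' @param t times in seconds (vectorized).
#' @return `C(t)` values.
#' @export
tcf_eval <- function(spec, t) {
  stopifnot(inherits(spec, "lorentzian_spectrum"))
  vapply(t, function(ti) sum(spec$a * exp(-ti / spec$tau)), numeric(1))
}

#' Model-free spectrum of two peptide-plane vectors
#'
#' Builds the four-Lorentzian cross spectral density of two in-plane vectors
#' for axially symmetric tumbling plus fast isotropic internal motion: three
#' Woessner terms with amplitudes `S2 * A_k` and times [tau_eigenvalues()],
#' and an internal term with amplitude `(1 - S2) * P2(cos(angle(u, v)))` and
#' time `tau3 = 1 / (1/tau_int + 1/tau_eff)`. Terms with exactly zero
#' amplitude are dropped, so `S2 = 1` yields the rigid three-term spectrum and
#' `S2 = 0` the single isotropic term.
#'
#' @param u,v signed in-plane orientations (degrees from C'->Ca).
#' @param d a [diffusion_model()]; angles to the main axis are `u - beta` and
#'   `v - beta`.
#' @param m a [motion_model()].
#' @return a [lorentzian_spectrum()].
#' @export
#' @examples
#' d <- diffusion_model(tau_eff = 1e-9, anisotropy = 2.5)
#' s <- build_spectrum(57, 37, d, motion_model(S2 = 1))
#' sum(s$a) - p2(cos(20 * pi / 180))  # 0: normalization at t = 0
build_spectrum <- function(u, v, d, m = motion_model(S2 = 1)) {
  stopifnot(inherits(d, "diffusion_model"), inherits(m, "motion_model"))
  amps <- woessner_amplitudes(u - d$beta, v - d$beta)
  tau3 <- 1 / (1 / m$tau_int + 1 / d$tau_eff)
  a <- c(m$S2 * amps, (1 - m$S2) * p2(cos(angle_between(u, v) * pi / 180)))
  tau <- c(tau_eigenvalues(d), tau3)
  keep <- a != 0
  if (!any(keep)) keep[1] <- TRUE  # degenerate: all-zero TCF, keep one term
  lorentzian_spectrum(a[keep], tau[keep])
}

#' Isotropic limit of the J(0) ratio
#'
#' In the isotropic limit (no diffusion anisotropy, or no orientational weight
#' on the anisotropic terms) the zero-frequency spectral-density ratio of two
#' vector pairs sharing the same dynamics collapses to a ratio of geometric
#' projections: `P2(cos(angle(u, v))) / P2(cos(angle(x, y)))`.
#'
#' @param u,v first vector pair (signed in-plane orientations, degrees).
#' @param x,y second vector pair (the denominator).
#' @return dimensionless ratio.
#' @export
iso_ratio_limit <- function(u, v, x, y) {
  den <- p2(cos(angle_between(x, y) * pi / 180))
  if (abs(den) < 1e-9)
    stop("denominator pair is at the magic angle: P2 vanishes")
  p2(cos(angle_between(u, v) * pi / 180)) / den
}

#' Numerical spectral density from a sampled TCF
#'
#' Cosine-transform quadrature `J(omega) = integral C(t) cos(omega t) dt`
#' evaluated by the trapezoidal rule on a sampled time-correlation function.
#' Serves as the model-independent oracle for [j_lorentzian()]: the time grid
#' should resolve the slowest correlation time with at least ~50 points and
#' extend to ~10 times the slowest time.
#'
#' @param t time grid, seconds, strictly increasing from 0.
#' @param c_t sampled `C(t)` values.
#' @param omega angular frequency (rad/s), vectorized.
#' @return `J(omega)` in seconds.
#' @export
numeric_j <- function(t, c_t, omega = 0) {
  if (length(t) != length(c_t)) stop("t and c_t must have equal length")
  if (any(diff(t) <= 0)) stop("time grid must be strictly increasing")
  dt <- diff(t)
  vapply(omega, function(w) {
    f <- c_t * cos(w * t)
    sum(0.5 * (f[-1] + f[-length(f)]) * dt)
  }, numeric(1))
}
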