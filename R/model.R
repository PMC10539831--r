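#' Forward CCR model of a tumbling peptide plane
#'
#' Central constructor of the package: combines the peptide-plane geometry, an
#' axially symmetric rotational diffusion tensor with in-plane main axis, and
#' a model-free description of fast internal motion into a forward model of
#' the transverse/longitudinal CSA-dipole CCR rates of the 15N/N-HN and
#' 13C'/C'-Ca spin pairs and their zero-frequency ratio Q.
#'
#' The model is fully parametric (nothing is estimated from data), so the
#' usual extractor verbs act on the forward calculation: [predict.ccr_model()]
#' evaluates Q over diffusion-axis orientations, [simulate.ccr_model()] runs
#' Brownian rotational-diffusion trajectories consistent with the model, and
#' [plot.ccr_model()] draws the orientation profile of Q.
#'
#' @param tau_eff effective tumbling time `1/(4 D_perp + 2 D_par)`, seconds.
#' @param anisotropy `D_par / D_perp`.
#' @param beta in-plane orientation of the diffusion main axis, degrees from
#'   the C'->Ca axis (rotating towards the N-HN vector).
#' @param S2 generalized order parameter in `[0, 1]`.
#' @param tau_int internal correlation time, seconds.
#' @param B0 magnetic field, Tesla.
#' @param plane a [build_peptide_plane()] object.
#' @param D_par,D_perp alternative direct specification of the diffusion
#'   rates (overrides `tau_eff`/`anisotropy` when both are given).
#' @return object of class `ccr_model` with the geometry, dynamics, per-channel
#'   [rate_set()]s, spectral densities and the ratio `Q`.
#' @export
#' @examples
#' m <- ccr_model(tau_eff = 1e-9, anisotropy = 1, S2 = 0.5)
#' m$Q  # isotropic baseline, ~0.31
ccr_model <- function(tau_eff = 1e-9, anisotropy = 1, beta = 0,
                      S2 = 1, tau_int = 1e-10, B0 = 18.8,
                      plane = build_peptide_plane(),
                      D_par = NULL, D_perp = NULL) {
  d <- if (!is.null(D_par) && !is.null(D_perp))
    diffusion_model(D_par = D_par, D_perp = D_perp, beta = beta)
  else
    diffusion_model(tau_eff = tau_eff, anisotropy = anisotropy, beta = beta)
  m <- motion_model(S2 = S2, tau_int = tau_int)
  const <- physical_constants(B0 = B0)
  pairs <- list(N_NH = spin_pair("N_NH", const, plane$params),
                C_CCa = spin_pair("C_CCa", const, plane$params))
  ev <- eval_ccr(plane, d, m, const, pairs)
  structure(c(list(plane = plane, diffusion = d, motion = m,
                   constants = const, pairs = pairs), ev),
            class = "ccr_model")
}

# full forward evaluation: spectra -> rates -> Q
eval_ccr <- function(plane, d, m, const, pairs) {
  o <- plane$orientations
  s_nh <- build_spectrum(o["nh"], o["n_csa"], d, m)
  s_xx <- build_spectrum(o["c_ca"], o["c_xx"], d, m)
  s_yy <- build_spectrum(o["c_ca"], o["c_yy"], d, m)
  wn <- pairs$N_NH$omega
  wc <- pairs$C_CCa$omega
  n_rates <- rate_set(
    gamma_xy_n(j_lorentzian(s_nh, 0), j_lorentzian(s_nh, wn),
               pairs$N_NH, const),
    gamma_z_n(j_lorentzian(s_nh, wn), pairs$N_NH, const),
    "N_NH")
  c_rates <- rate_set(
    gamma_xy_c(j_lorentzian(s_xx, 0), j_lorentzian(s_xx, wc),
               j_lorentzian(s_yy, 0), j_lorentzian(s_yy, wc),
               pairs$C_CCa, const),
    gamma_z_c(j_lorentzian(s_xx, wc), j_lorentzian(s_yy, wc),
              pairs$C_CCa, const),
    "C_CCa")
  list(spectra = list(nh = s_nh, c_xx = s_xx, c_yy = s_yy),
       rates = list(N_NH = n_rates, C_CCa = c_rates),
       Q = q_ratio(c_rates, n_rates))
}

#' @export
print.ccr_model <- function(x, ...) {
  cat("Peptide-plane CCR forward model\n")
  cat(sprintf("  tau_eff = %.3g ns, D_par/D_perp = %.3g, beta = %g deg\n",
              x$diffusion$tau_eff * 1e9, x$diffusion$anisotropy,
              x$diffusion$beta))
  cat(sprintf("  S2 = %.3g, tau_int = %.3g ps, B0 = %.3g T\n",
              x$motion$S2, x$motion$tau_int * 1e12, x$constants$B0))
  cat(sprintf("  Q = %.4f\n", x$Q))
  invisible(x)
}

#' @export
coef.ccr_model <- function(object, ...) {
  c(D_par = object$diffusion$D_par, D_perp = object$diffusion$D_perp,
    beta = object$diffusion$beta, S2 = object$motion$S2,
    tau_int = object$motion$tau_int, B0 = object$constants$B0)
}

#' @export
summary.ccr_model <- function(object, ...) {
  rt <- do.call(rbind, lapply(object$rates, function(r)
    data.frame(pair = r$pair, gamma_xy_s1 = r$gamma_xy,
               gamma_z_s1 = r$gamma_z, j0_comb_s1 = r$j0_combination)))
  rownames(rt) <- NULL
  out <- list(coef = coef(object), rates = rt, Q = object$Q,
              Q_iso = iso_baseline(object$plane, object$constants),
              orientations = object$plane$orientations)
  class(out) <- "summary.ccr_model"
  out
}

#' @export
print.summary.ccr_model <- function(x, ...) {
  cat("Peptide-plane CCR forward model\n\nParameters:\n")
  print(x$coef)
  cat("\nCCR rates (1/s):\n")
  print(x$rates, row.names = FALSE)
  cat(sprintf("\nQ = %.4f (isotropic baseline %.4f)\n", x$Q, x$Q_iso))
  invisible(x)
}

# geometric isotropic baseline of Q from the plane constants alone
iso_baseline <- function(plane = build_peptide_plane(),
                         constants = physical_constants()) {
  p <- plane$params
  o <- plane$orientations
  kn <- k_prefactor(spin_pair("N_NH", constants, p), constants)
  kc <- k_prefactor(spin_pair("C_CCa", constants, p), constants)
  d2r <- pi / 180
  num <- (p$sigma_xx_c - p$sigma_zz_c) *
    p2(cos(angle_between(o["c_ca"], o["c_xx"]) * d2r)) +
    (p$sigma_yy_c - p$sigma_zz_c) *
    p2(cos(angle_between(o["c_ca"], o["c_yy"]) * d2r))
  den <- p$delta_n * p2(cos(angle_between(o["nh"], o["n_csa"]) * d2r))
  (kc / kn) * num / den
}

#' Predict Q over diffusion-axis orientations
#'
#' Re-evaluates the forward model on a vector of main-axis orientations,
#' holding all other parameters fixed.
#'
#' @param object a [ccr_model()].
#' @param beta orientations in degrees (default 0 to 180 in 1 degree steps).
#' @param ... unused.
#' @return data frame with columns `beta_deg` and `Q` (plus the per-channel
#'   `j0_comb` columns).
#' @export
predict.ccr_model <- function(object, beta = seq(0, 180, by = 1), ...) {
  rows <- lapply(beta, function(b) {
    d <- diffusion_model(D_par = object$diffusion$D_par,
                         D_perp = object$diffusion$D_perp, beta = b)
    ev <- eval_ccr(object$plane, d, object$motion, object$constants,
                   object$pairs)
    data.frame(beta_deg = b,
               j0_comb_N = ev$rates$N_NH$j0_combination,
               j0_comb_C = ev$rates$C_CCa$j0_combination,
               Q = ev$Q)
  })
  do.call(rbind, rows)
}

#' Plot the orientation profile of Q
#'
#' Draws Q as a function of the diffusion main-axis orientation, with dashed
#' vertical lines at the N-HN and Ca-Ca orientations.
#'
#' @param x a [ccr_model()].
#' @param beta orientations in degrees.
#' @param ... passed to [graphics::plot()].
#' @return the predicted data frame, invisibly.
#' @export
plot.ccr_model <- function(x, beta = seq(0, 180, by = 1), ...) {
  pr <- predict(x, beta = beta)
  graphics::plot(pr$beta_deg, pr$Q, type = "l",
                 xlab = expression(beta ~ "(degrees from C'-C" * alpha * ")"),
                 ylab = "Q", ...)
  o <- x$plane$orientations
  graphics::abline(v = abs(wrap_angle(o["nh"])) %% 180, lty = 2, col = "grey40")
  graphics::abline(v = abs(wrap_angle(o["ca_ca"])) %% 180, lty = 2,
                   col = "grey40")
  invisible(pr)
}

#' Simulate Brownian tumbling trajectories consistent with the model
#'
#' Runs the rigid-body rotational-diffusion simulator with the model's
#' diffusion tensor. Internal motion (`S2 < 1`) is not simulated; the
#' trajectories realize the rigid (`S2 = 1`) limit that the Woessner spectral
#' densities describe.
#'
#' @param object a [ccr_model()].
#' @param nsim number of independent trajectories.
#' @param seed RNG seed (passed to [set.seed()]).
#' @param dt time step, seconds.
#' @param n_steps steps per trajectory.
#' @param stride save every `stride`-th frame.
#' @param ... unused.
#' @return a list of [simulate_rotor()] trajectories (length `nsim`).
#' @export
simulate.ccr_model <- function(object, nsim = 1, seed = NULL,
                               dt = 1e-12, n_steps = 2e5, stride = 10, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    simulate_rotor(object$diffusion, dt = dt, n_steps = n_steps,
                   stride = stride))
}
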