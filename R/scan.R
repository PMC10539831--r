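#' Parameter grid for the Q sensitivity scan
#'
#' Default grid mirroring the sensitivity analysis of the forward model:
#' the diffusion main axis rotated from 0 to 180 degrees (from the C'-Ca
#' orientation towards the N-HN vector), order parameters 0 to 1, effective
#' tumbling times of 1 and 2.5 ns, internal correlation times of 100 and
#' 500 ps, and anisotropies of 1.5 and 2.5 at 18.8 T.
#'
#' @param beta main-axis orientations, degrees in `[0, 180]`.
#' @param S2 order parameters in `[0, 1]`.
#' @param tau_eff effective tumbling times, seconds.
#' @param tau_int internal correlation times, seconds.
#' @param anisotropy `D_par / D_perp` values.
#' @param B0 magnetic field, Tesla.
#' @return object of class `scan_grid`.
#' @export
scan_grid <- function(beta = seq(0, 180, by = 1),
                      S2 = seq(0, 1, by = 0.1),
                      tau_eff = c(1e-9, 2.5e-9),
                      tau_int = c(1e-10, 5e-10),
                      anisotropy = c(1.5, 2.5),
                      B0 = 18.8) {
  if (!length(beta) || !length(S2) || !length(tau_eff) ||
      !length(tau_int) || !length(anisotropy))
    stop("all grid dimensions must be non-empty")
  if (any(beta < 0 | beta > 180)) stop("beta must lie in [0, 180] degrees")
  if (any(S2 < 0 | S2 > 1)) stop("S2 must lie in [0, 1]")
  structure(list(beta = beta, S2 = S2, tau_eff = tau_eff,
                 tau_int = tau_int, anisotropy = anisotropy, B0 = B0),
            class = "scan_grid")
}

# Q over a beta vector for one (S2, tau_eff, tau_int, anisotropy) slice.
# Lean vectorized path used by run_scan; equivalent to (and cross-checked
# against) the ccr_model object pipeline.
q_curve <- function(beta, S2, tau_eff, tau_int, anisotropy,
                    plane, constants) {
  d2r <- pi / 180
  o <- plane$orientations
  p <- plane$params
  D_perp <- 1 / (tau_eff * (4 + 2 * anisotropy))
  D_par <- anisotropy * D_perp
  tauk <- 1 / (6 * D_perp + (0:2)^2 * (D_par - D_perp))
  tau3 <- 1 / (1 / tau_int + 1 / tau_eff)

  # J(0) of the four-term spectrum for a vector pair, vectorized over beta
  j0_pair <- function(u, v) {
    tu <- (u - beta) * d2r
    tv <- (v - beta) * d2r
    a0 <- p2(cos(tu)) * p2(cos(tv))
    a1 <- 0.75 * sin(2 * tu) * sin(2 * tv)
    a2 <- 0.75 * sin(tu)^2 * sin(tv)^2
    S2 * (a0 * tauk[1] + a1 * tauk[2] + a2 * tauk[3]) +
      (1 - S2) * p2(cos((u - v) * d2r)) * tau3
  }
  kn <- k_prefactor(spin_pair("N_NH", constants, p), constants)
  kc <- k_prefactor(spin_pair("C_CCa", constants, p), constants)
  num <- 4 * kc * ((p$sigma_xx_c - p$sigma_zz_c) * j0_pair(o["c_ca"], o["c_xx"]) +
                   (p$sigma_yy_c - p$sigma_zz_c) * j0_pair(o["c_ca"], o["c_yy"]))
  den <- 4 * kn * p$delta_n * j0_pair(o["nh"], o["n_csa"])
  bad <- abs(den) < 1e-300
  if (any(bad))
    stop("Q undefined (zero denominator) at beta = ",
         paste(beta[bad], collapse = ", "),
         " for S2 = ", S2, ", tau_eff = ", tau_eff,
         ", tau_int = ", tau_int, ", anisotropy = ", anisotropy)
  num / den
}

#' Run the Q sensitivity scan
#'
#' Evaluates Q on the full grid: for every combination of order parameter,
#' tumbling time, internal time and anisotropy, the diffusion main axis is
#' rotated through the `beta` values and Q computed from the J(0)-isolating
#' CCR combinations of both channels.
#'
#' @param grid a [scan_grid()].
#' @param plane a [build_peptide_plane()] object.
#' @return data frame of class `ccr_scan` with columns `beta_deg`, `s2`,
#'   `tau_eff_s`, `tau_int_s`, `anisotropy`, `Q`. Attributes `nh_beta` and
#'   `caca_beta` give the in-plane orientations (mod 180) of the N-HN and
#'   Ca-Ca vectors for annotation.
#' @export
#' @examples
#' sc <- run_scan(scan_grid(beta = seq(0, 180, 30), S2 = c(0, 1)))
#' subset(sc, s2 == 0)$Q  # flat isotropic baseline
run_scan <- function(grid = scan_grid(), plane = build_peptide_plane()) {
  stopifnot(inherits(grid, "scan_grid"))
  constants <- physical_constants(B0 = grid$B0)
  combos <- expand.grid(s2 = grid$S2, tau_eff_s = grid$tau_eff,
                        tau_int_s = grid$tau_int,
                        anisotropy = grid$anisotropy,
                        KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    data.frame(beta_deg = grid$beta, s2 = cb$s2, tau_eff_s = cb$tau_eff_s,
               tau_int_s = cb$tau_int_s, anisotropy = cb$anisotropy,
               Q = q_curve(grid$beta, cb$s2, cb$tau_eff_s, cb$tau_int_s,
                           cb$anisotropy, plane, constants))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  o <- plane$orientations
  attr(out, "nh_beta") <- unname(o["nh"]) %% 180
  attr(out, "caca_beta") <- unname(o["ca_ca"]) %% 180
  class(out) <- c("ccr_scan", "data.frame")
  out
}

#' Locate the extrema of a Q orientation profile
#'
#' Grid-resolution argmin/argmax of Q over beta for a single parameter slice.
#'
#' @param result a [run_scan()] result.
#' @param s2,tau_eff,tau_int,anisotropy values selecting one curve.
#' @return list with `beta_at_min`, `beta_at_max`, `q_min`, `q_max`.
#' @export
q_extrema <- function(result, s2, tau_eff, tau_int, anisotropy) {
  sl <- result[result$s2 == s2 & result$tau_eff_s == tau_eff &
               result$tau_int_s == tau_int &
               result$anisotropy == anisotropy, ]
  if (!nrow(sl)) stop("empty slice: no grid points match the selection")
  list(beta_at_min = sl$beta_deg[which.min(sl$Q)],
       beta_at_max = sl$beta_deg[which.max(sl$Q)],
       q_min = min(sl$Q), q_max = max(sl$Q))
}

#' Orientation sensitivity of Q across the grid
#'
#' Summarizes, for each (anisotropy, tau_eff, tau_int) panel and order
#' parameter, the spread of Q over the main-axis orientation
#' (`max Q - min Q`). Larger spreads mean Q is a more sensitive reporter of
#' the diffusion-tensor orientation: the spread grows with the tumbling time
#' and shrinks with the internal correlation time (at fixed `S2 < 1`), and is
#' independent of `tau_int` at `S2 = 1`.
#'
#' @param result a [run_scan()] result.
#' @return data frame with columns `anisotropy`, `tau_eff_s`, `tau_int_s`,
#'   `s2`, `q_spread`, ordered by decreasing spread within each panel.
#' @export
sensitivity_ordering <- function(result) {
  key <- interaction(result$anisotropy, result$tau_eff_s,
                     result$tau_int_s, result$s2, drop = TRUE)
  spread <- tapply(result$Q, key, function(q) max(q) - min(q))
  first <- !duplicated(key)
  out <- data.frame(anisotropy = result$anisotropy[first],
                    tau_eff_s = result$tau_eff_s[first],
                    tau_int_s = result$tau_int_s[first],
                    s2 = result$s2[first],
                    q_spread = as.numeric(spread[as.character(key[first])]))
  out[order(out$anisotropy, out$tau_eff_s, out$tau_int_s, -out$q_spread), ]
}

#' Plot a Q sensitivity scan
#'
#' One panel per (anisotropy, tau_eff, tau_int) combination, curves
#' color-coded by order parameter, dashed lines at the N-HN and Ca-Ca
#' orientations.
#'
#' @param x a [run_scan()] result.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.ccr_scan <- function(x, ...) {
  panels <- unique(x[, c("anisotropy", "tau_eff_s", "tau_int_s")])
  op <- graphics::par(mfrow = grDevices::n2mfrow(nrow(panels)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  s2s <- sort(unique(x$s2))
  cols <- grDevices::hcl.colors(length(s2s), "viridis")
  for (i in seq_len(nrow(panels))) {
    p <- panels[i, ]
    sl <- x[x$anisotropy == p$anisotropy & x$tau_eff_s == p$tau_eff_s &
            x$tau_int_s == p$tau_int_s, ]
    qm <- sapply(s2s, function(s) sl$Q[sl$s2 == s])
    graphics::matplot(unique(sl$beta_deg), qm, type = "l", lty = 1,
                      col = cols, xlab = expression(beta ~ "(deg)"),
                      ylab = "Q",
                      main = sprintf("D||/D- = %g, %g ns / %g ps",
                                     p$anisotropy, p$tau_eff_s * 1e9,
                                     p$tau_int_s * 1e12), ...)
    graphics::abline(v = attr(x, "nh_beta"), lty = 2, col = "grey40")
    graphics::abline(v = attr(x, "caca_beta"), lty = 2, col = "grey40")
  }
  invisible(x)
}
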