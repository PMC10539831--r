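#' CCR rate from doublet intensities
#'
#' Converts the intensity asymmetry of a J-coupled doublet relaxing for a
#' delay `T` into a cross-correlated relaxation rate,
#' `Gamma = log(Ia / Ib) / (2 T)` (natural logarithm: relaxation decays are
#' exponential in e). If per-intensity noise `sigma_I` is supplied, the
#' first-order propagated uncertainty
#' `sigma_Gamma = sigma_I / (2 T) * sqrt(1/Ia^2 + 1/Ib^2)` is returned.
#' Records with non-positive intensities or delay are flagged with a warning
#' and returned as `NA`; the remaining records are still processed. Which
#' doublet component is `Ia` is an assignment convention; `swap = TRUE`
#' negates the sign.
#'
#' @param doublets data frame with columns `Ia`, `Ib`, `T_s` and optionally
#'   `residue` and `sigma_I`.
#' @param swap negate the rate sign (swap the doublet component assignment).
#' @return data frame with columns `residue`, `gamma_s1` and (when `sigma_I`
#'   is present) `sigma_gamma_s1`.
#' @export
#' @examples
#' rate_from_doublet(data.frame(Ia = exp(1), Ib = 1, T_s = 0.5))$gamma_s1  # 1
rate_from_doublet <- function(doublets, swap = FALSE) {
  need <- c("Ia", "Ib", "T_s")
  if (!all(need %in% names(doublets)))
    stop("doublets must have columns Ia, Ib, T_s")
  res <- if ("residue" %in% names(doublets)) doublets$residue
         else seq_len(nrow(doublets))
  bad <- !(doublets$Ia > 0 & doublets$Ib > 0 & doublets$T_s > 0)
  bad[is.na(bad)] <- TRUE
  if (any(bad))
    warning("invalid intensities or delay for record(s): ",
            paste(res[bad], collapse = ", "), "; returned as NA")
  g <- rep(NA_real_, nrow(doublets))
  g[!bad] <- log(doublets$Ia[!bad] / doublets$Ib[!bad]) /
    (2 * doublets$T_s[!bad])
  if (swap) g <- -g
  out <- data.frame(residue = res, gamma_s1 = g)
  if ("sigma_I" %in% names(doublets)) {
    out$sigma_gamma_s1 <- ifelse(bad, NA_real_,
      doublets$sigma_I / (2 * doublets$T_s) *
        sqrt(1 / doublets$Ia^2 + 1 / doublets$Ib^2))
  }
  out
}

#' Spectral density mapping from 15N/N-HN CCR rates
#'
#' Inverts the rate expressions of the 15N channel:
#' `J(omega_N) = Gamma_z / (6 k DeltaN)` and
#' `J(0) = (Gamma_xy - 0.5 Gamma_z) / (4 k DeltaN)`.
#' The inversion is exact (it round-trips [gamma_xy_n()] / [gamma_z_n()]).
#' Uncertainties, if given, are propagated to first order.
#'
#' @param gamma_xy,gamma_z measured CCR rates, 1/s (vectorized).
#' @param pair the `"N_NH"` [spin_pair()].
#' @param constants a [physical_constants()].
#' @param sigma_xy,sigma_z optional rate uncertainties, 1/s.
#' @param residue optional labels.
#' @return data frame with columns `residue`, `J0_s`, `JwN_s` and, when
#'   uncertainties are given, `sigma_J0_s`, `sigma_JwN_s`.
#' @export
map_j_from_rates <- function(gamma_xy, gamma_z, pair,
                             constants = physical_constants(),
                             sigma_xy = NULL, sigma_z = NULL,
                             residue = seq_along(gamma_xy)) {
  stopifnot(pair$name == "N_NH")
  k <- k_prefactor(pair, constants)
  if (k == 0) stop("zero prefactor: cannot invert rates")
  kd <- k * pair$delta
  out <- data.frame(residue = residue,
                    J0_s = (gamma_xy - 0.5 * gamma_z) / (4 * kd),
                    JwN_s = gamma_z / (6 * kd))
  if (!is.null(sigma_xy) && !is.null(sigma_z)) {
    out$sigma_J0_s <- sqrt(sigma_xy^2 + 0.25 * sigma_z^2) / abs(4 * kd)
    out$sigma_JwN_s <- sigma_z / abs(6 * kd)
  }
  out
}

#' Composite J(0) from 13C'/C'-Ca CCR rates
#'
#' The 13C' channel mixes two in-plane CSA components, so the individual
#' `Jxx(0)` and `Jyy(0)` cannot be separated; the combination
#' `(Gamma_xy - 0.5 Gamma_z) / (4 k)` returns the composite
#' `(sxx - szz) Jxx(0) + (syy - szz) Jyy(0)` in ppm * s.
#'
#' @param gamma_xy,gamma_z measured CCR rates, 1/s (vectorized).
#' @param pair the `"C_CCa"` [spin_pair()].
#' @param constants a [physical_constants()].
#' @param residue optional labels.
#' @return data frame with columns `residue` and `J0_composite_ppm_s`.
#' @export
map_j0_composite_c <- function(gamma_xy, gamma_z, pair,
                               constants = physical_constants(),
                               residue = seq_along(gamma_xy)) {
  stopifnot(pair$name == "C_CCa")
  k <- k_prefactor(pair, constants)
  if (k == 0) stop("zero prefactor: cannot invert rates")
  data.frame(residue = residue,
             J0_composite_ppm_s = (gamma_xy - 0.5 * gamma_z) / (4 * k))
}

#' Synthesize doublet intensity tables from known rates
#'
#' Fixture generator: produces doublet records whose intensity ratio encodes
#' the given ground-truth rates, `Ia / Ib = exp(2 Gamma T)`, with optional
#' multiplicative Gaussian noise on each intensity. Deterministic under a
#' fixed seed. The delay should satisfy `|Gamma| * 2 * T <= ~3` for the
#' mixing-time regime the extraction formula assumes.
#'
#' @param gamma true rates, 1/s (one record per element).
#' @param T_s relaxation delay, seconds.
#' @param noise relative intensity noise (standard deviation as a fraction of
#'   the intensity).
#' @param seed RNG seed (optional).
#' @param I0 unperturbed geometric-mean intensity.
#' @param residue labels.
#' @return data frame with columns `residue`, `Ia`, `Ib`, `T_s`, `sigma_I`.
#' @export
synth_doublets <- function(gamma, T_s, noise = 0, seed = NULL, I0 = 1e5,
                           residue = seq_along(gamma)) {
  if (T_s <= 0) stop("T_s must be positive")
  if (noise < 0) stop("noise must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- length(gamma)
  ia <- I0 * exp(gamma * T_s)
  ib <- I0 * exp(-gamma * T_s)
  if (noise > 0) {
    ia <- ia * (1 + stats::rnorm(n, sd = noise))
    ib <- ib * (1 + stats::rnorm(n, sd = noise))
  }
  data.frame(residue = residue, Ia = ia, Ib = ib, T_s = T_s,
             sigma_I = noise * I0)
}
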