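#' Physical constants and field strength
#'
#' CODATA values of the constants entering the CCR rate prefactors, plus the
#' static field. The 15N gyromagnetic ratio is negative.
#'
#' @param B0 magnetic field strength in Tesla (default 18.8 T, i.e. 800 MHz
#'   proton Larmor frequency).
#' @return object of class `physical_constants`: `mu0` (vacuum permeability,
#'   SI), `hbar` (reduced Planck constant, SI), `gamma_h`, `gamma_n`,
#'   `gamma_c` (rad/s/T) and `B0`.
#' @export
physical_constants <- function(B0 = 18.8) {
  if (!is.numeric(B0) || B0 <= 0) stop("B0 must be positive")
  structure(list(mu0 = 1.25663706212e-6,
                 hbar = 1.054571817e-34,
                 gamma_h = 2.6752218744e8,
                 gamma_n = -2.71261804e7,
                 gamma_c = 6.728284e7,
                 B0 = B0),
            class = "physical_constants")
}

#' CSA-dipole spin pair specification
#'
#' Bundles the dipolar vector, internuclear distance, CSA parameters and the
#' Larmor frequency of the relaxing nucleus for the two CCR channels of the
#' peptide plane: `"N_NH"` (15N CSA with the N-HN dipole) and `"C_CCa"`
#' (13C' CSA with the C'-Ca dipole).
#'
#' @param name `"N_NH"` or `"C_CCa"`.
#' @param constants a [physical_constants()] object.
#' @param params a [plane_params()] object supplying distances and CSA values.
#' @return object of class `spin_pair`: dipole gyromagnetic ratios `g1`, `g2`,
#'   distance `r` (m), CSA gyromagnetic ratio `g_csa`, Larmor frequency
#'   `omega` (rad/s) of the relaxing nucleus, and the CSA sizes in ppm
#'   (`delta` for 15N; `sigma_xx`, `sigma_yy`, `sigma_zz` for 13C').
#' @export
spin_pair <- function(name = c("N_NH", "C_CCa"),
                      constants = physical_constants(),
                      params = plane_params()) {
  name <- match.arg(name)
  if (name == "N_NH") {
    structure(list(name = name,
                   g1 = constants$gamma_n, g2 = constants$gamma_h,
                   r = params$r_n_h * 1e-10,
                   g_csa = constants$gamma_n,
                   omega = abs(constants$gamma_n) * constants$B0,
                   delta = params$delta_n),
              class = "spin_pair")
  } else {
    structure(list(name = name,
                   g1 = constants$gamma_c, g2 = constants$gamma_c,
                   r = params$r_ca_c * 1e-10,
                   g_csa = constants$gamma_c,
                   omega = abs(constants$gamma_c) * constants$B0,
                   sigma_xx = params$sigma_xx_c,
                   sigma_yy = params$sigma_yy_c,
                   sigma_zz = params$sigma_zz_c),
              class = "spin_pair")
  }
}

#' CCR rate prefactor
#'
#' The constant multiplying `(CSA in ppm) * J` in the CSA-dipole CCR rate
#' expressions:
#' `k = (2/5) (1/12) (mu0 hbar / 4 pi) (g1 g2 / r^3) (B0 g_csa) * 1e-6`,
#' with the factor `1e-6` converting the CSA from ppm. For the 15N/N-HN pair
#' the product contains `gamma_n^2` (so the sign of `gamma_n` cancels); for
#' 13C'/C'-Ca it contains `gamma_c^3`. The absolute scale of `k` is
#' convention-dependent; every quantity derived here (the ratio Q and all
#' J(0)/J(omega) extractions) involves only ratios or inversions of `k`.
#'
#' @param pair a [spin_pair()].
#' @param constants a [physical_constants()].
#' @return prefactor in 1/s^2 (so that `k * J` with `J` in s is a rate).
#' @export
k_prefactor <- function(pair, constants = physical_constants()) {
  stopifnot(inherits(pair, "spin_pair"))
  if (pair$r <= 0) stop("internuclear distance must be positive")
  (2 / 5) * (1 / 12) * (constants$mu0 * constants$hbar / (4 * pi)) *
    pair$g1 * pair$g2 / pair$r^3 * constants$B0 * pair$g_csa * 1e-6
}

#' Transverse and longitudinal CCR rates, 15N/N-HN channel
#'
#' Cross-correlated relaxation rates between the (axially symmetric) 15N CSA
#' and the N-HN dipole:
#' `Gamma_xy = k DeltaN (4 J(0) + 3 J(omega_N))` and
#' `Gamma_z = k DeltaN 6 J(omega_N)`, where `J` is the cross spectral density
#' of the N-HN dipole vector and the CSA unique axis. The combination
#' `Gamma_xy - 0.5 Gamma_z = 4 k DeltaN J(0)` isolates the zero-frequency
#' spectral density.
#'
#' @param j0 `J(0)` in seconds.
#' @param jw `J(omega_N)` in seconds.
#' @param pair the `"N_NH"` [spin_pair()].
#' @param constants a [physical_constants()].
#' @return rate in 1/s.
#' @export
gamma_xy_n <- function(j0, jw, pair, constants = physical_constants()) {
  stopifnot(pair$name == "N_NH")
  k_prefactor(pair, constants) * pair$delta * (4 * j0 + 3 * jw)
}

#' @rdname gamma_xy_n
#' @export
gamma_z_n <- function(jw, pair, constants = physical_constants()) {
  stopifnot(pair$name == "N_NH")
  k_prefactor(pair, constants) * pair$delta * 6 * jw
}

#' Transverse and longitudinal CCR rates, 13C'/C'-Ca channel
#'
#' Cross-correlated relaxation between the fully anisotropic 13C' CSA and the
#' C'-Ca dipole. Both in-plane CSA components contribute:
#' `Gamma_xy = k [(sxx - szz)(4 Jxx(0) + 3 Jxx(wC)) +
#'               (syy - szz)(4 Jyy(0) + 3 Jyy(wC))]`,
#' `Gamma_z  = k [(sxx - szz) 6 Jxx(wC) + (syy - szz) 6 Jyy(wC)]`,
#' where `Jxx`/`Jyy` are the cross spectral densities of the C'-Ca dipole with
#' the xx/yy CSA axes. The combination `Gamma_xy - 0.5 Gamma_z =
#' 4 k [(sxx - szz) Jxx(0) + (syy - szz) Jyy(0)]` again isolates J(0).
#'
#' @param jxx0,jyy0 `J(0)` for the xx and yy CSA axes, seconds.
#' @param jxxw,jyyw `J(omega_C)` for the xx and yy CSA axes, seconds.
#' @param pair the `"C_CCa"` [spin_pair()].
#' @param constants a [physical_constants()].
#' @return rate in 1/s.
#' @export
gamma_xy_c <- function(jxx0, jxxw, jyy0, jyyw, pair,
                       constants = physical_constants()) {
  stopifnot(pair$name == "C_CCa")
  k <- k_prefactor(pair, constants)
  k * ((pair$sigma_xx - pair$sigma_zz) * (4 * jxx0 + 3 * jxxw) +
       (pair$sigma_yy - pair$sigma_zz) * (4 * jyy0 + 3 * jyyw))
}

#' @rdname gamma_xy_c
#' @export
gamma_z_c <- function(jxxw, jyyw, pair, constants = physical_constants()) {
  stopifnot(pair$name == "C_CCa")
  k <- k_prefactor(pair, constants)
  k * ((pair$sigma_xx - pair$sigma_zz) * 6 * jxxw +
       (pair$sigma_yy - pair$sigma_zz) * 6 * jyyw)
}

#' Bundle a transverse/longitudinal CCR rate pair
#'
#' @param gamma_xy transverse CCR rate, 1/s.
#' @param gamma_z longitudinal CCR rate, 1/s.
#' @param pair_name channel tag (e.g. `"N_NH"`).
#' @return object of class `rate_set` with the J(0)-isolating combination
#'   `j0_combination = gamma_xy - 0.5 * gamma_z`.
#' @export
rate_set <- function(gamma_xy, gamma_z, pair_name = "") {
  structure(list(gamma_xy = gamma_xy, gamma_z = gamma_z,
                 j0_combination = gamma_xy - 0.5 * gamma_z,
                 pair = pair_name),
            class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("CCR rates [%s]: Gamma_xy = %.4g /s, Gamma_z = %.4g /s, ",
              x$pair, x$gamma_xy, x$gamma_z))
  cat(sprintf("Gxy - Gz/2 = %.4g /s\n", x$j0_combination))
  invisible(x)
}

#' Zero-frequency CCR ratio Q
#'
#' The ratio of the J(0)-isolating combinations of the 13C'/C'-Ca and
#' 15N/N-HN channels,
#' `Q = (Gxy_C - 0.5 Gz_C) / (Gxy_N - 0.5 Gz_N)`.
#' The field strength cancels between the two prefactors, so Q is independent
#' of B0. Isotropic dynamics drive Q to a fixed geometric baseline (about
#' 0.31 for the default plane constants); diffusion anisotropy moves it away.
#'
#' @param c_rates [rate_set()] for the 13C'/C'-Ca channel (numerator).
#' @param n_rates [rate_set()] for the 15N/N-HN channel (denominator).
#' @return dimensionless ratio.
#' @export
q_ratio <- function(c_rates, n_rates) {
  stopifnot(inherits(c_rates, "rate_set"), inherits(n_rates, "rate_set"))
  if (abs(n_rates$j0_combination) < 1e-15)
    stop("denominator J(0) combination is numerically zero")
  c_rates$j0_combination / n_rates$j0_combination
}
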