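#' Peptide-plane constants
#'
#' Bond lengths, bond angles and CSA tensor parameters defining the canonical
#' (trans) peptide plane used throughout the package. Defaults are the standard
#' crystallographic peptide-plane geometry with an N-H bond of 1.04 Angstrom
#' and solid-state-calibrated CSA tensors: the 15N CSA is treated as axially
#' symmetric with anisotropy `delta_n` and its unique axis tilted `alpha_n`
#' degrees from the N-H bond towards the N-C' bond; the 13C' CSA is fully
#' anisotropic with in-plane principal axes xx and yy (zz normal to the plane)
#' and `alpha_c` the angle between the xx axis and the C'-N bond line.
#'
#' @param r_ca_c,r_c_o,r_c_n,r_n_ca,r_n_h bond lengths in Angstrom.
#' @param ang_ca_c_o,ang_ca_c_n,ang_o_c_n bond angles around C' in degrees;
#'   they must sum to 360.
#' @param ang_c_n_h,ang_c_n_ca,ang_h_n_ca bond angles around N in degrees;
#'   they must sum to 360.
#' @param delta_n 15N CSA anisotropy (sigma_xx - sigma_zz) in ppm.
#' @param alpha_n tilt of the 15N CSA unique axis from the N-H bond, degrees.
#' @param sigma_xx_c,sigma_yy_c,sigma_zz_c 13C' CSA principal values in ppm.
#' @param alpha_c angle between the 13C' CSA xx axis and the C'-N bond line,
#'   degrees, in `[0, 90]`.
#' @param json optional path to a JSON file overriding any of the above by
#'   field name; values given explicitly in the call take precedence.
#'
#' @return An object of class `plane_params` (a validated named list).
#' @seealso [build_peptide_plane()]
#' @export
#' @examples
#' p <- plane_params()
#' p$ang_ca_c_n  # 114 degrees
plane_params <- function(r_ca_c = 1.53, r_c_o = 1.24, r_c_n = 1.32,
                         r_n_ca = 1.47, r_n_h = 1.04,
                         ang_ca_c_o = 121, ang_ca_c_n = 114, ang_o_c_n = 125,
                         ang_c_n_h = 123, ang_c_n_ca = 123, ang_h_n_ca = 114,
                         delta_n = 170, alpha_n = 20,
                         sigma_xx_c = 249.4, sigma_yy_c = 191.1,
                         sigma_zz_c = 87.9, alpha_c = 37,
                         json = NULL) {
  p <- list(r_ca_c = r_ca_c, r_c_o = r_c_o, r_c_n = r_c_n,
            r_n_ca = r_n_ca, r_n_h = r_n_h,
            ang_ca_c_o = ang_ca_c_o, ang_ca_c_n = ang_ca_c_n,
            ang_o_c_n = ang_o_c_n,
            ang_c_n_h = ang_c_n_h, ang_c_n_ca = ang_c_n_ca,
            ang_h_n_ca = ang_h_n_ca,
            delta_n = delta_n, alpha_n = alpha_n,
            sigma_xx_c = sigma_xx_c, sigma_yy_c = sigma_yy_c,
            sigma_zz_c = sigma_zz_c, alpha_c = alpha_c)
  if (!is.null(json)) {
    override <- jsonlite::read_json(json, simplifyVector = TRUE)
    unknown <- setdiff(names(override), names(p))
    if (length(unknown))
      stop("unknown plane parameter(s) in JSON config: ",
           paste(unknown, collapse = ", "))
    given <- names(as.list(match.call()))  # explicit args win over JSON
    for (nm in setdiff(names(override), given)) p[[nm]] <- override[[nm]]
  }
  validate_plane_params(p)
}

validate_plane_params <- function(p) {
  lens <- c("r_ca_c", "r_c_o", "r_c_n", "r_n_ca", "r_n_h")
  for (nm in lens)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop("bond length '", nm, "' must be a positive scalar")
  sum_c <- p$ang_ca_c_o + p$ang_ca_c_n + p$ang_o_c_n
  if (abs(sum_c - 360) > 1e-9)
    stop("bond angles around C' sum to ", format(sum_c),
         " degrees; they must sum to 360")
  sum_n <- p$ang_c_n_h + p$ang_c_n_ca + p$ang_h_n_ca
  if (abs(sum_n - 360) > 1e-9)
    stop("bond angles around N sum to ", format(sum_n),
         " degrees; they must sum to 360")
  if (p$alpha_c < 0 || p$alpha_c > 90)
    stop("alpha_c must lie in [0, 90] degrees")
  if (p$alpha_n < 0 || p$alpha_n > 90)
    stop("alpha_n must lie in [0, 90] degrees")
  structure(p, class = "plane_params")
}

# wrap a signed in-plane angle into (-180, 180]
wrap_angle <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Second-order Legendre polynomial
#'
#' `P2(x) = 1.5 x^2 - 0.5`, the orientational kernel of rank-2 spin
#' interactions. Input is a cosine, so it must lie in `[-1, 1]`.
#'
#' @param x numeric vector of cosines.
#' @return `1.5 * x^2 - 0.5`, in `[-0.5, 1]`.
#' @export
#' @examples
#' p2(1)                 # 1
#' p2(cos(54.7356 * pi / 180))  # ~0, the magic angle
p2 <- function(x) {
  if (any(abs(x) > 1 + 1e-12, na.rm = TRUE))
    stop("p2() takes a cosine: |x| must not exceed 1")
  x <- pmin(1, pmax(-1, x))
  1.5 * x^2 - 0.5
}

#' Angle between two in-plane orientations
#'
#' Orientations are signed in-plane angles in degrees; the result is the
#' unsigned angle between the corresponding unit vectors, in `[0, 180]`.
#'
#' @param u,v signed orientation angles in degrees (recycled).
#' @return angle(s) in degrees in `[0, 180]`.
#' @export
#' @examples
#' angle_between(170, -170)  # 20
angle_between <- function(u, v) {
  if (!is.numeric(u) || !is.numeric(v) || anyNA(u) || anyNA(v))
    stop("orientations must be finite numeric angles in degrees")
  abs(wrap_angle(u - v))
}

#' Build the canonical peptide plane
#'
#' Places the six peptide-plane atoms Ca(i), C', O, N, HN and Ca(i+1) in a 2-D
#' in-plane frame and derives the signed orientations (degrees, relative to
#' the C'->Ca(i) axis) of every dipole vector and CSA principal axis needed by
#' the relaxation model. The construction is deterministic: C' sits at the
#' origin with C'->Ca(i) along the reference axis, N above the axis and O
#' below, the peptide bond is trans (Ca(i) and Ca(i+1) on opposite sides of
#' the C'-N bond), and HN lies on the side of the C'-N bond opposite Ca(i+1).
#' With the default constants the N->HN vector ends up at +57 degrees, so the
#' diffusion-axis rotation angle beta (measured counterclockwise from C'->Ca)
#' runs from the C'Ca orientation towards the N-HN vector.
#'
#' Named orientations returned: `c_ca` (C'->Ca(i) dipole, 0 by construction),
#' `nh` (N->HN dipole), `ca_ca` (virtual Ca(i)->Ca(i+1) vector), `n_csa`
#' (unique axis of the 15N CSA, `alpha_n` from the N-H bond towards N-C'),
#' `c_xx` and `c_yy` (in-plane 13C' CSA axes; `c_xx` lies at `alpha_c` from
#' the C'-N bond line so that the angle between `c_xx` and C'->Ca equals
#' `180 - ang_ca_c_n - alpha_c`, and `c_yy = c_xx + 90`; the zz axis is the
#' plane normal).
#'
#' @param params a [plane_params()] object.
#' @return An object of class `peptide_plane` with elements `coords` (6 x 2
#'   matrix, Angstrom), `orientations` (named signed angles in degrees) and
#'   `params`.
#' @export
#' @examples
#' pl <- build_peptide_plane()
#' pl$orientations["nh"]   # 57 degrees from the C'->Ca axis
build_peptide_plane <- function(params = plane_params()) {
  if (!inherits(params, "plane_params")) params <- validate_plane_params(params)
  p <- params
  d2r <- pi / 180
  polar <- function(r, ang) r * c(cos(ang * d2r), sin(ang * d2r))

  cprime <- c(0, 0)
  ca_i <- polar(p$r_ca_c, 0)
  n <- polar(p$r_c_n, p$ang_ca_c_n)       # N above the reference axis
  o <- polar(p$r_c_o, -p$ang_ca_c_o)      # O below (opposite side)

  n_to_c <- wrap_angle(p$ang_ca_c_n - 180)           # direction N -> C'
  dir_ca2 <- wrap_angle(n_to_c - p$ang_c_n_ca)       # trans peptide bond
  dir_h <- wrap_angle(n_to_c + p$ang_c_n_h)          # HN opposite Ca(i+1)
  ca_ip1 <- n + polar(p$r_n_ca, dir_ca2)
  hn <- n + polar(p$r_n_h, dir_h)

  vca <- ca_ip1 - ca_i
  orientations <- c(
    c_ca = 0,
    nh = dir_h,
    ca_ca = wrap_angle(atan2(vca[2], vca[1]) / d2r),
    n_csa = wrap_angle(dir_h - p$alpha_n),
    c_xx = wrap_angle(p$alpha_c - (180 - p$ang_ca_c_n)),
    c_yy = wrap_angle(p$alpha_c - (180 - p$ang_ca_c_n) + 90)
  )

  coords <- rbind(ca_i = ca_i, c = cprime, o = o, n = n,
                  hn = hn, ca_ip1 = ca_ip1)
  colnames(coords) <- c("x", "y")

  out <- structure(list(coords = coords, orientations = orientations,
                        params = p),
                   class = "peptide_plane")
  # reconstruction check: inter-atom distances must reproduce the inputs
  stopifnot(
    abs(dist2(coords["n", ], coords["hn", ]) - p$r_n_h) < 1e-9,
    abs(dist2(coords["n", ], coords["ca_ip1", ]) - p$r_n_ca) < 1e-9,
    abs(dist2(coords["c", ], coords["ca_i", ]) - p$r_ca_c) < 1e-9,
    abs(dist2(coords["c", ], coords["o", ]) - p$r_c_o) < 1e-9,
    abs(dist2(coords["c", ], coords["n", ]) - p$r_c_n) < 1e-9
  )
  out
}

dist2 <- function(a, b) sqrt(sum((a - b)^2))

#' In-plane CSA principal axes
#'
#' Returns the signed in-plane orientations of the CSA principal axes for the
#' requested nucleus. For 13C' these are the xx and yy axes of the fully
#' anisotropic tensor (zz is the plane normal); for 15N the tensor is treated
#' as axially symmetric and `xx` is the unique axis (the returned `yy`, its
#' in-plane perpendicular, carries no CSA weight).
#'
#' @param plane a [build_peptide_plane()] object.
#' @param nucleus `"C13prime"` or `"N15"`.
#' @return named numeric vector `c(xx = , yy = )`, degrees.
#' @export
csa_axes <- function(plane, nucleus = c("C13prime", "N15")) {
  stopifnot(inherits(plane, "peptide_plane"))
  nucleus <- match.arg(nucleus)
  o <- plane$orientations
  if (nucleus == "C13prime") c(xx = unname(o["c_xx"]), yy = unname(o["c_yy"]))
  else c(xx = unname(o["n_csa"]), yy = wrap_angle(unname(o["n_csa"]) + 90))
}

#' @export
print.peptide_plane <- function(x, ...) {
  cat("Canonical peptide plane (trans)\n")
  cat("In-plane orientations (degrees from C'->Ca):\n")
  print(round(x$orientations, 4))
  invisible(x)
}

#' Named orientations as a data frame
#'
#' Convenience dump of all named in-plane orientations, e.g. for CSV export.
#'
#' @param plane a [build_peptide_plane()] object.
#' @return data frame with columns `vector` and `angle_deg`.
#' @export
geometry_dump <- function(plane = build_peptide_plane()) {
  data.frame(vector = names(plane$orientations),
             angle_deg = unname(plane$orientations))
}
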