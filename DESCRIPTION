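Package: ccrq
Title: Cross-Correlated Relaxation Ratios for Anisotropic Segmental
    Dynamics in Disordered Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward model for detecting anisotropic segmental dynamics in
    intrinsically disordered proteins from NMR cross-correlated relaxation
    (CCR). Builds the canonical peptide-plane geometry with 15N and 13C'
    chemical shift anisotropy (CSA) tensor orientations, evaluates Woessner
    spectral densities for axially symmetric rotational diffusion with a
    model-free internal-motion extension, computes transverse and
    longitudinal CSA-dipole CCR rates for the 15N/N-HN and 13C'/C'-Ca spin
    pairs, and forms the zero-frequency ratio Q that reports on diffusion
    anisotropy. Includes a Brownian rotational-diffusion simulator as a
    stochastic oracle for the closed-form spectral densities, a sensitivity
    scan of Q over diffusion-tensor orientations, and the experiment-side
    arithmetic converting measured doublet intensities into rates and
    spectral density values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
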