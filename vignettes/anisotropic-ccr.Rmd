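---
title: "Detecting anisotropic segmental dynamics from cross-correlated relaxation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting anisotropic segmental dynamics from cross-correlated relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccrq)
```

## The problem

Backbone dynamics of intrinsically disordered proteins (IDPs) are not well
described as perturbations of a rigid tumbling frame: each peptide plane can
carry its own, possibly anisotropic, reorientational dynamics. Segments with
persistent local structure (an extended chain, a transient helix) should
tumble like elongated bodies, i.e. with an axially symmetric rotational
diffusion tensor whose unique axis lies roughly along the segment. A single
spin probe per residue (the usual amide ¹⁵N) cannot see this: one needs at
least two interaction frames with different orientations in the *same*
peptide plane.

`ccrq` implements a forward model for exactly this design. It combines two
cross-correlated relaxation (CCR) channels of one peptide plane — the ¹⁵N CSA
with the N–Hᴺ dipole, and the ¹³C′ CSA with the C′–Cα dipole — into a
zero-frequency ratio

$$
Q \;=\; \frac{\Gamma^{C'/C'C\alpha}_{xy} - \tfrac12\,\Gamma^{C'/C'C\alpha}_{z}}
             {\Gamma^{N/NH}_{xy} - \tfrac12\,\Gamma^{N/NH}_{z}},
$$

which is a pure function of zero-frequency spectral densities. For isotropic
local dynamics $Q$ collapses to a fixed geometric baseline; anisotropic
tumbling moves it away from that baseline in an orientation-dependent way.
The package computes everything needed to evaluate and stress-test this
measure: the peptide-plane geometry, the spectral densities, the rates, the
orientation scan, a stochastic simulation oracle, and the arithmetic that
turns measured doublet intensities into rates.

## The model

### Geometry

The canonical trans peptide plane is built from standard bond lengths
(Cα–C′ 1.53 Å, C′–O 1.24 Å, C′–N 1.32 Å, N–Cα 1.47 Å, N–H 1.04 Å) and bond
angles (121°/114°/125° around C′, 123°/123°/114° around N). All vectors of
interest are coplanar, so the construction is two-dimensional: C′ sits at the
origin, C′→Cα(i) defines the 0° reference axis, N is placed above the axis
and O below, and signed in-plane angles in (−180°, 180°] identify every
direction. With these conventions the N→Hᴺ vector lies at +57° and the
virtual Cα(i)→Cα(i+1) vector at +157.8°.

Two CSA tensors ride on the plane:

* the ¹⁵N CSA is treated as axially symmetric with anisotropy
  $\Delta_N = 170$ ppm; its unique axis is tilted $\alpha_N = 20°$ from the
  N–H bond towards the N–C′ bond (at +37° in plane coordinates);
* the ¹³C′ CSA is fully anisotropic ($\sigma_{xx} = 249.4$,
  $\sigma_{yy} = 191.1$, $\sigma_{zz} = 87.9$ ppm) with $zz$ normal to the
  plane and the in-plane $xx$ axis at $\alpha_C = 37°$ from the C′–N bond
  line, on the carbonyl side, so that the angle between $xx$ and C′→Cα is
  $66° - \alpha_C = 29°$ and $yy$ ($xx + 90°$) runs nearly along the C′=O
  bond. This orientation convention is the physically standard one for
  carbonyl CSA tensors and is locked in by a regression test on the $P_2$
  projection bounds below; it must not be changed silently, since the sign
  choice feeds the orientation scan.

All constants can be overridden through a JSON config with the field names of
`plane_params()`; validation enforces positive lengths and 360° angle sums
around C′ and N.

### Spectral densities

Orientational memory is encoded in second-rank time-correlation functions
$C_{u,v}(t) = \langle P_2(\mathbf u(0)\cdot\mathbf v(t))\rangle$ with
$P_2(x) = (3x^2-1)/2$, and probed through their cosine transforms
$J_{u,v}(\omega) = \int_0^\infty C_{u,v}(t)\cos(\omega t)\,dt$. No extra
normalization factor (such as 2/5) is folded into $J$; with this convention
$J(0)$ is literally the area under the TCF, i.e. an equal-weight average of
all correlation times.

For an axially symmetric rotor, $C_{u,v}$ is a sum of three exponentials with
Woessner amplitudes; for vectors coplanar with the unique axis (signed angles
$\theta_u$, $\theta_v$ from the axis):

$$
A_0 = P_2(\cos\theta_u)P_2(\cos\theta_v),\quad
A_1 = \tfrac34 \sin 2\theta_u \sin 2\theta_v,\quad
A_2 = \tfrac34 \sin^2\theta_u \sin^2\theta_v,
$$

with decay times $\tau_k = [6D_\perp + k^2(D_\parallel - D_\perp)]^{-1}$,
$k = 0,1,2$. The signed angles absorb the azimuthal phase, and the closure
identity $A_0+A_1+A_2 = P_2(\cos(\theta_u - \theta_v))$ holds for every pair
(property-tested). Fast isotropic internal motion is added in model-free
fashion as a fourth Lorentzian: amplitudes $S^2 A_k$ for the tumbling terms
plus $(1-S^2)\,P_2(\cos\angle(u,v))$ at
$\tau_3^{-1} = \tau_{int}^{-1} + \tau_{eff}^{-1}$, where
$\tau_{eff} = (4D_\perp + 2D_\parallel)^{-1}$. A single shared $S^2$ and
$\tau_{int}$ are used for all vector pairs of the plane; this is exact only
in the rigid ($S^2=1$) and fully isotropic ($S^2=0$ or
$D_\parallel/D_\perp=1$) limits and is an interpolation in between — by
construction, since the aim is only to split $J(0)$ into contributions with
and without orientational bias.

### CCR rates and Q

The transverse/longitudinal CCR rates of the two channels are

$$
\Gamma^{N/NH}_{xy} = k_{N/NH}\,\Delta_N\,[4J_{NH,xx}(0) + 3J_{NH,xx}(\omega_N)],
\qquad
\Gamma^{N/NH}_{z} = k_{N/NH}\,\Delta_N\,6J_{NH,xx}(\omega_N),
$$

and, with both in-plane CSA components contributing,

$$
\Gamma^{C'/C'C\alpha}_{xy} = k_{C'/C'C\alpha}\!\left[
  (\sigma_{xx}-\sigma_{zz})(4J_{xx}(0) + 3J_{xx}(\omega_C)) +
  (\sigma_{yy}-\sigma_{zz})(4J_{yy}(0) + 3J_{yy}(\omega_C))\right],
$$
$$
\Gamma^{C'/C'C\alpha}_{z} = k_{C'/C'C\alpha}\!\left[
  (\sigma_{xx}-\sigma_{zz})\,6J_{xx}(\omega_C) +
  (\sigma_{yy}-\sigma_{zz})\,6J_{yy}(\omega_C)\right],
$$

with prefactors
$k = \tfrac{2}{5}\cdot\tfrac{1}{12}\,\frac{\mu_0 \hbar}{4\pi}\,
\frac{\gamma_1\gamma_2}{r^3}\,B_0\gamma_{CSA}\times 10^{-6}$ (the $10^{-6}$
converts ppm). The transverse and longitudinal frequency coefficients are
deliberately symmetric between the two channels (4/3 and 6): this is what
makes $\Gamma_{xy} - \tfrac12\Gamma_z$ cancel every finite-frequency term
*exactly*, which the tests verify by varying the Larmor frequencies tenfold.
The absolute prefactor convention matters for the printed size of individual
rates but cancels in $Q$ and in every spectral-density extraction; docs flag
it as convention-dependent. $Q$ is also exactly independent of $B_0$ and of a
global rescaling of $(D_\parallel, D_\perp)$ at fixed anisotropy.

In the isotropic limit every $J(0)$ ratio collapses to a $P_2$ projection
ratio, so the baseline

$$
Q_{iso} = \frac{k_{C'/C'C\alpha}}{k_{N/NH}}\cdot
\frac{(\sigma_{xx}-\sigma_{zz})P_2(\cos 29°) + (\sigma_{yy}-\sigma_{zz})P_2(\cos 61°)}
     {\Delta_N\,P_2(\cos 20°)} \approx 0.310
$$

depends only on the plane constants. The test suite computes this number
through the full rate pipeline and through the geometric closed form and
checks they agree to 1e-9.

## The orientation scan

`run_scan()` rotates the diffusion main axis in the plane from β = 0°
(along C′→Cα) to 180° (through the N–Hᴺ orientation at 57°) and evaluates Q
on a grid of $S^2$ (0–1, step 0.1), $\tau_{eff}$ (1, 2.5 ns), $\tau_{int}$
(100, 500 ps) and anisotropy (1.5, 2.5). The grid defaults are the study
conditions of interest for IDP segments: tumbling times of a nanosecond and
up, internal motions an order of magnitude faster, and the anisotropy values
asserted for extended/helical segmental tumbling. The 1° β step and 0.1 S²
step are resolution choices for smooth curves at negligible cost (the full
default grid of 15 928 points runs in seconds).

Properties verified on this grid by the tests:

* $S^2 = 0$ rows are flat in β and identical across all panels (the
  isotropic baseline, computed value 0.3098);
* anisotropy 1 collapses every curve to the same baseline within 1e-9;
* Q(β) is 180°-periodic;
* at anisotropy 2.5 and $S^2 = 1$ the extrema of Q sit at β = 75° and 162°
  on the 1° grid — within 20° of the N–Hᴺ (57°) and Cα–Cα (157.8°)
  orientations respectively, so minimum and maximum of Q flag the two
  physically meaningful axis alignments (for an extended chain the main axis
  is near Cα–Cα and N–Hᴺ is near-perpendicular; in a helix the roles swap);
* the β-spread of Q grows with $\tau_{eff}$ and shrinks with $\tau_{int}$ at
  fixed $S^2 < 1$, and is $\tau_{int}$-independent at $S^2 = 1$.

Extrema are reported at grid resolution; a ten-fold β refinement moves them
by less than one coarse step (tested), so no continuous optimizer is used.

## Stochastic oracle: the Brownian rotor

Because the Woessner amplitudes and eigenvalue times are easy to mistranscribe,
the package carries an independent stochastic oracle: rigid-body Brownian
rotational diffusion. Each step applies small Gaussian rotations about the
three body axes (variances $2D_\perp dt$, $2D_\perp dt$, $2D_\parallel dt$)
composed in random order; the body-to-lab matrix is re-orthonormalized every
1000 steps (drift stays below 1e-9). The step bound
$dt \le 0.02/\max(6D_\parallel, 6D_\perp)$ keeps the small-angle scheme's
discretization bias well below the statistical noise; violating it is an
error, not a warning. TCFs are estimated by lag averaging over all time
origins, symmetrized in the pair order, with the inner loops in C++.

`validate_against_analytic()` compares simulated TCFs with the closed forms.
The pass/fail measure is the RMS deviation of the TCF over lags up to ten
times the slowest correlation time: TCF amplitudes are O(1), so this is the
natural scale. The deviation of the windowed $J(0)$ integral is reported as a
diagnostic, normalized by the slowest-correlation-time integral rather than
by the pair's own $J(0)$ — cross pairs near the magic angle have $J(0)$ near
zero, which would make a relative measure meaningless. At the test settings
(2×10⁶ steps of 10 ps, i.e. 20 µs of diffusion) the RMS deviations are a few 10⁻³ against tolerances of 0.02
(isotropic) and 0.05 (anisotropic), and a deliberately mis-oriented
comparison fails — a negative control that the test is actually sensitive.
A further test closes the loop to the observable: simulated $J(0)$ values for
the three vector pairs, block-averaged over eight trajectory segments,
reproduce the model's Q within Monte-Carlo error bars.

What the simulator does *not* emulate: internal motion (no $S^2 < 1$
trajectories — the rotor realizes the rigid limit only), distance
fluctuations, CSA tensor variability, and chemical exchange. Passing these
tests therefore shows the closed-form tumbling machinery is right; it says
nothing about how well the model-free interpolation describes a real IDP.

## Experiment-side arithmetic

Longitudinal CCR rates are extracted from the asymmetry of a ¹³C′–¹³Cα
doublet after a relaxation delay $T$ as $\Gamma = \ln(I_a/I_b)/(2T)$ — the
logarithm is natural, since the underlying relaxation is exponential in $e$.
Which component is $I_a$ is an assignment convention (`swap` negates the
sign). First-order error propagation gives
$\sigma_\Gamma = \frac{\sigma_I}{2T}\sqrt{I_a^{-2}+I_b^{-2}}$. The
`synth_doublets()` generator inverts this map ($I_a/I_b = e^{2\Gamma T}$,
multiplicative Gaussian intensity noise, seeded), and the tests require exact
round trips at zero noise for $|\Gamma|\,2T \le 5$ and 3σ recovery of a known
rate from 200 noisy records at 1% intensity noise — the regime
($\Gamma = 2$ s⁻¹, $T = 50$ ms) where the short-mixing-time assumption holds.
The generator emulates only intensity noise on ideal exponential doublets; it
does not model ¹³C′–¹³Cβ contamination (a real contribution of up to ~20% of
the CCR in crowded spectra), partial overlap, or baseline distortions.

For the ¹⁵N channel the rate equations invert exactly:
$J(\omega_N) = \Gamma_z/(6k\Delta_N)$,
$J(0) = (\Gamma_{xy}-\tfrac12\Gamma_z)/(4k\Delta_N)$. The ¹³C′ channel mixes
two CSA components, so only the composite
$(\sigma_{xx}-\sigma_{zz})J_{xx}(0) + (\sigma_{yy}-\sigma_{zz})J_{yy}(0)$ is
recoverable — `map_j0_composite_c()` returns exactly that and nothing more.

## Numerical choices

* Angles are stored as signed degrees in (−180°, 180°]; all trigonometry goes
  through one wrap helper, and `p2()` clamps cosines to [−1, 1] after
  rejecting inputs beyond 1 + 1e-12.
* Spectrum terms with exactly zero amplitude are dropped (so $S^2=1$ gives a
  three-term spectrum, $S^2=0$ a single term); a fully zero TCF keeps one
  zero-amplitude term rather than an empty object.
* `iso_ratio_limit()` refuses denominators with $|P_2| < 10^{-9}$ (magic
  angle) and `q_ratio()` refuses denominator combinations below
  $10^{-15}\,s^{-1}$, both as explicit errors with context.
* `numeric_j()` uses plain trapezoidal quadrature; with ≥ 50 points per
  slowest correlation time and a 10–12 τ window the quadrature error is
  below 0.1%, which is the agreement contract tested against
  `j_lorentzian()`.
* The (τ_eff, anisotropy) ↔ (D∥, D⊥) conversion is closed-form in both
  directions and round-trips to 1e-12.
* Problem sizes in the stochastic tests (2×10⁶ steps, dt = 10 ps, stride 2)
  were sized so the Monte-Carlo noise sits several-fold below each stated
  tolerance; seeds are fixed.

## Limitations

* The model-free extension uses one $S^2$/$\tau_{int}$ for all vector pairs;
  differential local dynamics between the two channels will read out as
  apparent anisotropy in Q. This is intentional — Q is a detector, not an
  estimator, and quantitative extraction of $D_\parallel/D_\perp$ from
  experimental Q profiles is out of scope.
* The diffusion main axis is constrained to the peptide plane; out-of-plane
  tensors, 3D-GAF-style restricted local motions, multi-timescale internal
  dynamics and correlation-time distributions are not modeled.
* Absolute rate magnitudes inherit the stated prefactor convention; compare
  ratios, not raw rates, across software.
* The ¹⁵N CSA is axially symmetric by construction here; the small rhombicity
  of real amide tensors is absorbed into $\Delta_N$. $\sigma_{yy} = 191.1$
  ppm for ¹³C′ is taken as a fixed calibration constant and not re-derived.
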