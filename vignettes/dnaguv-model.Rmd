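---
title: "Modelling the thermal response of DNA-linked vesicle pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the thermal response of DNA-linked vesicle pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnaguv)
```

## The system and the model

Giant unilamellar vesicles (GUVs) coated with mobile DNA tethers adhere to
each other when complementary sticky ends hybridize across the gap between
two membranes, forming *bridges*. The same tethers can also hybridize on a
single vesicle, forming non-adhesive *loops*. Because the tethers diffuse
freely on the fluid bilayer, and because the bilayer area expands with
temperature while the enclosed volume stays essentially fixed, the
equilibrium shape of an adhering pair is set by a competition between

* the membrane's stretching elasticity, which resists any deviation of the
  area $A$ from its unstretched value $\bar A(T)$, and
* the free energy of the DNA, which rewards a large adhesion patch (more
  room for bridges) and slightly rewards stretched membranes (more room for
  every tether).

`dnaguv` implements this competition for a symmetric pair of identical
vesicles and exposes every stage — forward prediction, neutral-temperature
fitting, Monte-Carlo uncertainty propagation, fluorescence-based estimation,
and synthetic-data generation — as tested package functions.

### Geometry

Each vesicle is a sphere of radius $R$ truncated by a flat adhesion disc;
the trial contact angle $\tilde\theta$ between the centre-to-centre axis and
a radius subtending the patch edge is the single shape coordinate. With
$c=\cos\tilde\theta$,

$$A_p = \pi R^2 (1 - c^2), \qquad
  A = 2\pi R^2 (1+c) + A_p, \qquad
  D = 2Rc, \qquad
  V = \tfrac{\pi}{3} R^3 (1+c)^2 (2-c).$$

Vesicles are treated as water-impermeable, so $V$ is pinned to the reference
sphere volume $\tfrac43\pi R_0^3$ at every angle by solving for $R(\tilde\theta)$
(`geometry_at_angle()`). The dimensionless reduced volume
$\nu = 6\sqrt{\pi}\, V / A^{3/2}$ then has the closed form
$2\sqrt{1+c}\,(2-c)/(3-c)^{3/2}$, which the tests verify against the direct
definition to $10^{-12}$ across the whole angle range. Thermal area
expansion enters through $\bar A(T) = 4\pi R_0^2 (1 + \alpha (T - T_0))$;
the *neutral temperature* $T_0$, at which an isolated vesicle is exactly
spherical and tensionless, is the model's only fitted parameter. The
zero-stretch angle $\tilde\theta_0(T)$ solves
$\nu(\tilde\theta_0)= (1+\alpha(T-T_0))^{-3/2}$ by bracketed root finding
to $10^{-6}$ rad and is the shape an adhering pair would adopt if adhesion
consumed exactly the thermal excess area.

The centre-to-centre distance deliberately excludes the ~15 nm
inter-membrane gap, which is far below the optical resolution of the
measurements the model is compared against.

### DNA thermodynamics

A single tethered bond carries the free energy (in units of $k_BT$ at the
current temperature)

$$\Delta G_{b/l} = \Delta G^0(T) - T\Delta S^{rot} - T\Delta S^{trans}_{b/l},$$

where $\Delta G^0 = \Delta H^0 - T\Delta S^0$ is the solution hybridization
free energy of the sticky ends and the two configurational terms describe
tethering. Modelling tethers as freely pivoting rigid rods of length $L$
with point sticky ends, the orientational cost after averaging over the
lateral displacement of the tether points is
$-T\Delta S^{rot} = \ln(4\pi\rho_0 L^3)$ — about $10.0\,k_BT$ for
$L = 14.5$ nm — and is identical for loops and bridges: the loop
(half-orbit, $K_l = 1/2$, $d_t = y \le 2L$) and bridge ($K_b = 1$,
$d_t = \sqrt{L^2+y^2}$, $y \le \sqrt3 L$) displacement integrals of the
bound-pair density $K/(2\pi\rho_0 d_t L^2)$ both evaluate to exactly
$1/(\rho_0 L)$, a fact the test suite confirms by numerical quadrature.
The translational cost is
$-T\Delta S^{trans} = \ln\!\big(A^2/(4\pi L^2 \tilde A)\big)$ with available
area $\tilde A = A$ for loops and $\tilde A = \tilde A_p$ for bridges, so
geometry couples to the DNA only through areas, and
$\Delta G_l - \Delta G_b = \ln(\tilde A_p / A)$ exactly.

Bridges can form not only on the flat disc but in a narrow rim around it
where the membranes diverge with gap $L + 2s\tan\tilde\theta$; requiring the
gap to stay below $2L$ gives rim width $L/(2\tan\tilde\theta)$ and the
effective area $\tilde A_p = A_p + \pi R L\cos\tilde\theta$. This form is
continuous, tends to $\pi R L$ as the patch closes (keeping the bridge
entropy finite), and is negligible relative to $A_p$ at large angles. It is
a reconstruction from the gap construction rather than a transcription of a
published formula; both printed constraints it must satisfy (finite
small-angle limit, vanishing relative contribution at large angle) are
tested.

With $N$ tethers per vesicle ($N = \rho_{DNA} 4\pi R_0^2$, fixed at
grafting; half per species) the equilibrium fractions of tethers in bridges
($x_b$) and loops ($x_l$) solve the mean-field gap equations
$x_i = (1 - x_b - x_l)^2 q_i$ with $q_i = (N/2) e^{-\Delta G_i}$. The $N/2$
multiplicity carries the combinatorial attraction of mobile multivalent
binding (magnitude $\ln N \approx 13$ for typical coatings); adding a
separate $-\ln N$ term would double-count it. The total bound fraction has
the closed form $x = 1 - 2/(1+\sqrt{1+4q})$, $q = q_b + q_l$, which is
numerically stable at both extremes and reproduces the series
$x \simeq q - 2q^2$ for $q \to 0$. The hybridization free energy is
$U_{hyb} = 2N[\ln(1-x) + x/2]$. An exact finite-$N$ enumeration of the
pairing partition function (`exact_bond_fractions()`, $O(m^3)$ by
factorizing the two bridge directions) serves as an independent oracle: the
mean-field fractions agree within the expected $O(1/N)$ error at $N$ as
small as 2 and converge as $N$ grows.

### Assembling and minimizing the free energy

$$U(\tilde\theta; T) = \underbrace{2\tfrac{K_a}{2}\frac{(A-\bar A)^2}{\bar A}}_{U_{membrane}}
 + \underbrace{U_{hyb} - 2N\ln(A/\bar A)}_{U_{DNA}} - U_0 .$$

The confinement term $-2N\ln(A/\bar A)$ accounts for the extra translational
room every tether gains when the membrane stretches; it is applied to all
$2N$ tethers and referenced to $\bar A(T)$ so the energy vanishes in the
no-bond, no-stretch limit (any other reference shifts $U$ by an
angle-independent constant). $U_0$ is the loops-only hybridization free
energy of two isolated unstretched vesicles. Bending elasticity and
fluctuation repulsion are neglected (strong-adhesion regime), and the
quadratic stretching penalty is kept also for $A < \bar A$; near equilibrium
the DNA attraction keeps $A \ge \bar A$, so this floppy-side approximation
is inert.

`equilibrium_state()` scans $\tilde\theta$ on a dense grid (0.05° steps over
[0.1°, 89°]; the 89° cap avoids the degenerate hemisphere limit) and then
refines the bracketing interval by golden-section search to $10^{-4}$ rad,
never accepting a refinement worse than the best grid point. The
grid-then-refine strategy is global, which matters near the melting region
where bound and unbound branches can coexist. The Monte-Carlo loops use a
parabolic three-point refinement instead (no extra energy evaluations);
the two refinements agree to well under the grid step. Because the membrane
term is steep ($K_a \bar A \sim 10^{10}\,k_BT$ per unit relative strain
squared) while the DNA terms vary by $10^4\,k_BT$ across the scan, the
equilibrium angle tracks $\tilde\theta_0(T)$ closely from above — the
predicted deviation is small but strictly positive for $T > T_0$, and grows
with DNA coverage.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `alpha` | area thermal expansion | $1.3\pm0.7\times10^{-3}$ | K$^{-1}$ |
| `Ka` | stretching modulus | $240\pm90$ | mN m$^{-1}$ |
| `rho_dna` | tether coverage (both species) | $390\pm90$ | $\mu$m$^{-2}$ |
| `L` | duplex spacer length (43 bp × 0.338 nm) | 14.5 | nm |
| `dH0` | sticky-end enthalpy | $-68.5\pm3$ | kcal mol$^{-1}$ |
| `dS0` | sticky-end entropy | $-193.5\pm8$ | cal mol$^{-1}$K$^{-1}$ |
| `rho0` | standard-state concentration (1 M) | 0.6 | nm$^{-3}$ |
| `T0` | neutral temperature (fitted) | $-3$ | °C |
| `R0` | reference radius | 10 | $\mu$m |

Temperatures cross every interface in °C (the convention of the
measurements) and are converted to kelvin at the point of use; energies are
expressed in $k_BT$ at the *current* temperature, recomputed per state
point, because the model mixes $k_BT$-denominated entropies with
kcal mol$^{-1}$ enthalpies; lengths are nm internally with areas reported in
$\mu$m². The enthalpy/entropy error bars absorb the inert-tail correction;
computing $\Delta H^0,\Delta S^0$ from sequence is out of scope, so Table
values are inputs.

## Fitting and uncertainty propagation

`fit_neutral_temperature()` minimizes
$\sum_T (\theta_{pred}(T; T_0) - \theta_{obs}(T))^2$ on a 0.25 °C grid over
$[\min T_{obs} - 15, \min T_{obs} + 10]$ °C, refined locally to 0.05 °C.
The contact angle is the primary observable and the objective is a
least-squares choice of this package (the measurement protocol it mirrors
does not state one); a weighted multi-observable objective is available but
off by default. Observations at duplicate temperatures are averaged.

`propagate_uncertainty()` draws $\alpha$, $K_a$, $\rho_{DNA}$ from normal
distributions truncated to positive values by rejection (the relative error
on $\alpha$ is 54%, so plain normals would produce unphysical draws), and
couples $\Delta H^0$ and $\Delta S^0$ through a single shared z-score, which
keeps the duplex melting temperature nearly fixed (sd below 1 K) instead of
letting it fluctuate unphysically. Summaries are the median and the
16th/84th percentiles, and the three nested propagation sets
($\alpha$; $\alpha + K_a$; full) use common random numbers so the bands
nest draw by draw. Solver failures are counted and reported, never silently
dropped; `L`, $\rho_0$, $T_0$ and $R_0$ are not propagated.

## Estimators and the synthetic generator

The estimators start from fitted per-frame quantities (circle radii, patch
chord $L_p$, mean intensities), not pixels: $A_p = \pi (L_p/2)^2$,
$\theta = \arcsin(L_p/2R)$, $A = 2\pi R^2(1+\cos\theta) + A_p$ (flat-chord
approximation throughout). The bridge fraction uses per-vesicle signals
$S_v = (I_v - I_{bg}) A$ and $S_b = \tfrac12 (I_p - 2I_v + I_{bg}) A_p$ —
the patch is diminished by *two* membranes' worth of non-bridge signal,
which makes the estimator exactly unbiased on the forward intensity model;
the single-subtraction variant is available behind a switch and
overestimates. Being a ratio, the estimator is invariant under any common
rescaling of background-subtracted intensities, which is what corrects for
the dye's monotonic brightness decay with temperature. The ~10% brightness
excess of a bound pair (95 vs 86 paired bases) is neglected in the
estimator, exactly as in the analysis it mirrors; the generator can switch
it on to measure the resulting upward bias.

`generate_pair_series()` runs the forward model on a 0–40 °C grid (1 °C
steps by default, the resolution of the imaging ramp it emulates), converts
to measurables, and adds Gaussian noise: `sigma_R = sigma_Lp = 0.1` µm
(optical scale), 2% relative intensity noise, and a dye-brightness decay of
0.005 per °C. The decay magnitude is a plumbing choice — only its monotone
decrease is anchored — and the brightness must stay positive on the grid.
The intensity bookkeeping conserves the tether count exactly, keeps the
in-patch density inside the ideal-gas validity bound
($\rho_{patch} L^2 < 1$), and the two vesicles are generated identical with
any $R_1/R_2$ asymmetry injected as measurement noise only. Conditioning
transients (sudden pore-opening relaxation events seen in fresh samples)
are deliberately not simulated: the model describes the post-conditioning,
fully reversible regime. Passing tests on these synthetic tables therefore
demonstrates the internal consistency of estimators and model under the
model's own assumptions — not robustness to curved patches, unequal vesicle
sizes, segmentation artefacts or non-Gaussian imaging noise, none of which
the generator produces.

The coverage calibration assumes the equatorial membrane band inside a
confocal slice of thickness $\delta$ projects onto an annulus of width
$\delta^2/8R$, giving $I_v - I_d = C d \rho\, 8R/\delta$ and the inverse
$\rho_{DNA} = J\delta/C$ with $J = (I_v - I_d)/(8 d R)$; the slice
thickness cancels, which is tested as an algebraic property. The bulk
dilution series is linear with slope $C d \delta$, and `C = 2.7` µm,
`d = 0.076` µm are the default calibration constants.

## Numerical choices and problem sizes

* Angle grid 0.05° (1779 points), refinement $10^{-4}$ rad; halving the
  grid moves the optimum by < 0.01°.
* Root finds (zero-stretch angle) by `uniroot` to $10^{-6}$ rad.
* Gap-equation residuals below $10^{-12}$; all fraction formulas use
  cancellation-free forms (`log1p`, $1-x = 2/(1+\sqrt{1+4q})$).
* The test suite runs the uncertainty propagation at $n = 10^4$ draws per
  band on a four-temperature grid, the enumeration oracle up to $N = 10^3$
  tethers, and the fit-recovery study over 50 seeds on an eight-temperature
  ramp — sizes chosen so the whole suite completes in a few minutes while
  leaving every statistical check well-powered.

## Known limitations

* Symmetric pairs only: unequal radii or excess areas (and the curved
  patches they produce) are outside the geometry closure.
* The inter-membrane distance is pinned at $h = L$; the generalized
  $h$-resolved theory, finite sticky-end size, and loop depletion for
  $h < L$ are not implemented.
* Constant-volume closure: the osmotically equilibrated variant is not
  implemented.
* No bending/fluctuation contributions, no kinetics or hysteresis, no
  many-vesicle networks.
* At central parameters the model predicts the patch area at 0 °C to be
  ~28% of its 40 °C value, a strong but not total shrinkage; pairs with
  lower $T_0$ or smaller excess area shrink further.
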