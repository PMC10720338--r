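---
title: "Osmotic force balance analysis of aqueous electrolytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Osmotic force balance analysis of aqueous electrolytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmobalance)
```

## The method

In an osmotic force balance simulation an external potential $U(z)$ acts
along one axis of the box on the dissolved ions only, not on the water. At
equilibrium the restraint force on the solutes is balanced by the gradient
of the osmotic pressure,
$$\frac{d\Pi}{dz} = -\nu\, C_s(z)\, \frac{dU}{dz},$$
where $C_s(z)$ is the local salt concentration and $\nu = \nu_+ + \nu_-$
is the number of ions per formula unit. Integrating inward from the pure
water reservoir (where $\Pi \to 0$) turns a single simulated concentration
profile into the full osmotic equation of state $\Pi(C_s)$: every
concentration between zero and the peak value is visited somewhere in the
box. `osmotic_pressure_direct()` performs exactly this integration
(trapezoid rule on the bin grid, tails closed with $C = 0$).

The same profile also encodes the salt's free energy. Writing the salt
chemical potential at constant water chemical potential $\mu_w$ as
$$\mu_s = \mu_s^0 + \nu R T \ln\!\big(C_s\,\gamma_\pm(C_s)\big),\qquad
\ln\gamma_\pm = -\frac{A\sqrt{C_s}}{1 + B\sqrt{C_s}} +
\sum_{i=1}^{i_\mathrm{max}} \alpha_i C_s^i,$$
an extended Debye–Hückel (modDH) form, the equilibrium condition under the
restraint becomes
$$\ln\!\big(C\gamma(C)\big) = \ln\!\big(C_{\max}\gamma(C_{\max})\big) -
U(z)/RT,$$
which `predicted_profile()` solves for $C(z)$ by bracketed bisection. With
$\gamma \equiv 1$ this is the Boltzmann Gaussian
$C(z) = C_{\max} e^{-U(z)/RT}$ and the pressure reduces to the van 't Hoff
law $\Pi = \nu R T C$; deviations from the Gaussian are precisely what the
fit converts into activity information.

Gibbs–Duhem integration of the modDH expression has a closed form used
throughout the package:
$$\Pi(C) = \nu R T \left[ C - \frac{A}{B^3}\Big( u - 2\ln u -
\tfrac{1}{u} \Big) + \sum_i \frac{i}{i+1}\,\alpha_i\, C^{i+1}
\right],\qquad u = 1 + B\sqrt{C}.$$
The same algebra on the molality scale gives the water activity at
constant pressure,
$\ln a_w(m) = -\nu M_w^{\mathrm{kg}}\,[\,m - \cdots\,]$, and
$\Pi = -RT \ln a_w / \bar V_w$. Because several of these integrated forms
are easy to get subtly wrong, the package carries independent adaptive
quadrature oracles (`osmotic_pressure_molar_quadrature()`,
`ln_water_activity_quadrature()`), and the test suite requires closed form
and quadrature to agree to $10^{-8}$ relative on random stable parameter
sets. One such check caught a wrong series coefficient in the $B = 0$
limit during development: the limiting bracketed term is
$(B\sqrt C)^3/3$, giving $A C^{3/2}/3$, not $\tfrac{2}{3} A C^{3/2}$.

## Two thermodynamic routes and the B calibration

The force balance fixes $\mu_w$ (the box ends are pure-water reservoirs),
while experimental activity data are taken at fixed pressure, where
molality is the natural composition variable. The package therefore keeps
two parameter sets: molar $(A, B, \alpha_i)$ and molal
$(\tilde A, \tilde B, \tilde\alpha_i)$, tied in the dilute limit by
$\tilde X = X\sqrt{\rho_{w0}}$ (where $C \approx \rho_{w0} m$).

The staged fit (`fit_osmotic_balance()`) mirrors the method's own
procedure:

1. $A$ is never fitted: it comes from Debye–Hückel theory,
   $A = \tfrac{1}{2} l_B \sqrt{8000\pi\, l_B N_A}$ with $l_B$ the Bjerrum
   length (natural log, molarity basis). For a dielectric constant of
   59.1 at 298.15 K this evaluates to 1.7964 M$^{-1/2}$, the convention
   check built into the tests.
2. For fixed $B$, the $\alpha_i$ minimise the squared deviation between
   the predicted and observed profiles over bins with $C \ge$ 10 mM
   (Levenberg–Marquardt). At every step $C_{\max}$ is *eliminated*, not
   fitted: `cmax_from_mass_balance()` solves
   $L_x L_y \int C(z)\,dz = N_s$ so the model always carries the correct
   ion count.
3. The $\tilde\alpha_i$ follow by *linear* least squares of the molal
   pressure expression against the force-balance pressures integrated
   directly from the profile.
4. An outer scalar search (`calibrate_B()`, Brent minimisation bracketed
   around the standard starting value $B = 1.5$ M$^{-1/2}$, tolerance
   $10^{-3}$) picks the $B$ that minimises the mean squared difference
   between the two pressure routes over the sampled range.

On noiseless synthetic profiles this pipeline recovers the generating
$\alpha_i$ and $C_{\max}$ to $10^{-6}$; with counting noise at the
$10^4$-effective-frame scale the recovered $\Pi(C)$ stays within 2% of
the generating curve (both are asserted in the test suite).

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `k` | kJ/(mol Å²) | 0.025 | confines ~3.5 M peak in a 100 Å box |
| restraint convention | — | `half-k` ($U = \tfrac12 k z^2$) | common MD position-restraint form; a flag selects $k z^2$ |
| `i_max` | — | 2 | two polynomial terms describe alkali halides to ~3.5 M |
| `floor` | M | 0.01 | below ~10 mM counting noise breaks local electroneutrality |
| `B_init` | M$^{-1/2}$ | 1.5 | standard starting value for the calibration |
| bin width | Å | 0.5 | resolves the profile; route agreement holds to ≤0.5% here |
| $\bar V_w$ | cm³/mol | $M_w/\rho_{w0} \approx 18.07$ | pure-water value; correct to ~3% (see below) |

All internal consistency results (for example, force-balance integration
versus the closed form) are invariant to the restraint convention, but
comparisons with external simulation data must use the matching one — the
spring constants quoted for a given data set pair with a specific
convention, and the package deliberately refuses to guess.

## Densities, ensembles, and $\bar V_w$

Solution densities from force-balance runs are at constant $\mu_w$;
experimental densities are at constant $P$. Both are represented by
$\rho(m) = \rho_{w0} + \theta_1 m + \theta_{3/2} m^{3/2} + \theta_2 m^2$
(`fit_density()`; this power family is distinct from the integer-power
$\alpha$ polynomial and the two are separate types). The conversion
between ensembles uses the first-order compression
$\rho(m|P) = \rho(m|\mu_w)\,(1 - \kappa_\mathrm{eff}\Pi(m))$; at
$\kappa_\mathrm{eff}\Pi \ll 1$ the difference from the alternative
$\rho/(1+\kappa\Pi)$ form is far below fit noise, which is why the
simpler product form was chosen. The partial molar volume of water
follows from the fit as $\bar V_w = M_w^{\mathrm{kg}}(v - m\,dv/dm)$ with
$v = (1000 + m M_s)/\rho$ the volume per kilogram of water; it is
validated in the tests by the Euler relation
$n_w \bar V_w + n_s \bar V_s = V$. Across the bundled constant-$P$
coefficient sets, $\bar V_w$ stays within about 2.5% of the pure-water
value up to 4 molal, which is what justifies using $M_w/\rho_{w0}$ in the
molal pressure route when no density information is available.

## The χ transform for LJ cross interactions

Multiplying the repulsive $r^{-12}$ part of a Lennard-Jones cross
interaction by $1+\chi$ leaves a Lennard-Jones potential with
$\sigma' = \sigma(1+\chi)^{1/6}$ and $\varepsilon' =
\varepsilon/(1+\chi)$ — an exact identity in $r$, asserted pointwise in
the tests. `apply_chi()`, `infer_chi()` and `eos_mse()` support the
workflow of tuning $\chi$ per salt so that simulated osmotic pressures
match an experimental reference equation of state; the per-χ pressure
curves themselves must come from simulations, so `select_chi()` only
scores user-supplied curves, it does not generate them.

## What the synthetic generator does and does not emulate

`generate_profile()` draws multinomial counting noise, independently for
cations and anions, around the exact model profile (the effective frame
count standing in for the autocorrelation time of a real trajectory).
This captures the finite-sampling character of binned MD histograms —
including realistic charge imbalance in the dilute tails, which is what
the electroneutrality audit and the 10 mM analysis floor respond to —
but not temporal correlation, ion pairing beyond what modDH encodes,
finite-size electrostatics, or solvent structuring near high ion
density. Passing the recovery tests therefore demonstrates the
*estimator* is correct and stable under counting noise; it does not
certify any force field. `simulate_ideal_solutes()` is a genuinely
independent cross-check for the ideal limit: a Metropolis walk whose
stationary histogram must reproduce the Boltzmann Gaussian
($\sigma_z = \sqrt{RT/k}$) and the ideal gas law without reference to
any of the modDH machinery.

## Numerical choices and degenerate inputs

* Quadrature: `stats::integrate` at `rel.tol = 1e-10`; the profile solve
  is 80-step bisection on $\ln C$ (machine precision); the mass-balance
  integral uses a substitution $C = C_{\max}e^{-t^2}$ that removes the
  square-root singularity at the peak, then a 4001-point trapezoid —
  accurate to ~$10^{-6}$ relative, with `uniroot` at `tol = 1e-12` on top.
* Stability: the modDH model is only meaningful where
  $d\ln(C\gamma)/dC > 0$; `predicted_profile()` refuses unstable
  parameter sets, and during fitting the mass-balance cap adapts to the
  stability boundary while infeasible trial steps incur a smooth penalty
  instead of aborting the optimiser.
* Edge cases handled by analytic limits rather than exceptions: $C = 0$
  (all integrated quantities vanish), $B = 0$ (series limit above),
  $\varphi(0) = 1$ by continuity.
* Least-squares weighting across bins is uniform by default (the
  procedure does not prescribe weights); a Poisson-like
  $1/\sqrt{C}$ weighting is available behind a flag.
* Test problem sizes were chosen to probe each claim at the smallest
  scale that exercises it: e.g. 300 walkers × 8000 sweeps for the
  Metropolis check, $10^4$ effective frames for noisy recovery.

## Known limitations

Single-temperature method; 1:1 electrolytes are the tested path (the
types carry general stoichiometry, but asymmetric valences change the
Debye–Hückel prefactor in ways the bundled $A$ helper does not cover);
no Pitzer/eNRTL-class models; no dielectric decrement with concentration;
the χ objective cannot be closed without running new simulations for each
candidate χ.
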