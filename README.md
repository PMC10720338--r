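# osmobalance

Analysis toolkit for **osmotic force balance** simulations of aqueous
electrolytes. In this simulation technique an external potential $U(z)$ is
applied along one box axis to the dissolved ions only; at equilibrium the
restraint is balanced by the gradient of the osmotic pressure,

$$\frac{d\Pi}{dz} = -\nu\,C_s(z)\,\frac{dU}{dz},$$

so a *single* restrained run yields the full osmotic equation of state
$\Pi(C_s)$ — every concentration from the pure-water reservoir to the peak
appears somewhere along $z$. The package is aimed at simulators developing
and validating ion force fields, and at anyone who needs osmotic
pressures, water activities and mean ionic activity coefficients from
restrained-simulation concentration profiles.

What it does:

* fits the **modified Debye–Hückel (modDH)** free-energy model
  $\ln\gamma_\pm = -A\sqrt{C}/(1+B\sqrt{C}) + \sum_i \alpha_i C^i$
  to z-binned concentration profiles under a hard mass-balance
  constraint, with $A$ from Debye–Hückel theory and $B$ calibrated so the
  constant-$\mu_w$ (molar) and constant-$P$ (molal) pressure routes
  agree;
* integrates profiles directly to $\Pi(z)$ (force balance), and provides
  closed-form $\Pi(C)$, $\ln a_w(m)$, $\varphi(m)$ and $\ln\gamma_\pm$
  with independent quadrature oracles;
* converts solution densities between the constant-$\mu_w$ and
  constant-$P$ ensembles and derives partial molar volumes;
* applies the **χ repulsion-scaling transform** for Lennard-Jones
  cation–anion cross interactions
  ($\sigma' = \sigma(1+\chi)^{1/6}$, $\varepsilon' = \varepsilon/(1+\chi)$)
  and its inverse, with the mean-square EOS objective used to select χ;
* generates synthetic data (noisy binned profiles with multinomial
  counting noise, an ideal-solute Metropolis sampler, reference
  osmotic-coefficient tables) so the entire pipeline runs and is tested
  without molecular dynamics;
* reads plain TSV and GROMACS `.xvg` profile tables, Hamer–Wu-style
  osmotic-coefficient CSVs, LJ parameter CSVs and YAML generator
  configs; writes versioned JSON fit reports. A command-line front end
  (`exec/osmobalance`) exposes `fit`, `pressure`, `activity`, `rescale`,
  `chi`, `simulate` and `check` subcommands.

## Worked example

Generate a noisy synthetic NaBr-like profile (60 ion pairs in a
30 × 30 × 100 Å box, half-k harmonic restraint k = 0.025 kJ/(mol Å²),
10⁴ effective frames) and run the full staged fit:

```r
library(osmobalance)

solv <- solvent_spec()                      # dielectric 59.1, 298.15 K
salt <- alkali_halide_salt("NaBr")
cfg  <- generator_config(n_frames = 1e4, seed = 42)
prof <- generate_profile(cfg)

rep <- fit_osmotic_balance(prof, A = debye_huckel_A(solv),
                           salt = salt, solvent = solv)
print(rep)
#> Osmotic force balance fit: NaBr
#> modDH (molar basis): A = 1.7964, B = 1.2532 M^-1/2; alpha = (0.184816, 0.020432)
#> modDH (molal basis): A~ = 1.7937, B~ = 1.2514 molal^-1/2; alpha~ = (0.0248489, -0.00324116)
#>   C_max = 3.6745 M; residual norm = 0.138 M; route MSE = 0.0108 bar^2
#>   max charge imbalance (C >= 0.01 M): 0.164

osmotic_pressure_molar(c(1, 2, 3.5), rep$molar, salt, solv)
#> [1]  46.5 106.0 230.1   # bar
```

Reading the output: `A` is pinned at the Debye–Hückel value for the
solvent (1.7964 M⁻¹ᐟ² at dielectric 59.1); `B` and the two polynomial
coefficients are fitted; `C_max = 3.6745 M` is the peak concentration
that carries exactly 60 ion pairs (the generating value was 3.6762 M);
the route MSE of ~0.01 bar² says the constant-$\mu_w$ and constant-$P$
pressure expressions agree essentially to line thickness after the B
calibration. The pressures at 1, 2 and 3.5 M sit below the ideal-gas
values (49.6, 99.2, 173.5 bar) at low concentration — Debye–Hückel
screening — and above them at high concentration, where the polynomial
term dominates. The charge imbalance of 0.16 is the expected counting
noise of the dilute tail bins at this effective frame count.

The χ transform reproduces tabulated optimized cross interactions:

```r
apply_chi(lj_pair(3.1787, 17.524), 0.75)   # LiCl
#> LJ pair: sigma = 3.4894 A, eps = 10.014 K, chi = 0.75
```

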