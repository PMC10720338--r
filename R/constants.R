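# Physical constants (CODATA 2018) and unit conversion factors.
# Internal unit conventions across the package:
#   energy kJ/mol, length Angstrom, concentration mol/L (M), molality mol/kg,
#   pressure bar, density g/cm^3, temperature K, LJ well-depth K.

#' Physical constants used throughout the package
#'
#' Gas constant in kJ/(mol K), Avogadro's number, elementary charge (C),
#' vacuum permittivity (F/m), Boltzmann constant (J/K), and the conversion
#' factor from M x kJ/mol to bar.
#'
#' @format Named list.
#' @export
osmo_constants <- list(
  R_kJ    = 8.31446e-3,       # kJ/(mol K)
  N_A     = 6.02214076e23,    # 1/mol
  e_C     = 1.602176634e-19,  # C
  eps0    = 8.8541878128e-12, # F/m
  k_B     = 1.380649e-23,     # J/K
  # 1 (mol/L)*(kJ/mol) = 1 kJ/L = 1e6 J/m^3 = 1e6 Pa = 10 bar
  MkJ_to_bar = 10,
  # 1 (kJ/mol)/(cm^3/mol) = 1 kJ/cm^3 = 1e9 Pa = 1e4 bar
  kJcm3_to_bar = 1e4
)

RT_kJ <- function(temperature) osmo_constants$R_kJ * temperature
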