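# Domain types: salts, solvents, modDH parameter sets, boxes, restraints.
# Lightweight validated S3 records, in the style of base-R scientific packages.

stop_domain <- function(...) stop(..., call. = FALSE)

#' Electrolyte specification
#'
#' Describes one salt X_{nu+} Y_{nu-}: stoichiometric coefficients, ion
#' charges (in units of the elementary charge) and the molar mass of the
#' formula unit. The formula unit must be electroneutral.
#'
#' @param name Salt name, e.g. \code{"NaBr"}.
#' @param nu_plus,nu_minus Stoichiometric coefficients (positive integers).
#' @param z_plus,z_minus Cation/anion charges in elementary-charge units.
#' @param molar_mass_salt Molar mass of the formula unit, g/mol.
#' @return An object of class \code{salt_spec}.
#' @examples
#' salt_spec("NaBr", 1, 1, 1, -1, 102.894)
#' @export
salt_spec <- function(name, nu_plus = 1L, nu_minus = 1L,
                      z_plus = 1L, z_minus = -1L, molar_mass_salt) {
  nu_plus <- as.integer(nu_plus); nu_minus <- as.integer(nu_minus)
  z_plus <- as.integer(z_plus); z_minus <- as.integer(z_minus)
  if (nu_plus < 1L || nu_minus < 1L)
    stop_domain("stoichiometric coefficients must be positive integers")
  if (nu_plus * z_plus + nu_minus * z_minus != 0L)
    stop_domain("formula unit is not electroneutral: nu+ z+ + nu- z- != 0")
  if (!is.numeric(molar_mass_salt) || molar_mass_salt <= 0)
    stop_domain("molar_mass_salt must be positive (g/mol)")
  structure(list(name = as.character(name), nu_plus = nu_plus,
                 nu_minus = nu_minus, z_plus = z_plus, z_minus = z_minus,
                 nu = nu_plus + nu_minus,
                 molar_mass_salt = as.numeric(molar_mass_salt)),
            class = "salt_spec")
}

#' Solvent specification
#'
#' Dielectric constant, temperature, pure-solvent density and molar mass.
#' Defaults describe TIP4P/2005 water at 25 C (dielectric constant 59.1,
#' density 0.997 g/cm^3).
#'
#' @param dielectric Relative dielectric constant (> 1).
#' @param temperature Temperature in K.
#' @param rho_w0 Density of the pure solvent, g/cm^3.
#' @param molar_mass_w Solvent molar mass, g/mol.
#' @return An object of class \code{solvent_spec}.
#' @export
solvent_spec <- function(dielectric = 59.1, temperature = 298.15,
                         rho_w0 = 0.997, molar_mass_w = 18.015) {
  if (!is.numeric(dielectric) || dielectric <= 1)
    stop_domain("dielectric must exceed 1")
  if (!is.numeric(temperature) || temperature <= 0)
    stop_domain("temperature must be positive (K)")
  if (rho_w0 <= 0.9 || rho_w0 >= 1.1)
    stop_domain("rho_w0 outside the plausible aqueous range (0.9, 1.1) g/cm^3")
  structure(list(dielectric = as.numeric(dielectric),
                 temperature = as.numeric(temperature),
                 rho_w0 = as.numeric(rho_w0),
                 molar_mass_w = as.numeric(molar_mass_w)),
            class = "solvent_spec")
}

#' Modified Debye-Huckel parameters, molarity basis
#'
#' Coefficients of ln gamma+- (C) = -A sqrt(C)/(1 + B sqrt(C)) + sum_i
#' alpha_i C^i, the extended Debye-Huckel expression plus an empirical
#' polynomial, on the molar (constant water-chemical-potential)
#' concentration scale.
#'
#' @param A Debye-Huckel limiting-law coefficient, M^-1/2 (natural-log basis).
#' @param B Denominator coefficient, M^-1/2.
#' @param alphas Numeric vector of polynomial coefficients alpha_i for the
#'   integer powers i = 1..length(alphas); units M^-i.
#' @return An object of class \code{moddh_molar}.
#' @examples
#' moddh_molar(A = 1.7964, B = 1.3145, alphas = c(0.17100, 0.022058))
#' @export
moddh_molar <- function(A, B, alphas = numeric(0)) {
  if (A < 0) stop_domain("A must be non-negative")
  if (B < 0) stop_domain("B must be non-negative")
  structure(list(A = as.numeric(A), B = as.numeric(B),
                 alphas = as.numeric(alphas)),
            class = "moddh_molar")
}

#' Modified Debye-Huckel parameters, molality basis
#'
#' Same functional form as [moddh_molar()] with molality replacing molarity,
#' used for the constant-pressure description. Related to the molar
#' coefficients by A~ = A sqrt(rho_w0), B~ = B sqrt(rho_w0) in the dilute
#' limit.
#'
#' @param A_tilde,B_tilde Coefficients, molal^-1/2.
#' @param alphas_tilde Polynomial coefficients, units molal^-i.
#' @return An object of class \code{moddh_molal}.
#' @export
moddh_molal <- function(A_tilde, B_tilde, alphas_tilde = numeric(0)) {
  if (A_tilde < 0) stop_domain("A_tilde must be non-negative")
  if (B_tilde < 0) stop_domain("B_tilde must be non-negative")
  structure(list(A = as.numeric(A_tilde), B = as.numeric(B_tilde),
                 alphas = as.numeric(alphas_tilde)),
            class = "moddh_molal")
}

#' Simulation box geometry
#'
#' Rectangular box with the origin at the center; z runs from -Lz/2 to Lz/2.
#' Lengths in Angstrom.
#'
#' @param Lx,Ly,Lz Box edge lengths, Angstrom.
#' @return An object of class \code{box_spec}.
#' @export
box_spec <- function(Lx, Ly, Lz) {
  if (any(c(Lx, Ly, Lz) <= 0)) stop_domain("box lengths must be positive")
  structure(list(Lx = as.numeric(Lx), Ly = as.numeric(Ly),
                 Lz = as.numeric(Lz)), class = "box_spec")
}

#' Harmonic restraint applied to the solutes
#'
#' External potential along z acting on each ion. Two common spring-constant
#' conventions exist in MD packages; the default is U(z) = (1/2) k z^2
#' (\code{convention = "half-k"}), the alternative U(z) = k z^2
#' (\code{convention = "k"}). All internal consistency results are invariant
#' to this choice, but comparisons against external simulation data must use
#' the matching convention.
#'
#' @param k Spring constant, kJ/(mol Angstrom^2).
#' @param convention \code{"half-k"} (default) or \code{"k"}.
#' @return An object of class \code{restraint_spec}.
#' @export
restraint_spec <- function(k, convention = c("half-k", "k")) {
  convention <- match.arg(convention)
  if (!is.numeric(k) || k <= 0) stop_domain("spring constant k must be positive")
  structure(list(k = as.numeric(k), convention = convention),
            class = "restraint_spec")
}

# U(z) and dU/dz in kJ/mol and kJ/(mol A), honouring the convention flag
restraint_energy <- function(restraint, z) {
  pref <- if (restraint$convention == "half-k") 0.5 else 1
  pref * restraint$k * z^2
}
restraint_force_grad <- function(restraint, z) {
  pref <- if (restraint$convention == "half-k") 1 else 2
  pref * restraint$k * z
}

#' @export
print.salt_spec <- function(x, ...) {
  cat(sprintf("Salt %s: nu = (%d, %d), z = (%+d, %+d), M = %.3f g/mol\n",
              x$name, x$nu_plus, x$nu_minus, x$z_plus, x$z_minus,
              x$molar_mass_salt))
  invisible(x)
}

#' @export
print.moddh_molar <- function(x, ...) {
  cat(sprintf("modDH (molar basis): A = %.5g, B = %.5g M^-1/2; alpha = (%s)\n",
              x$A, x$B, paste(signif(x$alphas, 6), collapse = ", ")))
  invisible(x)
}

#' @export
print.moddh_molal <- function(x, ...) {
  cat(sprintf(
    "modDH (molal basis): A~ = %.5g, B~ = %.5g molal^-1/2; alpha~ = (%s)\n",
    x$A, x$B, paste(signif(x$alphas, 6), collapse = ", ")))
  invisible(x)
}
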