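# modDH free-energy model and the closed-form thermodynamics that follow
# from it by Gibbs-Duhem integration, on both the molar (constant mu_w) and
# molal (constant P) scales.

#' Debye-Huckel limiting-law coefficient A (molarity basis, natural log)
#'
#' Computes A for a 1:1 electrolyte from fundamental constants:
#' A = (l_B/2) sqrt(8000 pi l_B N_A), with l_B = e^2/(4 pi eps0 eps k_B T)
#' the Bjerrum length. On this convention the limiting law reads
#' ln gamma+- = -A sqrt(C) with C in mol/L. For TIP4P/2005 water
#' (eps = 59.1, T = 298.15 K) this gives 1.7964 M^-1/2.
#'
#' @param solvent A [solvent_spec()].
#' @return A in M^-1/2.
#' @examples
#' debye_huckel_A(solvent_spec(dielectric = 59.1, temperature = 298.15))
#' @export
debye_huckel_A <- function(solvent) {
  stopifnot(inherits(solvent, "solvent_spec"))
  cc <- osmo_constants
  lB <- cc$e_C^2 / (4 * pi * cc$eps0 * solvent$dielectric *
                      cc$k_B * solvent$temperature)        # m
  (lB / 2) * sqrt(8000 * pi * lB * cc$N_A)
}

# ln gamma and its concentration derivative; x is molarity or molality
# depending on the basis of `params` (the algebra is identical).
ln_gamma <- function(x, params) {
  if (any(x < 0)) stop_domain("concentration must be non-negative")
  s <- sqrt(x)
  out <- -params$A * s / (1 + params$B * s)
  for (i in seq_along(params$alphas))
    out <- out + params$alphas[i] * x^i
  out
}

dln_gamma_dx <- function(x, params) {
  s <- sqrt(x)
  # d/dx [-A sqrt(x)/(1+B sqrt(x))] = -A / (2 sqrt(x) (1+B sqrt(x))^2)
  out <- ifelse(x > 0, -params$A / (2 * s * (1 + params$B * s)^2), -Inf)
  if (params$A == 0) out <- rep(0, length(x))
  for (i in seq_along(params$alphas))
    out <- out + i * params$alphas[i] * x^(i - 1)
  out
}

# x * d ln gamma / dx, finite at x = 0
x_dln_gamma_dx <- function(x, params) {
  s <- sqrt(x)
  out <- -params$A * s / (2 * (1 + params$B * s)^2)
  for (i in seq_along(params$alphas))
    out <- out + i * params$alphas[i] * x^i
  out
}

# d ln(x gamma)/dx = 1/x + dlngamma/dx; must be > 0 for a stable model
dln_xgamma_dx <- function(x, params) 1 / x + dln_gamma_dx(x, params)

#' Mean ionic activity coefficient, molar basis
#'
#' ln gamma+-(C) = -A sqrt(C)/(1 + B sqrt(C)) + sum_i alpha_i C^i.
#'
#' @param C Salt molarity, M (vectorised, must be >= 0).
#' @param params A [moddh_molar()] parameter set.
#' @return ln gamma+- (dimensionless).
#' @export
ln_mean_activity_molar <- function(C, params) {
  stopifnot(inherits(params, "moddh_molar"))
  ln_gamma(C, params)
}

#' Mean ionic activity coefficient, molal basis
#'
#' Same functional form as [ln_mean_activity_molar()] with molality and the
#' molal coefficient set.
#'
#' @param m Salt molality, mol/kg (vectorised, >= 0).
#' @param params A [moddh_molal()] parameter set.
#' @return ln gamma+- (dimensionless).
#' @export
ln_mean_activity_molal <- function(m, params) {
  stopifnot(inherits(params, "moddh_molal"))
  ln_gamma(m, params)
}

#' Salt chemical potential difference between two molarities
#'
#' mu_s(C) - mu_s(C_ref) = nu R T ln( C gamma(C) / (C_ref gamma(C_ref)) )
#' per salt formula unit, at constant water chemical potential.
#'
#' @param C,C_ref Molarities, M; both must be strictly positive (the ideal
#'   log term diverges at C = 0).
#' @param params A [moddh_molar()].
#' @param salt A [salt_spec()].
#' @param solvent A [solvent_spec()].
#' @return Chemical potential difference in kJ/mol.
#' @export
chemical_potential_molar <- function(C, params, salt, solvent, C_ref) {
  stopifnot(inherits(params, "moddh_molar"), inherits(salt, "salt_spec"),
            inherits(solvent, "solvent_spec"))
  if (any(C <= 0) || any(C_ref <= 0))
    stop_domain("chemical potential diverges at zero concentration")
  salt$nu * RT_kJ(solvent$temperature) *
    (log(C) + ln_gamma(C, params) - log(C_ref) - ln_gamma(C_ref, params))
}

# Common closed-form Gibbs-Duhem integral:
#   I(x) = x - (A/B^3)[(1+B sqrt(x)) - 2 ln(1+B sqrt(x)) - 1/(1+B sqrt(x))]
#          + sum_i alpha_i * i/(i+1) * x^(i+1)
# which equals int_0^x x' dln(x' gamma(x')).  For B = 0 the DH term reduces
# to its series limit -(2/3) A x^(3/2).
gibbs_duhem_integral <- function(x, params) {
  A <- params$A; B <- params$B
  if (B > 0) {
    u <- 1 + B * sqrt(x)
    dh <- -(A / B^3) * (u - 2 * log(u) - 1 / u)
  } else {
    # B -> 0 limit of the bracketed term is (B sqrt(x))^3 / 3
    dh <- -A * x^1.5 / 3
  }
  out <- x + dh
  for (i in seq_along(params$alphas))
    out <- out + params$alphas[i] * (i / (i + 1)) * x^(i + 1)
  out
}

#' Osmotic pressure from the molar modDH model (closed form)
#'
#' Analytic Gibbs-Duhem integral of the modDH chemical potential at constant
#' water chemical potential:
#' Pi(C) = nu R T [ C - (A/B^3)((1+B sqrt(C)) - 2 ln(1+B sqrt(C)) -
#' 1/(1+B sqrt(C))) + sum_i alpha_i (i/(i+1)) C^(i+1) ].
#' With A = 0 and all alpha = 0 this reduces to the van 't Hoff ideal law
#' Pi = nu R T C. Validated against [osmotic_pressure_molar_quadrature()].
#'
#' @param C Molarity, M (vectorised, >= 0).
#' @param params A [moddh_molar()].
#' @param salt A [salt_spec()].
#' @param solvent A [solvent_spec()].
#' @return Osmotic pressure in bar.
#' @export
osmotic_pressure_molar <- function(C, params, salt, solvent) {
  stopifnot(inherits(params, "moddh_molar"), inherits(salt, "salt_spec"),
            inherits(solvent, "solvent_spec"))
  if (any(C < 0)) stop_domain("C must be non-negative")
  salt$nu * RT_kJ(solvent$temperature) * gibbs_duhem_integral(C, params) *
    osmo_constants$MkJ_to_bar
}

#' Osmotic pressure by adaptive quadrature (oracle for the closed form)
#'
#' Numerically integrates the constant-mu_w Gibbs-Duhem relation
#' dPi = nu R T C dln(C gamma) from 0 to C with adaptive quadrature.
#'
#' @inheritParams osmotic_pressure_molar
#' @param rel_tol Relative tolerance passed to [stats::integrate()].
#' @return Osmotic pressure in bar.
#' @export
osmotic_pressure_molar_quadrature <- function(C, params, salt, solvent,
                                              rel_tol = 1e-10) {
  stopifnot(inherits(params, "moddh_molar"))
  if (any(C < 0)) stop_domain("C must be non-negative")
  pref <- salt$nu * RT_kJ(solvent$temperature) * osmo_constants$MkJ_to_bar
  # integrand: C' dln(C' gamma)/dC' = 1 + C' dlngamma/dC'
  f <- function(x) 1 + x_dln_gamma_dx(x, params)
  vapply(C, function(ci) {
    if (ci == 0) return(0)
    q <- stats::integrate(f, 0, ci, rel.tol = rel_tol, abs.tol = 0,
                          subdivisions = 500L)
    if (q$message != "OK")
      stop("quadrature failed: ", q$message, call. = FALSE)
    pref * q$value
  }, numeric(1))
}

#' Map molar modDH coefficients to the molal basis (dilute-limit relation)
#'
#' In the low-concentration limit C ~ rho_w0 m, so A~ = A sqrt(rho_w0) and
#' B~ = B sqrt(rho_w0). The polynomial coefficients alpha~ are not mapped;
#' they are fitted separately on the molal side.
#'
#' @param params A [moddh_molar()].
#' @param solvent A [solvent_spec()] supplying rho_w0.
#' @return A [moddh_molal()] with empty \code{alphas_tilde}.
#' @export
molar_to_molal_params <- function(params, solvent) {
  stopifnot(inherits(params, "moddh_molar"), inherits(solvent, "solvent_spec"))
  s <- sqrt(solvent$rho_w0)
  moddh_molal(params$A * s, params$B * s)
}

#' Inverse of [molar_to_molal_params()]
#'
#' @param params A [moddh_molal()].
#' @param solvent A [solvent_spec()].
#' @return A [moddh_molar()] with empty \code{alphas}.
#' @export
molal_to_molar_params <- function(params, solvent) {
  stopifnot(inherits(params, "moddh_molal"), inherits(solvent, "solvent_spec"))
  s <- sqrt(solvent$rho_w0)
  moddh_molar(params$A / s, params$B / s)
}

#' Water activity from the molal modDH model (closed form)
#'
#' Constant-pressure Gibbs-Duhem integration of the molal modDH chemical
#' potential gives
#' ln a_w(m) = -nu M_w [ m - (A~/B~^3)((1+B~ sqrt(m)) - 2 ln(1+B~ sqrt(m)) -
#' 1/(1+B~ sqrt(m))) + sum_i alpha~_i (i/(i+1)) m^(i+1) ],
#' with M_w in kg/mol. Ideal parameters recover a_w = exp(-nu M_w m).
#'
#' @param m Molality, mol/kg (vectorised, >= 0).
#' @param params A [moddh_molal()].
#' @param salt A [salt_spec()].
#' @param solvent A [solvent_spec()].
#' @return ln a_w (dimensionless, <= 0).
#' @export
ln_water_activity <- function(m, params, salt, solvent) {
  stopifnot(inherits(params, "moddh_molal"), inherits(salt, "salt_spec"),
            inherits(solvent, "solvent_spec"))
  if (any(m < 0)) stop_domain("molality must be non-negative")
  -salt$nu * (solvent$molar_mass_w / 1000) * gibbs_duhem_integral(m, params)
}

#' Water activity by adaptive quadrature (oracle for the closed form)
#'
#' Integrates d ln a_w = -nu M_w m dln(m gamma~) numerically.
#'
#' @inheritParams ln_water_activity
#' @param rel_tol Relative tolerance for [stats::integrate()].
#' @return ln a_w.
#' @export
ln_water_activity_quadrature <- function(m, params, salt, solvent,
                                         rel_tol = 1e-10) {
  stopifnot(inherits(params, "moddh_molal"))
  if (any(m < 0)) stop_domain("molality must be non-negative")
  pref <- -salt$nu * (solvent$molar_mass_w / 1000)
  f <- function(x) 1 + x_dln_gamma_dx(x, params)
  vapply(m, function(mi) {
    if (mi == 0) return(0)
    q <- stats::integrate(f, 0, mi, rel.tol = rel_tol, abs.tol = 0,
                          subdivisions = 500L)
    if (q$message != "OK")
      stop("quadrature failed: ", q$message, call. = FALSE)
    pref * q$value
  }, numeric(1))
}

#' Osmotic pressure along the constant-pressure (molal) route
#'
#' Assuming an incompressible solution, Pi = -R T ln a_w / Vbar_w, where
#' Vbar_w is the partial molar volume of water. Using the pure-water molar
#' volume for Vbar_w is accurate to a few percent over the molality ranges
#' of interest (see [partial_molar_volume_water()]).
#'
#' @inheritParams ln_water_activity
#' @param Vbar_w Partial molar volume of water, cm^3/mol; either a single
#'   number or a vector matching \code{m}.
#' @return Osmotic pressure in bar.
#' @export
osmotic_pressure_molal <- function(m, params, salt, solvent,
                                   Vbar_w = solvent$molar_mass_w /
                                     solvent$rho_w0) {
  if (any(Vbar_w <= 0)) stop_domain("Vbar_w must be positive (cm^3/mol)")
  lnaw <- ln_water_activity(m, params, salt, solvent)
  -RT_kJ(solvent$temperature) * lnaw / Vbar_w * osmo_constants$kJcm3_to_bar
}

#' Osmotic coefficient phi(m)
#'
#' phi = -ln a_w / (nu M_w m); tends to 1 as m tends to 0 for any parameter
#' set (ideal-solution limit).
#'
#' @inheritParams ln_water_activity
#' @return phi (dimensionless); 1 at m = 0 by continuity.
#' @export
osmotic_coefficient <- function(m, params, salt, solvent) {
  lnaw <- ln_water_activity(m, params, salt, solvent)
  denom <- salt$nu * (solvent$molar_mass_w / 1000) * m
  ifelse(m > 0, -lnaw / denom, 1)
}

#' Convert molarity to molality
#'
#' m = C / (rho - C M_s / 1000) with rho the solution density in g/cm^3 and
#' M_s the salt molar mass in g/mol.
#'
#' @param C Molarity, M.
#' @param rho Solution density, g/cm^3 (scalar or vector matching C).
#' @param salt A [salt_spec()].
#' @return Molality, mol/kg.
#' @export
molarity_to_molality <- function(C, rho, salt) {
  stopifnot(inherits(salt, "salt_spec"))
  wmass <- rho - C * salt$molar_mass_salt / 1000  # kg water per L solution
  if (any(wmass <= 0))
    stop_domain("non-physical density: no water mass left at this molarity")
  C / wmass
}

#' Convert molality to molarity
#'
#' Inverse of [molarity_to_molality()]. \code{rho} may be a number (density
#' at that molality) or a [density_fit()] evaluated at \code{m}.
#'
#' @param m Molality, mol/kg.
#' @param rho Solution density, g/cm^3, or a [density_fit()].
#' @param salt A [salt_spec()].
#' @return Molarity, M.
#' @export
molality_to_molarity <- function(m, rho, salt) {
  stopifnot(inherits(salt, "salt_spec"))
  if (inherits(rho, "density_fit")) rho <- predict_density(rho, m)
  m * rho / (1 + m * salt$molar_mass_salt / 1000)
}
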