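# Solution densities: the molality polynomial rho(m) = rho_w0 + theta_1 m +
# theta_3/2 m^(3/2) + theta_2 m^2 fitted along lines of constant mu_w or
# constant P, the compressibility correction between the two ensembles, and
# the partial molar volume of water derived from the fit.

DENSITY_POWERS <- c(1, 1.5, 2)

#' Solution-density fit rho(m)
#'
#' @param rho_w0 Pure-water density intercept, g/cm^3.
#' @param thetas Coefficients for the powers m, m^(3/2), m^2 (length 3),
#'   units g/(cm^3 molal^p).
#' @param ensemble \code{"constant-mu_w"} (force-balance conditions) or
#'   \code{"constant-P"} (atmospheric pressure).
#' @return An object of class \code{density_fit}.
#' @export
density_fit <- function(rho_w0, thetas,
                        ensemble = c("constant-mu_w", "constant-P")) {
  ensemble <- match.arg(ensemble)
  if (rho_w0 <= 0) stop_domain("rho_w0 must be positive")
  if (length(thetas) != 3L)
    stop_domain("thetas must supply exactly the powers {1, 3/2, 2}")
  structure(list(rho_w0 = as.numeric(rho_w0), thetas = as.numeric(thetas),
                 powers = DENSITY_POWERS, ensemble = ensemble),
            class = "density_fit")
}

#' @export
print.density_fit <- function(x, ...) {
  cat(sprintf(
    "Density fit (%s): rho_w0 = %.5f; theta = (%s) g/(cm^3 molal^p), p = 1, 3/2, 2\n",
    x$ensemble, x$rho_w0, paste(signif(x$thetas, 5), collapse = ", ")))
  invisible(x)
}

#' Evaluate a density fit
#'
#' @param fit A [density_fit()].
#' @param m Molality, mol/kg (vectorised).
#' @return Density in g/cm^3.
#' @export
predict_density <- function(fit, m) {
  stopifnot(inherits(fit, "density_fit"))
  out <- rep(fit$rho_w0, length(m))
  for (j in seq_along(fit$powers))
    out <- out + fit$thetas[j] * m^fit$powers[j]
  out
}

# derivative d rho / d m
density_slope <- function(fit, m) {
  out <- rep(0, length(m))
  for (j in seq_along(fit$powers))
    out <- out + fit$thetas[j] * fit$powers[j] * m^(fit$powers[j] - 1)
  out
}

# molality at a given molarity under a density fit (scalar/vector C)
molality_from_molarity_fit <- function(C, fit, salt) {
  vapply(C, function(ci) {
    if (ci == 0) return(0)
    stats::uniroot(function(m) molality_to_molarity(m, fit, salt) - ci,
                   c(1e-12, 100), tol = 1e-12)$root
  }, numeric(1))
}

#' Fit the density polynomial to (m, rho) samples
#'
#' Linear least squares for rho_w0 and the theta coefficients of
#' rho(m) = rho_w0 + theta_1 m + theta_3/2 m^(3/2) + theta_2 m^2.
#'
#' @param m Molalities, mol/kg (>= 4 samples).
#' @param rho Densities, g/cm^3.
#' @param ensemble Ensemble tag for the returned [density_fit()].
#' @return List with \code{fit} ([density_fit()]) and \code{residuals}.
#' @export
fit_density <- function(m, rho, ensemble = c("constant-mu_w", "constant-P")) {
  ensemble <- match.arg(ensemble)
  if (length(m) != length(rho)) stop_domain("m and rho lengths differ")
  if (length(m) < 4L) stop_domain("need at least 4 density samples")
  X <- cbind(1, m, m^1.5, m^2)
  if (qr(X)$rank < 4L) stop_domain("degenerate molality design")
  beta <- qr.solve(X, rho)
  fit <- density_fit(beta[1], beta[2:4], ensemble = ensemble)
  list(fit = fit, residuals = rho - as.vector(X %*% beta))
}

#' Convert a constant-mu_w density fit to constant pressure
#'
#' Applies the first-order compressibility correction
#' rho(m|P) = rho(m|mu_w) (1 - kappa_eff Pi(m)) pointwise on a molality
#' grid and refits the polynomial. Constant-P densities are lower than
#' constant-mu_w densities wherever Pi > 0, reflecting the osmotic
#' compression present in the force-balance ensemble.
#'
#' @param fit_mu A [density_fit()] with ensemble \code{"constant-mu_w"}.
#' @param Pi_of_m Function mapping molality to osmotic pressure in bar
#'   (e.g. built from a fitted molal modDH model).
#' @param kappa_eff Effective solution compressibility, 1/bar.
#' @param m_grid Molality grid used for the refit.
#' @return A [density_fit()] with ensemble \code{"constant-P"}.
#' @export
density_to_constant_P <- function(fit_mu, Pi_of_m, kappa_eff,
                                  m_grid = seq(0, 4, by = 0.1)) {
  stopifnot(inherits(fit_mu, "density_fit"))
  if (kappa_eff < 0) stop_domain("kappa_eff must be non-negative")
  Pi <- Pi_of_m(m_grid)
  if (any(kappa_eff * Pi >= 1))
    stop_domain("kappa_eff * Pi >= 1: first-order compression invalid")
  rho_P <- predict_density(fit_mu, m_grid) * (1 - kappa_eff * Pi)
  fit_density(m_grid, rho_P, ensemble = "constant-P")$fit
}

#' Partial molar volume of water from a density fit
#'
#' With v(m) = (1000 + m M_s)/rho(m) the solution volume per kilogram of
#' water (cm^3), Vbar_w = M_w (v - m dv/dm) with M_w in kg/mol. At m = 0
#' this is the pure-water molar volume M_w/rho_w0. The companion salt
#' volume Vbar_s = dv/dm satisfies the Euler relation
#' n_w Vbar_w + m Vbar_s = v.
#'
#' @param fit A [density_fit()].
#' @param m Molality, mol/kg (vectorised).
#' @param solvent A [solvent_spec()].
#' @param salt A [salt_spec()].
#' @return Vbar_w in cm^3/mol.
#' @export
partial_molar_volume_water <- function(fit, m, solvent, salt) {
  stopifnot(inherits(fit, "density_fit"), inherits(salt, "salt_spec"))
  rho <- predict_density(fit, m)
  if (any(rho <= 0)) stop_domain("density fit non-positive at requested m")
  Ms <- salt$molar_mass_salt
  drho <- density_slope(fit, m)
  v <- (1000 + m * Ms) / rho
  dv <- (Ms * rho - (1000 + m * Ms) * drho) / rho^2
  (solvent$molar_mass_w / 1000) * (v - m * dv)
}

#' Partial molar volume of the salt from a density fit
#'
#' Vbar_s = dv/dm with v(m) the solution volume per kilogram of water.
#'
#' @inheritParams partial_molar_volume_water
#' @return Vbar_s in cm^3/mol.
#' @export
partial_molar_volume_salt <- function(fit, m, solvent, salt) {
  rho <- predict_density(fit, m)
  Ms <- salt$molar_mass_salt
  drho <- density_slope(fit, m)
  (Ms * rho - (1000 + m * Ms) * drho) / rho^2
}
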