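# Accessors for the bundled alkali-halide parameter tables (plain CSV under
# inst/extdata): Joung-Cheatham cation-anion LJ cross interactions with
# optimized chi, modDH fit coefficients, and solution-density fit
# coefficients for TIP4P/2005 water at 25 C.

extdata_path <- function(file)
  system.file("extdata", file, package = "osmobalance", mustWork = TRUE)

#' Bundled Lennard-Jones cross-interaction table
#'
#' Lorentz-Berthelot sigma/eps for the 15 alkali halide cation-anion pairs
#' (Joung-Cheatham ion parameters), the optimized chi for each salt, and
#' the resulting effective sigma/eps. Units: Angstrom and K.
#'
#' @return Data.frame with columns salt, sigma_A, eps_K, chi, sigma_opt_A,
#'   eps_opt_K.
#' @export
alkali_halide_lj <- function()
  utils::read.csv(extdata_path("alkali_halide_lj.csv"),
                  stringsAsFactors = FALSE)

#' Bundled modDH coefficients (molar basis, optimized interactions)
#'
#' Constant-mu_w modDH fit coefficients for eight alkali halides in
#' TIP4P/2005 water at 25 C (A fixed at 1.7964 M^-1/2). Units: A and B in
#' M^-1/2, alpha1 in M^-1, alpha2 in M^-2.
#'
#' @return Data.frame with columns salt, A, B, alpha1, alpha2.
#' @export
moddh_molar_fits <- function()
  utils::read.csv(extdata_path("moddh_molar_fits.csv"),
                  stringsAsFactors = FALSE)

#' Bundled solution-density fit coefficients
#'
#' rho(m) polynomial coefficients along constant mu_w and constant P for
#' eight alkali halides. Units: rho_w0 g/cm^3, theta_p g/(cm^3 molal^p).
#'
#' @return Data.frame with columns salt, rho_w0, theta1_mu, theta32_mu,
#'   theta2_mu, theta1_P, theta32_P, theta2_P.
#' @export
density_fit_table <- function()
  utils::read.csv(extdata_path("density_fits.csv"),
                  stringsAsFactors = FALSE)

#' Salt specification for a named alkali halide
#'
#' Builds a [salt_spec()] (1:1, monovalent) with the tabulated molar mass.
#'
#' @param name One of the 15 alkali halides, e.g. \code{"NaBr"}.
#' @return A [salt_spec()].
#' @export
alkali_halide_salt <- function(name) {
  tab <- utils::read.csv(extdata_path("salt_masses.csv"),
                         stringsAsFactors = FALSE)
  i <- match(name, tab$salt)
  if (is.na(i)) stop_domain("unknown salt: ", name)
  salt_spec(name, 1L, 1L, 1L, -1L, tab$molar_mass[i])
}

#' Density fit for a tabulated salt
#'
#' @param name Salt name present in [density_fit_table()].
#' @param ensemble \code{"constant-mu_w"} or \code{"constant-P"}.
#' @return A [density_fit()].
#' @export
tabulated_density_fit <- function(name,
                                  ensemble = c("constant-mu_w",
                                               "constant-P")) {
  ensemble <- match.arg(ensemble)
  tab <- density_fit_table()
  i <- match(name, tab$salt)
  if (is.na(i)) stop_domain("no density fit tabulated for ", name)
  if (ensemble == "constant-mu_w")
    density_fit(tab$rho_w0[i], c(tab$theta1_mu[i], tab$theta32_mu[i],
                                 tab$theta2_mu[i]), ensemble)
  else
    density_fit(tab$rho_w0[i], c(tab$theta1_P[i], tab$theta32_P[i],
                                 tab$theta2_P[i]), ensemble)
}

#' modDH molar parameters for a tabulated salt
#'
#' @param name Salt name present in [moddh_molar_fits()].
#' @return A [moddh_molar()].
#' @export
tabulated_moddh <- function(name) {
  tab <- moddh_molar_fits()
  i <- match(name, tab$salt)
  if (is.na(i)) stop_domain("no modDH fit tabulated for ", name)
  moddh_molar(tab$A[i], tab$B[i], c(tab$alpha1[i], tab$alpha2[i]))
}
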