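# Lennard-Jones cross-interaction utilities: Lorentz-Berthelot combining
# rules, the chi repulsion-scaling transform and its inverse, and the
# experimental-EOS mean-square objective used to select chi.

#' Lennard-Jones pair parameters
#'
#' Well-depth is stored in Kelvin (thermal units); [epsilon_K_to_kJ()]
#' converts to kJ/mol.
#'
#' @param sigma Diameter, Angstrom (> 0).
#' @param epsilon Well-depth, K (> 0).
#' @param chi Repulsion-scaling parameter (> -1); 0 means unmodified.
#' @return An object of class \code{lj_pair}.
#' @export
lj_pair <- function(sigma, epsilon, chi = 0) {
  if (sigma <= 0) stop_domain("sigma must be positive")
  if (epsilon <= 0) stop_domain("epsilon must be positive")
  if (chi <= -1) stop_domain("chi must exceed -1")
  structure(list(sigma = as.numeric(sigma), epsilon = as.numeric(epsilon),
                 chi = as.numeric(chi)), class = "lj_pair")
}

#' @export
print.lj_pair <- function(x, ...) {
  cat(sprintf("LJ pair: sigma = %.4f A, eps = %.3f K, chi = %.2f\n",
              x$sigma, x$epsilon, x$chi))
  invisible(x)
}

#' Convert an LJ well-depth from K to kJ/mol
#'
#' Multiplies by the molar Boltzmann constant (the gas constant).
#'
#' @param epsilon_K Well-depth in K.
#' @return Well-depth in kJ/mol.
#' @export
epsilon_K_to_kJ <- function(epsilon_K) epsilon_K * osmo_constants$R_kJ

#' Lorentz-Berthelot combining rules
#'
#' sigma_+- = (sigma_+ + sigma_-)/2, eps_+- = sqrt(eps_+ eps_-).
#'
#' @param sigma_plus,epsilon_plus Cation LJ parameters (Angstrom, K).
#' @param sigma_minus,epsilon_minus Anion LJ parameters (Angstrom, K).
#' @return An [lj_pair()] with chi = 0.
#' @export
lorentz_berthelot <- function(sigma_plus, epsilon_plus,
                              sigma_minus, epsilon_minus) {
  if (any(c(sigma_plus, epsilon_plus, sigma_minus, epsilon_minus) <= 0))
    stop_domain("LJ parameters must be positive")
  lj_pair((sigma_plus + sigma_minus) / 2,
          sqrt(epsilon_plus * epsilon_minus), chi = 0)
}

#' Apply the chi repulsion-scaling transform
#'
#' Multiplying the repulsive r^-12 part of 4 eps [(sigma/r)^12 -
#' (sigma/r)^6] by (1 + chi) while leaving the attractive part unchanged
#' yields another Lennard-Jones potential with
#' sigma' = sigma (1+chi)^(1/6) and eps' = eps/(1+chi), identically in r.
#'
#' @param pair An [lj_pair()] (its stored chi is ignored).
#' @param chi Scaling parameter, > -1.
#' @return An [lj_pair()] with the effective (sigma', eps') and the applied
#'   chi recorded.
#' @examples
#' apply_chi(lj_pair(3.1787, 17.524), 0.75)  # LiCl: (3.4895, 10.014)
#' @export
apply_chi <- function(pair, chi) {
  stopifnot(inherits(pair, "lj_pair"))
  if (chi <= -1) stop_domain("chi must exceed -1")
  lj_pair(pair$sigma * (1 + chi)^(1 / 6), pair$epsilon / (1 + chi),
          chi = chi)
}

#' Infer chi from a base and an optimized pair
#'
#' Inverse of [apply_chi()]: chi = (sigma'/sigma)^6 - 1, cross-checked
#' against the well-depth ratio eps/eps' = 1 + chi.
#'
#' @param base The unscaled [lj_pair()] (Lorentz-Berthelot values).
#' @param optimized The rescaled [lj_pair()].
#' @param tol Relative tolerance for the well-depth consistency check.
#' @return chi, with attribute \code{consistent} (logical).
#' @export
infer_chi <- function(base, optimized, tol = 5e-3) {
  stopifnot(inherits(base, "lj_pair"), inherits(optimized, "lj_pair"))
  chi <- (optimized$sigma / base$sigma)^6 - 1
  eps_ratio <- base$epsilon / optimized$epsilon
  consistent <- abs(eps_ratio - (1 + chi)) <= tol * abs(1 + chi)
  if (!consistent)
    warning(sprintf(
      "sigma ratio implies chi = %.4f but eps ratio implies %.4f",
      chi, eps_ratio - 1), call. = FALSE)
  structure(chi, consistent = consistent)
}

#' Evaluate the LJ pair potential
#'
#' u(r) = 4 eps [(1+chi)(sigma/r)^12 - (sigma/r)^6] with the stored chi.
#'
#' @param pair An [lj_pair()].
#' @param r Separation, Angstrom (vectorised, > 0).
#' @param chi Scaling applied on top of the stored sigma/eps (default: the
#'   pair's own chi).
#' @return Potential energy in K.
#' @export
lj_potential <- function(pair, r, chi = pair$chi) {
  if (any(r <= 0)) stop_domain("r must be positive")
  sr6 <- (pair$sigma / r)^6
  4 * pair$epsilon * ((1 + chi) * sr6^2 - sr6)
}

#' Mean squared difference between two osmotic equations of state
#'
#' Interpolates both Pi(C) sample sets onto a common concentration grid and
#' returns the mean of squared differences — the objective minimised when
#' selecting chi against an experimental reference.
#'
#' @param candidate Data.frame/list with \code{C} (M) and \code{Pi} (bar).
#' @param reference Same layout.
#' @param grid Concentrations at which to compare, M; must lie within both
#'   sample ranges.
#' @return Mean squared difference, bar^2.
#' @export
eos_mse <- function(candidate, reference, grid) {
  for (s in list(candidate, reference))
    if (is.null(s$C) || is.null(s$Pi)) stop_domain("need C and Pi columns")
  rng <- range(grid)
  if (rng[1] < min(candidate$C) || rng[2] > max(candidate$C) ||
      rng[1] < min(reference$C) || rng[2] > max(reference$C))
    stop_domain("grid extends beyond the sampled concentration range")
  pc <- stats::approx(candidate$C, candidate$Pi, xout = grid)$y
  pr <- stats::approx(reference$C, reference$Pi, xout = grid)$y
  mean((pc - pr)^2)
}

#' Pick the best chi from precomputed (chi, EOS) evaluations
#'
#' The osmotic pressure curve for each candidate chi comes from a separate
#' simulation, so this helper simply scores user-supplied curves against
#' the reference with [eos_mse()] and returns the minimiser (with a
#' parabolic refinement through the three lowest points when possible).
#'
#' @param chi_values Numeric vector of candidate chi.
#' @param eos_list List of Pi(C) sample sets (one per chi), each with
#'   \code{C} and \code{Pi}.
#' @param reference Reference EOS samples (\code{C}, \code{Pi}).
#' @param grid Comparison grid, M.
#' @return List with \code{chi_best}, \code{mse} (per candidate) and
#'   \code{chi_refined} (parabolic estimate, NA at the bracket edge).
#' @export
select_chi <- function(chi_values, eos_list, reference, grid) {
  if (length(chi_values) != length(eos_list))
    stop_domain("chi_values and eos_list lengths differ")
  mse <- vapply(eos_list, eos_mse, numeric(1), reference = reference,
                grid = grid)
  i <- which.min(mse)
  refined <- NA_real_
  if (i > 1 && i < length(mse)) {
    x <- chi_values[(i - 1):(i + 1)]; y <- mse[(i - 1):(i + 1)]
    d <- (x[3] - x[2]) * (y[1] - y[2]) - (x[1] - x[2]) * (y[3] - y[2])
    if (d != 0)
      refined <- x[2] + 0.5 * ((x[3] - x[2])^2 * (y[1] - y[2]) -
                                 (x[1] - x[2])^2 * (y[3] - y[2])) / d
  }
  list(chi_best = chi_values[i], mse = stats::setNames(mse, chi_values),
       chi_refined = refined)
}
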