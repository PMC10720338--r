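# The staged fitting procedure: profile least squares for the alpha_i under
# the mass-balance constraint (A fixed from Debye-Huckel theory), molal-side
# linear least squares of the constant-P pressure expression to
# force-balance pressures, and an outer scalar calibration of B that makes
# the two pressure routes agree.

#' Fit the molar modDH model to a concentration profile
#'
#' Least-squares fit of the model-predicted profile to the observed C(z)
#' over bins with C >= \code{floor}. A is held fixed (from Debye-Huckel
#' theory), B is held at the supplied value (see [calibrate_B()] for its
#' outer optimisation), and at every optimiser step C_max is eliminated via
#' the mass-balance constraint so that the fit always carries the correct
#' number of ions.
#'
#' @param profile A symmetrized [concentration_profile()]; its box,
#'   restraint and N_s are used.
#' @param A Fixed Debye-Huckel coefficient, M^-1/2.
#' @param solvent A [solvent_spec()].
#' @param B Value of B used during this fit, M^-1/2 (default 1.5, the
#'   standard starting value).
#' @param i_max Order of the polynomial correction (default 2).
#' @param floor Concentration floor in M (default 0.01); bins below it are
#'   excluded from the residuals.
#' @param weights \code{"uniform"} (default) or \code{"poisson"}
#'   (residuals scaled by 1/sqrt(C), approximating counting statistics).
#' @param alphas_init Optional starting values for the alpha_i.
#' @return List with \code{params} ([moddh_molar()]), \code{C_max},
#'   \code{N_s}, \code{residual_norm}, \code{n_bins_used}, \code{floor} and
#'   the \code{nls.lm} convergence info.
#' @export
fit_concentration_profile <- function(profile, A, solvent, B = 1.5,
                                      i_max = 2L, floor = 0.01,
                                      weights = c("uniform", "poisson"),
                                      alphas_init = NULL) {
  stopifnot(inherits(profile, "concentration_profile"),
            inherits(solvent, "solvent_spec"))
  weights <- match.arg(weights)
  if (is.null(profile$N_s))
    stop_domain("profile must carry N_s for the mass-balance constraint")
  z <- profile$bin_centers
  obs <- profile$C_s
  keep <- obs >= floor
  if (sum(keep) <= i_max)
    stop_domain("too few bins above the concentration floor to fit")
  # gross-mismatch guard: profile integral vs N_s
  conv <- osmo_constants$N_A * 1e-27
  n_obs <- sum(obs) * profile$bin_width * profile$box$Lx * profile$box$Ly *
    conv
  if (abs(n_obs / profile$N_s - 1) > 0.2)
    stop_domain(sprintf(
      "profile integrates to %.3g formula units but N_s = %g (>20%% off)",
      n_obs, profile$N_s))
  w <- if (weights == "poisson") 1 / sqrt(pmax(obs[keep], floor)) else
    rep(1, sum(keep))
  if (is.null(alphas_init)) alphas_init <- rep(0, i_max)

  resid_fun <- function(alphas) {
    # infeasible trial parameters get a large penalty so the optimiser
    # retreats instead of aborting
    tryCatch({
      par <- moddh_molar(A, B, alphas)
      cmax <- cmax_from_mass_balance(par, profile$restraint, profile$box,
                                     profile$N_s, solvent)
      pred <- predicted_profile(par, cmax, profile$restraint, profile$box,
                                solvent, grid = z)
      w * (pred$C_s[keep] - obs[keep])
    }, error = function(e) w * (10 + obs[keep]))
  }
  fit <- minpack.lm::nls.lm(
    par = alphas_init, fn = resid_fun,
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 200))
  if (fit$info == 0 || fit$info == 9)
    stop_domain("profile fit failed to converge: ", fit$message)
  params <- moddh_molar(A, B, fit$par)
  cmax <- cmax_from_mass_balance(params, profile$restraint, profile$box,
                                 profile$N_s, solvent)
  list(params = params, C_max = cmax, N_s = profile$N_s,
       residual_norm = sqrt(sum(fit$fvec^2)), n_bins_used = sum(keep),
       floor = floor, info = fit$info, message = fit$message)
}

#' Fit the molal polynomial coefficients to osmotic-pressure samples
#'
#' The constant-P pressure Pi(m) = -RT ln a_w(m)/Vbar_w is linear in the
#' alpha~_i, so given A~ and B~ the coefficients follow from linear least
#' squares against supplied (m, Pi) samples — typically the force-balance
#' pressures obtained by direct integration of a simulated profile.
#'
#' @param m Molalities of the samples, mol/kg.
#' @param Pi_bar Osmotic pressures at those molalities, bar.
#' @param A_tilde,B_tilde Fixed molal coefficients, molal^-1/2.
#' @param salt A [salt_spec()].
#' @param solvent A [solvent_spec()].
#' @param i_max Polynomial order (default 2).
#' @param Vbar_w Partial molar volume of water, cm^3/mol; scalar or vector
#'   along \code{m} (default: pure-water molar volume).
#' @return List with \code{params} ([moddh_molal()]) and \code{residuals}
#'   (bar).
#' @export
fit_molal_eos <- function(m, Pi_bar, A_tilde, B_tilde, salt, solvent,
                          i_max = 2L,
                          Vbar_w = solvent$molar_mass_w / solvent$rho_w0) {
  if (length(m) != length(Pi_bar)) stop_domain("m and Pi_bar lengths differ")
  if (length(m) < i_max + 1L)
    stop_domain("need at least i_max + 1 pressure samples")
  base <- moddh_molal(A_tilde, B_tilde)
  pref <- salt$nu * (solvent$molar_mass_w / 1000) *
    RT_kJ(solvent$temperature) * osmo_constants$kJcm3_to_bar / Vbar_w
  # Pi = pref * [ m - DH(m) + sum_i a_i (i/(i+1)) m^(i+1) ]
  offset <- pref * gibbs_duhem_integral(m, base)
  X <- sapply(seq_len(i_max), function(i) pref * (i / (i + 1)) * m^(i + 1))
  X <- matrix(X, ncol = i_max)
  if (qr(X)$rank < i_max)
    stop_domain("rank-deficient design: samples do not span the polynomial")
  beta <- qr.solve(X, Pi_bar - offset)
  params <- moddh_molal(A_tilde, B_tilde, beta)
  list(params = params,
       residuals = Pi_bar - (offset + as.vector(X %*% beta)))
}

#' Calibrate B by cross-route pressure agreement
#'
#' Outer scalar optimisation of the shared Debye-Huckel denominator
#' coefficient: for each candidate B, (i) the alpha_i are refitted to the
#' profile with [fit_concentration_profile()], (ii) the force-balance
#' pressures Pi(z) are computed from the observed profile and converted to
#' molalities, (iii) the alpha~_i are refitted with [fit_molal_eos()]
#' (A~, B~ from the dilute-limit relation), and (iv) the objective is the
#' mean squared difference between the constant-mu_w closed-form pressure
#' and the constant-P pressure over the sampled concentration range.
#'
#' @param profile A symmetrized [concentration_profile()] with N_s.
#' @param A Fixed Debye-Huckel coefficient, M^-1/2.
#' @param salt A [salt_spec()].
#' @param solvent A [solvent_spec()].
#' @param B_init Starting value (default 1.5 M^-1/2).
#' @param B_range Search bracket (default \code{c(0.3, 4)}).
#' @param i_max Polynomial order.
#' @param floor Concentration floor, M.
#' @param density Optional [density_fit()] used for the molarity-molality
#'   conversion; default uses the pure-water density.
#' @param tol Convergence tolerance on B (default 1e-3).
#' @return List with \code{B}, \code{objective} (bar^2), \code{molar} and
#'   \code{molal} fit results at the optimum, plus the evaluation
#'   \code{trace}.
#' @export
calibrate_B <- function(profile, A, salt, solvent, B_init = 1.5,
                        B_range = c(0.3, 4), i_max = 2L, floor = 0.01,
                        density = NULL, tol = 1e-3) {
  trace <- list()
  eval_B <- function(B) {
    molar <- fit_concentration_profile(profile, A, solvent, B = B,
                                       i_max = i_max, floor = floor)
    res <- route_comparison(profile, molar, salt, solvent, floor = floor,
                            density = density, i_max = i_max)
    trace[[length(trace) + 1L]] <<- c(B = B, objective = res$objective)
    list(molar = molar, molal = res$molal, objective = res$objective,
         grid_C = res$grid_C)
  }
  obj <- function(B) eval_B(B)$objective
  opt <- stats::optimize(obj, interval = B_range, tol = tol)
  best <- eval_B(opt$minimum)
  if (abs(best$objective - obj(B_init)) <
      1e-12 * max(best$objective, 1e-30)) {
    warning("flat B objective; returning B_init", call. = FALSE)
    best <- eval_B(B_init)
    opt$minimum <- B_init
  }
  list(B = opt$minimum, objective = best$objective, molar = best$molar,
       molal = best$molal, trace = do.call(rbind, trace))
}

# Shared inner step: direct pressures from the profile -> molal fit ->
# squared route difference on a concentration grid.
route_comparison <- function(profile, molar_fit, salt, solvent, floor = 0.01,
                             density = NULL, i_max = 2L) {
  direct <- osmotic_pressure_direct(profile, salt)
  keep <- direct$C >= floor & direct$z >= 0
  Cs <- direct$C[keep]; Pis <- direct$Pi[keep]
  to_molal <- function(C) {
    if (is.null(density)) molarity_to_molality(C, solvent$rho_w0, salt)
    else molality_from_molarity_fit(C, density, salt)
  }
  ms <- to_molal(Cs)
  tilde <- molar_to_molal_params(molar_fit$params, solvent)
  molal <- fit_molal_eos(ms, Pis, tilde$A, tilde$B, salt, solvent,
                         i_max = i_max)
  grid_C <- seq(floor, molar_fit$C_max, length.out = 60)
  grid_m <- to_molal(grid_C)
  p16 <- osmotic_pressure_molar(grid_C, molar_fit$params, salt, solvent)
  p21 <- osmotic_pressure_molal(grid_m, molal$params, salt, solvent)
  list(molal = molal, objective = mean((p16 - p21)^2), grid_C = grid_C)
}

#' Run the full staged fit on one profile
#'
#' Convenience wrapper: symmetrizes, audits electroneutrality when ion
#' profiles are present, calibrates B, and assembles a [fit_report()].
#'
#' @inheritParams calibrate_B
#' @param calibrate If \code{FALSE}, B is held at \code{B_init}.
#' @param seed Optional integer recorded in the report's provenance.
#' @return A [fit_report()].
#' @export
fit_osmotic_balance <- function(profile, A, salt, solvent, B_init = 1.5,
                                i_max = 2L, floor = 0.01, density = NULL,
                                calibrate = TRUE, seed = NULL) {
  profile <- symmetrize(profile)
  imbalance <- if (!is.null(profile$C_plus) && !is.null(profile$C_minus))
    check_electroneutrality(profile, salt, floor) else NA_real_
  if (calibrate) {
    cal <- calibrate_B(profile, A, salt, solvent, B_init = B_init,
                       i_max = i_max, floor = floor, density = density)
  } else {
    molar <- fit_concentration_profile(profile, A, solvent, B = B_init,
                                       i_max = i_max, floor = floor)
    res <- route_comparison(profile, molar, salt, solvent, floor = floor,
                            density = density, i_max = i_max)
    cal <- list(B = B_init, objective = res$objective, molar = molar,
                molal = res$molal, trace = NULL)
  }
  fit_report(molar = cal$molar$params, molal = cal$molal$params,
             C_max = cal$molar$C_max, salt = salt, solvent = solvent,
             residual_norm = cal$molar$residual_norm,
             route_mse = cal$objective, B_trace = cal$trace,
             floor = floor, electroneutrality = imbalance, seed = seed)
}

#' Container for a completed fit
#'
#' @param molar A [moddh_molar()].
#' @param molal A [moddh_molal()] (or NULL if not fitted).
#' @param C_max Peak concentration, M.
#' @param salt,solvent The specs used.
#' @param residual_norm Profile-fit residual norm, M.
#' @param route_mse Mean squared difference between the two pressure routes,
#'   bar^2.
#' @param B_trace Matrix of (B, objective) evaluations, or NULL.
#' @param floor Concentration floor used, M.
#' @param electroneutrality Max relative charge imbalance, or NA.
#' @param seed Optional seed recorded for provenance.
#' @param inputs Optional character vector of input file names.
#' @return An object of class \code{fit_report}.
#' @export
fit_report <- function(molar, molal, C_max, salt, solvent, residual_norm,
                       route_mse = NA_real_, B_trace = NULL, floor = 0.01,
                       electroneutrality = NA_real_, seed = NULL,
                       inputs = character(0)) {
  stopifnot(is.finite(residual_norm))
  structure(list(molar = molar, molal = molal, C_max = C_max, salt = salt,
                 solvent = solvent, residual_norm = residual_norm,
                 route_mse = route_mse, B_trace = B_trace, floor = floor,
                 electroneutrality = electroneutrality, seed = seed,
                 inputs = inputs,
                 tool_version = as.character(utils::packageVersion(
                   "osmobalance"))),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Osmotic force balance fit:", x$salt$name, "\n")
  print(x$molar)
  if (!is.null(x$molal)) print(x$molal)
  cat(sprintf("  C_max = %.4f M; residual norm = %.3g M; route MSE = %.3g bar^2\n",
              x$C_max, x$residual_norm, x$route_mse))
  if (is.finite(x$electroneutrality))
    cat(sprintf("  max charge imbalance (C >= %g M): %.3g\n", x$floor,
                x$electroneutrality))
  invisible(x)
}
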