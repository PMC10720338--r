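# z-binned concentration profiles from restrained simulations:
# construction, symmetrization, electroneutrality audit, direct force-balance
# pressure integration, model-predicted profiles, mass balance, and the
# box-consistency rescaling relations.

#' Binned salt concentration profile
#'
#' Holds C_s(z) on a uniform bin-center grid together with the box geometry,
#' restraint and ion count that produced it. Optionally carries separate
#' cation and anion profiles.
#'
#' @param bin_centers Bin centers along z, Angstrom; strictly increasing and
#'   uniformly spaced, with z = 0 at the box center.
#' @param C_s Salt concentration per bin, M (>= 0).
#' @param box A [box_spec()].
#' @param restraint A [restraint_spec()].
#' @param N_s Number of salt formula units in the box (optional).
#' @param C_plus,C_minus Optional per-species concentration profiles, M.
#' @return An object of class \code{concentration_profile}.
#' @export
concentration_profile <- function(bin_centers, C_s, box, restraint,
                                  N_s = NULL, C_plus = NULL, C_minus = NULL) {
  stopifnot(inherits(box, "box_spec"), inherits(restraint, "restraint_spec"))
  bin_centers <- as.numeric(bin_centers); C_s <- as.numeric(C_s)
  if (length(bin_centers) != length(C_s))
    stop_domain("bin_centers and C_s lengths differ")
  if (length(bin_centers) < 2) stop_domain("need at least two bins")
  dz <- diff(bin_centers)
  if (any(dz <= 0)) stop_domain("bin grid must be strictly increasing")
  if (max(abs(dz - dz[1])) > 1e-6 * dz[1])
    stop_domain("bin grid must be uniform")
  if (any(!is.finite(C_s)) || any(C_s < 0))
    stop_domain("concentrations must be finite and non-negative")
  for (side in list(C_plus, C_minus))
    if (!is.null(side) && length(side) != length(bin_centers))
      stop_domain("ion profile length does not match the grid")
  structure(list(bin_centers = bin_centers, C_s = C_s,
                 C_plus = if (is.null(C_plus)) NULL else as.numeric(C_plus),
                 C_minus = if (is.null(C_minus)) NULL else as.numeric(C_minus),
                 box = box, restraint = restraint,
                 N_s = if (is.null(N_s)) NULL else as.numeric(N_s),
                 bin_width = dz[1]),
            class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf(
    "Concentration profile: %d bins of %.3g A on [%.4g, %.4g] A; max C = %.4g M\n",
    length(x$bin_centers), x$bin_width, min(x$bin_centers),
    max(x$bin_centers), max(x$C_s)))
  cat(sprintf("  box %g x %g x %g A; k = %g kJ/(mol A^2) [%s]%s\n",
              x$box$Lx, x$box$Ly, x$box$Lz, x$restraint$k,
              x$restraint$convention,
              if (is.null(x$N_s)) "" else sprintf("; N_s = %g", x$N_s)))
  invisible(x)
}

# pair bins about z = 0; grid must map onto its mirror image
mirror_index <- function(z) {
  tol <- 1e-6 * max(abs(z), 1)
  idx <- vapply(z, function(zi) {
    j <- which(abs(z + zi) < tol)
    if (length(j) != 1L) NA_integer_ else j
  }, integer(1))
  if (any(is.na(idx)))
    stop_domain("grid is not symmetric about z = 0; cannot pair bins")
  idx
}

#' Symmetrize a profile about z = 0
#'
#' Averages C(z) with C(-z) bin by bin, the standard variance-reduction step
#' before fitting; idempotent. Applied to the salt profile and to any ion
#' profiles present.
#'
#' @param profile A [concentration_profile()].
#' @return The symmetrized [concentration_profile()].
#' @export
symmetrize <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  idx <- mirror_index(profile$bin_centers)
  sym <- function(v) if (is.null(v)) NULL else (v + v[idx]) / 2
  profile$C_s <- sym(profile$C_s)
  profile$C_plus <- sym(profile$C_plus)
  profile$C_minus <- sym(profile$C_minus)
  profile
}

#' Audit local electroneutrality of ion profiles
#'
#' Computes the maximum relative charge imbalance
#' |z+ C+ + z- C-| / (|z+| C+ + |z-| C-) over bins where the salt
#' concentration is at least \code{floor}. Sub-floor bins are excluded
#' because counting statistics there are too poor for the test to be
#' meaningful (the default 10 mM floor is an order of magnitude above where
#' sampling-induced imbalance appears).
#'
#' @param profile A [concentration_profile()] carrying \code{C_plus} and
#'   \code{C_minus}.
#' @param salt A [salt_spec()].
#' @param floor Concentration floor in M; default 0.01.
#' @return Maximum relative charge imbalance (0 = perfectly electroneutral).
#' @export
check_electroneutrality <- function(profile, salt, floor = 0.01) {
  stopifnot(inherits(profile, "concentration_profile"),
            inherits(salt, "salt_spec"))
  if (is.null(profile$C_plus) || is.null(profile$C_minus))
    stop_domain("profile lacks per-species ion profiles")
  cp <- profile$C_plus; cm <- profile$C_minus
  keep <- profile$C_s >= floor
  if (!any(keep)) return(0)
  num <- abs(salt$z_plus * cp[keep] + salt$z_minus * cm[keep])
  den <- abs(salt$z_plus) * cp[keep] + abs(salt$z_minus) * cm[keep]
  ratio <- ifelse(den > 0, num / den, 0)
  max(ratio)
}

#' Osmotic pressure profile by direct force-balance integration
#'
#' At equilibrium the restraint force on the solutes is balanced by the
#' osmotic pressure gradient, so
#' Pi(z) = nu int_z^{Lz/2} C_s(z') dU/dz' dz' (and symmetrically for z < 0),
#' evaluated with the trapezoid rule on the bin grid; the tail beyond the
#' last bin is closed with C = 0.
#'
#' @param profile A symmetrized [concentration_profile()].
#' @param salt A [salt_spec()].
#' @return A data.frame with columns \code{z} (Angstrom), \code{C} (M) and
#'   \code{Pi} (bar).
#' @export
osmotic_pressure_direct <- function(profile, salt) {
  stopifnot(inherits(profile, "concentration_profile"),
            inherits(salt, "salt_spec"))
  z <- profile$bin_centers
  C <- profile$C_s
  # integrand C(z) dU/dz in M kJ/(mol A); odd in z for a symmetric profile
  g <- C * restraint_force_grad(profile$restraint, z)
  n <- length(z)
  # cumulative trapezoid of g from each z out to the top edge (tail C = 0)
  upper <- rev(cumsum(rev(c((g[-1] + g[-n]) / 2 * diff(z), 0))))
  pos <- z >= 0
  pi_z <- numeric(n)
  pi_z[pos] <- upper[pos]
  # for z < 0 integrate downward: Pi(z) = -nu int_{-Lz/2}^{z} C dU/dz' dz'
  lower <- cumsum(c(0, (g[-1] + g[-n]) / 2 * diff(z)))
  pi_z[!pos] <- -lower[!pos]
  data.frame(z = z, C = C,
             Pi = salt$nu * pi_z * osmo_constants$MkJ_to_bar)
}

# ln(C gamma(C)) for internal use
ln_activity_product <- function(C, params) log(C) + ln_gamma(C, params)

# Solve ln(C gamma(C)) = target for C in (0, C_hi] by vectorised bisection
# on ln C.  Requires d ln(C gamma)/dC > 0 (thermodynamic stability).
solve_concentration <- function(target, params, C_hi, iter = 80L) {
  lo <- rep(log(1e-15), length(target))
  hi <- rep(log(C_hi), length(target))
  f_hi <- ln_activity_product(C_hi, params)
  for (it in seq_len(iter)) {
    mid <- (lo + hi) / 2
    fm <- ln_activity_product(exp(mid), params)
    up <- fm < target
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  out <- exp((lo + hi) / 2)
  out[target >= f_hi] <- C_hi
  out
}

check_model_monotone <- function(params, C_max) {
  cgrid <- seq(1e-6, C_max, length.out = 400)
  if (any(dln_xgamma_dx(cgrid, params) <= 0))
    stop_domain("ln(C gamma) is non-monotone on (0, C_max]: ",
                "unphysical modDH parameters for profile prediction")
}

#' Model-predicted concentration profile under a harmonic restraint
#'
#' Solves the equilibrium condition
#' ln(C gamma(C)) = ln(C_max gamma(C_max)) - U(z)/RT
#' for C at each requested z (bracketed bisection on ln C). With gamma = 1
#' this reduces to the ideal Boltzmann Gaussian
#' C(z) = C_max exp(-U(z)/RT).
#'
#' @param params A [moddh_molar()].
#' @param C_max Concentration at the potential minimum (z = 0), M.
#' @param restraint A [restraint_spec()].
#' @param box A [box_spec()].
#' @param solvent A [solvent_spec()].
#' @param grid Bin centers, Angstrom. Default: uniform 0.5 A bins spanning
#'   the box.
#' @param N_s Optional ion-pair count stored on the returned profile.
#' @return A [concentration_profile()].
#' @export
predicted_profile <- function(params, C_max, restraint, box, solvent,
                              grid = NULL, N_s = NULL) {
  stopifnot(inherits(params, "moddh_molar"), inherits(box, "box_spec"),
            inherits(restraint, "restraint_spec"))
  if (C_max <= 0) stop_domain("C_max must be positive")
  check_model_monotone(params, C_max)
  if (is.null(grid)) {
    nb <- max(2L, floor(box$Lz / 0.5))
    edges <- seq(-box$Lz / 2, box$Lz / 2, length.out = nb + 1L)
    grid <- (edges[-1] + edges[-length(edges)]) / 2
  }
  C <- predict_concentration(params, C_max, restraint, solvent, grid)
  concentration_profile(grid, C, box, restraint, N_s = N_s)
}

#' Model concentration at arbitrary positions
#'
#' Same equilibrium solve as [predicted_profile()] but returns a bare
#' numeric vector and accepts any z values (no binning requirements).
#'
#' @inheritParams predicted_profile
#' @param z Positions, Angstrom.
#' @return Concentrations, M.
#' @export
predict_concentration <- function(params, C_max, restraint, solvent, z) {
  if (C_max <= 0) stop_domain("C_max must be positive")
  check_model_monotone(params, C_max)
  RT <- RT_kJ(solvent$temperature)
  target <- ln_activity_product(C_max, params) -
    restraint_energy(restraint, z) / RT
  solve_concentration(target, params, C_max)
}

#' Position at which the model profile reaches a given concentration
#'
#' Inverts the equilibrium condition analytically for a harmonic restraint:
#' z(C) = sqrt( (RT/pref k) ln[C_max gamma(C_max) / (C gamma(C))] ), with
#' pref = 1/2 for the half-k convention.
#'
#' @param C Concentration, M, in (0, C_max].
#' @param params A [moddh_molar()].
#' @param C_max Peak concentration, M.
#' @param restraint A [restraint_spec()].
#' @param solvent A [solvent_spec()].
#' @return z in Angstrom (non-negative branch).
#' @export
profile_position <- function(C, params, C_max, restraint, solvent) {
  if (any(C <= 0) || any(C > C_max))
    stop_domain("C must lie in (0, C_max]")
  RT <- RT_kJ(solvent$temperature)
  pref <- if (restraint$convention == "half-k") 0.5 else 1
  darg <- ln_activity_product(C_max, params) - ln_activity_product(C, params)
  sqrt(RT * pmax(darg, 0) / (pref * restraint$k))
}

# integral of C(z) dz over the half box [0, Lz/2] for the model profile,
# by change of variable to t = sqrt(s), C = C_max exp(-t^2) (removes the
# sqrt singularity at the peak); vectorised Simpson rule.
model_half_integral <- function(params, C_max, restraint, box, solvent,
                                n = 4001L) {
  RT <- RT_kJ(solvent$temperature)
  pref <- if (restraint$convention == "half-k") 0.5 else 1
  # z(C): s = ln(Cmax g(Cmax)) - ln(C g(C)); z = sqrt(RT s / (pref k))
  # parameterize C = C_max exp(-t^2)
  lam <- ln_activity_product(C_max, params)
  # choose t_max so that z(t_max) >= Lz/2 or C negligibly small
  t_hi <- sqrt(log(C_max / 1e-14))
  tt <- seq(0, t_hi, length.out = n)
  C <- C_max * exp(-tt^2)
  s <- lam - ln_activity_product(C, params)
  s[1] <- 0
  z <- sqrt(RT * pmax(s, 0) / (pref * restraint$k))
  # ds/dt = 2 t * (1 + C dlngamma/dC)|_C  (since dC/dt = -2 t C)
  dsdt <- 2 * tt * (1 + x_dln_gamma_dx(C, params))
  dzdt <- ifelse(z > 0, RT * dsdt / (pref * restraint$k) / (2 * z), NA)
  # limit at t = 0: z ~ t sqrt(RT c0 / (pref k)) with c0 = 1 + Cmax dlng
  c0 <- 1 + x_dln_gamma_dx(C_max, params)
  dzdt[1] <- sqrt(RT * c0 / (pref * restraint$k))
  integrand <- C * dzdt
  # truncate at the box edge: keep z <= Lz/2 (beyond it C ~ 0 contribution
  # is excluded; the model box integral must stop at the wall)
  zmax <- box$Lz / 2
  inside <- z <= zmax
  if (!all(inside)) {
    j <- which(!inside)[1]
    # linear sliver between z[j-1] and the wall
    frac <- (zmax - z[j - 1]) / (z[j] - z[j - 1])
    tt_w <- tt[j - 1] + frac * (tt[j] - tt[j - 1])
    keep <- seq_len(j - 1)
    tt2 <- c(tt[keep], tt_w)
    y2 <- c(integrand[keep],
            integrand[j - 1] + frac * (integrand[j] - integrand[j - 1]))
  } else {
    tt2 <- tt; y2 <- integrand
  }
  sum(diff(tt2) * (y2[-1] + y2[-length(y2)]) / 2)  # M * Angstrom
}

#' Peak concentration satisfying the mass-balance constraint
#'
#' Finds C_max such that the model profile integrates to the prescribed
#' number of salt formula units:
#' Lx Ly int_{-Lz/2}^{Lz/2} C(z; C_max) dz = N_s (with M to count/A^3
#' conversion via Avogadro's number). The integral is monotone in C_max, so
#' the root is unique.
#'
#' @param params A [moddh_molar()].
#' @param restraint A [restraint_spec()].
#' @param box A [box_spec()].
#' @param N_s Number of salt formula units.
#' @param solvent A [solvent_spec()].
#' @param C_cap Upper bound for the search, M; exceeded means the requested
#'   N_s is infeasible for this model and box.
#' @return C_max in M.
#' @export
cmax_from_mass_balance <- function(params, restraint, box, N_s, solvent,
                                   C_cap = 30) {
  if (N_s <= 0) stop_domain("N_s must be positive")
  # restrict the search to the model's thermodynamic stability range,
  # d ln(C gamma)/dC > 0
  cgrid <- exp(seq(log(1e-4), log(C_cap), length.out = 600))
  bad <- which(1 + x_dln_gamma_dx(cgrid, params) <= 0)
  if (length(bad)) {
    if (bad[1] == 1L)
      stop_domain("modDH parameters unstable at all concentrations")
    C_cap <- 0.999 * cgrid[bad[1] - 1L]
  }
  conv <- osmo_constants$N_A * 1e-27  # (mol/L) -> count per A^3
  count_of <- function(cmax)
    2 * box$Lx * box$Ly *
      model_half_integral(params, cmax, restraint, box, solvent) * conv
  f <- function(cmax) count_of(cmax) - N_s
  if (f(C_cap) < 0)
    stop_domain("requested N_s = ", N_s, " is unreachable below the ",
                "concentration cap of ", signif(C_cap, 4), " M")
  stats::uniroot(f, c(1e-8, C_cap), tol = 1e-12)$root
}

#' Number of formula units implied by a model profile
#'
#' Forward form of the mass balance: the box-integrated ion-pair count for a
#' given C_max.
#'
#' @inheritParams cmax_from_mass_balance
#' @param C_max Peak concentration, M.
#' @return Expected count of salt formula units.
#' @export
mass_balance_count <- function(params, C_max, restraint, box, solvent) {
  conv <- osmo_constants$N_A * 1e-27
  2 * box$Lx * box$Ly *
    model_half_integral(params, C_max, restraint, box, solvent) * conv
}

#' Spring constant for a thermodynamically consistent companion box
#'
#' Two force-balance runs with equal water and salt content are consistent
#' when their harmonic constants satisfy k2 = k1 (Lz1/Lz2)^2; their profiles
#' then collapse when plotted against the reduced coordinate 2 z / Lz.
#'
#' @param box1 Reference [box_spec()].
#' @param k1 Spring constant in box 1, kJ/(mol Angstrom^2).
#' @param box2 Target [box_spec()].
#' @return List with \code{k2} and a function \code{reduced(z, box)} mapping
#'   z to 2 z / Lz.
#' @export
consistency_rescale <- function(box1, k1, box2) {
  stopifnot(inherits(box1, "box_spec"), inherits(box2, "box_spec"))
  list(k2 = k1 * (box1$Lz / box2$Lz)^2,
       reduced = function(z, box) 2 * z / box$Lz)
}
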