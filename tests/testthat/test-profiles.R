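# Profile processing: symmetrization, electroneutrality, direct
# force-balance pressure, model prediction, mass balance and the
# box-consistency relations.

test_that("symmetrize averages mirror bins and is idempotent", {
  box <- box_spec(10, 10, 5)
  p <- concentration_profile(-2:2, c(1, 2, 3, 2, 5), box, std_restraint())
  s <- symmetrize(p)
  expect_equal(s$C_s, c(3, 2, 3, 2, 3))
  expect_equal(symmetrize(s)$C_s, s$C_s)
  # asymmetric grid cannot be paired
  bad <- concentration_profile(c(0, 1, 2, 3), c(1, 1, 1, 1),
                               box_spec(10, 10, 8), std_restraint())
  expect_error(symmetrize(bad), "not symmetric")
})

test_that("profile constructor validates grid and values", {
  box <- std_box(); r <- std_restraint()
  expect_error(concentration_profile(c(0, 1, 3), c(1, 1, 1), box, r),
               "uniform")
  expect_error(concentration_profile(c(1, 0, -1), c(1, 1, 1), box, r),
               "increasing")
  expect_error(concentration_profile(0:2, c(1, -1, 1), box, r),
               "non-negative")
})

test_that("electroneutrality audit masks sub-floor bins", {
  box <- box_spec(10, 10, 5)
  z <- -2:2
  base <- c(0.005, 1, 2, 1, 0.005)
  mk <- function(cp, cm) concentration_profile(z, (cp + cm) / 2, box,
                                               std_restraint(),
                                               C_plus = cp, C_minus = cm)
  expect_equal(check_electroneutrality(mk(base, base), std_salt()), 0)
  imb <- check_electroneutrality(mk(1.01 * base, base), std_salt())
  expect_equal(imb, 0.01 / 2.01, tolerance = 1e-6)
  # imbalance only below the floor is invisible
  cp <- base; cp[1] <- 0.009; cm <- base; cm[1] <- 0.001
  expect_equal(check_electroneutrality(mk(cp, cm), std_salt(),
                                       floor = 0.01), 0)
  expect_error(check_electroneutrality(
    concentration_profile(z, base, box, std_restraint()), std_salt()),
    "lacks")
})

test_that("direct force-balance pressure reproduces the ideal law", {
  s <- std_salt()
  zero <- gaussian_profile(C_max = 3.5)
  zero$C_s[] <- 0
  expect_true(all(osmotic_pressure_direct(zero, s)$Pi == 0))
  # exact Gaussian: Pi(z) = nu RT C(z) at every bin
  g <- gaussian_profile(C_max = 3.5, k = 0.025, bin = 0.25)
  dp <- osmotic_pressure_direct(g, s)
  ideal <- s$nu * RT_std() * g$C_s * 10
  # exclude bins where the truncated tail beyond the box dominates
  keep <- g$C_s > 0.05
  expect_true(all(abs(dp$Pi[keep] / ideal[keep] - 1) < 1e-3))
  # grid refinement changes Pi(0) by < 0.1%
  g2 <- gaussian_profile(C_max = 3.5, k = 0.025, bin = 0.125)
  p1 <- max(dp$Pi)
  p2 <- max(osmotic_pressure_direct(g2, s)$Pi)
  expect_lt(abs(p1 / p2 - 1), 1e-3)
})

test_that("predicted profile solves the equilibrium condition", {
  w <- std_solvent(); box <- std_box(); r <- std_restraint()
  # gamma = 1 gives the Boltzmann Gaussian
  ide <- moddh_molar(0, 1)
  pp <- predicted_profile(ide, 3.5, r, box, w)
  expect_equal(pp$C_s, 3.5 * exp(-0.5 * r$k * pp$bin_centers^2 / RT_std()),
               tolerance = 1e-9)
  # peak at z = 0
  p <- nabr_params()
  expect_equal(profile_position(3.2, p, 3.2, r, w), 0)
  # z(C) then numeric inversion recovers C
  C_test <- c(0.05, 0.5, 1.8, 3.1)
  z_test <- profile_position(C_test, p, 3.2, r, w)
  expect_equal(predict_concentration(p, 3.2, r, w, z_test), C_test,
               tolerance = 1e-10)
  # residual of the equilibrium condition is tiny at every bin
  pp3 <- predicted_profile(p, 3.5, r, box, w)
  lhs <- log(pp3$C_s) + ln_mean_activity_molar(pp3$C_s, p)
  rhs <- log(3.5) + ln_mean_activity_molar(3.5, p) -
    0.5 * r$k * pp3$bin_centers^2 / RT_std()
  keep <- pp3$C_s > 1e-12
  expect_true(all(abs(lhs - rhs)[keep] < 1e-9))
  # a destabilising alpha makes ln(C gamma) non-monotone -> model error
  expect_error(predicted_profile(moddh_molar(0, 1, c(-2)), 3, r, box, w),
               "non-monotone")
})

test_that("mass balance matches the analytic Gaussian normalization", {
  w <- std_solvent(); box <- std_box(); r <- std_restraint()
  ide <- moddh_molar(0, 1)
  # closed-form Gaussian integral (tails negligible at Lz = 100)
  ns_analytic <- box$Lx * box$Ly * 3.5 * sqrt(2 * pi * RT_std() / r$k) *
    6.02214076e23 * 1e-27
  expect_equal(mass_balance_count(ide, 3.5, r, box, w), ns_analytic,
               tolerance = 1e-5)
  # doubling the cross-section doubles the count at fixed C_max
  box2 <- box_spec(2 * box$Lx, box$Ly, box$Lz)
  expect_equal(mass_balance_count(ide, 3.5, r, box2, w),
               2 * mass_balance_count(ide, 3.5, r, box, w),
               tolerance = 1e-12)
  # solve-then-integrate round trip
  p <- nabr_params()
  cm <- cmax_from_mass_balance(p, r, box, 60, w)
  expect_equal(mass_balance_count(p, cm, r, box, w), 60, tolerance = 1e-8)
  expect_error(cmax_from_mass_balance(p, r, box, 1e6, w), "unreachable")
})

test_that("box-consistency rescaling follows the (Lz1/Lz2)^2 law", {
  b100 <- box_spec(30, 30, 100)
  b50 <- box_spec(30, 30, 50)
  b28 <- box_spec(28.23, 28.23, 28.23)
  expect_equal(consistency_rescale(b100, 0.025, b50)$k2, 0.1)
  expect_equal(consistency_rescale(b100, 0.0225, b28)$k2, 0.2823,
               tolerance = 2e-4)
  expect_equal(consistency_rescale(b100, 0.025, b100)$k2, 0.025)
})

test_that("consistency-related boxes collapse on the reduced coordinate", {
  w <- std_solvent(); p <- nabr_params()
  b1 <- box_spec(30, 30, 100); k1 <- 0.025
  b2 <- box_spec(30, 30, 50)
  k2 <- consistency_rescale(b1, k1, b2)$k2
  u <- seq(0, 0.9, by = 0.05)           # reduced coordinate 2 z / Lz
  pp1 <- predicted_profile(p, 3.5, restraint_spec(k1), b1, w,
                           grid = u * b1$Lz / 2)
  pp2 <- predicted_profile(p, 3.5, restraint_spec(k2), b2, w,
                           grid = u * b2$Lz / 2)
  expect_equal(pp1$C_s, pp2$C_s, tolerance = 1e-10)
})
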