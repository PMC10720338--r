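# The staged fitting procedure and the density/partial-molar-volume layer.

test_that("noiseless profiles return the generating parameters exactly", {
  w <- std_solvent()
  prof <- generate_profile(generator_config(n_frames = Inf))
  truth <- attr(prof, "truth")
  fit <- fit_concentration_profile(prof, A = 1.7964, w, B = 1.3145)
  expect_equal(fit$params$alphas, c(0.17100, 0.022058), tolerance = 1e-6)
  expect_equal(fit$C_max, truth$C_max, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-8)
})

test_that("ideal Gaussian input with A = 0 yields near-zero alphas", {
  w <- std_solvent()
  cfg <- generator_config(params = moddh_molar(0, 1.5), n_frames = Inf)
  prof <- generate_profile(cfg)
  fit <- fit_concentration_profile(prof, A = 0, w, B = 1.5)
  expect_true(all(abs(fit$params$alphas) < 1e-8))
})

test_that("profile/N_s gross mismatch is rejected", {
  w <- std_solvent()
  prof <- generate_profile(generator_config(n_frames = Inf))
  prof$N_s <- prof$N_s * 2
  expect_error(fit_concentration_profile(prof, 1.7964, w), "20%")
})

test_that("molal EOS fit is an exact linear round trip", {
  s <- std_salt(); w <- std_solvent()
  truth <- moddh_molal(1.79, 1.31, c(0.21, 0.013))
  m <- seq(0.2, 4, length.out = 12)
  Pi <- osmotic_pressure_molal(m, truth, s, w)
  fit <- fit_molal_eos(m, Pi, truth$A, truth$B, s, w)
  expect_equal(fit$params$alphas, truth$alphas, tolerance = 1e-10)
  # ideal samples with zero DH part give zero alphas
  ide <- moddh_molal(0, 1)
  Pi0 <- osmotic_pressure_molal(m, ide, s, w)
  fit0 <- fit_molal_eos(m, Pi0, 0, 1, s, w)
  expect_true(all(abs(fit0$params$alphas) < 1e-10))
  expect_error(fit_molal_eos(m[1:2], Pi[1:2], 1.79, 1.31, s, w),
               "at least")
})

test_that("molal EOS fit is unbiased under Gaussian pressure noise", {
  s <- std_salt(); w <- std_solvent()
  truth <- moddh_molal(1.79, 1.31, c(0.21, 0.013))
  m <- seq(0.2, 4, length.out = 15)
  Pi <- osmotic_pressure_molal(m, truth, s, w)
  set.seed(5)
  reps <- t(vapply(1:100, function(i) {
    fit_molal_eos(m, Pi + rnorm(length(m), sd = 1), truth$A, truth$B,
                  s, w)$params$alphas
  }, numeric(2)))
  se <- apply(reps, 2, sd) / sqrt(nrow(reps))
  expect_true(all(abs(colMeans(reps) - truth$alphas) < 3 * se + 1e-12))
})

test_that("B calibration recovers the generating B and is a local minimum", {
  w <- std_solvent(); s <- std_salt()
  truth <- moddh_molar(1.7964, 1.5, c(0.17, 0.02))
  prof <- generate_profile(generator_config(params = truth, n_frames = Inf))
  cal <- calibrate_B(prof, 1.7964, s, w)
  expect_equal(cal$B, 1.5, tolerance = 0.1)
  obj_at <- function(B) {
    mf <- fit_concentration_profile(prof, 1.7964, w, B = B)
    osmobalance:::route_comparison(prof, mf, s, w)$objective
  }
  expect_lte(cal$objective, obj_at(1.5) * (1 + 1e-8))
  expect_gt(obj_at(cal$B - 0.5), cal$objective)
  expect_gt(obj_at(cal$B + 0.5), cal$objective)
})

test_that("noisy full pipeline recovers the generating pressure curve", {
  w <- std_solvent(); s <- std_salt()
  cfg <- generator_config(n_frames = 1e4, seed = 7)
  prof <- generate_profile(cfg)
  truth <- attr(prof, "truth")
  rep <- fit_osmotic_balance(prof, A = 1.7964, salt = s, solvent = w)
  Cg <- seq(0.01, truth$C_max, length.out = 60)
  p_true <- osmotic_pressure_molar(Cg, truth$params, s, w)
  p_fit <- osmotic_pressure_molar(Cg, rep$molar, s, w)
  expect_lt(max(abs(p_fit / p_true - 1)), 0.02)
  # the two routes agree after calibration to within the residual scale
  m_g <- molarity_to_molality(Cg, w$rho_w0, s)
  p21 <- osmotic_pressure_molal(m_g, rep$molal, s, w)
  expect_lt(max(abs(p21 - p_fit)), 5)   # bar, small vs Pi(C_max) ~ 250 bar
})

test_that("density fit is an exact polynomial round trip", {
  # NaBr constant-mu_w coefficients as generator
  gen <- density_fit(0.99695, c(0.099941, -0.0054726, -0.0010888))
  m <- seq(0, 4, by = 0.4)
  rho <- predict_density(gen, m)
  fit <- fit_density(m, rho)
  expect_equal(fit$fit$rho_w0, gen$rho_w0, tolerance = 1e-10)
  expect_equal(fit$fit$thetas, gen$thetas, tolerance = 1e-10)
  # sample order invariance
  ord <- sample(length(m))
  fit2 <- fit_density(m[ord], rho[ord])
  expect_equal(fit2$fit$thetas, fit$fit$thetas, tolerance = 1e-12)
  # pure-water-only samples: thetas ~ 0
  fit3 <- fit_density(m, rep(0.997, length(m)))
  expect_true(all(abs(fit3$fit$thetas) < 1e-12))
  expect_error(fit_density(m[1:3], rho[1:3]), "at least 4")
})

test_that("compressibility correction lowers densities where Pi > 0", {
  gen <- tabulated_density_fit("NaBr")
  s <- std_salt(); w <- std_solvent()
  pm <- moddh_molal(1.7937, 1.3125, c(0.2, 0.01))
  Pi_of_m <- function(m) osmotic_pressure_molal(m, pm, s, w)
  # kappa = 0 and Pi = 0 are identities
  same <- density_to_constant_P(gen, Pi_of_m, 0)
  expect_equal(predict_density(same, 0:4), predict_density(gen, 0:4),
               tolerance = 1e-10)
  same2 <- density_to_constant_P(gen, function(m) rep(0, length(m)), 3.95e-5)
  expect_equal(predict_density(same2, 0:4), predict_density(gen, 0:4),
               tolerance = 1e-10)
  corr <- density_to_constant_P(gen, Pi_of_m, 3.95e-5)
  m <- seq(0.2, 4, by = 0.2)
  expect_true(all(predict_density(corr, m) < predict_density(gen, m)))
  expect_equal(corr$ensemble, "constant-P")
  expect_error(density_to_constant_P(gen, function(m) rep(1e9, length(m)),
                                     3.95e-5), "invalid")
})

test_that("partial molar volume has the right limit and Euler identity", {
  w <- std_solvent(); s <- std_salt()
  fit <- tabulated_density_fit("NaBr", "constant-P")
  expect_equal(partial_molar_volume_water(fit, 0, w, s),
               18.015 / fit$rho_w0, tolerance = 1e-10)
  # n_w Vbar_w + n_s Vbar_s = V (per kg water)
  for (m in c(0.5, 2, 3.8)) {
    v <- (1000 + m * s$molar_mass_salt) / predict_density(fit, m)
    lhs <- (1000 / 18.015) * partial_molar_volume_water(fit, m, w, s) +
      m * partial_molar_volume_salt(fit, m, w, s)
    expect_equal(lhs, v, tolerance = 1e-8)
  }
})

test_that("water's partial molar volume stays near its pure-water value", {
  w <- std_solvent()
  tab <- density_fit_table()
  for (i in seq_len(nrow(tab))) {
    salt <- alkali_halide_salt(tab$salt[i])
    fit <- tabulated_density_fit(tab$salt[i], "constant-P")
    m <- seq(0, 4, by = 0.05)
    Vw <- partial_molar_volume_water(fit, m, w, salt)
    expect_lt(max(abs(Vw / Vw[1] - 1)), 0.035)
  }
})
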