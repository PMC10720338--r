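# The modDH activity model and the closed-form thermodynamics derived from
# it by Gibbs-Duhem integration, on both concentration scales.

test_that("Debye-Huckel A reproduces known solvent values and scalings", {
  # TIP4P/2005-like dielectric at 25 C
  expect_equal(debye_huckel_A(std_solvent()), 1.7964, tolerance = 0.003)
  # real water: ln-basis equivalent of the tabulated log10 constant 0.511
  aw <- debye_huckel_A(solvent_spec(dielectric = 78.41))
  expect_equal(aw, 0.511 * log(10), tolerance = 0.005)
  # A ~ eps^(-3/2): quadrupling the dielectric divides A by 8
  s1 <- solvent_spec(dielectric = 20)
  s4 <- solvent_spec(dielectric = 80)
  expect_equal(debye_huckel_A(s1) / debye_huckel_A(s4), 8, tolerance = 1e-12)
  # strictly decreasing in dielectric and temperature
  epss <- seq(10, 100, by = 10)
  As <- vapply(epss, function(e)
    debye_huckel_A(solvent_spec(dielectric = e)), numeric(1))
  expect_true(all(diff(As) < 0))
  Ts <- seq(260, 380, by = 20)
  At <- vapply(Ts, function(T)
    debye_huckel_A(solvent_spec(temperature = T)), numeric(1))
  expect_true(all(diff(At) < 0))
  expect_error(solvent_spec(dielectric = -2), "dielectric")
  expect_error(solvent_spec(temperature = 0), "temperature")
})

test_that("ln gamma has the modDH form and dilute limits", {
  p <- moddh_molar(1.7964, 1.5, c(0, 0))
  expect_identical(ln_mean_activity_molar(0, p), 0)
  expect_equal(ln_mean_activity_molar(1, p), -1.7964 / 2.5,
               tolerance = 1e-12)
  # limiting law: ln gamma / (-A sqrt(C)) -> 1 as C -> 0
  C <- 10^seq(-6, -10, by = -1)
  ratio <- ln_mean_activity_molar(C, p) / (-p$A * sqrt(C))
  expect_true(all(abs(ratio - 1) < 1e-2))
  expect_true(abs(ratio[length(ratio)] - 1) < 1e-4)
  expect_error(ln_mean_activity_molar(-0.1, p), "non-negative")
})

test_that("chemical potential differences are path independent", {
  p <- nabr_params(); s <- std_salt(); w <- std_solvent()
  expect_equal(chemical_potential_molar(2, p, s, w, C_ref = 2), 0)
  # ideal limit
  ide <- moddh_molar(0, 1)
  expect_equal(chemical_potential_molar(2, ide, s, w, C_ref = 1),
               s$nu * RT_std() * log(2), tolerance = 1e-12)
  # additivity along a path
  m12 <- chemical_potential_molar(1.7, p, s, w, C_ref = 0.3)
  m23 <- chemical_potential_molar(3.1, p, s, w, C_ref = 1.7)
  m13 <- chemical_potential_molar(3.1, p, s, w, C_ref = 0.3)
  expect_equal(m12 + m23, m13, tolerance = 1e-12)
  # antisymmetry
  expect_equal(chemical_potential_molar(2, p, s, w, C_ref = 0.5),
               -chemical_potential_molar(0.5, p, s, w, C_ref = 2),
               tolerance = 1e-12)
  expect_error(chemical_potential_molar(0, p, s, w, C_ref = 1), "diverges")
})

test_that("closed-form osmotic pressure matches quadrature of Gibbs-Duhem", {
  s <- std_salt(); w <- std_solvent()
  # ideal gas law
  ide <- moddh_molar(0, 1)
  expect_equal(osmotic_pressure_molar(1, ide, s, w), 49.58,
               tolerance = 1e-4)
  expect_identical(osmotic_pressure_molar(0, nabr_params(), s, w), 0)
  # NaBr parameters at 2 M against the quadrature oracle
  expect_equal(osmotic_pressure_molar(2, nabr_params(), s, w),
               osmotic_pressure_molar_quadrature(2, nabr_params(), s, w),
               tolerance = 1e-8)
  # B = 0 series limit is still exact against quadrature
  p0 <- moddh_molar(1.2, 0, c(0.05))
  expect_equal(osmotic_pressure_molar(1.5, p0, s, w),
               osmotic_pressure_molar_quadrature(1.5, p0, s, w),
               tolerance = 1e-8)
})

test_that("closed forms equal quadrature on random stable parameter sets", {
  s <- std_salt(); w <- std_solvent()
  set.seed(11)
  for (p in random_stable_params(100, seed = 13)) {
    C <- runif(1, 0.05, 3.5)
    expect_equal(osmotic_pressure_molar(C, p, s, w),
                 osmotic_pressure_molar_quadrature(C, p, s, w),
                 tolerance = 1e-8)
  }
  for (p in random_stable_params(100, molal = TRUE, seed = 17)) {
    m <- runif(1, 0.05, 3.5)
    expect_equal(ln_water_activity(m, p, s, w),
                 ln_water_activity_quadrature(m, p, s, w),
                 tolerance = 1e-8)
  }
})

test_that("pressure is monotone in concentration for tabulated salts", {
  s <- std_salt(); w <- std_solvent()
  tab <- moddh_molar_fits()
  Cg <- seq(0.01, 3.5, length.out = 80)
  for (i in seq_len(nrow(tab))) {
    p <- moddh_molar(tab$A[i], tab$B[i], c(tab$alpha1[i], tab$alpha2[i]))
    expect_true(all(diff(osmotic_pressure_molar(Cg, p, s, w)) > 0),
                info = tab$salt[i])
  }
})

test_that("molar-molal coefficient mapping is the sqrt(rho_w0) relation", {
  p <- nabr_params()
  ident <- molar_to_molal_params(p, solvent_spec(rho_w0 = 0.9999999))
  expect_equal(ident$A, p$A, tolerance = 1e-6)
  w <- std_solvent()
  t <- molar_to_molal_params(p, w)
  expect_equal(t$A, 1.7964 * sqrt(0.997), tolerance = 1e-12)
  expect_equal(t$B, 1.3145 * sqrt(0.997), tolerance = 1e-12)
  back <- molal_to_molar_params(t, w)
  expect_equal(back$A, p$A, tolerance = 1e-12)
  expect_equal(back$B, p$B, tolerance = 1e-12)
})

test_that("water activity and the molal pressure route behave", {
  s <- std_salt(); w <- std_solvent()
  ide <- moddh_molal(0, 1)
  expect_identical(ln_water_activity(0, ide, s, w), 0)
  expect_equal(ln_water_activity(1, ide, s, w), -2 * 0.018015,
               tolerance = 1e-12)
  expect_identical(osmotic_pressure_molal(0, ide, s, w), 0)
  expect_equal(osmotic_pressure_molal(1, ide, s, w, Vbar_w = 18.07),
               RT_std() * 2 * 0.018015 / 18.07 * 1e4, tolerance = 1e-12)
  expect_error(osmotic_pressure_molal(1, ide, s, w, Vbar_w = -1), "Vbar_w")
  # dilute agreement between the two routes with matched coefficients
  p <- nabr_params()
  t <- molar_to_molal_params(p, w)
  for (m in c(0.01, 0.03, 0.05)) {
    C <- w$rho_w0 * m
    pm <- osmotic_pressure_molar(C, p, s, w)
    pt <- osmotic_pressure_molal(m, t, s, w)
    expect_lt(abs(pt / pm - 1), 0.01)
  }
})

test_that("osmotic coefficient tends to 1 at infinite dilution", {
  s <- std_salt(); w <- std_solvent()
  for (p in random_stable_params(20, molal = TRUE, seed = 23)) {
    phi <- osmotic_coefficient(c(1e-6, 1e-8), p, s, w)
    expect_true(all(abs(phi - 1) < 5e-3))
  }
  expect_equal(osmotic_coefficient(0, moddh_molal(1, 1), s, w), 1)
})

test_that("molarity-molality conversion and its inverse round trip", {
  nacl <- salt_spec("NaCl", 1, 1, 1, -1, 58.44)
  expect_identical(molarity_to_molality(0, 0.997, nacl), 0)
  expect_equal(molarity_to_molality(1, 0.997, nacl), 1 / (0.997 - 0.05844),
               tolerance = 1e-12)
  m <- molarity_to_molality(2.5, 1.05, nacl)
  expect_equal(molality_to_molarity(m, 1.05, nacl), 2.5, tolerance = 1e-12)
  expect_error(molarity_to_molality(20, 0.997, nacl), "non-physical")
})
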