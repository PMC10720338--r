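# Shared fixtures: TIP4P/2005-like solvent, NaBr-like salt, the standard
# 30 x 30 x 100 A force-balance box, and small profile builders.

std_solvent <- function() solvent_spec(dielectric = 59.1,
                                       temperature = 298.15,
                                       rho_w0 = 0.997)

std_salt <- function() salt_spec("NaBr", 1, 1, 1, -1, 102.894)

std_box <- function() box_spec(30, 30, 100)

std_restraint <- function(k = 0.025) restraint_spec(k)

# modDH coefficients of the NaBr constant-mu_w fit
nabr_params <- function() moddh_molar(1.7964, 1.3145, c(0.17100, 0.022058))

RT_std <- function() 8.31446e-3 * 298.15

# ideal Boltzmann Gaussian profile on a uniform grid
gaussian_profile <- function(C_max = 3.5, k = 0.025, bin = 0.5,
                             box = std_box(), N_s = NULL) {
  nb <- round(box$Lz / bin)
  edges <- seq(-box$Lz / 2, box$Lz / 2, length.out = nb + 1)
  z <- (edges[-1] + edges[-length(edges)]) / 2
  C <- C_max * exp(-0.5 * k * z^2 / RT_std())
  concentration_profile(z, C, box, std_restraint(k), N_s = N_s)
}

# random but thermodynamically stable modDH parameter draws
random_stable_params <- function(n, molal = FALSE, seed = 42) {
  set.seed(seed)
  out <- list()
  while (length(out) < n) {
    A <- runif(1, 0, 3); B <- runif(1, 0.5, 3.5)
    al <- runif(2, -0.1, 0.3)
    p <- if (molal) moddh_molal(A, B, al) else moddh_molar(A, B, al)
    x <- seq(1e-4, 3.5, length.out = 200)
    dln <- 1 / x + osmobalance:::dln_gamma_dx(x, p)
    if (all(dln > 0)) out[[length(out) + 1L]] <- p
  }
  out
}
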