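# Synthetic-data generators emulating osmotic force balance simulation
# output, so the full analysis pipeline can be exercised without molecular
# dynamics: noisy binned ion profiles from a known modDH ground truth, a toy
# Metropolis sampler of ideal restrained solutes, and osmotic-coefficient
# reference tables from known molal parameters.

#' Configuration for the synthetic profile generator
#'
#' Defaults emulate the standard study conditions: a NaBr-like 1:1 salt in
#' TIP4P/2005-like water (dielectric 59.1, 25 C), a 30 x 30 x 100 A box with
#' 60 ion pairs under a half-k harmonic restraint of 0.025 kJ/(mol A^2),
#' 0.5 A bins, and a finite-sampling noise scale of 10^4 effective frames
#' (an effective-frames knob standing in for the autocorrelation of a long
#' production run).
#'
#' @param params Ground-truth [moddh_molar()] parameters.
#' @param salt A [salt_spec()].
#' @param solvent A [solvent_spec()].
#' @param box A [box_spec()].
#' @param restraint A [restraint_spec()].
#' @param N_s Number of salt formula units.
#' @param n_frames Effective number of independent frames; \code{Inf}
#'   disables noise.
#' @param bin_width Bin width, Angstrom.
#' @param seed Integer seed recorded in all outputs.
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(params = moddh_molar(1.7964, 1.3145,
                                                  c(0.17100, 0.022058)),
                             salt = salt_spec("NaBr", 1, 1, 1, -1, 102.894),
                             solvent = solvent_spec(),
                             box = box_spec(30, 30, 100),
                             restraint = restraint_spec(0.025),
                             N_s = 60, n_frames = 1e4, bin_width = 0.5,
                             seed = 1L) {
  if (n_frames < 1) stop_domain("n_frames must be >= 1")
  if (bin_width <= 0) stop_domain("bin_width must be positive")
  structure(list(params = params, salt = salt, solvent = solvent, box = box,
                 restraint = restraint, N_s = N_s, n_frames = n_frames,
                 bin_width = bin_width, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a noisy binned concentration profile from a known ground truth
#'
#' Computes the exact model profile (peak concentration from the mass
#' balance), converts it to expected ion counts per bin, and draws
#' multinomial counting noise independently for cations and anions
#' (\code{n_frames} frames of \code{nu_+- N_s} ions allocated across bins).
#' The independent draws give the electroneutrality audit realistic
#' small-sample imbalance in the dilute tails.
#'
#' @param config A [generator_config()].
#' @return A [concentration_profile()] with \code{C_plus}/\code{C_minus},
#'   plus attributes \code{truth} (list with params, C_max) and \code{seed}.
#' @export
generate_profile <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  box <- config$box
  nb <- max(2L, round(box$Lz / config$bin_width))
  edges <- seq(-box$Lz / 2, box$Lz / 2, length.out = nb + 1L)
  grid <- (edges[-1] + edges[-length(edges)]) / 2
  dz <- diff(edges)[1]
  C_max <- cmax_from_mass_balance(config$params, config$restraint, box,
                                  config$N_s, config$solvent)
  exact <- predicted_profile(config$params, C_max, config$restraint, box,
                             config$solvent, grid = grid, N_s = config$N_s)
  conv <- osmo_constants$N_A * 1e-27
  vol_bin <- box$Lx * box$Ly * dz            # A^3
  lambda <- exact$C_s * vol_bin * conv       # expected pairs per bin/frame
  if (sum(lambda) < 10)
    stop_domain("expected total ion count below 10: degenerate setup")
  if (is.finite(config$n_frames)) {
    set.seed(config$seed)
    nf <- as.integer(config$n_frames)
    p <- lambda / sum(lambda)
    draw_species <- function(n_ions) {
      # n_ions allocated across bins each frame; per-frame average count
      counts <- rowSums(stats::rmultinom(nf, size = n_ions, prob = p))
      counts / nf / (vol_bin * conv)         # back to M
    }
    C_plus <- draw_species(round(config$salt$nu_plus * config$N_s))
    C_minus <- draw_species(round(config$salt$nu_minus * config$N_s))
    C_s <- (C_plus / config$salt$nu_plus + C_minus / config$salt$nu_minus) / 2
  } else {
    C_plus <- config$salt$nu_plus * exact$C_s
    C_minus <- config$salt$nu_minus * exact$C_s
    C_s <- exact$C_s
  }
  out <- concentration_profile(grid, C_s, box, config$restraint,
                               N_s = config$N_s, C_plus = C_plus,
                               C_minus = C_minus)
  attr(out, "truth") <- list(params = config$params, C_max = C_max)
  attr(out, "seed") <- config$seed
  out
}

#' Metropolis sampler of ideal (noninteracting) restrained solutes
#'
#' One-dimensional Metropolis walk of N independent particles in the
#' restraint potential, with reflecting walls at +-Lz/2. The stationary
#' histogram is the Boltzmann profile C(z) proportional to exp(-U(z)/RT); for
#' a half-k harmonic restraint its standard deviation is sqrt(RT/k).
#'
#' @param N Number of particles.
#' @param restraint A [restraint_spec()].
#' @param box A [box_spec()].
#' @param solvent A [solvent_spec()] (supplies the temperature).
#' @param n_sweeps Number of Monte Carlo sweeps (one attempted move per
#'   particle per sweep).
#' @param step_size Maximum displacement per move, Angstrom.
#' @param seed Integer seed.
#' @param bin_width Histogram bin width, Angstrom.
#' @param burn_in Sweeps discarded before accumulating the histogram.
#' @return A [concentration_profile()] (the particle concentration per bin,
#'   M) with attributes \code{acceptance} and \code{z_samples_sd}.
#' @export
simulate_ideal_solutes <- function(N, restraint, box, solvent,
                                   n_sweeps = 2000L, step_size = 5,
                                   seed = 1L, bin_width = 1,
                                   burn_in = 200L) {
  if (N < 1) stop_domain("N must be >= 1")
  set.seed(seed)
  RT <- RT_kJ(solvent$temperature)
  half <- box$Lz / 2
  # start from the Boltzmann distribution itself (exact equilibrium for
  # noninteracting solutes), clamped to the box
  pref <- if (restraint$convention == "half-k") 0.5 else 1
  z <- pmin(pmax(stats::rnorm(N, 0, sqrt(RT / (2 * pref * restraint$k))),
                 -half), half)
  nb <- max(2L, round(box$Lz / bin_width))
  edges <- seq(-half, half, length.out = nb + 1L)
  counts <- numeric(nb)
  n_kept <- 0L
  accepted <- 0; attempted <- 0
  ssum <- 0; ssum2 <- 0; nsamp <- 0
  for (sweep in seq_len(n_sweeps)) {
    prop <- z + stats::runif(N, -step_size, step_size)
    # reflecting walls
    prop <- ifelse(prop > half, 2 * half - prop, prop)
    prop <- ifelse(prop < -half, -2 * half - prop, prop)
    dU <- restraint_energy(restraint, prop) - restraint_energy(restraint, z)
    acc <- stats::runif(N) < exp(-dU / RT)
    z[acc] <- prop[acc]
    accepted <- accepted + sum(acc); attempted <- attempted + N
    if (sweep > burn_in) {
      h <- tabulate(findInterval(z, edges, rightmost.closed = TRUE), nb)
      counts <- counts + h
      n_kept <- n_kept + 1L
      ssum <- ssum + sum(z); ssum2 <- ssum2 + sum(z^2); nsamp <- nsamp + N
    }
  }
  if (accepted == 0)
    stop_domain("zero acceptance: step_size too large for this restraint")
  conv <- osmo_constants$N_A * 1e-27
  dz <- diff(edges)[1]
  C <- counts / n_kept / (box$Lx * box$Ly * dz * conv)
  out <- concentration_profile((edges[-1] + edges[-length(edges)]) / 2, C,
                               box, restraint, N_s = N)
  attr(out, "acceptance") <- accepted / attempted
  attr(out, "z_samples_sd") <- sqrt(ssum2 / nsamp - (ssum / nsamp)^2)
  attr(out, "seed") <- seed
  out
}

#' Reference osmotic-coefficient table from known molal parameters
#'
#' Builds an experimental-style table of molality, osmotic coefficient and
#' mean ionic activity coefficient from a molal modDH parameter set, for use
#' as a stand-in reference equation of state.
#'
#' @param params A [moddh_molal()].
#' @param salt A [salt_spec()].
#' @param solvent A [solvent_spec()].
#' @param m_grid Positive ascending molalities.
#' @return Data.frame with columns \code{m}, \code{phi}, \code{ln_gamma}.
#' @export
generate_experimental_table <- function(params, salt, solvent, m_grid) {
  if (any(m_grid <= 0) || is.unsorted(m_grid, strictly = TRUE))
    stop_domain("m_grid must be positive and strictly ascending")
  data.frame(m = m_grid,
             phi = osmotic_coefficient(m_grid, params, salt, solvent),
             ln_gamma = ln_mean_activity_molal(m_grid, params))
}
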