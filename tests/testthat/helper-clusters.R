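# Shared fixtures built in code.

# Default acquisition constants used across tests: 20 MHz modulation,
# 50 ns period, donor lifetime 12 ns.
OMEGA20 <- angular_frequency(2e7)

# Simulate a membrane-like phasor cluster directly (no scene geometry):
# n_px pixels whose state fraction of the quenched species varies around f,
# Poisson photon noise, ideal IRF. Returns the uncalibrated phasor_image of
# the stack plus the realized per-pixel fractions.
sim_cluster <- function(f, e_high, n_px = 150, photons = 1e5,
                        fraction_sd = 0.1, tau_donor = 12,
                        bins = 256L, period = 50, seed = 1) {
  set.seed(seed)
  f_i <- pmin(pmax(stats::rnorm(n_px, f, fraction_sd), 0), 1)
  p_d <- expected_decay(lifetime_mixture(tau_donor, 1), bins = bins,
                        period = period, irf_width = 0, irf_t0 = 0)
  p_q <- expected_decay(lifetime_mixture(tau_donor * (1 - e_high), 1),
                        bins = bins, period = period, irf_width = 0,
                        irf_t0 = 0)
  lam <- photons * (outer(1 - f_i, as.numeric(p_d)) +
                      outer(f_i, as.numeric(p_q)))
  counts <- array(0, c(n_px, 1, bins))
  counts[, 1, ] <- stats::rpois(length(lam), lam)
  dec <- decay_image(counts, attr(p_d, "bin_centers"), period)
  # mixture fractions are intensity fractions and every pixel carries the
  # same photon budget, so the cluster's true intensity fraction is mean(f_i)
  list(phasor = decay_to_phasor(dec),
       f_realized = f_i,
       f_int_true = mean(f_i))
}

# Noise-free single-pixel decay image of a mixture at fine binning.
noise_free_decay <- function(mixture, bins = 4096L, period = 50,
                             irf_width = 0, irf_t0 = 0) {
  p <- expected_decay(mixture, bins = bins, period = period,
                      irf_width = irf_width, irf_t0 = irf_t0)
  decay_image(array(p, c(1, 1, bins)), attr(p, "bin_centers"), period)
}

# Small two-state FLIM scene used by several suites.
small_fret_scene <- function(f = 0.35, e_high = 0.53, seed = 1,
                             photons_membrane = 1e5, size = 48) {
  scene_spec(size = size,
             membrane = fret_membrane_mixture(12, e_high, f),
             photons = c(membrane = photons_membrane, cytosol = 2e3,
                         extracellular = 0),
             seed = seed)
}
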