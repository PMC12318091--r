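test_that("mono-exponential phasors sit on the universal semicircle", {
  taus <- c(0, 0.5, 1, 3.6, 7.96, 12, 50, 500)
  gs <- mono_phasor(taus, OMEGA20)
  expect_equal((gs[, 1] - 0.5)^2 + gs[, 2]^2, rep(0.25, length(taus)),
               tolerance = 1e-15)
  expect_equal(unname(mono_phasor(0, OMEGA20)), c(1, 0))
  expect_equal(unname(mono_phasor(1 / OMEGA20, OMEGA20)), c(0.5, 0.5),
               tolerance = 1e-15)
  expect_equal(mono_phasor(3.6, OMEGA20)[["G"]],
               1 / (1 + (2 * pi * 2e7 * 3.6e-9)^2), tolerance = 1e-15)
  expect_error(mono_phasor(-1, OMEGA20), "non-negative")
})

test_that("longer lifetimes move clockwise from (1,0) along the semicircle", {
  taus <- seq(0.1, 40, length.out = 60)
  g <- mono_phasor(taus, OMEGA20)[, 1]
  expect_true(all(diff(g) < 0))
})

test_that("a delta decay maps to (1,0) and a uniform decay to the origin", {
  bins <- 64L
  # all counts in a single bin centered at t = 0
  counts <- array(0, c(1, 1, bins))
  counts[1, 1, 1] <- 500
  dec <- decay_image(counts, seq(0, 49, length.out = bins), 50)
  ph <- decay_to_phasor(dec)
  expect_equal(c(ph$G[1, 1], ph$S[1, 1]), c(1, 0))

  unif <- decay_image(array(7, c(1, 1, bins)),
                      (seq_len(bins) - 0.5) * 50 / bins, 50)
  ph_u <- decay_to_phasor(unif)
  expect_lt(abs(ph_u$G[1, 1]), 1e-12)
  expect_lt(abs(ph_u$S[1, 1]), 1e-12)
})

test_that("zero-intensity pixels are flagged invalid without NaN", {
  counts <- array(0, c(2, 1, 16))
  counts[1, 1, ] <- 1
  dec <- decay_image(counts, (1:16 - 0.5) * 50 / 16, 50)
  ph <- decay_to_phasor(dec)
  expect_false(ph$valid[2, 1])
  expect_true(ph$valid[1, 1])
  expect_false(anyNA(c(ph$G, ph$S)))
  expect_error(decay_to_phasor(dec, harmonic = 0), "harmonic")
  dark <- decay_image(array(0, c(1, 1, 16)), (1:16 - 0.5) * 50 / 16, 50)
  expect_error(decay_to_phasor(dark), "positive intensity")
})

test_that("the phasor of a summed histogram is the intensity-weighted mean", {
  bins <- 128L
  a <- expected_decay(lifetime_mixture(12, 1), bins = bins, irf_width = 0.2)
  b <- expected_decay(lifetime_mixture(4, 1), bins = bins, irf_width = 0.2)
  t_k <- attr(a, "bin_centers")
  wa <- 3; wb <- 7
  stack <- array(0, c(3, 1, bins))
  stack[1, 1, ] <- wa * a
  stack[2, 1, ] <- wb * b
  stack[3, 1, ] <- wa * a + wb * b
  ph <- decay_to_phasor(decay_image(stack, t_k, 50))
  expect_equal(ph$G[3, 1],
               (wa * ph$G[1, 1] + wb * ph$G[2, 1]) / (wa + wb),
               tolerance = 1e-14)
  expect_equal(ph$S[3, 1],
               (wa * ph$S[1, 1] + wb * ph$S[2, 1]) / (wa + wb),
               tolerance = 1e-14)
})

test_that("harmonics of a mono-exponential reproduce the analytic phasor", {
  dec <- noise_free_decay(lifetime_mixture(8, 1))
  for (n in 1:2) {
    ph <- decay_to_phasor(dec, harmonic = n)
    truth <- mono_phasor(8, angular_frequency(2e7, n))
    expect_equal(c(ph$G[1, 1], ph$S[1, 1]), unname(truth), tolerance = 1e-6)
  }
})

test_that("calibration against a matched reference recovers the semicircle", {
  # IRF shift of 2 ns rotates phasors off the semicircle; calibrating with a
  # reference acquired through the same instrument puts mono-exponential
  # pixels back to their analytic positions
  dec <- noise_free_decay(lifetime_mixture(12, 1), irf_width = 0.2,
                          irf_t0 = 2)
  raw <- decay_to_phasor(dec)
  semicirc_res <- abs((raw$G[1, 1] - 0.5)^2 + raw$S[1, 1]^2 - 0.25)
  expect_gt(semicirc_res, 1e-3)

  refdec <- noise_free_decay(lifetime_mixture(3.6, 1), irf_width = 0.2,
                             irf_t0 = 2)
  ref <- calibration_ref(decay_to_phasor(refdec), 3.6)
  cal <- calibrate(raw, ref)
  truth <- mono_phasor(12, OMEGA20)
  expect_lt(max(abs(c(cal$G[1, 1], cal$S[1, 1]) - truth)), 1e-6)

  # calibrating the reference acquisition itself is exact by construction
  calref <- calibrate(decay_to_phasor(refdec), ref)
  expect_equal(c(calref$G[1, 1], calref$S[1, 1]),
               unname(mono_phasor(3.6, OMEGA20)), tolerance = 1e-14)
})

test_that("a perfect instrument makes calibration the identity", {
  ref <- calibration_ref(mono_phasor(3.6, OMEGA20), 3.6)
  dec <- noise_free_decay(lifetime_mixture(12, 1), bins = 256)
  ph <- decay_to_phasor(dec)
  cal <- calibrate(ph, ref)
  expect_equal(cal$G, ph$G, tolerance = 1e-14)
  expect_equal(cal$S, ph$S, tolerance = 1e-14)
  expect_error(calibration_ref(c(0, 0), 3.6), "degenerate")
  expect_error(calibration_ref(c(0.5, 0.4), -1), "positive")
})

test_that("phase and modulation lifetimes invert the phasor coordinates", {
  pt <- mono_phasor(12, OMEGA20)
  taus <- phase_mod_lifetimes(pt, OMEGA20)
  expect_equal(unname(taus), c(12, 12), tolerance = 1e-12)

  apex <- phase_mod_lifetimes(c(0.5, 0.5), OMEGA20)
  expect_equal(unname(apex), rep(1 / OMEGA20, 2), tolerance = 1e-12)

  # an interior point (background-displaced membrane donor): tau_phi = 11.7,
  # tau_m = 12.6 ns corresponds to (G, S) close to (0.300, 0.442)
  phi <- atan(OMEGA20 * 11.7)
  m <- 1 / sqrt(1 + (OMEGA20 * 12.6)^2)
  pt2 <- c(m * cos(phi), m * sin(phi))
  expect_equal(pt2, c(0.300, 0.442), tolerance = 2e-3)
  back <- phase_mod_lifetimes(pt2, OMEGA20)
  expect_equal(unname(back), c(11.7, 12.6), tolerance = 1e-9)

  expect_error(phase_mod_lifetimes(c(0.9, 0.5), OMEGA20), "modulus")
})

test_that("smoothing is the identity at size 1 and preserves constants", {
  dec <- noise_free_decay(lifetime_mixture(12, 1), bins = 64)
  ph <- decay_to_phasor(dec)
  big <- ph
  big$G <- matrix(0.4, 8, 8); big$S <- matrix(0.3, 8, 8)
  big$intensity <- matrix(1, 8, 8); big$valid <- matrix(TRUE, 8, 8)
  expect_identical(smooth_phasor(big, "median", 1), big)
  for (m in c("median", "gaussian")) {
    sm <- smooth_phasor(big, m, 3)
    expect_equal(sm$G, big$G, tolerance = 1e-12)
    expect_equal(sm$S, big$S, tolerance = 1e-12)
    expect_identical(sm$intensity, big$intensity)
  }
  expect_error(smooth_phasor(big, "median", 4), "odd")
})

test_that("a median filter replaces a single-pixel outlier", {
  ph <- structure(list(G = matrix(0.4, 5, 5), S = matrix(0.3, 5, 5),
                       intensity = matrix(1, 5, 5),
                       valid = matrix(TRUE, 5, 5),
                       harmonic = 1L, omega = OMEGA20, frequency_hz = 2e7),
                  class = "phasor_image")
  ph$G[3, 3] <- 0.99
  sm <- smooth_phasor(ph, "median", 3)
  expect_equal(sm$G[3, 3], 0.4)   # the neighborhood median
  expect_equal(sm$G[1, 1], 0.4)
})

test_that("membrane masking selects the bright quantile", {
  img <- matrix(c(rep(0, 10), rep(10, 45), rep(100, 45)), 10, 10)
  m <- mask_membrane(img, 0.5)
  expect_identical(unname(m), unname(img == 100))
  m_all <- mask_membrane(img, 1e-9)
  expect_identical(unname(m_all), unname(img > 0))
  expect_warning(m0 <- mask_membrane(matrix(0, 4, 4), 0.9), "empty mask")
  expect_false(any(m0))
  expect_error(mask_membrane(img, 1.5), "quantile")
})

test_that("the membrane mask recovers the true ring in a synthetic scene", {
  spec <- small_fret_scene(seed = 9, photons_membrane = 1e3)
  scene <- make_scene(spec)
  mask <- mask_membrane(scene$co_channel, 0.9)
  ring <- scene_regions(spec) == "membrane"
  expect_gte(sum(mask & ring) / sum(mask), 0.95)
})
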