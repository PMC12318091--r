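P_D12 <- mono_phasor(12, OMEGA20)

test_that("background correction exactly inverts uniform-background mixing", {
  expect_equal(correct_background(c(0.3, 0.4), 0), c(G = 0.3, S = 0.4))
  for (b in c(0.05, 0.3, 0.8)) {
    mixed <- (1 - b) * P_D12 + b * c(0, 0)
    expect_equal(unname(correct_background(mixed, b)), unname(P_D12),
                 tolerance = 1e-14)
    bg <- c(0.1, 0.05)
    mixed2 <- (1 - b) * P_D12 + b * bg
    expect_equal(unname(correct_background(mixed2, b, bg)), unname(P_D12),
                 tolerance = 1e-14)
  }
  expect_error(correct_background(c(0.3, 0.4), 1), "fraction")
})

test_that("background-corrected noisy pixels return near the semicircle", {
  set.seed(2)
  b <- 0.05
  p_d <- expected_decay(lifetime_mixture(12, 1), bins = 256, irf_width = 0,
                        irf_t0 = 0)
  lam <- 1e6 * ((1 - b) * as.numeric(p_d) + b / 256)
  counts <- array(rpois(256 * 20, rep(lam, each = 20)), c(20, 1, 256))
  ph <- decay_to_phasor(decay_image(counts, attr(p_d, "bin_centers"), 50))
  pts <- correct_background(cbind(as.vector(ph$G), as.vector(ph$S)), b)
  res <- abs((pts[, 1] - 0.5)^2 + pts[, 2]^2 - 0.25)
  expect_lt(stats::median(res), 1e-3)
})

test_that("the weighted major axis matches a brute-force direction search", {
  set.seed(7)
  n <- 18
  pts <- cbind(0.4 + 0.1 * stats::rnorm(n), 0.3 + 0.02 * stats::rnorm(n))
  w <- stats::runif(n, 0.5, 2)
  line <- fit_major_axis(pts, w)
  # oracle: exhaustive scan over axis angles maximizing projected variance
  ang <- seq(0, pi, by = 1e-4)
  ctr <- colSums(pts * (w / sum(w)))
  d <- sweep(pts, 2, ctr)
  v <- vapply(ang, function(a) {
    pr <- d %*% c(cos(a), sin(a))
    sum(w / sum(w) * pr^2)
  }, numeric(1))
  best <- ang[which.max(v)]
  got <- atan2(line$direction[2], line$direction[1]) %% pi
  expect_lt(min(abs(got - best), pi - abs(got - best)), 1e-3)
})

test_that("collinear points give a capped elongation along the segment", {
  t <- seq(0, 1, length.out = 10)
  pts <- cbind(0.2 + 0.5 * t, 0.45 - 0.2 * t)
  line <- fit_major_axis(pts)
  expect_equal(line$elongation, 1e6)
  slope <- line$direction[2] / line$direction[1]
  expect_equal(unname(slope), -0.4, tolerance = 1e-10)
  expect_error(fit_major_axis(matrix(0.3, 5, 2)), "degenerate")
  expect_error(fit_major_axis(pts[1:2, ]), "3 points")
})

test_that("an isotropic cloud is flagged as having no unmixing axis", {
  set.seed(12)
  pts <- cbind(0.5 + 0.01 * stats::rnorm(400), 0.4 + 0.01 * stats::rnorm(400))
  line <- fit_major_axis(pts)
  expect_lt(line$elongation, 1.2)
  expect_false(line$axis_ok)
})

test_that("a noisy two-state cluster recovers the chord direction", {
  cl <- sim_cluster(f = 0.5, e_high = 0.53, n_px = 300, seed = 3)
  ph <- cl$phasor
  line <- fit_major_axis(cbind(as.vector(ph$G), as.vector(ph$S)),
                         as.vector(ph$intensity))
  chord <- mono_phasor(12 * 0.47, OMEGA20) - P_D12
  ang_true <- atan2(chord[2], chord[1]) %% pi
  ang_got <- atan2(line$direction[2], line$direction[1]) %% pi
  err <- min(abs(ang_got - ang_true), pi - abs(ang_got - ang_true))
  expect_lt(err * 180 / pi, 5)
})

test_that("the semicircle endpoint picks the shorter-lifetime intersection", {
  line_gaxis <- list(center = c(0.5, 0), direction = c(1, 0))
  expect_equal(unname(semicircle_endpoint(line_gaxis)), c(1, 0))

  p_f <- mono_phasor(12 * (1 - 0.53), OMEGA20)  # 5.64 ns
  chord <- list(center = P_D12, direction = p_f - P_D12)
  expect_equal(unname(semicircle_endpoint(chord)), unname(p_f),
               tolerance = 1e-12)

  tangent <- list(center = c(0.5, 0.5), direction = c(1, 0))
  expect_equal(unname(semicircle_endpoint(tangent)), c(0.5, 0.5),
               tolerance = 1e-7)
  miss <- list(center = c(0.5, 0.8), direction = c(1, 0))
  expect_error(semicircle_endpoint(miss), "intersect")
})

test_that("exact chord mixtures unmix to machine precision", {
  cfg <- unmix_config(donor_tau = 12)
  p_f <- mono_phasor(12 * (1 - 0.53), OMEGA20)
  for (f in c(0.2, 0.5, 0.8)) {
    fr <- f + c(-0.1, 0, 0.1)
    pts <- cbind((1 - fr) * P_D12[1] + fr * p_f[1],
                 (1 - fr) * P_D12[2] + fr * p_f[2])
    res <- unmix_two_state(pts, cfg)
    expect_equal(res$f_int, f, tolerance = 1e-10)
    expect_equal(res$e_high, 0.53, tolerance = 1e-10)
  }
})

test_that("single-point clusters map to the fraction endpoints", {
  cfg <- unmix_config(donor_tau = 12)
  at_d <- unmix_two_state(matrix(P_D12, 1, 2), cfg)
  expect_equal(at_d$f_int, 0, tolerance = 1e-12)
  p_f <- mono_phasor(5.64, OMEGA20)
  at_f <- unmix_two_state(matrix(p_f, 1, 2), cfg)
  expect_equal(at_f$f_int, 1, tolerance = 1e-10)
  expect_equal(at_f$e_high, 1 - 5.64 / 12, tolerance = 1e-10)
})

test_that("a measured donor phasor takes precedence over the lifetime", {
  p_f <- mono_phasor(6, OMEGA20)
  p_d10 <- mono_phasor(10, OMEGA20)
  pts <- rbind((1 - 0.3) * p_d10 + 0.3 * p_f,
               (1 - 0.5) * p_d10 + 0.5 * p_f,
               (1 - 0.7) * p_d10 + 0.7 * p_f)
  cfg <- unmix_config(donor_tau = 12, donor_phasor = p_d10)
  res <- unmix_two_state(pts, cfg)
  expect_equal(res$f_int, 0.5, tolerance = 1e-9)
  expect_equal(res$e_high, 1 - 6 / 10, tolerance = 1e-9)
})

test_that("molecular fractions correct for quenched-state dimming", {
  expect_equal(molecular_fraction(0.35, 0), 0.35)
  expect_equal(molecular_fraction(1, 0.53), 1)
  expect_equal(molecular_fraction(0.35, 0.53),
               0.35 / (0.47 * 0.65 + 0.35), tolerance = 1e-12)
  expect_equal(molecular_fraction(0.35, 0.53), 0.534, tolerance = 1e-3)
  f <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(molecular_fraction(f, 0.5) >= f))
  expect_error(molecular_fraction(0.5, 1), "undefined brightness")
})

test_that("recovered fractions increase with the true fraction", {
  cfg <- unmix_config(donor_tau = 12)
  fs <- seq(0.1, 0.9, by = 0.2)
  got <- vapply(fs, function(f) {
    cl <- sim_cluster(f = f, e_high = 0.5, n_px = 120, seed = 31)
    ph <- cl$phasor
    unmix_two_state(cbind(as.vector(ph$G), as.vector(ph$S)), cfg,
                    weights = as.vector(ph$intensity))$f_int
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("fraction and efficiency recover across a seeded Poisson sweep", {
  cfg <- unmix_config(donor_tau = 12)
  cases <- expand.grid(f = seq(0.1, 0.9, by = 0.2), e = c(0.3, 0.5, 0.7))
  ok_f <- logical(nrow(cases)); err_e <- numeric(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    cl <- sim_cluster(f = cases$f[i], e_high = cases$e[i], n_px = 150,
                      photons = 1e5, seed = 100 + i)
    ph <- cl$phasor
    res <- unmix_two_state(cbind(as.vector(ph$G), as.vector(ph$S)), cfg,
                           weights = as.vector(ph$intensity))
    ok_f[i] <- abs(res$f_int - cl$f_int_true) <= 0.03
    err_e[i] <- abs(res$e_high - cases$e[i])
  }
  expect_gte(mean(ok_f), 0.9)
  expect_gte(mean(err_e <= 0.05), 0.9)
})
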