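#' Mixture of mono-exponential lifetime components
#'
#' @param tau Lifetimes in ns, all > 0.
#' @param fraction Intensity fractions; must sum to 1 (tolerance 1e-9).
#' @return A `lifetime_mixture`: data frame with columns `tau`, `fraction`.
#' @export
lifetime_mixture <- function(tau, fraction = rep(1 / length(tau), length(tau))) {
  if (length(tau) != length(fraction)) stop("tau and fraction lengths differ")
  if (any(tau <= 0)) stop("all lifetimes must be positive")
  if (any(fraction < 0)) stop("fractions must be non-negative")
  if (abs(sum(fraction) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(data.frame(tau = tau, fraction = fraction),
            class = c("lifetime_mixture", "data.frame"))
}

#' Membrane mixture of donor-alone and FRET-quenched species
#'
#' Convenience constructor for the two-state membrane model: a donor with
#' lifetime `tau_donor` of which an intensity fraction `state_fraction` is
#' quenched to `tau_donor * (1 - e_high)` by high-FRET acceptors.
#'
#' @param tau_donor Donor-alone lifetime in ns.
#' @param e_high FRET efficiency of the quenched (high-FRET) state, in [0,1).
#' @param state_fraction Intensity fraction of the quenched species, in [0,1].
#' @return A [lifetime_mixture()].
#' @export
fret_membrane_mixture <- function(tau_donor = 12, e_high = 0.53,
                                  state_fraction = 0.35) {
  if (e_high < 0 || e_high >= 1) stop("e_high must be in [0, 1)")
  if (state_fraction < 0 || state_fraction > 1)
    stop("state_fraction must be in [0, 1]")
  if (state_fraction == 0) return(lifetime_mixture(tau_donor, 1))
  if (state_fraction == 1) return(lifetime_mixture(tau_donor * (1 - e_high), 1))
  lifetime_mixture(c(tau_donor, tau_donor * (1 - e_high)),
                   c(1 - state_fraction, state_fraction))
}

# Wrapped exponentially-modified-Gaussian density at times t (ns), for an
# excitation pulse at t0 with Gaussian IRF width sigma, decay lifetime tau,
# wrapped on the circle of period T. With sigma = 0 this is the shifted
# wrapped exponential. Wrap terms decay as exp(-m*T/tau).
wrapped_emg <- function(t, tau, sigma, t0, period) {
  lam <- 1 / tau
  n_wrap <- ceiling(tau / period * log(1e16)) + 1L
  out <- numeric(length(t))
  if (sigma <= 0) {
    for (m in 0:n_wrap) {
      x <- t + m * period - t0
      out <- out + ifelse(x >= 0, lam * exp(-lam * x), 0)
    }
  } else {
    for (m in 0:n_wrap) {
      x <- t + m * period - t0
      logamp <- lam * (lam * sigma^2 / 2 - x)
      e <- pracma::erfc((lam * sigma^2 - x) / (sigma * sqrt(2)))
      out <- out + ifelse(e > 0, lam / 2 * exp(logamp) * e, 0)
    }
  }
  out
}

#' Expected decay histogram of a lifetime mixture
#'
#' Noise-free model: the mixture of wrapped exponentials, convolved on the
#' circle of one modulation period with a wrapped Gaussian instrument
#' response centered at `irf_t0`, evaluated at bin centers and normalized
#' to unit sum. This is the probability vector from which photon counts are
#' drawn.
#'
#' @param components A [lifetime_mixture()].
#' @param bins Number of time bins, >= 16.
#' @param period Modulation period in ns.
#' @param irf_width Gaussian IRF standard deviation in ns (0 = ideal pulse).
#' @param irf_t0 IRF center in ns (default 2).
#' @return Numeric vector of bin probabilities with attribute
#'   `bin_centers` (ns).
#' @export
expected_decay <- function(components, bins = 256L, period = 50,
                           irf_width = 0.2, irf_t0 = 2) {
  stopifnot(inherits(components, "lifetime_mixture"))
  if (period <= 0) stop("period must be positive")
  if (bins < 16) stop("bins must be >= 16")
  if (any(components$tau > period))
    warning("lifetime exceeds the modulation period; decay wraps around")
  t_k <- (seq_len(bins) - 0.5) * period / bins
  p <- numeric(bins)
  for (i in seq_len(nrow(components))) {
    # each component normalized to unit photon count before mixing, so the
    # intensity fractions are exact photon fractions and mixing is linear
    d <- wrapped_emg(t_k, components$tau[i], irf_width, irf_t0, period)
    p <- p + components$fraction[i] * d / sum(d)
  }
  attr(p, "bin_centers") <- t_k
  p
}

#' Simulate a time-binned photon-count decay histogram
#'
#' Draws per-bin photon counts from a Poisson distribution around the
#' expected wrapped-decay histogram of [expected_decay()]. With
#' `n_photons = Inf` the normalized noise-free histogram is returned
#' (counts sum to 1).
#'
#' @inheritParams expected_decay
#' @param n_photons Expected total photon count (> 0), or `Inf` for the
#'   noise-free limit.
#' @param seed Optional integer seed for the Poisson draw.
#' @return Numeric vector of counts per bin, with attribute `bin_centers`.
#' @export
simulate_decay <- function(components, n_photons, bins = 256L, period = 50,
                           irf_width = 0.2, irf_t0 = 2, seed = NULL) {
  if (n_photons <= 0) stop("n_photons must be positive")
  if (bins <= 0) stop("bins must be positive")
  p <- expected_decay(components, bins = bins, period = period,
                      irf_width = irf_width, irf_t0 = irf_t0)
  if (!is.finite(n_photons)) return(p)
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rpois(length(p), n_photons * p)
  attr(counts, "bin_centers") <- attr(p, "bin_centers")
  counts
}

#' Specification of a synthetic FLIM scene
#'
#' Describes a cell-like image: a bright membrane ring carrying the
#' (possibly FRET-quenched) donor mixture, a cytosol filled with nonspecific
#' donor fluorescence, and empty extracellular space. Every pixel receives a
#' time-uniform background component at the stated intensity fraction.
#'
#' @param size Image size in pixels (square).
#' @param center Ring center `c(row, col)` (1-based pixel coordinates).
#' @param radius Ring radius in pixels.
#' @param thickness Ring thickness in pixels.
#' @param membrane,cytosol Region mixtures ([lifetime_mixture()]).
#' @param photons Named numeric: expected photons per pixel for `membrane`,
#'   `cytosol`, `extracellular`.
#' @param background Background intensity fraction in [0, 1]; background
#'   photons are uniform in time (their phasor is the origin).
#' @param fraction_sd Pixel-to-pixel standard deviation of the membrane
#'   state fraction (truncated to [0, 1]); emulates conformational
#'   heterogeneity across the channel ensemble, which elongates the phasor
#'   cluster along the donor/high-FRET chord. Applies only when the
#'   membrane mixture has two components. Default 0.1.
#' @param irf_width,irf_t0 Gaussian IRF width and center in ns.
#' @param frequency_hz Modulation frequency in Hz.
#' @param bins Number of time bins, >= 16.
#' @param seed Integer seed; all scene randomness flows from it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(size = 64L,
                       center = c((size + 1) / 2, (size + 1) / 2),
                       radius = size * 0.35,
                       thickness = 3,
                       membrane = fret_membrane_mixture(),
                       cytosol = lifetime_mixture(12, 1),
                       photons = c(membrane = 1e4, cytosol = 2e3,
                                   extracellular = 0),
                       background = 0.05,
                       fraction_sd = 0.1,
                       irf_width = 0.2, irf_t0 = 2,
                       frequency_hz = 2e7,
                       bins = 256L,
                       seed = 1L) {
  if (fraction_sd < 0) stop("fraction_sd must be non-negative")
  if (background < 0 || background > 1) stop("background must be in [0, 1]")
  if (bins < 16) stop("bins must be >= 16")
  if (radius + thickness / 2 > min(center[1], center[2],
                                   size - center[1] + 1, size - center[2] + 1))
    stop("membrane ring exceeds image bounds")
  need <- c("membrane", "cytosol", "extracellular")
  if (!all(need %in% names(photons))) stop("photons must name all regions")
  structure(list(size = as.integer(size), center = center, radius = radius,
                 thickness = thickness, membrane = membrane,
                 cytosol = cytosol, photons = photons[need],
                 background = background, fraction_sd = fraction_sd,
                 irf_width = irf_width,
                 irf_t0 = irf_t0, frequency_hz = frequency_hz,
                 bins = as.integer(bins), seed = as.integer(seed)),
            class = "scene_spec")
}

#' Region labels of a scene
#'
#' @param spec A [scene_spec()].
#' @return Character matrix with values `"membrane"`, `"cytosol"`,
#'   `"extracellular"`; the three regions are disjoint and cover the image.
#' @export
scene_regions <- function(spec) {
  n <- spec$size
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  d <- sqrt((rr - spec$center[1])^2 + (cc - spec$center[2])^2)
  reg <- matrix("extracellular", n, n)
  reg[d < spec$radius - spec$thickness / 2] <- "cytosol"
  reg[abs(d - spec$radius) <= spec$thickness / 2] <- "membrane"
  reg
}

#' Generate a synthetic FLIM acquisition with known ground truth
#'
#' Builds the per-pixel expected decay for each region (mixing in the
#' uniform background at the stated fraction), draws Poisson photon counts,
#' and renders a membrane-bright co-channel intensity image (the YFP
#' stand-in used for membrane masking). Running twice with the same spec
#' gives bit-identical output.
#'
#' @param spec A [scene_spec()].
#' @return List with elements `decay` ([decay_image()]), `co_channel`
#'   (intensity matrix) and `truth` (class `ground_truth`).
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  period <- 1e9 / spec$frequency_hz
  reg <- scene_regions(spec)
  n <- spec$size
  counts <- array(0, c(n, n, spec$bins))
  mixes <- list(membrane = spec$membrane, cytosol = spec$cytosol,
                extracellular = NULL)
  for (r in c("membrane", "cytosol", "extracellular")) {
    idx <- which(reg == r)
    budget <- spec$photons[[r]]
    if (length(idx) == 0 || budget <= 0) next
    mix <- mixes[[r]]
    hetero <- r == "membrane" && !is.null(mix) && nrow(mix) == 2 &&
      spec$fraction_sd > 0
    if (hetero) {
      # per-pixel state fraction of the quenched (shorter-lifetime) species:
      # conformational heterogeneity elongates the cluster along the chord
      qi <- which.min(mix$tau)
      f0 <- mix$fraction[qi]
      f_i <- pmin(pmax(stats::rnorm(length(idx), f0, spec$fraction_sd), 0), 1)
      dens_q <- expected_decay(lifetime_mixture(mix$tau[qi], 1),
                               bins = spec$bins, period = period,
                               irf_width = spec$irf_width, irf_t0 = spec$irf_t0)
      dens_d <- expected_decay(lifetime_mixture(mix$tau[-qi], 1),
                               bins = spec$bins, period = period,
                               irf_width = spec$irf_width, irf_t0 = spec$irf_t0)
      pmat <- outer(1 - f_i, as.numeric(dens_d)) + outer(f_i, as.numeric(dens_q))
      lam <- budget * ((1 - spec$background) * pmat +
                         spec$background / spec$bins)
      m <- matrix(stats::rpois(length(lam), lam), length(idx), spec$bins)
    } else {
      p <- if (is.null(mix)) rep(1 / spec$bins, spec$bins) else
        expected_decay(mix, bins = spec$bins, period = period,
                       irf_width = spec$irf_width, irf_t0 = spec$irf_t0)
      lam <- budget * ((1 - spec$background) * p + spec$background / spec$bins)
      draws <- stats::rpois(length(idx) * spec$bins,
                            rep(lam, each = length(idx)))
      m <- matrix(draws, length(idx), spec$bins)
    }
    for (b in seq_len(spec$bins)) counts[idx + (b - 1) * n * n] <- m[, b]
  }
  t_k <- (seq_len(spec$bins) - 0.5) * period / spec$bins
  decay <- decay_image(counts, t_k, period, spec$frequency_hz)
  co <- matrix(0, n, n)
  co[reg == "membrane"] <- 1000
  co[reg == "cytosol"] <- 100
  co <- matrix(stats::rpois(n * n, co), n, n)
  truth <- scene_ground_truth(spec)
  list(decay = decay, co_channel = co, truth = truth)
}

# Ground truth record derived from a scene spec
scene_ground_truth <- function(spec) {
  mem <- spec$membrane
  tau_d <- max(mem$tau)
  if (nrow(mem) == 2) {
    qi <- which.min(mem$tau)
    e_high <- 1 - mem$tau[qi] / tau_d
    f_int <- mem$fraction[qi]
  } else {
    e_high <- 0
    f_int <- 0
  }
  f_mol <- if (e_high < 1) molecular_fraction(f_int, e_high) else 1
  structure(list(
    membrane = as.data.frame(spec$membrane),
    cytosol = as.data.frame(spec$cytosol),
    tau_donor = tau_d,
    e_high = e_high,
    state_fraction_intensity = f_int,
    state_fraction_molecular = f_mol,
    fraction_sd = spec$fraction_sd,
    background = spec$background,
    frequency_hz = spec$frequency_hz,
    seed = spec$seed
  ), class = "ground_truth")
}

#' Write / read scene ground truth as JSON
#'
#' The round trip is lossless: `read_ground_truth(write_ground_truth(x))`
#' reproduces `x` exactly.
#'
#' @param truth A `ground_truth` object.
#' @param path File path.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` returns the `ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$membrane <- as.data.frame(x$membrane)
  x$cytosol <- as.data.frame(x$cytosol)
  structure(x, class = "ground_truth")
}

#' Simulate a conductance-voltage dataset
#'
#' Normalized conductances follow the two-state Boltzmann activation curve
#' G/Gmax = 1/(1 + exp((v_half - V)/v_slope)) with additive Gaussian noise,
#' clipped to [0, 1.05].
#'
#' @param v_half Half-activation voltage in mV.
#' @param v_slope Slope factor in mV, > 0.
#' @param voltages Test potentials in mV (non-empty).
#' @param noise_sd Gaussian noise standard deviation (on the normalized
#'   conductance scale).
#' @param seed Optional integer seed.
#' @return Data frame with columns `voltage_mV`, `g_over_gmax`.
#' @export
make_gv_dataset <- function(v_half, v_slope, voltages = seq(-60, 60, by = 10),
                            noise_sd = 0.02, seed = NULL) {
  if (v_slope <= 0) stop("v_slope must be positive")
  if (length(voltages) == 0) stop("voltage list must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  g <- boltzmann_gv(voltages, v_half, v_slope)
  if (noise_sd > 0) g <- g + stats::rnorm(length(g), sd = noise_sd)
  g <- pmin(pmax(g, 0), 1.05)
  data.frame(voltage_mV = voltages, g_over_gmax = g)
}
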