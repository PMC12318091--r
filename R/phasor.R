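#' Angular frequency of the modulated excitation
#'
#' Converts a laser modulation frequency in Hz to the angular frequency used
#' throughout the package, in rad/ns, optionally at a higher harmonic.
#'
#' @param frequency_hz Modulation frequency in Hz (e.g. `2e7` for 20 MHz).
#' @param harmonic Harmonic index, an integer >= 1.
#' @return Angular frequency in rad/ns.
#' @export
angular_frequency <- function(frequency_hz, harmonic = 1L) {
  if (frequency_hz <= 0) stop("frequency_hz must be positive")
  if (harmonic < 1) stop("harmonic must be >= 1")
  2 * pi * frequency_hz * 1e-9 * harmonic
}

#' Theoretical phasor of a mono-exponential decay
#'
#' For a decay with lifetime `tau` under sinusoidal excitation at angular
#' frequency `omega`, the phasor coordinates are
#' G = 1 / (1 + (omega*tau)^2) and S = omega*tau / (1 + (omega*tau)^2).
#' Every mono-exponential decay lies on the universal semicircle
#' (G - 1/2)^2 + S^2 = 1/4, with tau = 0 at (1, 0) and tau -> Inf
#' approaching the origin.
#'
#' @param tau Lifetime in ns, >= 0. Vectorized.
#' @param omega Angular frequency in rad/ns (see [angular_frequency()]).
#' @return A length-2 numeric `c(G, S)`, or a 2-column matrix when `tau`
#'   has length > 1.
#' @export
mono_phasor <- function(tau, omega) {
  if (any(tau < 0)) stop("tau must be non-negative")
  wt <- omega * tau
  g <- 1 / (1 + wt^2)
  s <- wt / (1 + wt^2)
  if (length(tau) == 1L) c(G = g, S = s) else cbind(G = g, S = s)
}

#' Per-pixel decay image
#'
#' Container for a time-binned fluorescence decay image: a (rows, cols, bins)
#' array of photon counts together with the time grid and modulation
#' frequency. Bin centers must be strictly increasing and lie inside one
#' modulation period.
#'
#' @param counts Numeric array (rows, cols, bins) of non-negative counts.
#' @param bin_centers Bin-center times in ns, strictly increasing, < period.
#' @param period Modulation period in ns.
#' @param frequency_hz Modulation frequency in Hz; defaults to `1e9/period`
#'   (one period per excitation cycle).
#' @return An object of class `decay_image`.
#' @export
decay_image <- function(counts, bin_centers, period,
                        frequency_hz = 1e9 / period) {
  if (length(dim(counts)) != 3L)
    stop("counts must be a (rows, cols, bins) array")
  if (dim(counts)[3] != length(bin_centers))
    stop("third dimension of counts must match length(bin_centers)")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(diff(bin_centers) <= 0)) stop("bin_centers must be strictly increasing")
  if (any(bin_centers >= period)) stop("bin_centers must be < period")
  if (abs(frequency_hz * 1e-9 * period - 1) > 1e-6)
    stop("period and frequency_hz are inconsistent")
  structure(list(counts = counts, bin_centers = bin_centers,
                 period = period, frequency_hz = frequency_hz),
            class = "decay_image")
}

#' @export
print.decay_image <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("decay_image: %d x %d pixels, %d time bins over %.3g ns (%.3g MHz)\n",
              d[1], d[2], d[3], x$period, x$frequency_hz / 1e6))
  cat(sprintf("  total counts: %.4g\n", sum(x$counts)))
  invisible(x)
}

#' Phasor transform of a decay image
#'
#' Computes the per-pixel phasor by discrete sine and cosine transforms of
#' the decay histogram at the requested harmonic of the modulation frequency:
#' G = sum(c_k cos(n w t_k)) / sum(c_k), S = sum(c_k sin(n w t_k)) / sum(c_k),
#' with t_k the bin centers. Pixels with zero total intensity are flagged
#' invalid (G = S = 0, valid = FALSE) rather than propagating NaN.
#'
#' @param decay A [decay_image()].
#' @param harmonic Harmonic index >= 1 (default 1).
#' @return An object of class `phasor_image` with matrices `G`, `S`,
#'   `intensity`, logical `valid`, plus `harmonic`, `omega` (rad/ns) and
#'   `frequency_hz`.
#' @export
decay_to_phasor <- function(decay, harmonic = 1L) {
  stopifnot(inherits(decay, "decay_image"))
  if (harmonic < 1) stop("harmonic must be >= 1")
  d <- dim(decay$counts)
  omega <- angular_frequency(decay$frequency_hz, harmonic)
  t_k <- decay$bin_centers
  m <- matrix(decay$counts, nrow = d[1] * d[2], ncol = d[3])
  intensity <- rowSums(m)
  if (all(intensity == 0)) stop("no pixel with positive intensity")
  gs <- m %*% cbind(cos(omega * t_k), sin(omega * t_k))
  valid <- intensity > 0
  g <- ifelse(valid, gs[, 1] / intensity, 0)
  s <- ifelse(valid, gs[, 2] / intensity, 0)
  structure(list(G = matrix(g, d[1], d[2]),
                 S = matrix(s, d[1], d[2]),
                 intensity = matrix(intensity, d[1], d[2]),
                 valid = matrix(valid, d[1], d[2]),
                 harmonic = as.integer(harmonic),
                 omega = omega,
                 frequency_hz = decay$frequency_hz),
            class = "phasor_image")
}

#' @export
print.phasor_image <- function(x, ...) {
  cat(sprintf("phasor_image: %d x %d pixels, harmonic %d (omega = %.4g rad/ns)\n",
              nrow(x$G), ncol(x$G), x$harmonic, x$omega))
  m <- phasor_mean(x)
  cat(sprintf("  %d valid pixels; intensity-weighted mean (G, S) = (%.4f, %.4f)\n",
              sum(x$valid), m[1], m[2]))
  invisible(x)
}

#' Phasor table as a data frame
#'
#' @param x A `phasor_image`.
#' @param row.names,optional,... Ignored; present for generic compatibility.
#' @return Data frame with 0-based `pixel_x` (column), `pixel_y` (row),
#'   `G`, `S`, `intensity`, `valid`.
#' @export
as.data.frame.phasor_image <- function(x, row.names = NULL, optional = FALSE, ...) {
  nr <- nrow(x$G); nc <- ncol(x$G)
  data.frame(pixel_x = rep(seq_len(nc) - 1L, each = nr),
             pixel_y = rep(seq_len(nr) - 1L, times = nc),
             G = as.vector(x$G), S = as.vector(x$S),
             intensity = as.vector(x$intensity),
             valid = as.vector(x$valid))
}

#' Intensity-weighted mean phasor of the valid (optionally masked) pixels
#'
#' @param phasor A `phasor_image`.
#' @param mask Optional logical matrix selecting pixels.
#' @return `c(G, S)`.
#' @export
phasor_mean <- function(phasor, mask = NULL) {
  sel <- phasor$valid
  if (!is.null(mask)) sel <- sel & mask
  w <- phasor$intensity[sel]
  if (length(w) == 0 || sum(w) == 0) return(c(G = NA_real_, S = NA_real_))
  c(G = sum(phasor$G[sel] * w) / sum(w),
    S = sum(phasor$S[sel] * w) / sum(w))
}

#' Calibration reference for the phasor transform
#'
#' A reference acquisition of a fluorophore with known mono-exponential
#' lifetime (e.g. Atto 425 in water, 3.6 ns) pins down the instrument
#' response: the measured reference phasor is compared with its theoretical
#' position and the complex ratio is applied to every sample pixel.
#'
#' @param measured Measured reference phasor: a `c(G, S)` point or a
#'   `phasor_image` (reduced to its intensity-weighted mean).
#' @param tau_ref Known reference lifetime in ns, > 0.
#' @return An object of class `calibration_ref`.
#' @export
calibration_ref <- function(measured, tau_ref) {
  if (tau_ref <= 0) stop("reference lifetime must be positive")
  if (inherits(measured, "phasor_image")) measured <- phasor_mean(measured)
  measured <- as.numeric(measured)
  mod <- sqrt(sum(measured^2))
  if (mod == 0) stop("degenerate calibration: measured reference modulus is zero")
  structure(list(G = measured[1], S = measured[2], tau_ref = tau_ref),
            class = "calibration_ref")
}

#' Calibrate a phasor image against a reference fluorophore
#'
#' Multiplies every pixel phasor (as a complex number G + iS) by the
#' correction factor theoretical/measured of the reference: equivalently,
#' subtracts the reference phase error and divides by the reference
#' modulation error. Calibrating the reference acquisition itself lands it
#' exactly on its theoretical semicircle position.
#'
#' @param phasor A `phasor_image`.
#' @param ref A [calibration_ref()].
#' @return A calibrated `phasor_image`.
#' @export
calibrate <- function(phasor, ref) {
  stopifnot(inherits(phasor, "phasor_image"), inherits(ref, "calibration_ref"))
  meas <- complex(real = ref$G, imaginary = ref$S)
  if (Mod(meas) == 0) stop("degenerate calibration: zero reference modulus")
  theo <- mono_phasor(ref$tau_ref, phasor$omega)
  fac <- complex(real = theo[1], imaginary = theo[2]) / meas
  z <- complex(real = phasor$G, imaginary = phasor$S) * fac
  out <- phasor
  out$G <- matrix(Re(z), nrow(phasor$G), ncol(phasor$G))
  out$S <- matrix(Im(z), nrow(phasor$G), ncol(phasor$G))
  out$G[!phasor$valid] <- 0
  out$S[!phasor$valid] <- 0
  out
}

#' Phase and modulation lifetimes of a phasor point
#'
#' tau_phi = tan(phase)/omega and tau_m = sqrt(1/(G^2+S^2) - 1)/omega.
#' The two agree exactly for points on the universal semicircle
#' (mono-exponential decays); mixtures and background displace the point
#' inside the semicircle, where tau_m > tau_phi.
#'
#' @param point Phasor point `c(G, S)`.
#' @param omega Angular frequency in rad/ns.
#' @return `c(tau_phi, tau_m)` in ns.
#' @export
phase_mod_lifetimes <- function(point, omega) {
  g <- point[1]; s <- point[2]
  mod2 <- g^2 + s^2
  if (mod2 > 1 + 1e-9)
    stop("phasor modulus exceeds 1: out of physical range (mis-calibration?)")
  if (mod2 == 0) stop("zero-modulus phasor has no defined lifetime")
  if (g <= 0 && s <= 0) stop("phasor in non-physical quadrant")
  tau_phi <- tan(atan2(s, g)) / omega
  tau_m <- sqrt(max(1 / mod2 - 1, 0)) / omega
  c(tau_phi = tau_phi, tau_m = tau_m)
}

# replicate-pad a matrix by k pixels on each side
pad_replicate <- function(m, k) {
  ri <- pmin(pmax(seq_len(nrow(m) + 2 * k) - k, 1), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m) + 2 * k) - k, 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

filter_median <- function(m, valid, size) {
  k <- (size - 1L) %/% 2L
  mp <- pad_replicate(m, k)
  vp <- pad_replicate(valid, k)
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  offs <- expand.grid(di = -k:k, dj = -k:k)
  # stack of shifted neighborhoods: rows = pixels, cols = kernel offsets
  stk <- vapply(seq_len(nrow(offs)), function(o) {
    as.vector(mp[(1 + k + offs$di[o]):(nr + k + offs$di[o]),
                 (1 + k + offs$dj[o]):(nc + k + offs$dj[o])])
  }, numeric(nr * nc))
  vst <- vapply(seq_len(nrow(offs)), function(o) {
    as.vector(vp[(1 + k + offs$di[o]):(nr + k + offs$di[o]),
                 (1 + k + offs$dj[o]):(nc + k + offs$dj[o])])
  }, logical(nr * nc))
  res <- vapply(seq_len(nr * nc), function(i) {
    v <- stk[i, vst[i, ]]
    if (length(v) == 0) m[i] else stats::median(v)
  }, numeric(1))
  matrix(res, nr, nc)
}

filter_gaussian <- function(m, valid, size) {
  k <- (size - 1L) %/% 2L
  sigma <- if (k == 0) 1 else size / 4  # kernel tapers to ~2 sigma at edge
  w1 <- stats::dnorm(-k:k, sd = sigma)
  ker <- outer(w1, w1)
  mp <- pad_replicate(m * valid, k)
  vp <- pad_replicate(valid * 1, k)
  nr <- nrow(m); nc <- ncol(m)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  for (di in -k:k) for (dj in -k:k) {
    wt <- ker[di + k + 1, dj + k + 1]
    num <- num + wt * mp[(1 + k + di):(nr + k + di), (1 + k + dj):(nc + k + dj)]
    den <- den + wt * vp[(1 + k + di):(nr + k + di), (1 + k + dj):(nc + k + dj)]
  }
  out <- m
  pos <- den > 0
  out[pos] <- num[pos] / den[pos]
  out
}

#' Spatially smooth the G and S maps of a phasor image
#'
#' Filters the G and S coordinate maps independently with a median or
#' normalized Gaussian kernel; the intensity map is left untouched. Invalid
#' pixels are excluded from every neighborhood so zero-intensity regions do
#' not bleed into the membrane. Kernel size 1 is the identity.
#'
#' @param image A `phasor_image`.
#' @param method `"median"` or `"gaussian"`.
#' @param size Odd kernel size in pixels, >= 1.
#' @return The smoothed `phasor_image`.
#' @export
smooth_phasor <- function(image, method = c("median", "gaussian"), size = 3L) {
  stopifnot(inherits(image, "phasor_image"))
  method <- match.arg(method)
  if (size < 1 || size %% 2 == 0) stop("kernel size must be odd and >= 1")
  if (size == 1L) return(image)
  f <- if (method == "median") filter_median else filter_gaussian
  out <- image
  out$G <- f(image$G, image$valid, size)
  out$S <- f(image$S, image$valid, size)
  out$G[!image$valid] <- 0
  out$S[!image$valid] <- 0
  out
}

#' Intensity-based membrane mask
#'
#' Selects pixels whose co-channel intensity (e.g. membrane-targeted YFP)
#' is at or above the stated quantile of the nonzero pixels, emulating
#' intensity-based selection of the membrane region.
#'
#' @param co_channel Intensity matrix.
#' @param threshold_quantile Quantile in (0, 1) of the nonzero intensities.
#' @return Logical matrix, `TRUE` on selected pixels.
#' @export
mask_membrane <- function(co_channel, threshold_quantile = 0.9) {
  if (threshold_quantile <= 0 || threshold_quantile >= 1)
    stop("threshold_quantile must be in (0, 1)")
  nz <- co_channel[co_channel > 0]
  if (length(nz) == 0) {
    warning("all-zero co-channel image: empty mask")
    return(matrix(FALSE, nrow(co_channel), ncol(co_channel)))
  }
  thr <- stats::quantile(nz, threshold_quantile, names = FALSE, type = 7)
  co_channel >= thr & co_channel > 0
}
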