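#' FRET-trajectory model
#'
#' One-parameter family of mixture phasors tracing the path a donor
#' population follows as FRET quenching increases: it starts at the
#' donor-alone phasor (E = 0) and ends at the background phasor (default the
#' origin, where uncorrelated background sits) at the theoretical 100% FRET
#' limit. Quenching shortens the donor lifetime to tau_D * (1 - E) and also
#' dims the donor by the factor (1 - E), while background photons are
#' unaffected; the trajectory point is the photon-weighted mean of the two.
#'
#' @param tau_donor Donor-alone lifetime in ns, > 0.
#' @param f_bg Background intensity fraction at E = 0, in [0, 1).
#' @param bg Background phasor `c(G, S)` (default origin).
#' @param frequency_hz Modulation frequency in Hz.
#' @param harmonic Harmonic index >= 1.
#' @return An object of class `fret_trajectory`.
#' @export
fret_trajectory <- function(tau_donor, f_bg = 0, bg = c(0, 0),
                            frequency_hz = 2e7, harmonic = 1L) {
  if (tau_donor <= 0) stop("tau_donor must be positive")
  if (f_bg < 0 || f_bg >= 1) stop("f_bg must be in [0, 1)")
  if (sum(bg^2) > 1 + 1e-9) stop("background phasor outside the unit circle")
  structure(list(tau_donor = tau_donor, f_bg = f_bg, bg = as.numeric(bg),
                 omega = angular_frequency(frequency_hz, harmonic),
                 frequency_hz = frequency_hz, harmonic = as.integer(harmonic)),
            class = "fret_trajectory")
}

#' @export
print.fret_trajectory <- function(x, ...) {
  cat(sprintf("FRET trajectory: tau_donor = %.3g ns, f_bg = %.3g, bg = (%.3g, %.3g)\n",
              x$tau_donor, x$f_bg, x$bg[1], x$bg[2]))
  invisible(x)
}

#' Phasor position along a FRET trajectory
#'
#' @param model A [fret_trajectory()].
#' @param E FRET efficiencies in [0, 1]; vectorized.
#' @return A 2-column matrix of (G, S), or `c(G, S)` for scalar `E`.
#' @export
trajectory_point <- function(model, E) {
  stopifnot(inherits(model, "fret_trajectory"))
  if (any(E < 0 | E > 1)) stop("E must be in [0, 1]")
  # photon weights: donor dimmed by (1 - E), background constant
  w_d <- (1 - model$f_bg) * (1 - E)
  w_b <- model$f_bg
  tot <- w_d + w_b
  donor <- mono_phasor(model$tau_donor * (1 - E), model$omega)
  if (length(E) == 1L) donor <- matrix(donor, 1, 2)
  g <- ifelse(tot > 0, (w_d * donor[, 1] + w_b * model$bg[1]) / tot, model$bg[1])
  s <- ifelse(tot > 0, (w_d * donor[, 2] + w_b * model$bg[2]) / tot, model$bg[2])
  if (length(E) == 1L) c(G = g, S = s) else cbind(G = g, S = s)
}

#' Fit an apparent FRET efficiency by the trajectory method
#'
#' Finds the efficiency whose trajectory point is closest (Euclidean
#' distance in the phasor plane) to the measured phasor. The measurement may
#' be a single `c(G, S)` point or a `phasor_image` (optionally masked), which
#' is reduced to its intensity-weighted mean first — the trajectory method is
#' an ensemble readout and reports a single averaged efficiency. The search
#' runs on a dense grid (step 1e-3) refined by golden-section; ties break
#' toward smaller E.
#'
#' @param measured `c(G, S)` point or a `phasor_image`.
#' @param model A [fret_trajectory()].
#' @param mask Optional logical matrix when `measured` is a `phasor_image`.
#' @return Object of class `trajectory_fit`: `e_app`, `residual` (phasor
#'   units), `point` (fitted trajectory point), `measured`, `n_pixels`.
#' @export
fit_trajectory <- function(measured, model, mask = NULL) {
  stopifnot(inherits(model, "fret_trajectory"))
  n_pixels <- 1L
  if (inherits(measured, "phasor_image")) {
    n_pixels <- if (is.null(mask)) sum(measured$valid) else
      sum(measured$valid & mask)
    measured <- phasor_mean(measured, mask)
  }
  measured <- as.numeric(measured)
  if (any(!is.finite(measured))) stop("measured phasor is not finite")
  if (sum(measured^2) > (1 + 1e-6)^2)
    stop("measured phasor modulus exceeds 1: mis-calibrated input")
  d2 <- function(E) {
    p <- trajectory_point(model, E)
    (p[1] - measured[1])^2 + (p[2] - measured[2])^2
  }
  grid <- seq(0, 1, by = 1e-3)
  pts <- trajectory_point(model, grid)
  dd <- (pts[, 1] - measured[1])^2 + (pts[, 2] - measured[2])^2
  i <- which.min(dd)  # which.min takes the first minimum: ties go to smaller E
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(d2, c(lo, hi), tol = 1e-9)
  e_app <- opt$minimum
  if (d2(grid[i]) <= opt$objective) e_app <- grid[i]
  e_app <- min(max(e_app, 0), 1)
  structure(list(e_app = e_app, residual = sqrt(d2(e_app)),
                 point = trajectory_point(model, e_app),
                 measured = c(G = measured[1], S = measured[2]),
                 n_pixels = n_pixels, model = model),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("FRET trajectory fit: E_app = %.4f (residual %.3g phasor units, %d pixels)\n",
              x$e_app, x$residual, x$n_pixels))
  invisible(x)
}

#' @export
coef.trajectory_fit <- function(object, ...) c(e_app = object$e_app)
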