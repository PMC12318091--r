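#' Remove a uniform background contribution from phasor points
#'
#' By the phasor-addition law a measured point with background fraction `b`
#' is P = (1-b) * P_true + b * bg; this inverts the mixing:
#' P_true = (P - b * bg) / (1 - b). `b = 0` is the identity.
#'
#' @param points 2-column matrix (G, S) or a single `c(G, S)`.
#' @param b Background intensity fraction in [0, 1).
#' @param bg Background phasor (default origin).
#' @return Corrected points, same shape as the input.
#' @export
correct_background <- function(points, b, bg = c(0, 0)) {
  if (b < 0 || b >= 1) stop("background fraction must be in [0, 1)")
  vec <- is.null(dim(points))
  p <- if (vec) matrix(as.numeric(points), 1, 2) else as.matrix(points)
  out <- cbind((p[, 1] - b * bg[1]) / (1 - b),
               (p[, 2] - b * bg[2]) / (1 - b))
  colnames(out) <- c("G", "S")
  if (vec) c(G = unname(out[1, 1]), S = unname(out[1, 2])) else out
}

#' Intensity-weighted major axis of a phasor cluster
#'
#' First principal axis of the intensity-weighted covariance of (G, S):
#' a total-least-squares line through the cluster. The elongation ratio
#' (major/minor axis length, i.e. sqrt of the eigenvalue ratio) measures how
#' line-like the cluster is; an isotropic cloud has elongation near 1 and is
#' flagged as having no usable unmixing axis.
#'
#' @param points 2-column matrix of (G, S); >= 3 distinct points.
#' @param weights Non-negative weights (pixel intensities); default equal.
#' @param min_elongation Elongation below which `axis_ok` is `FALSE`
#'   (default 1.2).
#' @return List with `center` (weighted mean), `direction` (unit vector),
#'   `elongation` (capped at 1e6 when the minor axis is numerically zero),
#'   and `axis_ok`.
#' @export
fit_major_axis <- function(points, weights = NULL, min_elongation = 1.2) {
  p <- as.matrix(points)
  if (nrow(p) < 3) stop("need at least 3 points")
  if (is.null(weights)) weights <- rep(1, nrow(p))
  if (any(weights < 0)) stop("weights must be non-negative")
  w <- weights / sum(weights)
  ctr <- colSums(p * w)
  d <- sweep(p, 2, ctr)
  if (max(abs(d)) < 1e-14) stop("degenerate cluster: all points identical")
  cv <- crossprod(d * sqrt(w))
  e <- eigen(cv, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  elong <- if (lam[2] <= lam[1] * 1e-12) 1e6 else sqrt(lam[1] / lam[2])
  dir <- e$vectors[, 1]
  if (dir[1] < 0) dir <- -dir  # orient toward increasing G
  list(center = c(G = ctr[1], S = ctr[2]),
       direction = c(G = dir[1], S = dir[2]),
       elongation = min(elong, 1e6),
       axis_ok = elong >= min_elongation)
}

#' Intersection of a fitted line with the universal semicircle
#'
#' Solves for the points where the line `center + t * direction` meets
#' (G - 1/2)^2 + S^2 = 1/4 with S >= 0, and returns the intersection with
#' the larger G — the shorter-lifetime end, i.e. the pure high-FRET species
#' the cluster's chord points at.
#'
#' @param line A list with `center` and `direction` (as from
#'   [fit_major_axis()]).
#' @return Phasor point `c(G, S)` on the semicircle.
#' @export
semicircle_endpoint <- function(line) {
  p0 <- as.numeric(line$center) - c(0.5, 0)
  d <- as.numeric(line$direction)
  d <- d / sqrt(sum(d^2))
  # |p0 + t d|^2 = 1/4
  bq <- 2 * sum(p0 * d)
  cq <- sum(p0^2) - 0.25
  disc <- bq^2 - 4 * cq
  if (disc < 0)
    stop("line does not intersect the universal semicircle: no pure quenched endpoint")
  ts <- (-bq + c(-1, 1) * sqrt(disc)) / 2
  cand <- cbind(0.5 + p0[1] + ts * d[1], p0[2] + ts * d[2])
  cand <- cand[cand[, 2] >= -1e-12, , drop = FALSE]
  if (nrow(cand) == 0)
    stop("line meets the circle only at S < 0: no physical endpoint")
  i <- which.max(cand[, 1])
  c(G = cand[i, 1], S = max(cand[i, 2], 0))
}

# closest point on the semicircle to a point (fallback when the fitted line
# misses the circle)
nearest_semicircle_point <- function(pt) {
  v <- as.numeric(pt) - c(0.5, 0)
  if (sum(v^2) == 0) return(c(G = 1, S = 0))
  v <- v / sqrt(sum(v^2)) / 2
  c(G = 0.5 + v[1], S = max(v[2], 0))
}

# lifetime of a point on the universal semicircle (phase lifetime)
semicircle_lifetime <- function(pt, omega) {
  if (pt[1] <= 0) return(Inf)
  as.numeric(pt[2] / (pt[1] * omega))
}

#' Molecular fraction from an intensity fraction
#'
#' FRET quenching dims the high-FRET species by its relative brightness
#' a = 1 - E_high, so the intensity fraction read off the phasor chord
#' understates the fraction of molecules in that state:
#' f_mol = f_int / (a * (1 - f_int) + f_int). Always >= f_int.
#'
#' @param f_int Intensity fraction in [0, 1].
#' @param e_high High-FRET efficiency in [0, 1).
#' @return Molecular fraction in [0, 1].
#' @export
molecular_fraction <- function(f_int, e_high) {
  if (any(f_int < 0 | f_int > 1)) stop("f_int must be in [0, 1]")
  if (any(e_high < 0 | e_high > 1)) stop("e_high must be in [0, 1]")
  if (any(e_high == 1 & f_int < 1))
    stop("undefined brightness: E_high = 1 leaves the quenched species dark")
  a <- 1 - e_high
  f_int / (a * (1 - f_int) + f_int)
}

#' Configuration for two-state linear unmixing
#'
#' The four parameters of the unmixing procedure: background fractions in
#' the donor-alone (`b1`) and donor+acceptor (`b2`) samples, the background
#' phasor, and the donor-alone reference — either a measured donor phasor
#' (preferred when supplied; background-corrected with `b1`) or a donor
#' lifetime placed on the semicircle.
#'
#' @param donor_tau Donor-alone lifetime in ns (used if no phasor given).
#' @param donor_phasor Optional measured donor-alone phasor `c(G, S)`.
#' @param b1,b2 Background intensity fractions in [0, 1).
#' @param bg Background phasor (default origin).
#' @param frequency_hz Modulation frequency in Hz.
#' @param harmonic Harmonic index.
#' @return Object of class `unmix_config`.
#' @export
unmix_config <- function(donor_tau = 12, donor_phasor = NULL,
                         b1 = 0, b2 = 0, bg = c(0, 0),
                         frequency_hz = 2e7, harmonic = 1L) {
  if (b1 < 0 || b1 >= 1 || b2 < 0 || b2 >= 1) stop("b1, b2 must be in [0, 1)")
  structure(list(donor_tau = donor_tau, donor_phasor = donor_phasor,
                 b1 = b1, b2 = b2, bg = as.numeric(bg),
                 omega = angular_frequency(frequency_hz, harmonic),
                 frequency_hz = frequency_hz, harmonic = as.integer(harmonic)),
            class = "unmix_config")
}

#' Two-state linear unmixing of a phasor cluster
#'
#' Resolves a membrane phasor cloud into donor-alone and high-FRET species
#' by the phasor-addition law: background-correct the cluster, fit its
#' intensity-weighted major axis, extend the axis to the universal
#' semicircle to locate the pure high-FRET endpoint P_F, and read the state
#' fraction as the relative distance of the (projected) cluster mean from
#' the donor endpoint P_D along the chord. Fractional contributions of
#' lifetime species are inversely related to their distance from the
#' composite point, so f_int = |Pbar - P_D| / |P_F - P_D|.
#'
#' When the fitted axis misses the semicircle the nearest semicircle point
#' to the extrapolated end is used and the result is flagged
#' (`endpoint_fallback = TRUE`). Fractions outside [0, 1] from noise are
#' clamped with a warning.
#'
#' @param cluster A `phasor_image` (optionally masked) or 2-column (G, S)
#'   matrix.
#' @param config An [unmix_config()].
#' @param mask Optional logical matrix when `cluster` is a `phasor_image`.
#' @param weights Optional weights for a matrix cluster.
#' @return Object of class `unmix_result`: `e_high`, `f_int`, `f_mol`,
#'   `p_donor`, `p_fret`, `line`, `elongation`, `axis_ok`,
#'   `endpoint_fallback`, `n_pixels`.
#' @export
unmix_two_state <- function(cluster, config, mask = NULL, weights = NULL) {
  stopifnot(inherits(config, "unmix_config"))
  if (inherits(cluster, "phasor_image")) {
    sel <- if (is.null(mask)) cluster$valid else cluster$valid & mask
    pts <- cbind(cluster$G[sel], cluster$S[sel])
    weights <- cluster$intensity[sel]
  } else {
    pts <- as.matrix(cluster)
    if (is.null(weights)) weights <- rep(1, nrow(pts))
  }
  if (nrow(pts) < 1) stop("empty cluster")
  pts <- correct_background(pts, config$b2, config$bg)
  if (is.null(dim(pts))) pts <- matrix(pts, 1, 2)

  # donor reference: measured phasor wins over the lifetime
  p_d <- if (!is.null(config$donor_phasor)) {
    correct_background(as.numeric(config$donor_phasor), config$b1, config$bg)
  } else {
    mono_phasor(config$donor_tau, config$omega)
  }

  pbar <- c(sum(pts[, 1] * weights), sum(pts[, 2] * weights)) / sum(weights)

  if (nrow(pts) >= 3 && max(abs(sweep(pts, 2, pbar))) > 1e-14) {
    line <- fit_major_axis(pts, weights)
    if (!line$axis_ok) {
      # isotropic cluster: no usable major axis; anchor the chord at the
      # donor reference instead and keep the flag
      d <- pbar - as.numeric(p_d)
      if (sqrt(sum(d^2)) >= 1e-14)
        line <- list(center = pbar, direction = d / sqrt(sum(d^2)),
                     elongation = line$elongation, axis_ok = FALSE)
    }
  } else {
    # single point (or collinear-degenerate): chord through donor and point
    d <- pbar - as.numeric(p_d)
    if (sqrt(sum(d^2)) < 1e-14) d <- c(1, 0) * -1  # at the donor: f = 0
    line <- list(center = pbar, direction = d / sqrt(sum(d^2)),
                 elongation = NA_real_, axis_ok = TRUE)
  }

  endpoint_fallback <- FALSE
  p_f <- tryCatch(semicircle_endpoint(line), error = function(e) {
    endpoint_fallback <<- TRUE
    far <- line$center + sign(sum((line$center - p_d) * line$direction)) *
      line$direction
    nearest_semicircle_point(far)
  })

  tau_d <- semicircle_lifetime(p_d, config$omega)
  tau_f <- semicircle_lifetime(p_f, config$omega)
  e_high <- 1 - tau_f / tau_d
  if (e_high < -1e-6 || e_high > 1 + 1e-6)
    stop("inconsistent references: high-FRET efficiency outside [0, 1]")
  e_high <- min(max(e_high, 0), 1)

  # project the cluster mean onto the fitted line before taking distances
  u <- line$direction
  proj <- line$center + sum((pbar - line$center) * u) * u
  chord <- as.numeric(p_f) - as.numeric(p_d)
  f_int <- sum((proj - as.numeric(p_d)) * chord) / sum(chord^2)
  if (f_int < -1e-9 || f_int > 1 + 1e-9)
    warning("state fraction outside [0, 1]; clamped")
  f_int <- min(max(f_int, 0), 1)
  f_mol <- if (e_high < 1) molecular_fraction(f_int, e_high) else 1

  structure(list(e_high = e_high, f_int = f_int, f_mol = f_mol,
                 p_donor = c(G = p_d[[1]], S = p_d[[2]]),
                 p_fret = p_f,
                 line = line, elongation = line$elongation,
                 axis_ok = line$axis_ok,
                 endpoint_fallback = endpoint_fallback,
                 n_pixels = nrow(pts)),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  cat("Two-state phasor unmixing\n")
  cat(sprintf("  high-FRET efficiency E_high = %.3f\n", x$e_high))
  cat(sprintf("  state fraction: intensity %.3f, molecular %.3f\n",
              x$f_int, x$f_mol))
  cat(sprintf("  endpoints P_D = (%.4f, %.4f), P_F = (%.4f, %.4f)\n",
              x$p_donor[1], x$p_donor[2], x$p_fret[1], x$p_fret[2]))
  if (!is.na(x$elongation))
    cat(sprintf("  cluster elongation %.3g%s\n", x$elongation,
                if (!x$axis_ok) " (no clear unmixing axis)" else ""))
  if (x$endpoint_fallback)
    cat("  note: fitted axis missed the semicircle; nearest point used\n")
  invisible(x)
}

#' @export
coef.unmix_result <- function(object, ...) {
  c(e_high = object$e_high, f_int = object$f_int, f_mol = object$f_mol)
}
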