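#' Boltzmann activation curve
#'
#' Two-state voltage activation: G/Gmax = 1 / (1 + exp((v_half - v)/v_slope)).
#'
#' @param v Membrane potential(s) in mV.
#' @param v_half Half-activation voltage in mV.
#' @param v_slope Slope factor in mV, > 0.
#' @return Normalized conductance(s).
#' @export
boltzmann_gv <- function(v, v_half, v_slope) {
  if (v_slope <= 0) stop("v_slope must be positive")
  1 / (1 + exp((v_half - v) / v_slope))
}

# gas constant in kcal/(mol K)
R_GAS <- 1.987e-3

#' Fit a Boltzmann function to a conductance-voltage relationship
#'
#' Least-squares fit of G/Gmax = 1/(1 + exp((V1/2 - V)/Vs)). Initialization
#' scans a deterministic coarse grid of (V1/2, Vs) and the best cell is
#' refined by Nelder-Mead; the fit therefore has no seed dependence. The
#' gating free energy at 0 mV is reported as dG = R T V1/2 / Vs (positive
#' when the channel favors the closed state at 0 mV).
#'
#' @param data Data frame with columns `voltage_mV` and `g_over_gmax`
#'   (e.g. from [make_gv_dataset()]), or a voltage vector.
#' @param g Normalized conductances when `data` is a voltage vector.
#' @param temperature Temperature in K (default 297).
#' @return Object of class `boltzmann_fit` with components `coefficients`
#'   (`v_half`, `v_slope`), `dG` (kcal/mol), `rss`, `fitted.values`,
#'   `residuals`, `data`, `temperature`.
#' @export
fit_boltzmann <- function(data, g = NULL, temperature = 297) {
  if (is.data.frame(data)) {
    v <- data$voltage_mV; y <- data$g_over_gmax
  } else {
    v <- as.numeric(data); y <- as.numeric(g)
  }
  if (length(v) != length(y) || any(!is.finite(v)) || any(!is.finite(y)))
    stop("voltages and conductances must be finite and of equal length")
  if (length(v) < 4) stop("need at least 4 points to fit a Boltzmann")
  sse <- function(par) sum((y - boltzmann_gv(v, par[1], exp(par[2])))^2)
  # deterministic multi-start: midpoints across the voltage span, a ladder
  # of slope factors
  v_grid <- seq(min(v), max(v), length.out = 15)
  s_grid <- c(2, 4, 8, 16, 32, 64)
  grid <- expand.grid(vh = v_grid, vs = s_grid)
  obj <- mapply(function(vh, vs) sse(c(vh, log(vs))), grid$vh, grid$vs)
  best <- grid[which.min(obj), ]
  opt <- stats::optim(c(best$vh, log(best$vs)), sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (opt$convergence != 0)
    stop(sprintf("Boltzmann fit failed to converge (optim code %d, RSS %.3g)",
                 opt$convergence, opt$value))
  v_half <- opt$par[1]; v_slope <- exp(opt$par[2])
  fitted <- boltzmann_gv(v, v_half, v_slope)
  structure(list(coefficients = c(v_half = v_half, v_slope = v_slope),
                 dG = R_GAS * temperature * v_half / v_slope,
                 rss = opt$value,
                 fitted.values = fitted,
                 residuals = y - fitted,
                 data = data.frame(voltage_mV = v, g_over_gmax = y),
                 temperature = temperature),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann G-V fit: V1/2 = %.2f mV, Vs = %.2f mV\n",
              x$coefficients["v_half"], x$coefficients["v_slope"]))
  cat(sprintf("  dG(0 mV) = %.2f kcal/mol at %g K; RSS = %.3g (n = %d)\n",
              x$dG, x$temperature, x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) object$coefficients

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$voltage_mV
       else if (is.data.frame(newdata)) newdata$voltage_mV
       else as.numeric(newdata)
  boltzmann_gv(v, object$coefficients["v_half"], object$coefficients["v_slope"])
}

#' @export
residuals.boltzmann_fit <- function(object, ...) object$residuals

#' @export
fitted.boltzmann_fit <- function(object, ...) object$fitted.values

#' @export
summary.boltzmann_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Gating free energy from a state fraction
#'
#' Boltzmann free energy difference between closed and open channel given
#' the fraction p of voltage sensors in the activated (high-FRET) state:
#' dG = -n R T ln(p / (1 - p)), with n the number of subunits whose
#' activation the open state requires. Positive dG means the channel favors
#' the closed state.
#'
#' @param p State probability in (0, 1). Vectorized.
#' @param n Subunit exponent (default 3, the threshold of the 3-of-4 model).
#' @param temperature Temperature in K (default 297).
#' @return dG in kcal/mol.
#' @export
dg_from_fraction <- function(p, n = 3, temperature = 297) {
  if (any(p <= 0 | p >= 1))
    stop("p in {0, 1} gives infinite energy; p must be in (0, 1)")
  if (any(n < 1)) stop("n must be >= 1")
  -n * R_GAS * temperature * log(p / (1 - p))
}

#' Open probability of a k-of-4 subunit gating model
#'
#' Tetrameric channel that conducts when at least `k` of its 4 independent
#' subunits are activated, each with probability `p`: the binomial tail
#' P_open = sum_{j=k}^{4} C(4,j) p^j (1-p)^(4-j).
#'
#' @param p Per-subunit activation probability in [0, 1]. Vectorized.
#' @param k Activation threshold, an integer in 1..4 (default 3).
#' @return Open probability in [0, 1].
#' @export
p_open_binomial <- function(p, k = 3L) {
  if (!k %in% 1:4) stop("k must be in {1, 2, 3, 4}")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  stats::pbinom(k - 1, size = 4, prob = p, lower.tail = FALSE)
}

#' Compare k-of-4 subunit gating models
#'
#' For each state probability and each activation threshold k = 1..4,
#' tabulates the open probability (binomial tail) and the gating free energy
#' (with exponent n = k).
#'
#' @param p_values State probabilities in (0, 1).
#' @param temperature Temperature in K.
#' @return Data frame with columns `k`, `p`, `p_open`, `dG_kcal_mol`,
#'   sorted by k.
#' @export
scan_subunit_models <- function(p_values, temperature = 297) {
  if (any(p_values <= 0 | p_values >= 1)) stop("all p must be in (0, 1)")
  out <- expand.grid(p = p_values, k = 1:4)
  out <- out[order(out$k, out$p), c("k", "p")]
  out$p_open <- p_open_binomial(out$p, k = 1)  # placeholder, filled per k
  for (k in 1:4) out$p_open[out$k == k] <-
    p_open_binomial(out$p[out$k == k], k = k)
  out$dG_kcal_mol <- dg_from_fraction(out$p, n = out$k,
                                      temperature = temperature)
  rownames(out) <- NULL
  out
}
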