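# 32-bit TIFF samples are stored scaled to [0, 1]; integer counts below
# 2^32 survive the round trip exactly (doubles carry 53 bits).
TIFF_SCALE <- 2^32 - 1

#' Write a decay image as a multi-page TIFF plus JSON sidecar
#'
#' Page k of the TIFF holds the counts of time bin k as 32-bit samples; the
#' sidecar records the time axis: `frequency_hz`, `period_ns`,
#' `bin_edges_ns` (bins + 1 edges; centers are midpoints) and optionally a
#' seed.
#'
#' @param decay A [decay_image()].
#' @param tiff_path,json_path Output paths.
#' @param seed Optional integer recorded in the sidecar.
#' @return `tiff_path`, invisibly.
#' @export
write_decay_stack <- function(decay, tiff_path, json_path, seed = NULL) {
  stopifnot(inherits(decay, "decay_image"))
  nb <- dim(decay$counts)[3]
  pages <- lapply(seq_len(nb), function(b) decay$counts[, , b] / TIFF_SCALE)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32)
  dt <- diff(decay$bin_centers)
  edges <- c(decay$bin_centers[1] - dt[1] / 2,
             decay$bin_centers + c(dt, dt[length(dt)]) / 2)
  meta <- list(frequency_hz = decay$frequency_hz, period_ns = decay$period,
               bin_edges_ns = edges)
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' Read a decay image from a multi-page TIFF plus JSON sidecar
#'
#' @param tiff_path Multi-page TIFF, one page per time bin.
#' @param json_path Sidecar with `frequency_hz`, `period_ns`, `bin_edges_ns`.
#' @return A [decay_image()].
#' @export
read_decay_stack <- function(tiff_path, json_path) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  for (f in c("frequency_hz", "period_ns", "bin_edges_ns"))
    if (is.null(meta[[f]]))
      stop(sprintf("decay metadata is missing field '%s'", f))
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nb <- length(meta$bin_edges_ns) - 1L
  if (length(pages) != nb)
    stop(sprintf("decay stack has %d pages but metadata describes %d time bins",
                 length(pages), nb))
  counts <- array(0, c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) counts[, , b] <- round(pages[[b]] * TIFF_SCALE)
  centers <- (meta$bin_edges_ns[-1] + meta$bin_edges_ns[-(nb + 1)]) / 2
  decay_image(counts, centers, meta$period_ns, meta$frequency_hz)
}

#' Write an intensity image as a single-page TIFF
#'
#' @param image Intensity matrix (counts).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_tiff <- function(image, path) {
  tiff::writeTIFF(image / TIFF_SCALE, path, bits.per.sample = 32)
  invisible(path)
}

#' @rdname write_intensity_tiff
#' @export
read_intensity_tiff <- function(path) {
  round(tiff::readTIFF(path) * TIFF_SCALE)
}

#' Write / read a phasor table CSV
#'
#' Columns: `pixel_x`, `pixel_y` (0-based, x = column and y = row), `G`,
#' `S`, `intensity`, `valid`.
#'
#' @param phasor A `phasor_image`.
#' @param path CSV path.
#' @return `write_phasor_table` returns `path` invisibly;
#'   `read_phasor_table` returns the table as a data frame.
#' @export
write_phasor_table <- function(phasor, path) {
  utils::write.csv(as.data.frame(phasor), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phasor_table
#' @export
read_phasor_table <- function(path) utils::read.csv(path)

# stable hash of a config for provenance (md5 of its canonical JSON)
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full phasor FLIM-tmFRET pipeline on a synthetic scene
#'
#' Binds the stages end to end: simulate a scene (and a reference
#' acquisition of a fluorophore with known lifetime, used for IRF
#' calibration), transform to phasors, smooth, mask the membrane, fit the
#' FRET trajectory, unmix the two-state cluster, convert efficiencies to
#' mean distances through the FCG model, and tabulate subunit-gating
#' energetics from the recovered state fraction.
#'
#' @param spec A [scene_spec()] describing the acquisition.
#' @param ref_tau Reference-fluorophore lifetime in ns used for calibration
#'   (default 3.6, Atto 425 in water).
#' @param harmonic Phasor harmonic.
#' @param smooth_method,smooth_size Spatial filter for the G/S maps.
#' @param mask_quantile Membrane-mask intensity quantile.
#' @param b1,b2 Background fractions for unmixing (default: the scene's
#'   background fraction for both samples).
#' @param fcg An [fcg_model()] for distance conversion.
#' @param subunit_k Activation threshold of the k-of-4 gating model.
#' @param temperature Temperature in K.
#' @return Object of class `pipeline_result`: the per-stage results
#'   (`phasor`, `mask`, `trajectory`, `unmix`, `distances`, `energetics`)
#'   plus provenance (`config_hash`, `seed`, package version).
#' @export
run_pipeline <- function(spec,
                         ref_tau = 3.6,
                         harmonic = 1L,
                         smooth_method = "median",
                         smooth_size = 3L,
                         mask_quantile = 0.9,
                         b1 = spec$background,
                         b2 = spec$background,
                         fcg = fcg_model(),
                         subunit_k = 3L,
                         temperature = 297) {
  stopifnot(inherits(spec, "scene_spec"))
  config <- list(spec = unclass(spec), ref_tau = ref_tau, harmonic = harmonic,
                 smooth_method = smooth_method, smooth_size = smooth_size,
                 mask_quantile = mask_quantile, b1 = b1, b2 = b2,
                 fcg = unclass(fcg), subunit_k = subunit_k,
                 temperature = temperature)

  scene <- make_scene(spec)
  period <- 1e9 / spec$frequency_hz

  # reference acquisition: mono-exponential fluorophore of known lifetime,
  # noise-free through the same binning and IRF as the sample
  ref_hist <- expected_decay(lifetime_mixture(ref_tau, 1), bins = spec$bins,
                             period = period, irf_width = spec$irf_width,
                             irf_t0 = spec$irf_t0)
  ref_decay <- decay_image(array(ref_hist, c(1, 1, spec$bins)),
                           attr(ref_hist, "bin_centers"), period,
                           spec$frequency_hz)
  ref <- calibration_ref(decay_to_phasor(ref_decay, harmonic), ref_tau)

  phasor <- calibrate(decay_to_phasor(scene$decay, harmonic), ref)
  mask <- mask_membrane(scene$co_channel, mask_quantile)
  # smooth within the membrane mask only: the validity-aware kernels then
  # cannot bleed cytosolic donor signal into the ring
  phasor$valid <- phasor$valid & mask
  phasor <- smooth_phasor(phasor, smooth_method, smooth_size)

  traj <- fit_trajectory(phasor,
                         fret_trajectory(scene$truth$tau_donor, f_bg = b2,
                                         frequency_hz = spec$frequency_hz,
                                         harmonic = harmonic),
                         mask = mask)

  unmix <- unmix_two_state(phasor,
                           unmix_config(donor_tau = scene$truth$tau_donor,
                                        b1 = b1, b2 = b2,
                                        frequency_hz = spec$frequency_hz,
                                        harmonic = harmonic),
                           mask = mask)

  dist_high <- fcg_invert(min(max(unmix$e_high, 1e-6), 1 - 1e-6), fcg)
  dist_app <- if (traj$e_app > 0 && traj$e_app < 1)
    fcg_invert(traj$e_app, fcg) else NA_real_

  p <- min(max(unmix$f_int, 1e-6), 1 - 1e-6)
  energ <- list(p_open = p_open_binomial(p, subunit_k),
                dG_kcal_mol = dg_from_fraction(p, n = subunit_k,
                                               temperature = temperature),
                scan = scan_subunit_models(p, temperature))

  structure(list(phasor = phasor, mask = mask, trajectory = traj,
                 unmix = unmix,
                 distances = c(r_high_A = dist_high, r_apparent_A = dist_app),
                 energetics = energ,
                 truth = scene$truth,
                 provenance = list(config_hash = config_hash(config),
                                   seed = spec$seed,
                                   package_version =
                                     as.character(utils::packageVersion("phasorfret")))),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("phasor FLIM-tmFRET pipeline result\n")
  cat(sprintf("  membrane pixels: %d\n", sum(x$mask)))
  cat(sprintf("  trajectory E_app = %.3f\n", x$trajectory$e_app))
  cat(sprintf("  unmixing: E_high = %.3f, f_int = %.3f, f_mol = %.3f\n",
              x$unmix$e_high, x$unmix$f_int, x$unmix$f_mol))
  cat(sprintf("  distances: r_high = %.1f A, r_apparent = %.1f A\n",
              x$distances["r_high_A"], x$distances["r_apparent_A"]))
  cat(sprintf("  energetics (k-of-4): P_open = %.3f, dG = %.2f kcal/mol\n",
              x$energetics$p_open, x$energetics$dG_kcal_mol))
  cat(sprintf("  provenance: seed %d, config %s\n",
              x$provenance$seed, substr(x$provenance$config_hash, 1, 8)))
  invisible(x)
}

#' Serialize a pipeline result to JSON
#'
#' Writes the scalar stage outputs (trajectory fit, unmixing result,
#' distances, energetics table) and provenance at fixed precision: phasor
#' coordinates at 6 decimals, distances at 0.1 Angstrom, fractions at 1e-3.
#' Identical configs and seeds reproduce byte-identical files.
#'
#' @param result A `pipeline_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_result_bundle <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  bundle <- list(
    coordinate_convention = "pixel indices 0-based, (row, column) order",
    trajectory = list(e_app = round(result$trajectory$e_app, 3),
                      residual = round(result$trajectory$residual, 6),
                      n_pixels = result$trajectory$n_pixels),
    unmix = list(e_high = round(result$unmix$e_high, 3),
                 f_int = round(result$unmix$f_int, 3),
                 f_mol = round(result$unmix$f_mol, 3),
                 p_donor = round(result$unmix$p_donor, 6),
                 p_fret = round(result$unmix$p_fret, 6),
                 elongation = round(result$unmix$elongation, 3),
                 endpoint_fallback = result$unmix$endpoint_fallback),
    distances_A = round(result$distances, 1),
    energetics = list(p_open = round(result$energetics$p_open, 4),
                      dG_kcal_mol = round(result$energetics$dG_kcal_mol, 3),
                      scan = result$energetics$scan),
    provenance = result$provenance
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
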