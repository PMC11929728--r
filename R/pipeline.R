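#' Pipeline configuration
#'
#' Single home for every tunable constant of the processing workflow, with
#' the defaults used throughout: rest window 0-0.25 s, MAD multiplier 3,
#' Gaussian smoothing window 0.26 s, block smoothing width 1.04 s,
#' significance level 0.05, minimum pair separation 1 mm.
#'
#' @param t0_window Rest window `(start, end)`, s.
#' @param mad_k Scaled-MAD multiplier.
#' @param gaussian_window Gaussian smoothing window, s.
#' @param block_width Block smoothing width, s.
#' @param tol_area Trilateration centre-degeneracy tolerance, mm^2.
#' @param tol_h Sphere-miss clamp tolerance, mm^2 (default `(3 * 0.01)^2`,
#'   three times the default distance noise, squared).
#' @param residual_max Maximum admissible trilateration residual, mm.
#' @param side_rule Hemisphere rule for the first trilaterated sample
#'   (`NULL`: infer per crystal from the reference geometry).
#' @param min_separation Minimum pair baseline for strain, mm.
#' @param pair_override Named list region -> pair id, forcing pair
#'   selection (e.g. `list(ventricular = "B1-B3")`).
#' @param alpha Significance level for the force-strain correlation.
#' @param calibration_reducer `"mean"` or `"median"` over the rest window.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(t0_window = c(0, 0.25), mad_k = 3,
                            gaussian_window = 0.26, block_width = 1.04,
                            tol_area = 1e-6, tol_h = 9e-4,
                            residual_max = 1, side_rule = NULL,
                            min_separation = 1, pair_override = list(),
                            alpha = 0.05,
                            calibration_reducer = "mean") {
  if (t0_window[2] <= t0_window[1]) stop("t0_window must be non-empty")
  if (gaussian_window <= 0 || block_width <= 0) {
    stop("smoothing windows must be positive")
  }
  structure(list(t0_window = t0_window, mad_k = mad_k,
                 gaussian_window = gaussian_window,
                 block_width = block_width, tol_area = tol_area,
                 tol_h = tol_h, residual_max = residual_max,
                 side_rule = side_rule, min_separation = min_separation,
                 pair_override = pair_override, alpha = alpha,
                 calibration_reducer = calibration_reducer),
            class = "pipeline_config")
}

#' Run the full processing pipeline on one experiment
#'
#' Executes the complete workflow on one experiment's inputs: scaled-MAD
#' filtering of the raw distances, calibration against the reference
#' geometry, trilateration to 3D positions, rest-position error,
#' trajectory fits and traction-force direction (from this experiment's
#' crystals unless a direction estimated across experiments is supplied),
#' force-frame construction, displacement projection, crystal-pair
#' selection, strain computation, peak detection, and peak alignment of
#' strain and displacement with the force.
#'
#' @param distances An uncalibrated `distance_traces`.
#' @param force A `force_trace`.
#' @param reference A `reference_geometry`.
#' @param config A [pipeline_config()].
#' @param direction Optional traction-force direction (unit 3-vector)
#'   estimated across experiments; default: estimated from this
#'   experiment's trajectories.
#' @param region Region label used for the pair override lookup.
#' @return A `vad_run` list with elements `positions`, `position_error`,
#'   `direction`, `per_plane_angles`, `frame`, `displacement` (per-crystal
#'   series), `pair` (a `pair_selection`), `strain` (a `strain_trace`),
#'   `peaks` (force, per-crystal displacement, strain peaks and alignment
#'   shifts), `calibration`, `config`.
#' @export
run_pipeline <- function(distances, force, reference,
                         config = pipeline_config(), direction = NULL,
                         region = NULL) {
  stopifnot(inherits(distances, "distance_traces"),
            inherits(force, "force_trace"),
            inherits(reference, "reference_geometry"),
            inherits(config, "pipeline_config"))
  if (config$t0_window[1] < min(distances$time) - 1e-9 ||
      config$t0_window[2] > max(distances$time) + 1e-9) {
    stop("config t0_window lies outside the distance trace")
  }

  # stage 1: outlier filtering of the raw distance traces (spike removal
  # on locally detrended residuals, so quasi-static motion survives)
  d <- distances
  for (k in seq_len(ncol(d$d))) {
    s <- despike(vad_series(d$time, d$d[, k], d$mask[, k]),
                 k = config$mad_k, window = config$gaussian_window)
    d$mask[, k] <- s$mask
  }

  # stage 2: calibration against the reference geometry
  cal <- compute_calibration(d, reference, t0_window = config$t0_window,
                             reducer = config$calibration_reducer)
  d <- apply_calibration(d, cal)

  # stage 3: trilateration and rest-position error
  positions <- trilaterate_trace(d, reference,
                                 side_rule = config$side_rule,
                                 mad_k = config$mad_k,
                                 residual_max = config$residual_max,
                                 tol_area = config$tol_area,
                                 tol_h = config$tol_h)
  perr <- position_error(positions, reference,
                         t0_window = config$t0_window)

  # stage 4: trajectory direction and traction-force frame
  est <- estimate_force_direction(positions)
  if (is.null(direction)) direction <- est$direction
  frame <- build_force_frame(direction)

  # stage 5: displacement projection
  displacement <- project_displacement(positions, frame,
                                       t0_window = config$t0_window,
                                       gaussian_window =
                                         config$gaussian_window)

  # stage 6: pair selection on rest positions
  rest <- t(vapply(names(positions$crystals), function(b) {
    mean_position(positions, b, config$t0_window)
  }, numeric(3)))
  override <- if (!is.null(region)) config$pair_override[[region]] else NULL
  pair <- select_pair(rest, frame, min_separation = config$min_separation,
                      override = override)

  # stage 7: strain
  strain <- compute_strain(positions, pair, frame,
                           t0_window = config$t0_window,
                           mad_k = config$mad_k,
                           gaussian_window = config$gaussian_window,
                           block_width = config$block_width,
                           min_separation = config$min_separation)

  # stage 8: peaks and alignment with the force peak
  force_series <- vad_series(force$time_s, force$force_N)
  fpk <- find_peak(force_series)
  to_align <- c(list(strain = strain$strain), displacement)
  al <- align_peaks(force_series, to_align)
  peaks <- list(
    force_peak_N = fpk$value, force_peak_time_s = fpk$time,
    strain_peak = find_peak(strain$strain)$value,
    displacement_peaks_mm = vapply(displacement, function(s) {
      find_peak(s)$value
    }, numeric(1)),
    alignment_shifts_s = al$shifts_s
  )

  structure(list(positions = positions, position_error = perr,
                 direction = direction, per_plane_angles =
                   est$per_plane_angles, frame = frame,
                 displacement = displacement, pair = pair,
                 strain = strain, peaks = peaks, aligned = al$aligned,
                 calibration = cal, config = config),
            class = "vad_run")
}

#' Run the pipeline on a fixture directory and write report tables
#'
#' Thin wrapper: reads a fixture directory ([read_fixture()]), runs
#' [run_pipeline()], and writes the report tables (rest-position error,
#' per-plane trajectory angles, pair components, peak summary) plus a JSON
#' run manifest to an output directory.
#'
#' @param dir Fixture directory.
#' @param out_dir Output directory (created if absent); `NULL` skips
#'   writing.
#' @param config A [pipeline_config()].
#' @param direction Optional externally estimated force direction.
#' @return The `vad_run`, invisibly when writing.
#' @export
run_fixture <- function(dir, out_dir = NULL, config = pipeline_config(),
                        direction = NULL) {
  fx <- read_fixture(dir)
  region <- if (!is.null(fx$config)) fx$config$region else NULL
  run <- run_pipeline(fx$distances, fx$force, fx$reference,
                      config = config, direction = direction,
                      region = region)
  if (is.null(out_dir)) return(run)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$position_error,
                   file.path(out_dir, "position_error.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(run$per_plane_angles,
                   file.path(out_dir, "trajectory_angles.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(run$pair$components,
                   file.path(out_dir, "pair_components.csv"),
                   row.names = FALSE, quote = FALSE)
  pk <- run$peaks
  peak_tbl <- data.frame(
    quantity = c("force_peak_N", "strain_peak",
                 paste0("displacement_peak_mm_",
                        names(pk$displacement_peaks_mm))),
    value = c(pk$force_peak_N, pk$strain_peak,
              unname(pk$displacement_peaks_mm)))
  utils::write.csv(peak_tbl, file.path(out_dir, "peaks.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(fixture = normalizePath(dir),
                   config = unclass(config),
                   direction = as.numeric(run$direction),
                   selected_pair = paste(run$strain$pair, collapse = "-"),
                   package_version =
                     as.character(utils::packageVersion("vadstrain")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run)
}
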