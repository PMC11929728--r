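#' Published phantom pair-component measurements
#'
#' Inter-crystal rest distances for every crystal pair of each instrumented
#' region of the fetal-head phantom, decomposed in the traction-force
#' frame (force direction, two normal directions, total distance), as
#' measured in the manual and automatic force setups. These serve as
#' worked-example inputs for the pair-selection rule and as an internal
#' consistency check (the total distance should equal the Euclidean norm
#' of its three components).
#'
#' @param setup `"manual"` or `"automatic"`.
#' @return Data frame with columns `region`, `pair`, `force_mm`,
#'   `normal1_mm`, `normal2_mm`, `total_mm`, `selected` (the pair chosen
#'   for strain analysis in the original experiments).
#' @export
phantom_pair_components <- function(setup = c("manual", "automatic")) {
  setup <- match.arg(setup)
  if (setup == "manual") {
    df <- data.frame(
      region = rep(c("cortical_under_cup", "ventricular", "sensorimotor"),
                   each = 3),
      pair = rep(c("B1-B2", "B1-B3", "B2-B3"), 3),
      force_mm   = c(0.65, 11.15, 11.80,  8.15, 6.22, 1.93,
                     3.65, 8.89, 5.23),
      normal1_mm = c(4.85, 11.80, 6.14,   6.91, 5.33, 1.57,
                     17.79, 3.13, 20.92),
      normal2_mm = c(15.89, 6.25, 9.65,   2.57, 4.86, 2.29,
                     2.61, 4.15, 1.53),
      total_mm   = c(16.63, 16.86, 16.43, 10.99, 9.52, 3.39,
                     18.35, 10.30, 21.62),
      selected = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE,
                   FALSE, TRUE, FALSE)
    )
  } else {
    df <- data.frame(
      region = "cortical_under_cup",
      pair = c("B1-B2", "B1-B3", "B2-B3"),
      force_mm = c(9.34, 7.01, 16.36),
      normal1_mm = c(3.03, 3.27, 0.23),
      normal2_mm = c(13.42, 14.98, 1.56),
      total_mm = c(16.63, 16.86, 16.43),
      selected = c(FALSE, FALSE, TRUE)
    )
  }
  df
}

#' Published phantom trajectory-direction summaries
#'
#' Mean (SD) of the crystal-trajectory direction angle per Cartesian plane
#' of the initial reference frame, per crystal set, as measured on the
#' phantom. The manual-setup per-set means feed the "all crystal sets"
#' aggregation.
#'
#' @param setup `"manual"` or `"automatic"`.
#' @return Data frame with columns `region`, `plane`, `mean_deg`, `sd_deg`.
#' @export
phantom_trajectory_angles <- function(setup = c("manual", "automatic")) {
  setup <- match.arg(setup)
  if (setup == "manual") {
    data.frame(
      region = rep(c("cortical_under_cup", "ventricular", "sensorimotor"),
                   each = 3),
      plane = rep(c("XY", "XZ", "YZ"), 3),
      mean_deg = c(64.14, -69.49, -52.93,
                   63.67, -74.59, -59.18,
                   63.76, -66.60, -49.09),
      sd_deg = c(5.42, 4.57, 6.36,
                 6.12, 4.34, 5.24,
                 3.83, 2.53, 4.54)
    )
  } else {
    data.frame(
      region = "cortical_under_cup",
      plane = c("XY", "XZ", "YZ"),
      mean_deg = c(45.41, -61.59, -63.75),
      sd_deg = c(8.83, 6.18, 9.11)
    )
  }
}
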