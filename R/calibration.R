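#' Compute per-pair calibration factors
#'
#' The sonomicrometry channel carries a per-pair scale error; each pair's
#' factor is the ratio of the reference (CT) inter-crystal distance to the
#' mean measured distance over the initial rest window,
#' `f = D_CT / mean(D_sono(t0))`, so that multiplying the raw trace by `f`
#' anchors it to the CT geometry at rest.
#'
#' @param d An uncalibrated `distance_traces`.
#' @param ref A `reference_geometry` containing both crystals of every pair.
#' @param t0_window `(start, end)` initial window in seconds, default
#'   `c(0, 0.25)`.
#' @param reducer `"mean"` (default) or `"median"` over the window samples.
#' @return A `calibration_set`: named numeric vector of factors with
#'   attributes `t0_window` and `D_CT`.
#' @export
compute_calibration <- function(d, ref, t0_window = c(0, 0.25),
                                reducer = c("mean", "median")) {
  stopifnot(inherits(d, "distance_traces"), inherits(ref, "reference_geometry"))
  reducer <- match.arg(reducer)
  if (d$calibrated) stop("distance traces are already calibrated")
  if (t0_window[2] <= t0_window[1]) stop("t0_window must be non-empty")
  if (t0_window[1] < min(d$time) - 1e-9 || t0_window[2] > max(d$time) + 1e-9) {
    stop("t0_window must lie within the trace")
  }
  red <- if (reducer == "mean") mean else stats::median
  in_win <- d$time >= t0_window[1] & d$time <= t0_window[2]
  f <- numeric(ncol(d$d))
  dct <- numeric(ncol(d$d))
  names(f) <- names(dct) <- colnames(d$d)
  for (k in seq_len(ncol(d$d))) {
    sel <- in_win & d$mask[, k]
    if (!any(sel)) {
      stop("no valid samples in the t0 window for pair ", colnames(d$d)[k])
    }
    d0 <- red(d$d[sel, k])
    dct[k] <- reference_distance(ref, d$pairs$fixed[k], d$pairs$brain[k])
    if (dct[k] == 0) stop("reference distance is zero for pair ",
                          colnames(d$d)[k])
    f[k] <- dct[k] / d0
  }
  structure(f, t0_window = t0_window, D_CT = dct, class = "calibration_set")
}

#' Apply calibration factors to distance traces
#'
#' Multiplies every sample of each pair by that pair's factor and sets the
#' calibrated flag. Re-application to already calibrated traces is refused.
#'
#' @param d An uncalibrated `distance_traces`.
#' @param cal A `calibration_set` covering every pair in `d`.
#' @return The calibrated `distance_traces`.
#' @export
apply_calibration <- function(d, cal) {
  stopifnot(inherits(d, "distance_traces"), inherits(cal, "calibration_set"))
  if (d$calibrated) stop("distance traces are already calibrated")
  missing <- setdiff(colnames(d$d), names(cal))
  if (length(missing)) {
    stop("no calibration factor for pair(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(unclass(cal))) || any(unclass(cal) <= 0)) {
    stop("calibration factors must be positive and finite")
  }
  d$d <- sweep(d$d, 2, unclass(cal)[colnames(d$d)], `*`)
  d$calibrated <- TRUE
  d
}
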