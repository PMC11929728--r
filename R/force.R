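#' Generate a traction-force waveform
#'
#' Emulates the onset phase of a clinical VAD traction: a trapezoid holding
#' 0 N for an initial pad, ramping up at a constant rate to a predefined
#' peak, holding a plateau, ramping down at the same rate, and holding 0 N
#' for a final pad. The automatic setup (load-controlled testing machine,
#' 1000 Hz) reproduces the trapezoid exactly; the manual setup (hand-held
#' force gage, 10 Hz) perturbs ramp rate and peak with smooth seeded jitter
#' to emulate human variability, clipped at 0 N.
#'
#' @param peak Peak force, N (>= 0).
#' @param rate Ramp rate, N/s (> 0).
#' @param duration Total waveform duration, s.
#' @param pad Zero-force pad at each end, s (default 0.5).
#' @param sample_rate Sampling rate, Hz (default 1000 for automatic, 10 for
#'   manual if left `NULL`).
#' @param mode `"automatic"` or `"manual"`.
#' @param jitter For manual mode: list with `rate_sd` (relative SD of the
#'   ramp rate, default 0.10) and `peak_sd` (relative SD of the attained
#'   peak, default 0.02).
#' @param seed Integer seed for manual-mode jitter.
#' @return A `force_trace`: data frame with columns `time_s`, `force_N`,
#'   plus attributes `setup` and `sample_rate`.
#' @examples
#' f <- generate_force_waveform(peak = 110, rate = 30, duration = 10)
#' max(f$force_N)
#' @export
generate_force_waveform <- function(peak, rate = 30, duration = 10,
                                    pad = 0.5, sample_rate = NULL,
                                    mode = c("automatic", "manual"),
                                    jitter = list(rate_sd = 0.10,
                                                  peak_sd = 0.02),
                                    seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(sample_rate)) {
    sample_rate <- if (mode == "automatic") 1000 else 10
  }
  if (peak < 0) stop("`peak` must be >= 0")
  if (rate <= 0) stop("`rate` must be positive (N/s)")
  if (sample_rate <= 0) stop("`sample_rate` must be positive (Hz)")
  ramp <- peak / rate
  plateau <- duration - 2 * pad - 2 * ramp
  if (plateau < 0) {
    stop(sprintf(paste0("waveform does not fit: duration %.3g s leaves a ",
                        "negative plateau (%.3g s) for pad %.3g s and ramp ",
                        "%.3g s at %.3g N/s"),
                 duration, plateau, pad, ramp, rate))
  }
  time <- seq(0, duration, by = 1 / sample_rate)
  trapezoid <- function(t, pk, rt) {
    rmp <- pk / rt
    up0 <- pad
    up1 <- pad + rmp
    dn0 <- duration - pad - rmp
    dn1 <- duration - pad
    f <- numeric(length(t))
    f[t > up0 & t < up1] <- rt * (t[t > up0 & t < up1] - up0)
    f[t >= up1 & t <= dn0] <- pk
    f[t > dn0 & t < dn1] <- rt * (dn1 - t[t > dn0 & t < dn1])
    f
  }
  if (mode == "automatic" || peak == 0) {
    force <- trapezoid(time, peak, rate)
  } else {
    withr_seed(seed, {
      rate_j <- rate * max(0.1, 1 + stats::rnorm(1, sd = jitter$rate_sd))
      peak_j <- peak * max(0, 1 + stats::rnorm(1, sd = jitter$peak_sd))
      # low-frequency multiplicative wobble on the profile (~0.5 Hz max)
      nknots <- max(4L, as.integer(duration / 2))
      knots <- seq(0, duration, length.out = nknots)
      wob <- stats::rnorm(nknots, sd = jitter$rate_sd / 3)
      wobble <- stats::spline(knots, wob, xout = time)$y
    })
    force <- pmax(0, trapezoid(time, peak_j, rate_j) * (1 + wobble))
    # the wobble shapes the profile; the attained peak carries only the
    # peak jitter (SD `peak_sd`), keeping peak repeatability at its
    # configured level
    if (max(force) > 0) force <- force * (peak_j / max(force))
  }
  out <- data.frame(time_s = time, force_N = force)
  attr(out, "setup") <- mode
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("force_trace", "data.frame")
  out
}

#' Resample a force trace onto arbitrary times
#'
#' Linear interpolation, constant extrapolation at the ends. Used to drive
#' the kinematic simulation on the sonomicrometry clock.
#'
#' @param force A `force_trace`.
#' @param time Numeric vector of target times, s.
#' @return Numeric vector of forces, N.
#' @export
force_at <- function(force, time) {
  stats::approx(force$time_s, force$force_N, xout = time, rule = 2)$y
}
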