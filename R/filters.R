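#' Scaled-MAD outlier filter
#'
#' Marks invalid every sample whose deviation from the median exceeds `k`
#' times the scaled median absolute deviation (MAD). The MAD is scaled by
#' the Gaussian-consistency constant c = 1.4826 so that it estimates the
#' standard deviation for normally distributed data; with the default
#' `k = 3` the filter removes samples more than three scaled MADs from the
#' median. Removed samples are masked, never interpolated, so the time base
#' is unchanged.
#'
#' @param s A [vad_series()].
#' @param k Multiplier on the scaled MAD; default 3.
#' @return The input series with outlying samples masked.
#' @details If the scaled MAD is zero (more than half of the valid samples
#'   identical) the filter degenerates: only samples exactly equal to the
#'   median are kept, with a warning.
#' @examples
#' s <- vad_series(1:8, c(1, 2, 3, 4, 5, 6, 7, 100))
#' sum(!mad_filter(s)$mask)  # the single outlier
#' @export
mad_filter <- function(s, k = 3) {
  check_filterable(s)
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    stop("`k` must be a positive scalar")
  }
  v <- s$values[s$mask]
  med <- stats::median(v)
  smad <- 1.4826 * stats::median(abs(v - med))
  out <- s
  if (smad == 0) {
    warning("scaled MAD is zero; keeping only samples equal to the median")
    keep <- s$values == med
  } else {
    keep <- abs(s$values - med) <= k * smad
  }
  out$mask <- s$mask & keep
  out
}

#' Spike removal on locally detrended residuals
#'
#' Outlier removal for trending traces: subtracts a moving-median baseline
#' and applies the scaled-MAD rule of [mad_filter()] to the residuals, so
#' that genuine quasi-static motion (force ramps, plateaus) is never
#' classified as outlying while isolated spikes are. This is the filter
#' used by the pipeline stages; [mad_filter()] remains the global variant
#' for stationary series.
#'
#' @param s A [vad_series()].
#' @param k Multiplier on the scaled MAD of the residuals; default 3.
#' @param window Moving-median baseline window, s (default 0.26, the
#'   Gaussian smoothing window).
#' @return The series with spiking samples masked.
#' @details When the residual scaled MAD is zero (noise-free data) only
#'   samples whose residual is numerically zero are kept; with any
#'   measurement noise the threshold is about three noise SDs.
#' @export
despike <- function(s, k = 3, window = 0.26) {
  check_filterable(s)
  L <- window_samples(s, window)
  if (L < 3) return(mad_filter(s, k))
  if (L %% 2 == 0) L <- L + 1L
  # moving median needs a gap-free series: interpolate across masked runs
  filled <- s$values
  if (any(!s$mask)) {
    filled[!s$mask] <- stats::approx(s$time[s$mask], s$values[s$mask],
                                     xout = s$time[!s$mask], rule = 2)$y
  }
  base <- stats::runmed(filled, L, endrule = "median")
  r <- s$values - base
  rv <- r[s$mask]
  med <- stats::median(rv)
  smad <- 1.4826 * stats::median(abs(rv - med))
  tol <- if (smad > 0) k * smad else .Machine$double.eps^0.25
  out <- s
  out$mask <- s$mask & abs(r - med) <= tol
  out
}

# Internal: windowed weighted moving average over valid samples only.
# The kernel has exactly round(window * sample_rate) taps (for even lengths
# the window extends one sample further forward than back). Weights are
# renormalized over the valid samples actually present in each window, so
# edges and masked gaps do not attenuate the output.
weighted_moving_average <- function(s, kernel) {
  n <- length(s$values)
  half <- (length(kernel) - 1L) %/% 2L
  v <- ifelse(s$mask, s$values, 0)
  m <- as.numeric(s$mask)
  num <- rep(0, n)
  den <- rep(0, n)
  for (o in seq_along(kernel)) {
    off <- o - 1L - half
    w <- kernel[o]
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    num[ok] <- num[ok] + w * v[src[ok]]
    den[ok] <- den[ok] + w * m[src[ok]]
  }
  out <- s
  out$values <- ifelse(den > 0, num / den, NA_real_)
  out$mask <- den > 0
  out
}

# Internal: kernel length in samples for a time window, >= 1.
window_samples <- function(s, window) {
  max(1L, as.integer(round(window * sample_rate(s))))
}

#' Gaussian-weighted moving average
#'
#' Smooths a series with a normalized Gaussian kernel whose support covers a
#' fixed time window (default 0.26 s). The kernel standard deviation is
#' `window / 5`, so the window spans about +/- 2.5 sigma. Weights are
#' renormalized over the valid samples available in each window: masked
#' samples are skipped and edges are not attenuated.
#'
#' @param s A [vad_series()].
#' @param window Window length in seconds; default 0.26.
#' @return The smoothed series (same time vector; mask `TRUE` wherever at
#'   least one valid sample fell in the window).
#' @export
gaussian_smooth <- function(s, window = 0.26) {
  check_filterable(s)
  if (!is.numeric(window) || length(window) != 1 || window <= 0) {
    stop("`window` must be a positive scalar (seconds)")
  }
  L <- window_samples(s, window)
  if (L < 2) {
    warning("smoothing window shorter than 2 samples; returning input unchanged")
    return(s)
  }
  idx <- seq_len(L) - 1 - (L - 1) / 2   # centred; half-integer for even L
  sigma <- L / 5
  kernel <- exp(-idx^2 / (2 * sigma^2))
  weighted_moving_average(s, kernel / sum(kernel))
}

#' Block (boxcar) moving average
#'
#' Convolves a series with a normalized rectangular kernel of a fixed time
#' width (default 1.04 s). As with [gaussian_smooth()], weights are
#' renormalized over available valid samples, so the kernel weights sum to
#' one at every output sample including the edges.
#'
#' @param s A [vad_series()].
#' @param width Kernel width in seconds; default 1.04.
#' @return The smoothed series.
#' @export
block_smooth <- function(s, width = 1.04) {
  check_filterable(s)
  if (!is.numeric(width) || length(width) != 1 || width <= 0) {
    stop("`width` must be a positive scalar (seconds)")
  }
  L <- window_samples(s, width)
  if (L < 2) {
    warning("smoothing window shorter than 2 samples; returning input unchanged")
    return(s)
  }
  kernel <- rep(1 / L, L)
  weighted_moving_average(s, kernel)
}
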