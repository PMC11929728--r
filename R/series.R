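#' Masked time series
#'
#' The carrier object passed between pipeline stages: a strictly increasing
#' time vector, one value per time point, and a per-sample validity mask.
#' Filtering stages mark samples invalid rather than deleting them, so the
#' time base is preserved end to end.
#'
#' @param time Numeric vector of sample times in seconds, strictly increasing.
#' @param values Numeric vector of the same length; units depend on context
#'   (mm for distances and displacements, N for forces, dimensionless for
#'   strain).
#' @param mask Logical vector of the same length; `TRUE` marks a valid
#'   sample. Non-finite values are masked automatically.
#' @return An object of class `vad_series`: a list with elements `time`,
#'   `values` and `mask`.
#' @examples
#' s <- vad_series(seq(0, 1, by = 0.1), sin(seq(0, 1, by = 0.1)))
#' sample_rate(s)
#' @export
vad_series <- function(time, values, mask = NULL) {
  time <- as.numeric(time)
  values <- as.numeric(values)
  if (length(time) != length(values)) {
    stop("`time` and `values` must have equal length")
  }
  if (length(time) > 1 && any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing")
  }
  if (is.null(mask)) {
    mask <- rep(TRUE, length(values))
  }
  mask <- as.logical(mask)
  if (length(mask) != length(values)) {
    stop("`mask` must have the same length as `values`")
  }
  mask <- mask & is.finite(values)
  structure(list(time = time, values = values, mask = mask),
            class = "vad_series")
}

#' @export
print.vad_series <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("<vad_series> %d samples, %d valid, t = [%g, %g] s\n",
              n, sum(x$mask), if (n) x$time[1] else NA,
              if (n) x$time[n] else NA))
  invisible(x)
}

#' @export
length.vad_series <- function(x) length(x$time)

#' Median sampling rate of a series
#'
#' @param s A [vad_series()].
#' @return Sampling rate in Hz, from the median inter-sample interval.
#' @export
sample_rate <- function(s) {
  stopifnot(inherits(s, "vad_series"))
  if (length(s$time) < 2) stop("need at least 2 samples to estimate a rate")
  1 / stats::median(diff(s$time))
}

#' Valid values of a series
#'
#' @param s A [vad_series()].
#' @return Numeric vector of the values at valid (unmasked) samples.
#' @export
valid_values <- function(s) {
  stopifnot(inherits(s, "vad_series"))
  s$values[s$mask]
}

# Internal: check a series is usable for filtering.
check_filterable <- function(s) {
  stopifnot(inherits(s, "vad_series"))
  if (sum(s$mask) < 2) stop("series must contain at least 2 valid samples")
  invisible(s)
}
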