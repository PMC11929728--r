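#' Inter-crystal distance traces
#'
#' Time-indexed sonomicrometry distances for every fixed-brain crystal
#' pair, with a per-sample validity mask and a calibration flag.
#'
#' @param time Numeric vector of sample times, s, strictly increasing.
#' @param d Numeric matrix (samples x pairs), columns named
#'   `"<fixedID>-<brainID>"`, distances in mm.
#' @param mask Logical matrix of the same shape; defaults to finiteness.
#' @param calibrated Logical flag; `FALSE` for raw instrument data.
#' @return A `distance_traces` object.
#' @export
distance_traces <- function(time, d, mask = NULL, calibrated = FALSE) {
  time <- as.numeric(time)
  d <- as.matrix(d)
  if (length(time) != nrow(d)) stop("time length must match rows of `d`")
  if (length(time) > 1 && any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing")
  }
  if (is.null(colnames(d))) stop("`d` must have pair column names")
  prs <- strsplit(colnames(d), "-", fixed = TRUE)
  if (any(lengths(prs) != 2)) {
    stop("pair columns must be named '<fixedID>-<brainID>'")
  }
  if (anyDuplicated(colnames(d))) stop("duplicated pair column")
  if (is.null(mask)) mask <- is.finite(d)
  mask <- mask & is.finite(d)
  structure(list(time = time, d = d, mask = mask,
                 pairs = data.frame(fixed = vapply(prs, `[`, "", 1),
                                    brain = vapply(prs, `[`, "", 2),
                                    pair = colnames(d)),
                 calibrated = isTRUE(calibrated)),
            class = "distance_traces")
}

#' @export
print.distance_traces <- function(x, ...) {
  cat(sprintf("<distance_traces> %d samples x %d pairs, %scalibrated\n",
              length(x$time), ncol(x$d), if (x$calibrated) "" else "un"))
  invisible(x)
}

#' Extract one pair's distance trace as a series
#'
#' @param d A `distance_traces`.
#' @param pair Pair name, e.g. `"F1-B2"`.
#' @return A [vad_series()].
#' @export
pair_series <- function(d, pair) {
  stopifnot(inherits(d, "distance_traces"))
  if (!pair %in% colnames(d$d)) stop("unknown pair '", pair, "'")
  vad_series(d$time, d$d[, pair], d$mask[, pair])
}

#' Reference crystal geometry
#'
#' Per-crystal reference positions in the initial reference frame, obtained
#' from a CT scan of the instrumented phantom (or from synthetic ground
#' truth). Houses the reference inter-crystal distances used by the
#' calibration stage.
#'
#' @param crystals Data frame with columns `id`, `role`, `region`, `x`,
#'   `y`, `z` (mm).
#' @param provenance `"CT"` or `"synthetic-truth"`.
#' @return A `reference_geometry` object.
#' @export
reference_geometry <- function(crystals, provenance = c("CT", "synthetic-truth")) {
  provenance <- match.arg(provenance)
  geom <- crystal_layout(crystals)
  attr(geom, "provenance") <- provenance
  class(geom) <- c("reference_geometry", class(geom))
  geom
}

#' Reference distance between two crystals
#'
#' @param ref A `reference_geometry`.
#' @param fixed,brain Crystal ids.
#' @return Euclidean distance in mm.
#' @export
reference_distance <- function(ref, fixed, brain) {
  pos <- crystal_positions(ref)
  if (!all(c(fixed, brain) %in% rownames(pos))) {
    stop("crystal '", setdiff(c(fixed, brain), rownames(pos))[1],
         "' not in reference geometry")
  }
  sqrt(sum((pos[fixed, ] - pos[brain, ])^2))
}

#' Trilaterated 3D position trace
#'
#' @param time Numeric vector of sample times, s.
#' @param crystals Named list of (samples x 3) position matrices, mm.
#' @param residual Optional (samples x crystals) matrix of RMS distance
#'   mismatches at the solution, mm.
#' @param valid Optional logical matrix of per-sample validity.
#' @return A `position_trace` object.
#' @export
position_trace <- function(time, crystals, residual = NULL, valid = NULL) {
  time <- as.numeric(time)
  stopifnot(is.list(crystals), length(crystals) >= 1,
            !is.null(names(crystals)))
  for (m in crystals) {
    if (!is.matrix(m) || ncol(m) != 3 || nrow(m) != length(time)) {
      stop("each crystal entry must be a (samples x 3) matrix")
    }
  }
  k <- length(crystals)
  if (is.null(residual)) residual <- matrix(0, length(time), k)
  if (is.null(valid)) {
    valid <- vapply(crystals, function(m) apply(is.finite(m), 1, all),
                    logical(length(time)))
    valid <- matrix(valid, length(time), k)
  }
  colnames(residual) <- colnames(valid) <- names(crystals)
  structure(list(time = time, crystals = crystals, residual = residual,
                 valid = valid),
            class = "position_trace")
}

#' @export
print.position_trace <- function(x, ...) {
  cat(sprintf("<position_trace> %d samples, crystals: %s\n",
              length(x$time), paste(names(x$crystals), collapse = ", ")))
  invisible(x)
}

#' Mean position of a crystal over a time window
#'
#' @param p A `position_trace`.
#' @param crystal Crystal id.
#' @param window `(start, end)` window in seconds.
#' @return 3-vector of the mean position over valid samples in the window.
#' @export
mean_position <- function(p, crystal, window = c(0, 0.25)) {
  stopifnot(inherits(p, "position_trace"))
  sel <- p$time >= window[1] & p$time <= window[2] & p$valid[, crystal]
  if (!any(sel)) stop("no valid samples for '", crystal, "' in the window")
  colMeans(p$crystals[[crystal]][sel, , drop = FALSE])
}
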