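#' Decompose crystal-pair separations in the force frame
#'
#' For each pair among the three crystals of a region, the rest separation
#' vector decomposed into the traction-force direction and the two normal
#' directions, plus the total distance — the per-region pair table used for
#' pair selection.
#'
#' @param positions 3x3 matrix of rest positions (rows = crystal ids), mm.
#' @param frame A `force_frame`.
#' @return Data frame: `pair`, `force_mm`, `normal1_mm`, `normal2_mm`,
#'   `total_mm` (absolute components).
#' @export
pair_components <- function(positions, frame) {
  stopifnot(is.matrix(positions), nrow(positions) == 3,
            inherits(frame, "force_frame"))
  ids <- rownames(positions)
  prs <- utils::combn(ids, 2, simplify = FALSE)
  do.call(rbind, lapply(prs, function(p) {
    v <- to_force_frame(frame, positions[p[1], ] - positions[p[2], ])
    data.frame(pair = paste0(p[1], "-", p[2]),
               force_mm = abs(v[3]), normal1_mm = abs(v[1]),
               normal2_mm = abs(v[2]), total_mm = sqrt(sum(v^2)))
  }))
}

#' Select the crystal pair for strain computation
#'
#' Chooses, within one region, the pair best aligned with the traction
#' force and with the largest separation along it: the default rule scores
#' each pair by cosine alignment `|force component| / total distance` and
#' selects the maximum, breaking ties by larger force component and then by
#' lexicographic pair id. Pairs closer together than `min_separation` are
#' excluded (too small a baseline for reliable strain). The full
#' components table for all three pairs is returned for reporting.
#'
#' @param components Data frame from [pair_components()], or a 3x3 rest
#'   position matrix (then `frame` is required).
#' @param frame A `force_frame`; only used when `components` is a position
#'   matrix.
#' @param min_separation Minimum total pair distance, mm (default 1).
#' @param override Optional pair id (e.g. `"B1-B3"`) forcing the selection;
#'   provided because the alignment rule is a heuristic and a practitioner
#'   may fix the pair per region.
#' @return A `pair_selection` list: `pair` (ordered ids), `components`
#'   (table for all pairs with a `selected` column), `score`.
#' @export
select_pair <- function(components, frame = NULL, min_separation = 1,
                        override = NULL) {
  if (is.matrix(components)) {
    if (is.null(frame)) stop("`frame` is required with a position matrix")
    components <- pair_components(components, frame)
  }
  tbl <- components
  req <- c("pair", "force_mm", "normal1_mm", "normal2_mm", "total_mm")
  stopifnot(all(req %in% names(tbl)))
  tbl$score <- tbl$force_mm / tbl$total_mm
  eligible <- tbl$total_mm >= min_separation
  if (any(!eligible)) {
    warning("excluding pair(s) below the minimum separation: ",
            paste(tbl$pair[!eligible], collapse = ", "))
  }
  if (!any(eligible)) stop("all pairs below the minimum separation")
  if (!is.null(override)) {
    if (!override %in% tbl$pair) stop("override pair '", override,
                                      "' not in the components table")
    pick <- which(tbl$pair == override)
  } else {
    cand <- which(eligible)
    ord <- order(-tbl$score[cand], -tbl$force_mm[cand], tbl$pair[cand])
    pick <- cand[ord[1]]
  }
  tbl$selected <- seq_len(nrow(tbl)) == pick
  ids <- strsplit(tbl$pair[pick], "-", fixed = TRUE)[[1]]
  structure(list(pair = ids, components = tbl, score = tbl$score[pick]),
            class = "pair_selection")
}

#' Engineering strain along the traction-force direction
#'
#' The projected inter-crystal separation
#' `D(t) = (position_i(t) - position_j(t)) . force_direction` (crystals
#' ordered so the rest separation is positive) is outlier-filtered
#' ([mad_filter()]) and Gaussian-smoothed; the rest length `D0` is the mean
#' of the filtered separation over the initial window, and the strain is
#' the relative change `(D(t) - D0) / D0`, finally smoothed with the block
#' filter. Positive strain is tension along the traction direction.
#'
#' @param p A `position_trace` containing both crystals.
#' @param pair Character vector of the two crystal ids, or a
#'   `pair_selection`.
#' @param frame A `force_frame`.
#' @param t0_window Rest window, s.
#' @param mad_k MAD-filter multiplier (default 3).
#' @param gaussian_window Gaussian smoothing window, s (default 0.26).
#' @param block_width Block smoothing width, s (default 1.04); `NULL`
#'   skips the final smoothing.
#' @param min_separation Minimum admissible `D0`, mm (default 1).
#' @return A `strain_trace` list: `strain` (a [vad_series()]),
#'   `separation` (filtered projected separation, mm), `D0_mm`, `pair`.
#' @export
compute_strain <- function(p, pair, frame, t0_window = c(0, 0.25),
                           mad_k = 3, gaussian_window = 0.26,
                           block_width = 1.04, min_separation = 1) {
  stopifnot(inherits(p, "position_trace"), inherits(frame, "force_frame"))
  if (inherits(pair, "pair_selection")) pair <- pair$pair
  stopifnot(length(pair) == 2, all(pair %in% names(p$crystals)))
  dirv <- frame$force_direction
  i <- pair[1]; j <- pair[2]
  sep <- (p$crystals[[i]] - p$crystals[[j]]) %*% dirv
  ok <- p$valid[, i] & p$valid[, j]
  s <- vad_series(p$time, as.numeric(sep), mask = ok)
  in_win <- s$time >= t0_window[1] & s$time <= t0_window[2]
  if (!any(in_win & s$mask)) stop("no valid samples in the t0 window")
  if (mean(s$values[in_win & s$mask]) < 0) {
    # order the pair so that the rest separation is positive
    s$values <- -s$values
    pair <- rev(pair)
  }
  if (!is.null(mad_k)) {
    s <- despike(s, k = mad_k,
                 window = if (is.null(gaussian_window)) 0.26
                 else gaussian_window)
  }
  if (!is.null(gaussian_window)) s <- gaussian_smooth(s, gaussian_window)
  sel0 <- in_win & s$mask
  if (!any(sel0)) stop("no valid samples in the t0 window after filtering")
  D0 <- mean(s$values[sel0])
  if (abs(D0) < min_separation) {
    stop(sprintf(paste0("projected rest separation %.3g mm is below the ",
                        "minimum of %.3g mm: strain on this baseline is ",
                        "unreliable"), D0, min_separation))
  }
  strain <- vad_series(s$time, (s$values - D0) / D0, mask = s$mask)
  if (!is.null(block_width)) strain <- block_smooth(strain, block_width)
  structure(list(strain = strain, separation = s, D0_mm = D0, pair = pair),
            class = "strain_trace")
}

#' Global peak of a series
#'
#' @param s A [vad_series()].
#' @param polarity `"max"` (default) or `"min"`.
#' @return List with `value`, `time` (s), `index`, and `boundary` (`TRUE`
#'   with a warning if the extremum sits at the first or last valid
#'   sample).
#' @export
find_peak <- function(s, polarity = c("max", "min")) {
  stopifnot(inherits(s, "vad_series"))
  polarity <- match.arg(polarity)
  idx <- which(s$mask)
  if (!length(idx)) stop("no valid samples")
  v <- s$values[idx]
  k <- if (polarity == "max") which.max(v) else which.min(v)
  i <- idx[k]
  boundary <- k == 1L || k == length(idx)
  if (boundary) warning("peak found at a boundary sample")
  list(value = s$values[i], time = s$time[i], index = i,
       boundary = boundary)
}

#' Align series peaks in time
#'
#' Shifts each series so that its peak time coincides with the reference
#' series' peak time. Operates on peak times only: no resampling, so
#' series with different sampling rates (e.g. force vs strain) may be
#' aligned.
#'
#' @param reference A [vad_series()].
#' @param others List of [vad_series()] to align.
#' @param polarity Passed to [find_peak()].
#' @return List with `aligned` (list of shifted series) and `shifts_s`
#'   (numeric vector; each series' time was increased by this amount).
#' @export
align_peaks <- function(reference, others, polarity = "max") {
  tref <- find_peak(reference, polarity)$time
  shifts <- vapply(others, function(s) {
    tref - find_peak(s, polarity)$time
  }, numeric(1))
  aligned <- mapply(function(s, sh) {
    s$time <- s$time + sh
    s
  }, others, shifts, SIMPLIFY = FALSE)
  list(aligned = aligned, shifts_s = shifts)
}

#' Pearson correlation between peak force and peak strain
#'
#' @param force_peaks Numeric vector of peak forces, N.
#' @param strain_peaks Numeric vector of peak strains (same length).
#' @param conf_level Significance context; the test is two-sided on the
#'   t-distribution with n - 2 degrees of freedom.
#' @return List with `r`, `p`, `slope`, `intercept`, `n` (line from the
#'   least-squares fit of strain on force).
#' @export
correlate_force_strain <- function(force_peaks, strain_peaks,
                                   conf_level = 0.95) {
  x <- as.numeric(force_peaks)
  y <- as.numeric(strain_peaks)
  if (length(x) != length(y)) stop("inputs must have equal length")
  if (length(x) < 3) stop("need at least 3 force-strain pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in force or strain peaks: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson",
                        conf.level = conf_level)
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = length(x))
}

#' Repeatability of aligned repeated experiments
#'
#' Pointwise mean and standard deviation over peak-aligned repeats,
#' restricted to the overlapping time region and a common grid (the first
#' repeat's samples inside the overlap; other repeats are linearly
#' interpolated onto it). Peak statistics include the relative standard
#' deviation RSD = SD / mean at the peak, the repeatability metric.
#'
#' @param repeats List of >= 2 peak-aligned [vad_series()].
#' @param polarity Passed to [find_peak()] for the per-repeat peaks.
#' @return List with `time`, `mean`, `sd` (profiles over the overlap),
#'   `peak_mean`, `peak_sd`, `rsd` and `peaks` (per-repeat peak values).
#' @export
repeatability <- function(repeats, polarity = "max") {
  stopifnot(is.list(repeats), length(repeats) >= 2)
  t0 <- max(vapply(repeats, function(s) min(s$time[s$mask]), numeric(1)))
  t1 <- min(vapply(repeats, function(s) max(s$time[s$mask]), numeric(1)))
  if (t1 <= t0) stop("aligned repeats have no overlapping time region")
  grid <- repeats[[1]]$time[repeats[[1]]$time >= t0 &
                              repeats[[1]]$time <= t1]
  vals <- vapply(repeats, function(s) {
    stats::approx(s$time[s$mask], s$values[s$mask], xout = grid)$y
  }, numeric(length(grid)))
  peaks <- vapply(repeats, function(s) find_peak(s, polarity)$value,
                  numeric(1))
  pm <- mean(peaks)
  ps <- stats::sd(peaks)
  list(time = grid,
       mean = rowMeans(vals),
       sd = apply(vals, 1, stats::sd),
       peak_mean = pm, peak_sd = ps,
       rsd = if (pm != 0) ps / pm else NA_real_,
       peaks = peaks)
}
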