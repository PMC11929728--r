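# Canonical frame for three sphere centers: origin at c1, first axis along
# c2 - c1, second axis in the (c1, c2, c3) plane. Returns the orthonormal
# basis and the in-frame scalars used by the closed-form solution.
trilateration_frame <- function(centers, tol_area = 1e-6) {
  stopifnot(is.matrix(centers), nrow(centers) == 3, ncol(centers) == 3)
  if (triangle_area(centers) < tol_area) {
    stop("sphere centers are collinear: trilateration is degenerate")
  }
  ex <- centers[2, ] - centers[1, ]
  dist12 <- sqrt(sum(ex^2))
  ex <- ex / dist12
  v3 <- centers[3, ] - centers[1, ]
  i <- sum(ex * v3)
  ey <- v3 - i * ex
  ey <- ey / sqrt(sum(ey^2))
  ez <- cross3(ex, ey)
  list(origin = centers[1, ], ex = ex, ey = ey, ez = ez,
       d = dist12, i = i, j = sum(ey * v3))
}

#' Three-sphere trilateration
#'
#' Locates a point from its distances to three known reference points
#' (sphere centers) by intersecting the three spheres in closed form. In
#' the canonical frame the in-plane coordinates follow from the standard
#' two-circle reduction; the out-of-plane coordinate is `z = +/- sqrt(h)`
#' with `h = r1^2 - x^2 - y^2`, leaving a mirror ambiguity across the
#' centers' plane. The sign is chosen as the solution nearest a prior
#' position when one is supplied, otherwise by a fixed hemisphere rule.
#' When measurement noise makes the spheres miss each other slightly
#' (`-tol_h <= h < 0`), `h` is clamped to zero; when they miss badly
#' (`h < -tol_h`), the point minimizing the sum of squared distance
#' mismatches is returned instead.
#'
#' @param centers 3x3 matrix, one center per row, mm.
#' @param radii Length-3 vector of distances, mm, all positive.
#' @param prior Optional 3-vector: previous position, used to resolve the
#'   mirror ambiguity.
#' @param side_rule `+1` or `-1`: hemisphere to pick (sign of the
#'   out-of-plane coordinate in the canonical frame) when no prior is
#'   available; anatomically, the side of the brain relative to the
#'   fixed-crystal plane.
#' @param tol_area Minimum triangle area of the centers, mm^2.
#' @param tol_h Clamp tolerance on `h`, mm^2.
#' @return List with `position` (3-vector, mm), `residual` (RMS of the
#'   three distance mismatches, mm), and `mirror_used` (`TRUE` if the
#'   prior flipped the hemisphere relative to `side_rule`).
#' @examples
#' centers <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
#' target <- c(3, 4, 5)
#' r <- sqrt(colSums((t(centers) - target)^2))
#' trilaterate(centers, r, side_rule = +1)$position
#' @export
trilaterate <- function(centers, radii, prior = NULL, side_rule = +1,
                        tol_area = 1e-6, tol_h = 9e-4) {
  if (any(radii <= 0)) stop("radii must be positive")
  fr <- trilateration_frame(centers, tol_area)
  sol <- trilaterate_core(fr, radii[1], radii[2], radii[3], tol_h)
  if (is.na(sol$z2)) {
    # spheres far from intersecting: least-squares fallback
    p <- trilaterate_lsq(centers, radii, fr, side_rule)
    return(list(position = p, residual = rms_mismatch(p, centers, radii),
                mirror_used = FALSE))
  }
  z <- sqrt(sol$z2)
  p_plus <- fr$origin + sol$x * fr$ex + sol$y * fr$ey + z * fr$ez
  p_minus <- fr$origin + sol$x * fr$ex + sol$y * fr$ey - z * fr$ez
  if (!is.null(prior)) {
    use_plus <- sum((p_plus - prior)^2) <= sum((p_minus - prior)^2)
  } else {
    use_plus <- side_rule >= 0
  }
  p <- if (use_plus) p_plus else p_minus
  list(position = p, residual = rms_mismatch(p, centers, radii),
       mirror_used = !is.null(prior) && (use_plus != (side_rule >= 0)))
}

# In-frame closed form; returns x, y and z^2 (NA when h < -tol_h).
trilaterate_core <- function(fr, r1, r2, r3, tol_h) {
  x <- (r1^2 - r2^2 + fr$d^2) / (2 * fr$d)
  y <- (r1^2 - r3^2 + fr$i^2 + fr$j^2 - 2 * fr$i * x) / (2 * fr$j)
  h <- r1^2 - x^2 - y^2
  z2 <- if (h >= 0) h else if (h >= -tol_h) 0 else NA_real_
  list(x = x, y = y, z2 = z2)
}

rms_mismatch <- function(p, centers, radii) {
  d <- sqrt(colSums((t(centers) - p)^2))
  sqrt(mean((d - radii)^2))
}

# Gauss-Newton style least-squares solve of sum(||p - c_i|| - r_i)^2 via
# optim/BFGS from a geometric starting point on the requested side.
trilaterate_lsq <- function(centers, radii, fr, side_rule) {
  x <- (radii[1]^2 - radii[2]^2 + fr$d^2) / (2 * fr$d)
  y <- (radii[1]^2 - radii[3]^2 + fr$i^2 + fr$j^2 - 2 * fr$i * x) / (2 * fr$j)
  start <- fr$origin + x * fr$ex + y * fr$ey +
    sign(side_rule) * 1e-3 * fr$ez
  obj <- function(p) {
    d <- sqrt(colSums((t(centers) - p)^2))
    sum((d - radii)^2)
  }
  grad <- function(p) {
    dv <- t(p - t(centers))            # 3 x 3: rows = spheres
    d <- sqrt(rowSums(dv^2))
    colSums(2 * (d - radii) / d * dv)
  }
  fit <- stats::optim(start, obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  fit$par
}

#' Trilaterate a full distance trace
#'
#' Reconstructs the 3D position of every brain crystal at every time sample
#' from its calibrated distances to the three fixed crystals, whose
#' reference positions are the (constant) sphere centers. The mirror
#' ambiguity is resolved by using each crystal's previous valid position as
#' the prior; the first sample uses the configured hemisphere rule. Each
#' recovered coordinate series is then passed through [mad_filter()] to
#' remove trilateration outliers.
#'
#' @param d A calibrated `distance_traces` with three fixed crystals.
#' @param ref A `reference_geometry` providing the fixed-crystal positions.
#' @param side_rule Hemisphere rule for the first sample (+1 or -1); if
#'   `NULL`, inferred per crystal from the reference position of that
#'   crystal (its side of the fixed-crystal plane).
#' @param mad_k Multiplier for the coordinate-wise MAD filter; `NULL`
#'   disables the filter.
#' @param residual_max Samples whose trilateration residual exceeds this
#'   (mm) are marked invalid.
#' @param tol_area,tol_h Geometry tolerances, see [trilaterate()].
#' @return A `position_trace` for the brain crystals.
#' @export
trilaterate_trace <- function(d, ref, side_rule = NULL, mad_k = 3,
                              residual_max = 1, tol_area = 1e-6,
                              tol_h = 9e-4) {
  stopifnot(inherits(d, "distance_traces"), inherits(ref, "reference_geometry"))
  if (!d$calibrated) stop("distance traces must be calibrated first")
  fids <- sort(unique(d$pairs$fixed))
  if (length(fids) != 3) stop("need distances to exactly 3 fixed crystals")
  centers <- crystal_positions(ref)[fids, ]
  fr <- trilateration_frame(centers, tol_area)
  bids <- sort(unique(d$pairs$brain))
  refpos <- crystal_positions(ref)

  n <- length(d$time)
  crystals <- list()
  residual <- matrix(NA_real_, n, length(bids),
                     dimnames = list(NULL, bids))
  valid <- matrix(FALSE, n, length(bids), dimnames = list(NULL, bids))
  frame_mat <- rbind(fr$ex, fr$ey, fr$ez)

  for (b in bids) {
    cols <- paste0(fids, "-", b)
    if (!all(cols %in% colnames(d$d))) {
      stop("crystal ", b, " lacks distances to all three fixed crystals")
    }
    r <- d$d[, cols, drop = FALSE]
    ok <- rowSums(d$mask[, cols, drop = FALSE]) == 3
    # vectorized closed form in the canonical frame
    x <- (r[, 1]^2 - r[, 2]^2 + fr$d^2) / (2 * fr$d)
    y <- (r[, 1]^2 - r[, 3]^2 + fr$i^2 + fr$j^2 - 2 * fr$i * x) / (2 * fr$j)
    h <- r[, 1]^2 - x^2 - y^2
    z2 <- ifelse(h >= 0, h, ifelse(h >= -tol_h, 0, NA_real_))
    zmag <- sqrt(z2)

    side0 <- if (is.null(side_rule)) {
      s <- sign(sum((refpos[b, ] - fr$origin) * fr$ez))
      if (s == 0) +1 else s
    } else side_rule
    pos <- matrix(NA_real_, n, 3)
    res <- rep(NA_real_, n)
    prev <- NULL
    for (t in seq_len(n)) {
      if (!ok[t]) next
      if (is.na(zmag[t])) {
        sol <- trilaterate(centers, r[t, ],
                           prior = prev, side_rule = side0,
                           tol_area = tol_area, tol_h = tol_h)
        pos[t, ] <- sol$position
        res[t] <- sol$residual
      } else {
        base <- fr$origin + x[t] * fr$ex + y[t] * fr$ey
        pp <- base + zmag[t] * fr$ez
        pm <- base - zmag[t] * fr$ez
        use_plus <- if (!is.null(prev)) {
          sum((pp - prev)^2) <= sum((pm - prev)^2)
        } else side0 >= 0
        pos[t, ] <- if (use_plus) pp else pm
        res[t] <- rms_mismatch(pos[t, ], centers, r[t, ])
      }
      if (is.finite(res[t]) && res[t] <= residual_max) prev <- pos[t, ]
    }
    keep <- ok & is.finite(res) & res <= residual_max
    valid[, b] <- keep
    residual[, b] <- res
    if (!is.null(mad_k)) {
      for (ax in 1:3) {
        s <- vad_series(d$time, ifelse(keep, pos[, ax], NA_real_),
                        mask = keep)
        if (sum(s$mask) >= 2) {
          s <- despike(s, k = mad_k)
          valid[, b] <- valid[, b] & (s$mask | !keep)
        }
      }
    }
    crystals[[b]] <- pos
    if (mean(valid[, b]) < 0.5) {
      warning("crystal ", b, " has more than 50% invalid samples")
    }
  }
  position_trace(d$time, crystals, residual = residual, valid = valid)
}

#' Crystal position error against the reference geometry
#'
#' Accuracy/precision summary of the reconstruction at rest: for every
#' brain crystal, the Euclidean distance between each trilaterated position
#' in the initial window and the reference (CT) position, reported as mean
#' and SD.
#'
#' @param p A `position_trace` (or list of traces from repeated
#'   experiments, aggregated together).
#' @param ref A `reference_geometry`.
#' @param t0_window `(start, end)` window, s.
#' @return Data frame: `crystal`, `mean_mm`, `sd_mm`, `n`.
#' @export
position_error <- function(p, ref, t0_window = c(0, 0.25)) {
  if (inherits(p, "position_trace")) p <- list(p)
  stopifnot(all(vapply(p, inherits, TRUE, "position_trace")),
            inherits(ref, "reference_geometry"))
  if (t0_window[2] <= t0_window[1]) stop("t0_window must be non-empty")
  refpos <- crystal_positions(ref)
  ids <- names(p[[1]]$crystals)
  out <- lapply(ids, function(b) {
    errs <- unlist(lapply(p, function(tr) {
      sel <- tr$time >= t0_window[1] & tr$time <= t0_window[2] &
        tr$valid[, b]
      if (!any(sel)) return(numeric())
      m <- tr$crystals[[b]][sel, , drop = FALSE]
      sqrt((m[, 1] - refpos[b, 1])^2 + (m[, 2] - refpos[b, 2])^2 +
             (m[, 3] - refpos[b, 3])^2)
    }))
    if (!length(errs)) stop("no valid samples in the window for ", b)
    data.frame(crystal = b, mean_mm = mean(errs),
               sd_mm = if (length(errs) > 1) stats::sd(errs) else 0,
               n = length(errs))
  })
  do.call(rbind, out)
}
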