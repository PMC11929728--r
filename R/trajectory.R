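#' Orthogonal line fit of a crystal trajectory in a Cartesian plane
#'
#' Projects a brain crystal's 3D trajectory onto one of the Cartesian
#' planes of the initial reference frame and fits the best line through the
#' 2D scatter by total least squares (minimizing perpendicular distances),
#' i.e. the principal axis of the centred scatter. The reported angle is
#' between the line and the plane's horizontal axis (X for the XY and XZ
#' planes, Y for the YZ plane), mapped to (-90, 90] degrees.
#'
#' @param p A `position_trace`.
#' @param crystal Crystal id.
#' @param plane `"XY"`, `"XZ"` or `"YZ"`.
#' @return A `trajectory_fit` list: `crystal`, `plane`, `angle_deg`,
#'   `rms_residual_mm`, `direction` (unit 2-vector).
#' @export
fit_plane_trajectory <- function(p, crystal, plane = c("XY", "XZ", "YZ")) {
  stopifnot(inherits(p, "position_trace"))
  plane <- match.arg(plane)
  axes <- switch(plane, XY = c(1, 2), XZ = c(1, 3), YZ = c(2, 3))
  sel <- p$valid[, crystal]
  if (sum(sel) < 3) stop("need at least 3 valid samples to fit a line")
  m <- p$crystals[[crystal]][sel, axes, drop = FALSE]
  ctr <- sweep(m, 2, colMeans(m))
  if (max(abs(ctr)) < 1e-9) stop("all points coincident: degenerate fit")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1]
  angle <- atan2(v[2], v[1]) * 180 / pi
  if (angle <= -90) angle <- angle + 180
  if (angle > 90) angle <- angle - 180
  perp <- ctr %*% pc$rotation[, 2]
  structure(list(crystal = crystal, plane = plane,
                 angle_deg = unname(angle),
                 rms_residual_mm = sqrt(mean(perp^2)),
                 direction = unname(v)),
            class = "trajectory_fit")
}

#' Aggregate per-set trajectory angles
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a
#' set of per-crystal-set mean angles, the "all crystal sets" summary row.
#'
#' @param per_set_means Numeric vector of per-set mean angles, degrees.
#' @return List with `mean` and `sd`, degrees.
#' @export
aggregate_angles <- function(per_set_means) {
  x <- as.numeric(per_set_means)
  if (length(x) < 2) stop("need at least 2 values to compute a SD")
  list(mean = mean(x), sd = stats::sd(x))
}

#' Estimate the traction-force direction from crystal trajectories
#'
#' Per crystal and per experiment, takes the 3D principal axis of the
#' position scatter, sign-aligned so that displacement at peak excursion is
#' positive along it; the traction-force direction is the normalized mean
#' of these unit vectors across all crystals and experiments. Per-plane 2D
#' angles from [fit_plane_trajectory()] are reported alongside for
#' comparison with the per-plane trajectory summaries.
#'
#' @param traces A `position_trace` or list of them (repeated experiments).
#' @param crystals Crystal ids to use; default all in the first trace.
#' @return List with `direction` (unit 3-vector), `per_axis` (matrix of the
#'   per-crystal/experiment axes), `per_plane_angles` (data frame:
#'   experiment, crystal, plane, angle_deg).
#' @export
estimate_force_direction <- function(traces, crystals = NULL) {
  if (inherits(traces, "position_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1)
  if (is.null(crystals)) crystals <- names(traces[[1]]$crystals)
  axes <- list()
  angles <- list()
  for (e in seq_along(traces)) {
    tr <- traces[[e]]
    for (b in intersect(crystals, names(tr$crystals))) {
      sel <- tr$valid[, b]
      if (sum(sel) < 3) next
      m <- tr$crystals[[b]][sel, , drop = FALSE]
      ctr <- sweep(m, 2, colMeans(m))
      if (max(abs(ctr)) < 1e-9) next
      pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
      v <- pc$rotation[, 1]
      # sign-align: displacement at the sample farthest from the start
      # must be positive along the axis
      disp <- sweep(m, 2, m[1, ])
      proj <- disp %*% v
      if (proj[which.max(abs(proj))] < 0) v <- -v
      axes[[length(axes) + 1L]] <- v
      for (pl in c("XY", "XZ", "YZ")) {
        # a trajectory can project to a single point in one plane
        ang <- tryCatch(fit_plane_trajectory(tr, b, pl)$angle_deg,
                        error = function(e) NA_real_)
        angles[[length(angles) + 1L]] <-
          data.frame(experiment = e, crystal = b, plane = pl,
                     angle_deg = ang)
      }
    }
  }
  if (!length(axes)) stop("degenerate scatter for all crystals")
  am <- do.call(rbind, axes)
  dirv <- colMeans(am)
  nd <- sqrt(sum(dirv^2))
  if (nd == 0) stop("mean trajectory axis is zero")
  list(direction = dirv / nd, per_axis = am,
       per_plane_angles = do.call(rbind, angles))
}

#' Build the traction-force reference frame
#'
#' Deterministic orthonormal completion of the traction-force direction
#' into a right-handed frame whose Z-axis is the force direction: X' is the
#' initial-frame X-axis minus its component along the direction (falling
#' back to the initial Y-axis when nearly parallel), Y' completes the
#' right-handed set.
#'
#' @param direction Unit 3-vector in the initial reference frame.
#' @return A `force_frame` list: `rotation` (3x3 orthonormal, rows X', Y',
#'   direction; maps initial-frame vectors into the force frame) and
#'   `force_direction`.
#' @export
build_force_frame <- function(direction) {
  nd <- sqrt(sum(direction^2))
  if (nd == 0) stop("direction must be non-zero")
  if (abs(nd - 1) > 1e-9) stop("direction must be a unit vector")
  dirv <- direction / nd
  seedx <- c(1, 0, 0)
  if (abs(sum(seedx * dirv)) > 0.99) seedx <- c(0, 1, 0)
  xp <- seedx - sum(seedx * dirv) * dirv
  xp <- xp / sqrt(sum(xp^2))
  yp <- cross3(dirv, xp)
  rot <- rbind(xp, yp, dirv)
  dimnames(rot) <- list(c("X'", "Y'", "Z'"), NULL)
  structure(list(rotation = rot, force_direction = dirv),
            class = "force_frame")
}

#' Express a vector in the traction-force frame
#'
#' @param frame A `force_frame`.
#' @param v 3-vector (or matrix with 3 columns) in the initial frame.
#' @return The same vector(s) with components (X', Y', Z' = force).
#' @export
to_force_frame <- function(frame, v) {
  stopifnot(inherits(frame, "force_frame"))
  if (is.matrix(v)) t(frame$rotation %*% t(v)) else
    as.numeric(frame$rotation %*% v)
}

#' Project crystal displacement on the traction-force direction
#'
#' For each crystal, the displacement from its mean rest position projected
#' on the force direction, then smoothed with the Gaussian-weighted moving
#' average.
#'
#' @param p A `position_trace`.
#' @param frame A `force_frame`.
#' @param t0_window Rest window defining the zero position, s.
#' @param gaussian_window Smoothing window, s; `NULL` to skip smoothing.
#' @return Named list of [vad_series()], displacement in mm per crystal.
#' @export
project_displacement <- function(p, frame, t0_window = c(0, 0.25),
                                 gaussian_window = 0.26) {
  stopifnot(inherits(p, "position_trace"), inherits(frame, "force_frame"))
  if (t0_window[2] <= t0_window[1]) stop("t0_window must be non-empty")
  dirv <- frame$force_direction
  out <- list()
  for (b in names(p$crystals)) {
    p0 <- mean_position(p, b, t0_window)
    disp <- sweep(p$crystals[[b]], 2, p0) %*% dirv
    s <- vad_series(p$time, as.numeric(disp), mask = p$valid[, b])
    if (!is.null(gaussian_window)) s <- gaussian_smooth(s, gaussian_window)
    out[[b]] <- s
  }
  out
}
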