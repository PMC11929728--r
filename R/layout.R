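#' Crystal layout
#'
#' Identities, roles, regions and initial (reference-frame) positions of all
#' piezoelectric crystals in a phantom experiment. The instrumented phantom
#' carries three fixed crystals (F1-F3) mounted in the rigid skull, which
#' serve as static trilateration references, and clusters of three brain
#' crystals (B1-B3) per instrumented brain region, which move with the brain
#' material.
#'
#' @param crystals A data frame with columns `id` (character), `role`
#'   (`"fixed"` or `"brain"`), `region` (`"cortical_under_cup"`,
#'   `"ventricular"`, `"sensorimotor"` or `"none"`), and numeric `x`, `y`,
#'   `z` positions in mm (initial reference frame).
#' @return A validated `crystal_layout` (the data frame with class added).
#' @details Invariants enforced: exactly three fixed crystals whose
#'   positions are non-collinear; each brain region present has exactly
#'   three brain crystals; all pairwise distances positive.
#' @export
crystal_layout <- function(crystals) {
  req <- c("id", "role", "region", "x", "y", "z")
  if (!is.data.frame(crystals) || !all(req %in% names(crystals))) {
    stop("`crystals` must be a data frame with columns ",
         paste(req, collapse = ", "))
  }
  crystals <- as.data.frame(crystals)[req]
  crystals$id <- as.character(crystals$id)
  crystals$role <- match.arg(crystals$role, c("fixed", "brain"),
                             several.ok = TRUE)
  fixed <- crystals[crystals$role == "fixed", ]
  if (nrow(fixed) != 3) stop("layout must contain exactly 3 fixed crystals")
  if (triangle_area(as.matrix(fixed[, c("x", "y", "z")])) < 1e-6) {
    stop("fixed crystals are collinear (degenerate trilateration base)")
  }
  brain <- crystals[crystals$role == "brain", ]
  for (reg in unique(brain$region)) {
    if (sum(brain$region == reg) != 3) {
      stop("brain region '", reg, "' must contain exactly 3 crystals")
    }
  }
  key <- paste(crystals$region, crystals$id)
  if (anyDuplicated(key)) stop("duplicate crystal id within a region")
  pos <- as.matrix(crystals[, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(pos))
  if (any(dmat[upper.tri(dmat)] <= 0)) {
    stop("all pairwise crystal distances must be positive")
  }
  class(crystals) <- c("crystal_layout", "data.frame")
  crystals
}

# Area of the triangle spanned by the rows of a 3x3 position matrix (mm^2).
triangle_area <- function(p) {
  stopifnot(is.matrix(p), nrow(p) == 3, ncol(p) == 3)
  0.5 * sqrt(sum(cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a crystal layout
#'
#' Builds either the named default phantom layout or validates an explicit
#' one. The default places three fixed crystals at the skull base and three
#' brain-crystal clusters (cortical region under the suction cup,
#' ventricular region, sensorimotor cortical region) whose within-region
#' pairwise separations fall in the 3-22 mm range observed in the phantom,
#' plus a small seeded positional jitter emulating imprecision of crystal
#' placement during casting.
#'
#' @param template `"phantom"` for the named default, or a data frame of
#'   explicit crystal positions (see [crystal_layout()]).
#' @param seed Integer seed for the placement jitter.
#' @param jitter_sd Standard deviation of the positional jitter, mm.
#' @return A `crystal_layout`.
#' @export
generate_layout <- function(template = "phantom", seed = 1L, jitter_sd = 0.4) {
  if (is.data.frame(template)) {
    return(crystal_layout(template))
  }
  if (!identical(template, "phantom")) {
    stop("unknown layout template '", template, "'")
  }
  fixed <- data.frame(
    id = c("F1", "F2", "F3"), role = "fixed", region = "none",
    x = c(-40, 45, 0), y = c(-30, -25, 40), z = c(0, 5, -5)
  )
  # Region centres (mm) and within-region offsets chosen so that pairwise
  # separations span roughly 3-22 mm and each cluster has one well-aligned
  # long pair along the nominal traction direction.
  regions <- list(
    cortical_under_cup = list(
      centre = c(10, 15, 60),
      offsets = rbind(c(0, 0, 0), c(3.5, 5.5, 15.0), c(9.5, 2.5, 2.0))
    ),
    ventricular = list(
      centre = c(0, 0, 35),
      offsets = rbind(c(0, 0, 0), c(2.5, 6.0, 7.5), c(1.5, 3.0, 11.0))
    ),
    sensorimotor = list(
      centre = c(-18, 20, 48),
      offsets = rbind(c(0, 0, 0), c(14.0, 4.0, 10.5), c(2.0, 3.5, 9.5))
    )
  )
  withr_seed(seed, {
    brain <- do.call(rbind, lapply(names(regions), function(reg) {
      r <- regions[[reg]]
      pos <- sweep(r$offsets, 2, r$centre, `+`) +
        matrix(stats::rnorm(9, sd = jitter_sd), 3, 3)
      data.frame(id = c("B1", "B2", "B3"), role = "brain", region = reg,
                 x = pos[, 1], y = pos[, 2], z = pos[, 3])
    }))
  })
  crystal_layout(rbind(fixed, brain))
}

# Run `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Positions of a set of crystals as a matrix
#'
#' @param layout A `crystal_layout` or reference-geometry data frame.
#' @param role Optional role filter (`"fixed"` or `"brain"`).
#' @param region Optional region filter.
#' @return Numeric matrix with one row per crystal, rownames = crystal ids.
#' @export
crystal_positions <- function(layout, role = NULL, region = NULL) {
  df <- as.data.frame(layout)
  if (!is.null(role)) df <- df[df$role == role, ]
  if (!is.null(region)) df <- df[df$region == region, ]
  pos <- as.matrix(df[, c("x", "y", "z")])
  rownames(pos) <- df$id
  pos
}

#' Single-region experiment view of a layout
#'
#' The sonomicrometry system drives six channels at a time (three fixed +
#' three brain crystals), so each experiment instruments one brain region.
#' This extracts the fixed crystals plus one region's brain crystals.
#'
#' @param layout A `crystal_layout`.
#' @param region Brain region to instrument.
#' @return A `crystal_layout` with 3 fixed + 3 brain crystals.
#' @export
experiment_layout <- function(layout, region) {
  df <- as.data.frame(layout)
  keep <- df$role == "fixed" | df$region == region
  if (sum(df$role == "brain" & df$region == region) != 3) {
    stop("region '", region, "' is not present in the layout")
  }
  crystal_layout(df[keep, ])
}

#' Deformation model for synthetic experiments
#'
#' Quasi-static affine response along a single direction: the position of
#' brain crystal b at time t is
#' `position0(b) + (rigid_compliance + per_crystal_compliance[b]) * F(t) * force_direction`.
#' Fixed crystals never move. The shared rigid compliance translates the
#' whole brain (zero strain); differences between per-crystal compliances
#' generate strain with a closed-form target.
#'
#' @param force_direction Unit 3-vector, initial reference frame.
#' @param rigid_compliance Shared displacement per unit force, mm/N.
#' @param per_crystal_compliance Named numeric vector, crystal id ->
#'   additional compliance, mm/N.
#' @return A `deformation_model` list.
#' @export
deformation_model <- function(force_direction = c(0.25, -0.35, 0.9),
                              rigid_compliance = 0.012,
                              per_crystal_compliance = c(B1 = 0.0060,
                                                         B2 = 0.0072,
                                                         B3 = 0.0048)) {
  nd <- sqrt(sum(force_direction^2))
  if (nd == 0) stop("force_direction must be non-zero")
  force_direction <- force_direction / nd
  if (rigid_compliance < 0 || any(per_crystal_compliance < 0)) {
    stop("compliances must be >= 0")
  }
  if (is.null(names(per_crystal_compliance))) {
    stop("per_crystal_compliance must be named by crystal id")
  }
  structure(list(force_direction = force_direction,
                 rigid_compliance = rigid_compliance,
                 per_crystal_compliance = per_crystal_compliance),
            class = "deformation_model")
}

#' Measurement-noise configuration for the synthetic sonomicrometry channel
#'
#' @param distance_noise_sd Gaussian noise on each measured distance, mm.
#' @param channel_scale_bias_range Per-pair multiplicative bias is drawn
#'   uniformly from this `(low, high)` interval, once per pair. Exercises
#'   the calibration stage.
#' @param outlier_rate Probability per sample of an injected outlier.
#' @param outlier_magnitude_sd SD of the additive outlier magnitude, mm.
#' @param seed Integer RNG seed.
#' @return A `measurement_noise` list.
#' @export
measurement_noise <- function(distance_noise_sd = 0.01,
                              channel_scale_bias_range = c(0.95, 1.05),
                              outlier_rate = 0.005,
                              outlier_magnitude_sd = 5,
                              seed = 1L) {
  if (distance_noise_sd < 0 || outlier_magnitude_sd < 0) {
    stop("noise standard deviations must be >= 0")
  }
  if (outlier_rate < 0 || outlier_rate >= 1) {
    stop("outlier_rate must be in [0, 1)")
  }
  r <- as.numeric(channel_scale_bias_range)
  if (length(r) != 2 || r[1] > r[2] || r[1] <= 0) {
    stop("channel_scale_bias_range must be (low, high) with 0 < low <= high")
  }
  structure(list(distance_noise_sd = distance_noise_sd,
                 channel_scale_bias_range = r,
                 outlier_rate = outlier_rate,
                 outlier_magnitude_sd = outlier_magnitude_sd,
                 seed = as.integer(seed)),
            class = "measurement_noise")
}
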