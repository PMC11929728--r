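#' Simulate ground-truth crystal kinematics
#'
#' Drives a crystal layout with a force trace under the quasi-static affine
#' deformation model: brain crystal `b` moves along the force direction by
#' `(rigid_compliance + per_crystal_compliance[b]) * F(t)` mm; fixed
#' crystals are static throughout. The closed-form ground-truth engineering
#' strain for an ordered brain-crystal pair `(i, j)` is
#' `(c_i - c_j) * F(t) / D0`, with `D0` the initial pair separation
#' projected on the force direction (pairs ordered so `D0 > 0`).
#'
#' @param layout A single-experiment `crystal_layout` (3 fixed + 3 brain).
#' @param force A `force_trace`.
#' @param model A [deformation_model()]; its compliance names must cover
#'   the layout's brain crystals.
#' @param sample_rate Sonomicrometry sampling rate, Hz (default 200.3).
#' @return A `kinematics_truth` list: `positions` (a `position_trace` of
#'   the brain crystals), `fixed` (static fixed-crystal positions),
#'   `force_on_clock` (force resampled on the sonomicrometry clock),
#'   `strain` (list of `vad_series`, one per ordered brain pair with
#'   `D0 > 0`), `pair_D0`, `model`.
#' @export
simulate_kinematics <- function(layout, force, model,
                                sample_rate = 200.3) {
  stopifnot(inherits(layout, "crystal_layout"),
            inherits(force, "force_trace"),
            inherits(model, "deformation_model"))
  brain <- crystal_positions(layout, role = "brain")
  if (!all(rownames(brain) %in% names(model$per_crystal_compliance))) {
    stop("model compliances must name every brain crystal in the layout")
  }
  duration <- max(force$time_s)
  time <- seq(0, duration, by = 1 / sample_rate)
  f <- force_at(force, time)
  dirv <- model$force_direction
  comp <- model$rigid_compliance +
    model$per_crystal_compliance[rownames(brain)]

  crystals <- lapply(seq_len(nrow(brain)), function(i) {
    outer(comp[i] * f, dirv) +
      matrix(brain[i, ], nrow = length(time), ncol = 3, byrow = TRUE)
  })
  names(crystals) <- rownames(brain)
  positions <- position_trace(time, crystals)

  ids <- rownames(brain)
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  strain <- list()
  pair_D0 <- list()
  for (p in pairs) {
    i <- p[1]; j <- p[2]
    D0 <- sum((brain[i, ] - brain[j, ]) * dirv)
    if (D0 < 0) { tmp <- i; i <- j; j <- tmp; D0 <- -D0 }
    key <- paste0(i, "-", j)
    if (abs(D0) < .Machine$double.eps^0.5) {
      # pair perpendicular to the force direction: strain undefined
      strain[[key]] <- NA
      pair_D0[[key]] <- 0
      next
    }
    dc <- model$per_crystal_compliance[i] - model$per_crystal_compliance[j]
    strain[[key]] <- vad_series(time, dc * f / D0)
    pair_D0[[key]] <- D0
  }
  structure(list(positions = positions,
                 fixed = crystal_positions(layout, role = "fixed"),
                 force_on_clock = vad_series(time, f),
                 strain = strain,
                 pair_D0 = unlist(pair_D0),
                 model = model),
            class = "kinematics_truth")
}

#' Synthesize sonomicrometry distance measurements
#'
#' Emulates the sonomicrometry channel: for every fixed-brain crystal pair
#' the measured distance at each sample is
#' `bias_pair * (true Euclidean distance + Gaussian noise)`, with sporadic
#' additive outliers injected at `outlier_rate`. The per-pair multiplicative
#' bias is drawn once per pair from the configured range and exercises the
#' calibration stage. The exact t = 0 positions are returned as the
#' reference geometry, playing the role of the CT scan of the phantom.
#'
#' @param truth A `kinematics_truth` from [simulate_kinematics()].
#' @param layout The `crystal_layout` used for the simulation.
#' @param noise A [measurement_noise()] configuration.
#' @return A list: `distances` (an uncalibrated `distance_traces`),
#'   `reference` (a `reference_geometry`), `bias` (named per-pair bias
#'   factors), `outliers` (data frame logging every injected outlier).
#' @export
synthesize_distances <- function(truth, layout, noise = measurement_noise()) {
  stopifnot(inherits(truth, "kinematics_truth"),
            inherits(noise, "measurement_noise"))
  fixed <- truth$fixed
  pos <- truth$positions
  time <- pos$time
  n <- length(time)
  fids <- rownames(fixed)
  bids <- names(pos$crystals)
  pairs <- expand.grid(fixed = fids, brain = bids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$fixed, pairs$brain), ]
  pair_names <- paste0(pairs$fixed, "-", pairs$brain)

  d <- matrix(NA_real_, n, nrow(pairs), dimnames = list(NULL, pair_names))
  for (k in seq_len(nrow(pairs))) {
    fp <- fixed[pairs$fixed[k], ]
    bp <- pos$crystals[[pairs$brain[k]]]
    d[, k] <- sqrt((bp[, 1] - fp[1])^2 + (bp[, 2] - fp[2])^2 +
                     (bp[, 3] - fp[3])^2)
  }

  outlog <- NULL
  withr_seed(noise$seed, {
    bias <- stats::runif(nrow(pairs), noise$channel_scale_bias_range[1],
                         noise$channel_scale_bias_range[2])
    names(bias) <- pair_names
    meas <- d + matrix(stats::rnorm(n * nrow(pairs),
                                    sd = noise$distance_noise_sd),
                       n, nrow(pairs))
    hit <- matrix(stats::runif(n * nrow(pairs)) < noise$outlier_rate,
                  n, nrow(pairs))
    if (any(hit)) {
      mag <- stats::rnorm(sum(hit), sd = noise$outlier_magnitude_sd)
      meas[hit] <- meas[hit] + mag
      idx <- which(hit, arr.ind = TRUE)
      outlog <- data.frame(sample = idx[, 1],
                           pair = pair_names[idx[, 2]],
                           magnitude = mag)
    }
    meas <- sweep(meas, 2, bias, `*`)
  })

  ref <- reference_geometry(layout_at_t0(layout, pos),
                            provenance = "synthetic-truth")
  list(distances = distance_traces(time, meas),
       reference = ref,
       bias = bias,
       outliers = if (is.null(outlog)) {
         data.frame(sample = integer(), pair = character(),
                    magnitude = numeric())
       } else outlog)
}

# Reference positions at t = 0: fixed crystals from the layout, brain
# crystals from the simulated (exact) initial positions.
layout_at_t0 <- function(layout, pos) {
  df <- as.data.frame(layout)
  for (id in names(pos$crystals)) {
    i <- which(df$id == id & df$role == "brain")
    df[i, c("x", "y", "z")] <- pos$crystals[[id]][1, ]
  }
  df
}

#' Simulate a complete synthetic VAD experiment
#'
#' Convenience wrapper chaining [generate_force_waveform()],
#' [simulate_kinematics()] and [synthesize_distances()] for one brain
#' region, mirroring one physical experiment (six active sonomicrometry
#' channels: three fixed plus three brain crystals).
#'
#' @param peak Peak traction force, N.
#' @param region Instrumented brain region.
#' @param mode `"manual"` or `"automatic"` force setup.
#' @param layout Full phantom `crystal_layout`.
#' @param model A [deformation_model()].
#' @param noise A [measurement_noise()]; its seed is combined with `seed`.
#' @param seed Integer experiment seed (drives force jitter and noise).
#' @param duration,rate,pad Waveform parameters, see
#'   [generate_force_waveform()].
#' @return A `vad_experiment` list: `force`, `truth`, `distances`,
#'   `reference`, `bias`, `outliers`, `layout` (the experiment view),
#'   `config`.
#' @export
simulate_experiment <- function(peak, region = "cortical_under_cup",
                                mode = c("manual", "automatic"),
                                layout = generate_layout(),
                                model = deformation_model(),
                                noise = measurement_noise(),
                                seed = 1L, duration = 10, rate = 30,
                                pad = 0.5) {
  mode <- match.arg(mode)
  exl <- experiment_layout(layout, region)
  force <- generate_force_waveform(peak, rate = rate, duration = duration,
                                   pad = pad, mode = mode, seed = seed)
  truth <- simulate_kinematics(exl, force, model)
  noise$seed <- as.integer(noise$seed + 1000L * seed) %% .Machine$integer.max
  syn <- synthesize_distances(truth, exl, noise)
  structure(list(force = force, truth = truth,
                 distances = syn$distances, reference = syn$reference,
                 bias = syn$bias, outliers = syn$outliers, layout = exl,
                 config = list(peak = peak, region = region, mode = mode,
                               seed = seed, duration = duration,
                               rate = rate, pad = pad, noise = unclass(noise))),
            class = "vad_experiment")
}
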