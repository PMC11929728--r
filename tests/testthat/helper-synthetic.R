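# Shared helpers for building small synthetic inputs in tests.

# A quick noiseless experiment (unit bias, no outliers) for exact-recovery
# checks. Short duration keeps the suite fast.
quiet_experiment <- function(peak = 100, duration = 8, seed = 1L,
                             region = "cortical_under_cup",
                             mode = "automatic",
                             model = deformation_model()) {
  noise <- measurement_noise(distance_noise_sd = 0,
                             channel_scale_bias_range = c(1, 1),
                             outlier_rate = 0, seed = seed)
  simulate_experiment(peak = peak, region = region, mode = mode,
                      model = model, noise = noise, seed = seed,
                      duration = duration)
}

# Independent brute-force scaled-MAD filter used as the oracle.
brute_mad_keep <- function(x, k = 3) {
  med <- median(x)
  smad <- 1.4826 * median(abs(x - med))
  abs(x - med) <= k * smad
}

# Independent multi-start least-squares trilateration oracle. Starts are
# drawn on the first sphere's surface (one constraint already satisfied),
# batches are added until the optimizer has converged to a tight optimum.
oracle_trilaterate <- function(centers, radii, n_starts = 8, seed = 1,
                               value_tol = NULL) {
  obj <- function(p) {
    d <- sqrt(colSums((t(centers) - p)^2))
    sum((d - radii)^2)
  }
  # Gauss-Newton polish: quadratic convergence on the residual vector
  # res_i(p) = ||p - c_i|| - r_i once inside the right basin
  polish <- function(p) {
    for (it in 1:30) {
      dv <- t(p - t(centers))
      d <- sqrt(rowSums(dv^2))
      res <- d - radii
      J <- dv / d
      step <- tryCatch(solve(crossprod(J) + 1e-12 * diag(3),
                             crossprod(J, res)),
                       error = function(e) NULL)
      if (is.null(step)) break
      # damped step: GN can overshoot when the spheres are inconsistent
      lambda <- 1
      v0 <- obj(p)
      repeat {
        cand <- p - lambda * as.numeric(step)
        if (obj(cand) <= v0 || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      if (obj(cand) > v0) break
      p <- cand
      if (lambda * sqrt(sum(step^2)) < 1e-12) break
    }
    p
  }
  set.seed(seed)
  best_p <- NULL
  best_v <- Inf
  for (batch in 1:5) {
    for (i in seq_len(n_starts)) {
      u <- rnorm(3)
      start <- centers[1, ] + radii[1] * u / sqrt(sum(u^2))
      fit <- optim(start, obj, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-16))
      p <- polish(fit$par)
      v <- obj(p)
      if (v < best_v) { best_v <- v; best_p <- p }
    }
    if (is.null(value_tol) || best_v < value_tol) break
  }
  best_p
}

# Angle in degrees between two 3-vectors, ignoring sign.
angle_between_deg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, ca)) * 180 / pi
}

# Fresh temporary directory cleaned up with the test run.
withr_tempdir <- function() {
  d <- tempfile("vadstrain-test-")
  dir.create(d)
  d
}

withr_seed <- vadstrain:::withr_seed
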