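ref6 <- function() {
  reference_geometry(data.frame(
    id = c("F1", "F2", "F3", "B1", "B2", "B3"),
    role = rep(c("fixed", "brain"), each = 3),
    region = rep(c("none", "cortical_under_cup"), each = 3),
    x = c(0, 10, 0, 3, 5, 1), y = c(0, 0, 10, 4, 2, 6),
    z = c(0, 0, 0, 5, 7, 4)), provenance = "synthetic-truth")
}

test_that("calibration factors are reference distance over window mean", {
  ref <- ref6()
  time <- seq(0, 1, by = 0.01)
  dct <- reference_distance(ref, "F1", "B1")
  # constant measured distance of 8 mm against a 10 mm reference -> f = 1.25
  d <- distance_traces(time, matrix(8, length(time), 1,
                                    dimnames = list(NULL, "F1-B1")))
  fake_ref <- reference_geometry(data.frame(
    id = c("F1", "F2", "F3", "B1", "B2", "B3"),
    role = rep(c("fixed", "brain"), each = 3),
    region = rep(c("none", "cortical_under_cup"), each = 3),
    x = c(0, 10, 0, 6, 5, 1), y = c(0, 0, 10, 8, 2, 6),
    z = c(0, 0, 0, 0, 7, 4)), provenance = "synthetic-truth")
  cal <- compute_calibration(d, fake_ref)
  expect_equal(unname(unclass(cal)["F1-B1"]), 1.25)
  # identity when the window mean equals the reference distance
  d2 <- distance_traces(time, matrix(dct, length(time), 1,
                                     dimnames = list(NULL, "F1-B1")))
  expect_equal(unname(unclass(compute_calibration(d2, ref))["F1-B1"]), 1)
})

test_that("calibration recovers the inverse of a synthetic per-pair bias", {
  noise <- measurement_noise(distance_noise_sd = 0,
                             channel_scale_bias_range = c(0.9, 1.1),
                             outlier_rate = 0, seed = 4)
  exp1 <- simulate_experiment(peak = 70, mode = "automatic", noise = noise,
                              duration = 8, seed = 4)
  cal <- compute_calibration(exp1$distances, exp1$reference)
  expect_equal(unclass(cal)[names(exp1$bias)], 1 / exp1$bias,
               tolerance = 1e-9)
  d <- apply_calibration(exp1$distances, cal)
  # post-calibration rest-window mean equals the reference distance
  in_win <- d$time <= 0.25
  for (k in seq_len(ncol(d$d))) {
    dct <- reference_distance(exp1$reference, d$pairs$fixed[k],
                              d$pairs$brain[k])
    expect_equal(mean(d$d[in_win, k]), dct, tolerance = 1e-9 * dct)
  }
  expect_true(d$calibrated)
  expect_error(apply_calibration(d, cal), "already calibrated")
})

test_that("calibration errors name the offending pair", {
  time <- seq(0, 1, by = 0.01)
  m <- matrix(10, length(time), 1, dimnames = list(NULL, "F1-B1"))
  mask <- matrix(TRUE, length(time), 1)
  mask[time <= 0.25, 1] <- FALSE
  d <- distance_traces(time, m, mask)
  expect_error(compute_calibration(d, ref6()), "F1-B1")
})

test_that("trilateration reproduces an exactly constructed point", {
  centers <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  target <- c(3, 4, 5)
  r <- sqrt(colSums((t(centers) - target)^2))
  sol <- trilaterate(centers, r, side_rule = +1)
  expect_equal(sol$position, target, tolerance = 1e-9)
  expect_lt(sol$residual, 1e-9)
  # mirror solution on the other hemisphere
  sol2 <- trilaterate(centers, r, side_rule = -1)
  expect_equal(sol2$position, c(3, 4, -5), tolerance = 1e-9)
  # prior overrides the hemisphere rule
  sol3 <- trilaterate(centers, r, prior = c(3, 4, -4.8), side_rule = +1)
  expect_equal(sol3$position, c(3, 4, -5), tolerance = 1e-9)
  expect_true(sol3$mirror_used)
})

test_that("a target in the centers' plane has a unique solution", {
  centers <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  target <- c(3, 4, 0)
  r <- sqrt(colSums((t(centers) - target)^2))
  for (side in c(+1, -1)) {
    sol <- trilaterate(centers, r, side_rule = side)
    expect_equal(sol$position, target, tolerance = 1e-7)
  }
})

test_that("non-intersecting spheres fall back to least squares", {
  centers <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  sol <- trilaterate(centers, c(1, 1, 1))
  oracle <- oracle_trilaterate(centers, c(1, 1, 1))
  expect_equal(
    sqrt(sum((sol$position - centers[1, ])^2)) - 1,
    sqrt(sum((oracle - centers[1, ])^2)) - 1,
    tolerance = 1e-3)
  expect_lt(sum(abs(sol$position[3])), 1e-3)  # optimum lies in the plane
  expect_gt(sol$residual, 1)
})

test_that("collinear centers are rejected", {
  centers <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0))
  expect_error(trilaterate(centers, c(1, 2, 3)), "collinear")
})

test_that("closed form agrees with the least-squares oracle on random geometry", {
  set.seed(21)
  for (i in 1:40) {
    centers <- matrix(runif(9, -50, 50), 3, 3)
    if (vadstrain:::triangle_area(centers) < 25) next
    target <- runif(3, -40, 40)
    r <- sqrt(colSums((t(centers) - target)^2))
    sol <- trilaterate(centers, r, prior = target + rnorm(3, sd = 0.1))
    oracle <- oracle_trilaterate(centers, r, seed = i)
    # the oracle may land on either mirror solution; compare residuals and
    # the solution nearest the target
    expect_lt(sqrt(sum((sol$position - target)^2)), 1e-6)
    expect_lt(vadstrain:::rms_mismatch(oracle, centers, r), 1e-5)
  }
})

test_that("trilateration is equivariant under rigid transforms", {
  set.seed(31)
  centers <- rbind(c(0, 0, 0), c(12, 0, 0), c(3, 9, 0))
  target <- c(4, 2, 6)
  r <- sqrt(colSums((t(centers) - target)^2))
  for (i in 1:5) {
    # random rotation (QR of a Gaussian matrix) + translation
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    tr <- runif(3, -20, 20)
    centers2 <- t(R %*% t(centers)) + matrix(tr, 3, 3, byrow = TRUE)
    prior2 <- as.numeric(R %*% target) + tr
    sol <- trilaterate(centers2, r, prior = prior2)
    expect_equal(sol$position, as.numeric(R %*% target) + tr,
                 tolerance = 1e-6)
  }
})

test_that("noiseless synthetic traces are recovered to numerical precision", {
  exp1 <- quiet_experiment(peak = 100, duration = 8)
  cal <- compute_calibration(exp1$distances, exp1$reference)
  d <- apply_calibration(exp1$distances, cal)
  pos <- trilaterate_trace(d, exp1$reference)
  for (b in names(pos$crystals)) {
    err <- pos$crystals[[b]] - exp1$truth$positions$crystals[[b]]
    expect_lt(max(abs(err[pos$valid[, b], ])), 1e-6)
    expect_true(all(pos$valid[, b]))
  }
  # rest-position error is numerically zero (noiseless)
  pe <- position_error(pos, exp1$reference)
  expect_lt(max(pe$mean_mm), 1e-6)
})

test_that("default-noise recovery stays within the noise floor", {
  exp1 <- simulate_experiment(peak = 100, mode = "automatic", seed = 9,
                              noise = measurement_noise(seed = 9))
  d <- exp1$distances
  for (k in seq_len(ncol(d$d))) {
    d$mask[, k] <- despike(vad_series(d$time, d$d[, k], d$mask[, k]))$mask
  }
  # every injected outlier exceeds the despike threshold on these traces
  caught <- mapply(function(i, p) !d$mask[i, p],
                   exp1$outliers$sample, exp1$outliers$pair)
  expect_gt(mean(caught), 0.95)
  cal <- compute_calibration(d, exp1$reference)
  pos <- trilaterate_trace(apply_calibration(d, cal), exp1$reference)
  rms <- sapply(names(pos$crystals), function(b) {
    ok <- pos$valid[, b]
    err <- pos$crystals[[b]][ok, ] - exp1$truth$positions$crystals[[b]][ok, ]
    sqrt(mean(rowSums(err^2)))
  })
  expect_lt(max(rms), 3 * 0.01)
})

test_that("despike removes spikes but never slow motion", {
  t <- seq(0, 10, by = 1 / 200)
  slow <- 2 * pmin(1, pmax(0, (t - 2) / 3))   # quasi-static ramp + plateau
  set.seed(6)
  x <- 10 + slow + rnorm(length(t), sd = 0.01)
  spikes <- sample(length(t), 8)
  x[spikes] <- x[spikes] + 5
  out <- despike(vad_series(t, x))
  expect_true(all(!out$mask[spikes]))
  # only the ~0.3-1% Gaussian tail beyond 3 scaled MADs goes with them
  expect_gt(mean(out$mask), 0.98)
  # a global MAD filter on the same trace would flag the whole rest phase;
  # despike keeps it (up to the same Gaussian tail)
  expect_gt(mean(out$mask[t <= 0.25]), 0.95)
})

test_that("position_error reports exact offsets", {
  exp1 <- quiet_experiment(peak = 50, duration = 8)
  pos <- exp1$truth$positions
  pos2 <- pos
  pos2$crystals <- lapply(pos$crystals, function(m) {
    m[, 1] <- m[, 1] + 0.1; m
  })
  pe <- position_error(pos2, exp1$reference)
  expect_equal(pe$mean_mm, rep(0.1, 3), tolerance = 1e-9)
  expect_equal(pe$sd_mm, rep(0, 3), tolerance = 1e-9)
  pe0 <- position_error(pos, exp1$reference)
  expect_equal(pe0$mean_mm, rep(0, 3), tolerance = 1e-12)
})

test_that("bias-corrupted noiseless data are fully recovered after calibration", {
  noise <- measurement_noise(distance_noise_sd = 0,
                             channel_scale_bias_range = c(0.95, 1.05),
                             outlier_rate = 0, seed = 12)
  exp1 <- simulate_experiment(peak = 90, mode = "automatic", noise = noise,
                              duration = 8, seed = 12)
  cal <- compute_calibration(exp1$distances, exp1$reference)
  pos <- trilaterate_trace(apply_calibration(exp1$distances, cal),
                           exp1$reference)
  for (b in names(pos$crystals)) {
    err <- pos$crystals[[b]] - exp1$truth$positions$crystals[[b]]
    expect_lt(max(abs(err)), 1e-6)
  }
})
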