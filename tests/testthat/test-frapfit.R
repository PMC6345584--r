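# FRAP normalization and mono-exponential recovery fitting.

test_that("normalization fixes the prebleach level and cancels common scaling", {
  # constant trace at the prebleach level normalizes to exactly 1
  tr <- frap_trace(times = 0:9 * 5, roi_intensity = rep(800, 10),
                   whole_image_intensity = rep(1200, 10), n_prebleach = 3)
  nt <- normalize_trace(tr)
  expect_equal(nt$f_norm, rep(1, 7), tolerance = 1e-12)
  expect_equal(nt$times_post, (1:7) * 5)

  # uniform halving of both ROI and whole image leaves f_norm unchanged
  roi <- c(rep(100, 3), 40 + 30 * (1 - exp(-0.05 * (1:10) * 5)))
  whole <- rep(900, 13)
  t1 <- frap_trace(0:12 * 5, roi, whole, 3)
  t2 <- frap_trace(0:12 * 5, roi / 2, whole / 2, 3)
  expect_equal(normalize_trace(t1)$f_norm, normalize_trace(t2)$f_norm,
               tolerance = 1e-12)

  expect_error(normalize_trace(frap_trace(0:5, rep(1, 6), c(1, 1, 1, 0, 1, 1))),
               "positive")
})

test_that("fading correction inverts the generator's fading exactly", {
  base <- frap_truth(0.0231, 0.75, postbleach_floor = 0.2, fading_rate = 0)
  faded <- frap_truth(0.0231, 0.75, postbleach_floor = 0.2,
                      fading_rate = 0.001)
  n0 <- normalize_trace(make_frap_series(base, 40))
  n1 <- normalize_trace(make_frap_series(faded, 40))
  expect_equal(n1$f_norm, n0$f_norm, tolerance = 1e-9)
})

test_that("noiseless fits reproduce the generating parameters", {
  tr <- make_frap_series(frap_truth(0.0231, 0.75, postbleach_floor = 0.2),
                         n_post = 36)
  fit <- fit_recovery(normalize_trace(tr))
  expect_equal(fit$t_half, 30.0, tolerance = 0.1 / 30)
  expect_equal(fit$mobile_fraction_pct, 75.0, tolerance = 0.1 / 75)
  expect_equal(fit$rate_k, 0.0231, tolerance = 1e-6)
  expect_equal(fit$plateau, 0.8, tolerance = 1e-6)
  expect_equal(fit$floor, 0.2, tolerance = 1e-6)
  expect_false(fit$non_recovering)
  # t_half * k = ln 2 exactly, by construction of the returned fit
  expect_equal(fit$t_half * fit$rate_k, log(2), tolerance = 1e-12)
  # predict/residuals methods are consistent
  expect_equal(predict(fit) + residuals(fit), fit$f_norm, tolerance = 1e-12)
})

test_that("a flat trace is flagged non-recovering with zero mobile fraction", {
  nt <- structure(list(times_post = (1:10) * 5, f_norm = rep(0.3, 10)),
                  class = "normalized_trace")
  fit <- fit_recovery(nt)
  expect_true(fit$non_recovering)
  expect_equal(fit$mobile_fraction_pct, 0, tolerance = 1e-6)
})

test_that("the fit is invariant to a consistent shift of the time origin", {
  tr <- make_frap_series(frap_truth(0.03, 0.8, postbleach_floor = 0.25,
                                    noise_sigma = 0.01, seed = 5),
                         n_post = 40)
  nt <- normalize_trace(tr)
  f1 <- fit_recovery(nt)
  # shift the clock and correct back: identical data, identical fit
  nt2 <- nt; nt2$times_post <- (nt$times_post + 17) - 17
  f2 <- fit_recovery(nt2)
  expect_equal(f1$rate_k, f2$rate_k, tolerance = 1e-6)
})

test_that("noisy recovery estimates k and mobile fraction within tolerance", {
  res <- vapply(1:30, function(seed) {
    tr <- make_frap_series(frap_truth(0.0231, 0.75, postbleach_floor = 0.2,
                                      noise_sigma = 0.02, seed = seed),
                           n_post = 36)
    fit <- fit_recovery(normalize_trace(tr))
    c(abs(fit$rate_k - 0.0231) / 0.0231,
      abs(fit$mobile_fraction_raw - 75))
  }, numeric(2))
  expect_lt(stats::median(res[1, ]), 0.10)  # k within 10% (median)
  expect_lt(stats::median(res[2, ]), 5)     # mobile fraction within 5 points
})

test_that("bootstrap confidence intervals cover the true rate", {
  cover <- vapply(1:25, function(seed) {
    tr <- make_frap_series(frap_truth(0.0231, 0.75, postbleach_floor = 0.2,
                                      noise_sigma = 0.02, seed = seed),
                           n_post = 36)
    fit <- fit_recovery(normalize_trace(tr))
    ci <- frap_boot_ci(fit, n_boot = 100, seed = seed)
    ci$k_lower <= 0.0231 && 0.0231 <= ci$k_upper
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("trace extraction from an image stack feeds the fit", {
  # flat frames whose ROI recovers while the whole image stays constant
  shape <- c(64, 64)
  mkframe <- function(roi_val) {
    x <- matrix(100, shape[1], shape[2])
    pr <- matrix(rep(0:(shape[1] - 1), shape[2]), shape[1])
    pc <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1])
    inroi <- (pr - 32)^2 + (pc - 32)^2 <= 12.5^2
    x[inroi] <- roi_val
    x
  }
  model <- c(rep(100, 3), 100 * (0.8 - 0.6 * exp(-0.0231 * (1:40) * 5)))
  frames <- lapply(model, mkframe)
  tr <- extract_frap_trace(frames, roi_center = c(32, 32), roi_diameter = 25,
                           frame_interval = 5, n_prebleach = 3)
  # the circular-ROI masked mean reproduces the per-frame ROI values
  expect_equal(tr$roi_intensity, model, tolerance = 1e-12)
  expect_equal(tr$times, 0:42 * 5)
  expect_identical(tr$n_prebleach, 3L)
})
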