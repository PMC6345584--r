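# Synthetic generators: determinism, closed-form agreement, and the
# construction rules the downstream tests rely on.

test_that("vesicle scenes follow the closed-form model and construction rules", {
  # no sources, no noise: both channels constant at background
  tr0 <- scene_truth(0, c(32, 32), background_level = 100, seed = 1)
  sc0 <- make_vesicle_scene(tr0)
  expect_true(all(sc0$channel_a == 100))
  expect_true(all(sc0$channel_b == 100))

  # single spot centered on an integer pixel: peak = background + amplitude
  tr1 <- scene_truth(1, c(33, 33), vesicle_centers = rbind(c(16, 16)),
                     vesicle_amplitudes = 50, background_level = 10, seed = 1)
  sc1 <- make_vesicle_scene(tr1)
  expect_equal(max(sc1$channel_a), 60, tolerance = 1e-12)
  expect_equal(unclass(sc1$channel_a)[17, 17], 60, tolerance = 1e-12,
               ignore_attr = TRUE)

  # coloc construction: exactly round(f * n) duplicated centers
  tr2 <- scene_truth(20, c(128, 128), coloc_fraction = 0.5, seed = 4)
  sc2 <- make_vesicle_scene(tr2)
  expect_identical(nrow(sc2$truth$coloc_centers_b), 10L)
  expect_true(all(sc2$truth$coloc_centers_b %in% tr2$vesicle_centers[1:10, ]))

  # out-of-bounds center is named in the error
  trb <- scene_truth(1, c(33, 33), vesicle_centers = rbind(c(1, 16)), seed = 1)
  expect_error(make_vesicle_scene(trb), "vesicle 1")
})

test_that("generators are bit-identical under the same seed and leave the global RNG alone", {
  tr <- scene_truth(10, c(64, 64), coloc_fraction = 0.4, noise_sigma = 5,
                    seed = 11)
  set.seed(999)
  before <- .Random.seed
  s1 <- make_vesicle_scene(tr)
  expect_identical(.Random.seed, before)
  s2 <- make_vesicle_scene(tr)
  expect_identical(unclass(s1$channel_a), unclass(s2$channel_a))
  expect_identical(unclass(s1$channel_b), unclass(s2$channel_b))

  ft <- frap_truth(0.02, 0.7, noise_sigma = 0.02, seed = 3)
  expect_identical(make_frap_series(ft, 20), make_frap_series(ft, 20))

  tt <- track_truth(0.5, seed = 5)
  expect_identical(make_tracks(tt, 3), make_tracks(tt, 3))

  bt <- binding_truth(1e-7, noise_sigma = 1, seed = 2)
  concs <- 1e-9 * 2^(0:15)
  expect_identical(make_titration(bt, concs), make_titration(bt, concs))

  dt <- decay_truth(2.5, 1e4, seed = 8)
  expect_identical(make_decay(dt), make_decay(dt))
})

test_that("FRAP series matches the recovery model, half-times and fading law", {
  # noise-free limit: plateau at floor + mf * (1 - floor)
  tr <- make_frap_series(frap_truth(0.05, 0.6, postbleach_floor = 0.3,
                                    frame_interval = 10), n_post = 400)
  plateau <- 0.3 + 0.6 * (1 - 0.3)
  expect_equal(tr$roi_intensity[length(tr$roi_intensity)], plateau,
               tolerance = 1e-6)

  # half-recovery at ln2 / k = 30 s for k = 0.0231
  tr2 <- make_frap_series(frap_truth(log(2) / 30, 0.75, postbleach_floor = 0.2,
                                     frame_interval = 5), n_post = 40)
  t_post <- tr2$times[-(1:3)] - tr2$times[3]
  i30 <- which(abs(t_post - 30) < 1e-9)
  plateau2 <- 0.2 + 0.75 * 0.8
  expect_equal(tr2$roi_intensity[3 + i30],
               0.2 + 0.5 * (plateau2 - 0.2), tolerance = 1e-9)

  # whole-image fading: half prebleach value at ln2 / fading_rate
  tr3 <- make_frap_series(frap_truth(0.02, 0.7, fading_rate = 0.001,
                                     frame_interval = 6.93), n_post = 110)
  i693 <- which(abs(tr3$times - 693) < 0.01)
  pre_mean <- mean(tr3$whole_image_intensity[1:3])
  expect_equal(tr3$whole_image_intensity[i693] / pre_mean, 0.5,
               tolerance = 0.01)

  expect_error(make_frap_series(frap_truth(0.02, 0.7), n_post = 2),
               "under-determined")
})

test_that("tracks honour speed, persistence and degenerate limits", {
  # zero speed: all positions identical
  t0 <- make_tracks(track_truth(0, seed = 1), 2)
  expect_true(all(apply(t0[[1]]$positions, 2, function(v) all(v == v[1]))))

  # full persistence, constant steps: straight line of known length
  t1 <- make_tracks(track_truth(0.5, persistence = 1, speed_cv = 0,
                                n_frames = 11, seed = 2), 1)[[1]]
  d <- diff(t1$positions) * t1$pixel_size
  expect_equal(sum(sqrt(rowSums(d^2))), 10 * 0.5 * 10, tolerance = 1e-9)
  # collinear steps
  expect_equal(max(abs(d[, 1] * d[1, 2] - d[, 2] * d[1, 1])), 0,
               tolerance = 1e-9)
})

test_that("titrations follow the saturation model at its limits", {
  bt <- binding_truth(kd = 1e-7, target_conc = 50e-9,
                      response_unbound = 800, response_bound = 860)
  s <- make_titration(bt, c(1e-12, 1e-11, 1e-10, 1e-6, 1e-4, 1e-2))
  expect_equal(s$response[length(s$response)], 860, tolerance = 1e-3)
  expect_equal(s$response[1], 800, tolerance = 1e-3)
  expect_error(make_titration(bt, c(1e-9, 1e-8, 1e-7, 1e-6, 1e-5)),
               "6 titration points")
})

test_that("decay histograms are multinomial-exact and exponential in expectation", {
  dt <- decay_truth(2.5, total_counts = 2e5, bin_width = 0.05,
                    n_bins = 400, seed = 7)
  d <- make_decay(dt)
  expect_identical(sum(d$counts), 2e5)

  # counts a lifetime apart fall by ~ e^-1 (averaged over early bins)
  i <- which(d$bin_centers <= 2.5)
  j <- i + 50          # +2.5 ns at 0.05 ns bins
  ratio <- sum(d$counts[j]) / sum(d$counts[i])
  expect_equal(ratio, exp(-1), tolerance = 0.05)

  expect_error(decay_truth(2.5, n_bins = 100, bin_width = 0.05),
               "5 lifetimes")
})
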