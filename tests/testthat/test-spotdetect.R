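# Vesicle detection: recovery of known scenes, splitting behaviour,
# equivariances, and the per-frame timecourse.

test_that("degenerate inputs yield empty vesicle sets, not errors", {
  z <- matrix(0, 48, 48)
  vs <- detect_vesicles(z)
  expect_identical(vs$n_vesicles, 0L)
  expect_identical(nrow(vs$stats), 0L)
  # pure noise with no structure: support mask may be empty
  set.seed(1)
  vn <- detect_vesicles(matrix(abs(rnorm(48 * 48)), 48, 48))
  expect_true(vs$n_vesicles >= 0L)
})

test_that("detection recovers known spots with sub-pixel centroids at SNR 10", {
  hits <- vapply(1:5, function(seed) {
    tr <- scene_truth(25, c(128, 128), vesicle_amplitudes = 100,
                      noise_sigma = 10, seed = seed)
    sc <- make_vesicle_scene(tr)
    vs <- detect_vesicles(sc$channel_a)
    m <- match_detections(tr$vesicle_centers,
                          cbind(vs$stats$centroid_row, vs$stats$centroid_col),
                          tol = 1)
    c(m$recall, m$precision, m$err)
  }, numeric(3))
  expect_true(all(hits[1, ] >= 0.95))   # recall per seed
  expect_true(all(hits[2, ] >= 0.95))   # precision per seed
  expect_true(all(hits[3, ] <= 1))      # centroid error within 1 px
})

test_that("touching spots split under watershed and merge without it", {
  ctr <- rbind(c(16, 14), c(16, 18))
  tr <- scene_truth(2, c(33, 33), vesicle_centers = ctr,
                    vesicle_amplitudes = 100, seed = 1)
  sc <- make_vesicle_scene(tr)
  expect_identical(
    detect_vesicles(sc$channel_a, detection_params(split_touching = TRUE))$n_vesicles,
    2L)
  expect_identical(
    detect_vesicles(sc$channel_a, detection_params(split_touching = FALSE))$n_vesicles,
    1L)
})

test_that("detection is translation-equivariant away from borders", {
  tr <- scene_truth(6, c(96, 96), noise_sigma = 4, seed = 21,
                    min_separation = 14)
  x <- unclass(make_vesicle_scene(tr)$channel_a)
  attributes(x) <- list(dim = dim(x))
  dr <- 3L; dc <- 5L
  shifted <- matrix(median(x), 96, 96)
  shifted[(1 + dr):96, (1 + dc):96] <- x[1:(96 - dr), 1:(96 - dc)]
  v1 <- detect_vesicles(x)
  v2 <- detect_vesicles(shifted)
  c1 <- cbind(v1$stats$centroid_row, v1$stats$centroid_col)
  c2 <- cbind(v2$stats$centroid_row, v2$stats$centroid_col)
  keep1 <- c1[, 1] < 90 - dr & c1[, 2] < 90 - dc & c1[, 1] > 6 & c1[, 2] > 6
  c1 <- c1[keep1, , drop = FALSE]
  c1s <- c1 + matrix(rep(c(dr, dc), each = nrow(c1)), ncol = 2)
  m <- match_detections(c1s, c2, tol = 0.2)
  expect_equal(m$recall, 1)
})

test_that("the label map is invariant to positive intensity rescaling", {
  tr <- scene_truth(10, c(96, 96), noise_sigma = 5, seed = 2)
  sc <- make_vesicle_scene(tr)
  x <- unclass(sc$channel_a); attributes(x) <- list(dim = dim(x))
  a <- detect_vesicles(x)$label_map
  b <- detect_vesicles(x * 4.2)$label_map
  expect_identical(a, b)
})

test_that("raising min_area never increases the vesicle count", {
  tr <- scene_truth(20, c(128, 128), noise_sigma = 8, seed = 13)
  sc <- make_vesicle_scene(tr)
  counts <- vapply(c(1L, 4L, 9L, 16L, 30L), function(ma) {
    detect_vesicles(sc$channel_a,
                    detection_params(min_area = ma))$n_vesicles
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-vesicle statistics are measured on the original image", {
  tr <- scene_truth(1, c(33, 33), vesicle_centers = rbind(c(16, 16)),
                    vesicle_amplitudes = 200, background_level = 20, seed = 1)
  sc <- make_vesicle_scene(tr)
  vs <- detect_vesicles(sc$channel_a)
  expect_identical(vs$n_vesicles, 1L)
  x <- unclass(sc$channel_a); attributes(x) <- list(dim = dim(x))
  sel <- vs$label_map == 1L
  expect_equal(vs$stats$total_intensity, sum(x[sel]), tolerance = 1e-12)
  expect_equal(vs$stats$mean_intensity, mean(x[sel]), tolerance = 1e-12)
})

test_that("timecourse counts spots per frame and rejects bad input", {
  frames <- lapply(c(5, 10, 15), function(n) {
    tr <- scene_truth(n, c(128, 128), vesicle_amplitudes = 100,
                      noise_sigma = 10, seed = 100 + n)
    make_vesicle_scene(tr)$channel_a
  })
  tc <- vesicle_timecourse(frames)
  expect_equal(tc$vesicle_count, c(5L, 10L, 15L))
  expect_equal(tc$frame_index, 0:2)

  tc2 <- vesicle_timecourse(list(frames[[1]], frames[[1]]))
  expect_identical(tc2$vesicle_count[1], tc2$vesicle_count[2])
  expect_identical(tc2$mean_area[1], tc2$mean_area[2])

  expect_error(vesicle_timecourse(list()), "non-empty")
  expect_error(vesicle_timecourse(list(matrix(0, 32, 32), matrix(0, 48, 48))),
               "same shape")
})
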