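# Colocalization and intensity quantification.

test_that("Pearson colocalization handles exact, degenerate and null cases", {
  a <- matrix(runif(400, 1, 10), 20, 20)
  expect_equal(pearson_coloc(a, a)$pearson_r, 1, tolerance = 1e-12)
  expect_equal(pearson_coloc(a, 50 - a)$pearson_r, -1, tolerance = 1e-12)
  # affine invariance with positive gain
  expect_equal(pearson_coloc(3 * a + 2, a)$pearson_r, 1, tolerance = 1e-12)
  expect_error(pearson_coloc(a, matrix(5, 20, 20)), "channel B")
  expect_error(pearson_coloc(matrix(1, 20, 20), a), "channel A")

  # independent channels: |r| stays small over repeated draws
  rs <- vapply(1:100, function(seed) {
    set.seed(seed)
    na <- matrix(rnorm(1e4), 100, 100)
    nb <- matrix(rnorm(1e4), 100, 100)
    pearson_coloc(na, nb)$pearson_r
  }, numeric(1))
  expect_lt(max(abs(rs)), 0.05)
})

test_that("leading-edge ROI matches geometry and the exhaustive distance oracle", {
  # horizontal segment: stadium area = width * L + pi * (width/2)^2
  path <- rbind(c(60, 20), c(60, 100))
  m <- leading_edge_roi(path, width = 10, shape = c(120, 120))
  expect_equal(attr(m, "kind"), "leading_edge_line")
  expect_equal(sum(m), 10 * 80 + pi * 25, tolerance = 0.02 * (800 + pi * 25))

  # width-1 straight segment rasterizes to the line itself
  m1 <- leading_edge_roi(rbind(c(5, 2), c(5, 12)), width = 1, shape = c(20, 20))
  expect_true(all(which(m1, arr.ind = TRUE)[, 1] == 6))
  expect_identical(sum(m1), 11L)

  # L-shaped path agrees exactly with the per-pixel oracle
  pathL <- rbind(c(10, 10), c(10, 30), c(28, 30))
  mL <- leading_edge_roi(pathL, width = 7, shape = c(40, 40))
  expect_identical(unclass(mL)[, ], oracle_polyline_mask(pathL, 7, c(40, 40)))

  expect_error(leading_edge_roi(rbind(c(5, 5)), 10, c(20, 20)), "2 vertices")
})

test_that("membrane band equals mask minus its erosion, matching the oracle", {
  sq <- matrix(FALSE, 31, 31); sq[6:26, 6:26] <- TRUE
  band <- membrane_band(region_mask(sq, "whole_cell"), width = 3)
  expect_equal(sum(band), 441 - 225)   # 216 px
  expect_error(membrane_band(region_mask(sq, "whole_cell"), width = 0), ">= 1")

  # disk mask: exact agreement with per-pixel box erosion
  rr <- outer((1:51) - 26, rep(1, 51)); cc <- t(rr)
  disk <- rr^2 + cc^2 <= 20^2
  band2 <- membrane_band(region_mask(disk, "whole_cell"), width = 2)
  expect_identical(unclass(band2)[, ], disk & !oracle_erode_box(disk, 2))

  thin <- matrix(FALSE, 10, 10); thin[5, 3:8] <- TRUE
  expect_error(membrane_band(region_mask(thin, "whole_cell"), 2), "thinner")
})

test_that("intensity levels reproduce masked means and normalization", {
  img <- matrix(7, 30, 30)
  cm <- matrix(FALSE, 30, 30); cm[5:25, 5:25] <- TRUE
  band <- membrane_band(region_mask(cm, "whole_cell"), 3)
  lv <- intensity_levels(img, region_mask(cm, "whole_cell"), band)
  expect_equal(lv$total_mean, 7)
  expect_equal(lv$surface_mean, 7)
  lvn <- intensity_levels(img, region_mask(cm, "whole_cell"), band,
                          control_means = c(7, 7))
  expect_equal(lvn$normalized_total, 1)
  expect_equal(lvn$normalized_surface, 1)

  # membrane-concentrated signal: ratio matches direct masked averaging
  tr <- scene_truth(0, c(30, 30), background_level = 0, seed = 1)
  sc <- make_vesicle_scene(tr)
  x <- unclass(sc$channel_a); attributes(x) <- list(dim = dim(x))
  set.seed(7)
  x <- x + matrix(runif(900), 30, 30)
  x[band] <- x[band] + 50
  lv2 <- intensity_levels(x, region_mask(cm, "whole_cell"), band)
  expect_equal(lv2$surface_mean / lv2$total_mean,
               mean(x[unclass(band)]) / mean(x[cm]), tolerance = 1e-12)

  bad <- region_mask(!cm, "custom")
  expect_error(intensity_levels(img, region_mask(cm, "whole_cell"), bad),
               "subset")
})

test_that("vesicle overlap is exact for identical and disjoint maps and tracks scene truth", {
  tr <- scene_truth(12, c(128, 128), noise_sigma = 8, seed = 3)
  sc <- make_vesicle_scene(tr)
  va <- detect_vesicles(sc$channel_a)
  expect_equal(vesicle_overlap(va, va)$overlap_fraction, 1)
  expect_length(vesicle_overlap(va, va)$per_vesicle, va$n_vesicles)

  # disjoint: build a set detected in an empty corner scene
  tr2 <- scene_truth(12, c(128, 128), noise_sigma = 8, seed = 301)
  vb <- detect_vesicles(make_vesicle_scene(tr2)$channel_b)  # coloc 0 -> empty B
  expect_error(vesicle_overlap(vb, va), "no labeled pixels")

  # ground-truth recovery at coloc_fraction 0.5, SNR 10 (5 seeds)
  errs <- vapply(1:5, function(seed) {
    trc <- scene_truth(20, c(128, 128), coloc_fraction = 0.5,
                       vesicle_amplitudes = 100, noise_sigma = 10,
                       seed = seed)
    scc <- make_vesicle_scene(trc)
    ov <- vesicle_overlap(detect_vesicles(scc$channel_a),
                          detect_vesicles(scc$channel_b))
    abs(ov$overlap_fraction - 0.5)
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("FACS background subtraction recovers known shifts", {
  expect_equal(facs_surface_level(c(5, 5, 5), c(5, 5))$level, 0)
  expect_equal(facs_surface_level(rep(500, 10), rep(200, 10))$level, 300)
  expect_equal(facs_surface_level(c(1, 2), c(10, 20))$level, 0)  # floored
  expect_error(facs_surface_level(numeric(), 1:3), "non-empty")

  # lognormal populations with a known location shift, 10 seeds
  errs <- vapply(1:10, function(seed) {
    set.seed(seed)
    bg <- rlnorm(1e4, meanlog = 4, sdlog = 0.25)
    sm <- rlnorm(1e4, meanlog = 4, sdlog = 0.25) + 150
    abs(facs_surface_level(sm, bg)$level - 150) / 150
  }, numeric(1))
  expect_lt(stats::median(errs), 0.03)

  # median statistic by flag
  expect_equal(facs_surface_level(c(1, 100, 1000), c(0, 100, 1e5),
                                  statistic = "median")$level, 0)
})

test_that("whole-scene Pearson increases with the colocalized fraction", {
  mean_r <- vapply(c(0, 0.5, 1), function(f) {
    rs <- vapply(1:6, function(seed) {
      tr <- scene_truth(20, c(128, 128), coloc_fraction = f,
                        vesicle_amplitudes = 100, noise_sigma = 10,
                        seed = seed)
      sc <- make_vesicle_scene(tr)
      pearson_coloc(sc$channel_a, sc$channel_b)$pearson_r
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})
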