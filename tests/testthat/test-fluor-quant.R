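test_that("illumination correction removes gradients and preserves flats", {
  nr <- nc <- 256
  flat <- matrix(100, nr, nc)
  grad <- outer(rep(1, nr), seq(0.7, 1.3, length.out = nc))
  corrected <- correct_illumination(flat * grad, 100, 0.65)
  # residual column trend under 5% of the injected trend
  col_means_in <- colMeans(flat * grad)
  col_means_out <- colMeans(corrected)
  slope_in <- stats::coef(stats::lm(col_means_in ~ seq_len(nc)))[2]
  slope_out <- stats::coef(stats::lm(col_means_out ~ seq_len(nc)))[2]
  expect_lt(abs(slope_out), 0.05 * abs(slope_in))

  # idempotent on an already-flat field
  out_flat <- correct_illumination(flat, 100, 0.65)
  expect_lt(max(abs(out_flat - flat)) / 100, 0.01)

  expect_error(correct_illumination(matrix(0, 64, 64), 100, 0.65),
               "non-positive")
})

test_that("per-cell intensity ranking survives gradient plus correction", {
  # objects of graded brightness on a background pedestal; a linear
  # gradient scrambles the raw ranking, correction must restore it
  set.seed(8)
  chan <- matrix(50, 400, 400)
  # brighter blobs in the dimmer half so the gradient flips the raw order
  amps <- c(125, 115, 105, 95, 85, 75, 65, 55)
  xs <- rep(c(80, 180, 280, 380) - 30, 2)
  ys <- rep(c(120, 280), each = 4)
  for (i in 1:8) chan <- paint_disk(chan, xs[i], ys[i], 20, amps[i])
  grad <- outer(seq(0.6, 1.4, length.out = 400), rep(1, 400))
  dirty <- chan * grad
  corr <- correct_illumination(dirty, 100, 0.65)
  per_blob <- function(img) {
    vapply(1:8, function(i) {
      stats::median(img[(ys[i] - 10):(ys[i] + 10), (xs[i] - 10):(xs[i] + 10)])
    }, numeric(1))
  }
  expect_false(identical(order(per_blob(dirty)), order(per_blob(chan))))
  expect_identical(order(per_blob(corr)), order(per_blob(chan)))
})

test_that("nucleus detection counts blobs and ignores blank fields", {
  opt <- test_optics(c(256L, 256L))
  px <- opt$pixel_size_um
  chan <- matrix(0, 256, 256)
  set.seed(3)
  pts <- cbind(x = seq(20, 236, length.out = 12),
               y = rep(c(60, 190), 6) + rnorm(12, 0, 5))
  for (i in 1:12) chan <- paint_disk(chan, pts[i, 1], pts[i, 2], 6, 800)
  chan <- chan + matrix(abs(rnorm(256^2, 0, 2)), 256, 256)
  ns <- detect_nuclei(chan, px)
  expect_identical(ns$count, 12L)

  blank <- matrix(abs(rnorm(256^2, 0, 2)), 256, 256)
  expect_identical(detect_nuclei(blank, px)$count, 0L)

  # against simulator truth: within 5% across default-noise fields
  opt_full <- test_optics(c(512L, 512L))
  total_truth <- total_det <- 0
  for (s in 1:4) {
    ph <- make_phantom_field(20, c(undifferentiated = 0.5, adipocytic = 0.3,
                                   dead = 0.2), optics = opt_full,
                             seed = s + 30)
    fl <- render_fluor_channels(ph)
    nucc <- correct_illumination(fl$nuclear, pixel_size_um = px)
    total_det <- total_det + detect_nuclei(nucc, px)$count
    total_truth <- total_truth + nrow(ph$truth_cells)
  }
  expect_lt(abs(total_det - total_truth) / total_truth, 0.05)
})

test_that("nucleus-anchored lipid readout is exact and monotone", {
  px <- 1
  chan <- matrix(0, 200, 200)
  chan <- paint_disk(chan, 100, 100, 30, 50)
  nuclei <- structure(list(centroids = cbind(x = 100, y = 100), count = 1L),
                      class = "nucleus_set")
  lr <- lipid_intensity_per_nucleus(chan, nuclei, radius_um = 20,
                                    pixel_size_um = px)
  expect_equal(lr$per_cell$median_intensity, 50)
  expect_false(lr$per_cell$clipped)
  expect_equal(lr$field_median, 50)

  zero <- lipid_intensity_per_nucleus(matrix(0, 200, 200), nuclei, 20, px)
  expect_equal(zero$field_median, 0)

  # nucleus near the edge is flagged as clipped
  nuc_edge <- structure(list(centroids = cbind(x = 5, y = 100), count = 1L),
                        class = "nucleus_set")
  expect_true(lipid_intensity_per_nucleus(chan, nuc_edge, 20,
                                          px)$per_cell$clipped)

  # monotone in droplet volume fraction on a constructed triple
  opt <- test_optics(c(320L, 320L))
  ph <- make_phantom_field(9, c(adipocytic = 1), optics = opt, seed = 44)
  fl <- render_fluor_channels(ph, stain_config(illumination_amplitude = 0,
                                               noise_sd = 0))
  tc <- ph$truth_cells[order(ph$truth_cells$droplet_volume_fraction), ]
  nuc <- structure(list(centroids = cbind(x = tc$x, y = tc$y),
                        count = nrow(tc)), class = "nucleus_set")
  lr2 <- lipid_intensity_per_nucleus(fl$lipid, nuc, radius_um = 10,
                                     pixel_size_um = opt$pixel_size_um)
  lo <- lr2$per_cell$median_intensity[1:3]
  hi <- lr2$per_cell$median_intensity[(nrow(tc) - 2):nrow(tc)]
  expect_gt(min(hi), max(lo) - 1e-9)
})

test_that("Nile Red branch measures droplets and flags failed stains", {
  px <- 1
  chan <- matrix(abs(rnorm(200 * 200, 0, 0.5)), 200, 200)
  chan <- paint_disk(chan, 60, 100, 25, 10)    # cytoplasm
  chan <- paint_disk(chan, 60, 100, 6, 100)    # droplet
  chan <- paint_disk(chan, 140, 100, 25, 10)
  chan <- paint_disk(chan, 140, 100, 5, 100)
  nr <- nile_red_quant(chan, px)
  expect_false(nr$flagged)
  expect_identical(nr$n_cells, 2L)
  expect_equal(nr$value, 100, tolerance = 0.05)

  blank <- matrix(abs(rnorm(200 * 200, 0, 0.5)), 200, 200)
  nb <- nile_red_quant(blank, px)
  expect_true(nb$flagged)

  expect_true(nile_red_quant(matrix(1, 64, 64), px)$flagged)

  # a stain-failure field reads flagged or far below the healthy value
  opt <- test_optics(c(256L, 256L))
  ph <- make_phantom_field(8, c(adipocytic = 1), optics = opt, seed = 77)
  ok <- render_fluor_channels(ph, seed = 9, stain_failure = FALSE)
  bad <- render_fluor_channels(ph, seed = 9, stain_failure = TRUE)
  v_ok <- nile_red_quant(correct_illumination(ok$lipid + 1,
                                              pixel_size_um =
                                                opt$pixel_size_um),
                         opt$pixel_size_um)
  v_bad <- nile_red_quant(correct_illumination(bad$lipid + 1,
                                               pixel_size_um =
                                                 opt$pixel_size_um),
                          opt$pixel_size_um)
  expect_false(v_ok$flagged)
  expect_true(v_bad$flagged || v_bad$value < 0.5 * v_ok$value)
})

test_that("Et-HD positive fraction matches constructed and simulated truth", {
  px <- 1
  chan <- matrix(0, 300, 300)
  xs <- seq(30, 270, length.out = 10)
  for (i in 1:10) {
    chan <- paint_disk(chan, xs[i], 150, 8, if (i <= 3) 400 else 5)
  }
  nuclei <- structure(list(centroids = cbind(x = xs, y = rep(150, 10)),
                           count = 10L), class = "nucleus_set")
  expect_equal(ethd_positive_fraction(chan, nuclei, fixed_cutoff = 50,
                                      pixel_size_um = px), 0.3)
  expect_equal(ethd_positive_fraction(chan, nuclei,
                                      fixed_cutoff = max(chan) + 1,
                                      pixel_size_um = px), 0)
  none <- structure(list(centroids = matrix(numeric(0), 0, 2,
                                            dimnames = list(NULL, c("x", "y"))),
                         count = 0L), class = "nucleus_set")
  v <- ethd_positive_fraction(chan, none)
  expect_true(is.nan(v) && isTRUE(attr(v, "flagged")))

  # cutoff calibrated from negative controls clears the live-cell signal
  cutoff <- calibrate_ethd_cutoff(matrix(abs(rnorm(1e4, 0, 2)), 100, 100))
  expect_gt(cutoff, 0)
  expect_lt(cutoff, 50)

  # agreement with simulator truth within 0.05 across fields
  opt <- test_optics(c(512L, 512L))
  diffs <- vapply(1:8, function(s) {
    ph <- make_phantom_field(22, c(undifferentiated = 0.6, dead = 0.4),
                             optics = opt, seed = s + 200, sample_mix = TRUE)
    if (nrow(ph$truth_cells) == 0) return(0)
    fl <- render_fluor_channels(ph)
    nucc <- correct_illumination(fl$nuclear,
                                 pixel_size_um = opt$pixel_size_um)
    dc <- correct_illumination(fl$death + 1,
                               pixel_size_um = opt$pixel_size_um)
    nuclei <- detect_nuclei(nucc, opt$pixel_size_um)
    est <- ethd_positive_fraction(dc, nuclei,
                                  pixel_size_um = opt$pixel_size_um)
    est - mean(ph$truth_cells$phenotype == "dead")
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("field medians are invariant to global intensity scale", {
  opt <- test_optics(c(256L, 256L))
  ph <- make_phantom_field(8, c(adipocytic = 1), optics = opt, seed = 91)
  fl <- render_fluor_channels(ph, stain_config(noise_sd = 0), seed = 2)
  px <- opt$pixel_size_um
  nucc <- correct_illumination(fl$nuclear, pixel_size_um = px)
  nuclei <- detect_nuclei(nucc, px)
  v1 <- lipid_intensity_per_nucleus(fl$lipid, nuclei,
                                    pixel_size_um = px)$field_median
  v2 <- lipid_intensity_per_nucleus(fl$lipid * 3, nuclei,
                                    pixel_size_um = px)$field_median
  expect_equal(v2, 3 * v1, tolerance = 1e-9)
  # fractions always within [0, 1]
  dc <- correct_illumination(fl$death + 1, pixel_size_um = px)
  f <- ethd_positive_fraction(dc, nuclei, pixel_size_um = px)
  expect_gte(f, 0); expect_lte(f, 1)
})
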