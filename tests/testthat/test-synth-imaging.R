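test_that("empty and single-phenotype fields honor construction guarantees", {
  opt <- noiseless_optics(c(128L, 128L))
  ph0 <- make_phantom_field(0, c(undifferentiated = 1), optics = opt, seed = 1)
  expect_identical(nrow(ph0$truth_cells), 0L)
  expect_true(all(ph0$thickness_nm == 0))
  expect_true(all(ph0$truth_label == 0L))

  opt2 <- noiseless_optics(c(512L, 512L))
  ph <- make_phantom_field(50, c(adipocytic = 1), optics = opt2, seed = 42)
  expect_identical(nrow(ph$truth_cells), 50L)
  expect_true(all(ph$truth_cells$phenotype == "adipocytic"))
  expect_true(all(ph$truth_cells$droplet_volume_fraction > 0))
})

test_that("phantom generation errors on invalid inputs", {
  expect_error(make_phantom_field(-1, c(undifferentiated = 1)), "non-negative")
  expect_error(make_phantom_field(5, c(undifferentiated = 0.5)), "sum to 1")
  expect_error(make_phantom_field(5, c(foo = 1)), "phenotype")
})

test_that("generation is bitwise-reproducible under a fixed seed", {
  opt <- test_optics(c(160L, 160L))
  a <- make_phantom_field(8, c(undifferentiated = 0.5, adipocytic = 0.5),
                          optics = opt, seed = 9)
  b <- make_phantom_field(8, c(undifferentiated = 0.5, adipocytic = 0.5),
                          optics = opt, seed = 9)
  expect_identical(a$thickness_nm, b$thickness_nm)
  expect_identical(a$refindex, b$refindex)
  expect_identical(a$truth_cells, b$truth_cells)
  expect_identical(render_phase_image(a)$opd_nm, render_phase_image(b)$opd_nm)
  fa <- render_fluor_channels(a)
  fb <- render_fluor_channels(b)
  expect_identical(fa$lipid, fb$lipid)
  expect_identical(fa$nuclear, fb$nuclear)
})

test_that("phantom maps satisfy their physical invariants", {
  for (s in 1:5) {
    ph <- make_phantom_field(10, c(undifferentiated = 0.4, adipocytic = 0.4,
                                   dead = 0.2),
                             optics = test_optics(c(192L, 192L)), seed = s)
    expect_true(all(ph$thickness_nm >= 0))
    cellpix <- ph$thickness_nm > 0
    expect_true(all(ph$refindex[cellpix] >= ph$medium_index))
    expect_true(all(ph$truth_cells$droplet_volume_fraction >= 0 &
                      ph$truth_cells$droplet_volume_fraction <= 1))
  }
})

test_that("noiseless rendering reproduces thickness x index-contrast exactly", {
  for (s in 1:20) {
    opt <- noiseless_optics(c(128L, 128L))
    ph <- make_phantom_field(6, c(undifferentiated = 0.4, adipocytic = 0.4,
                                  dead = 0.2), optics = opt, seed = s)
    img <- render_phase_image(ph, opt)
    expected <- ph$thickness_nm * (ph$refindex - ph$medium_index)
    expect_lt(max(abs(img$opd_nm - expected)) /
                max(max(abs(expected)), 1), 1e-9)
  }
})

test_that("single-pixel substitution gives the textbook numbers", {
  opt <- noiseless_optics(c(16L, 16L))
  thick <- matrix(0, 16, 16); thick[8, 8] <- 5000
  rid <- matrix(1.337, 16, 16); rid[8, 8] <- 1.380
  ph <- structure(list(thickness_nm = thick, refindex = rid,
                       medium_index = 1.337, truth_label = matrix(0L, 16, 16),
                       truth_cells = data.frame(), optics = opt,
                       geometry = phantom_geometry(), seed = 1L),
                  class = "phantom_field")
  img <- render_phase_image(ph, opt)
  expect_equal(img$opd_nm[8, 8], 5000 * (1.380 - 1.337), tolerance = 1e-12)

  rid[8, 8] <- 1.337  # zero contrast: thickness alone produces no signal
  ph$refindex <- rid
  expect_equal(render_phase_image(ph, opt)$opd_nm[8, 8], 0)
})

test_that("droplet pixels out-shine cytoplasm pixels of equal thickness", {
  g <- phantom_geometry()
  d <- 4000
  opd_cyto <- d * (g$cytoplasm_index - g$medium_index)
  opd_drop <- d * (g$droplet_index - g$medium_index)
  expect_gt(opd_drop, opd_cyto)
  # and in rendered fields: droplet-classified pixels exceed the cytoplasm
  ph <- make_phantom_field(5, c(adipocytic = 1),
                           optics = noiseless_optics(c(256L, 256L)), seed = 3)
  img <- render_phase_image(ph)
  drop <- ph$refindex >= g$droplet_index - 1e-12
  cyto <- ph$truth_label > 0 & !drop
  # compare at matched thickness: normalize OPD by thickness
  expect_gt(min(img$opd_nm[drop] / ph$thickness_nm[drop]),
            max(img$opd_nm[cyto] / ph$thickness_nm[cyto]) - 1e-9)
})

test_that("adipocytic cells have higher mean OPD than undifferentiated", {
  wins <- 0L
  for (s in 1:20) {
    opt <- noiseless_optics(c(256L, 256L))
    ph <- make_phantom_field(10, c(undifferentiated = 0.5, adipocytic = 0.5),
                             optics = opt, seed = s)
    opd <- render_phase_image(ph, opt)$opd_nm
    tc <- ph$truth_cells
    mu <- function(phen) {
      ids <- tc$cell_id[tc$phenotype == phen]
      mean(opd[ph$truth_label %in% ids])
    }
    if (mu("adipocytic") > mu("undifferentiated")) wins <- wins + 1L
  }
  expect_identical(wins, 20L)
})

test_that("fluorescence channels encode phenotype truthfully", {
  opt <- test_optics(c(256L, 256L))
  stain0 <- stain_config(illumination_amplitude = 0, noise_sd = 0)

  ph_live <- make_phantom_field(8, c(undifferentiated = 0.5, adipocytic = 0.5),
                                optics = opt, seed = 4)
  fl <- render_fluor_channels(ph_live, stain0)
  expect_lt(max(fl$death), 50)  # no dead cells: all below positivity cutoff
  expect_true(all(fl$nuclear >= 0 & fl$lipid >= 0 & fl$death >= 0))

  # integrated lipid intensity increases with droplet volume fraction
  ph_ad <- make_phantom_field(6, c(adipocytic = 1), optics = opt, seed = 5)
  fl_ad <- render_fluor_channels(ph_ad, stain0)
  tc <- ph_ad$truth_cells
  per_cell_mean <- vapply(tc$cell_id, function(id) {
    mean(fl_ad$lipid[ph_ad$truth_label == id])
  }, numeric(1))
  expect_gt(stats::cor(tc$droplet_volume_fraction, per_cell_mean,
                       method = "spearman"), 0.9)

  # stain failure is a pure global rescale of the lipid channel
  stain_g <- stain_config(noise_sd = 0)
  ok <- render_fluor_channels(ph_ad, stain_g, seed = 7, stain_failure = FALSE)
  bad <- render_fluor_channels(ph_ad, stain_g, seed = 7, stain_failure = TRUE)
  expect_identical(ok$nuclear, bad$nuclear)
  expect_equal(bad$lipid, ok$lipid * stain_g$stain_failure_scale,
               tolerance = 1e-12)
})

test_that("time-course truth follows the saturating differentiation model", {
  cfg <- timecourse_config()
  f_ind <- adipocytic_fraction_curve(1:6, TRUE, cfg)
  f_non <- adipocytic_fraction_curve(1:6, FALSE, cfg)
  expect_true(all(diff(f_ind) > 0))            # monotone under induction
  expect_equal(f_ind[1], f_non[1])             # day 1: not yet diverged
  expect_equal(f_non, rep(cfg$baseline_fraction, 6))
  expect_lt(abs(f_ind[6] - cfg$plateau_fraction), 0.02)

  # realized non-induced day-6 fraction stays near the spontaneous baseline
  opt <- test_optics(c(256L, 256L))
  sim <- simulate_timecourse(6, induced = FALSE, cfg, optics = opt,
                             seed = 21, render_fluor = FALSE)
  frac <- sum(sim$truth$n_adipocytic) / sum(sim$truth$n_cells)
  se <- sqrt(0.05 * 0.95 / sum(sim$truth$n_cells))
  expect_lt(abs(frac - cfg$baseline_fraction),
            4 * se + cfg$well_sd_fraction)
})

test_that("dose-response truth follows the Hill model with toxicity", {
  mod <- pparg_reference_compounds()
  ant <- mod[mod$compound == "T0070907", ]
  ago <- mod[mod$compound == "rosiglitazone", ]

  mid <- expected_dose_fraction(ant, ant$true_ec50_m)
  expect_equal(mid, (ant$baseline_fraction + ant$max_fraction) / 2)
  expect_equal(expected_dose_fraction(ago, 1e-15), ago$baseline_fraction,
               tolerance = 1e-5)

  # monotone on each side of the Hill curve
  conc <- dose_concentrations()
  expect_true(all(diff(expected_dose_fraction(ant, sort(conc))) < 0))
  expect_true(all(diff(expected_dose_fraction(ago, sort(conc))) > 0))

  # toxicity above 10 uM raises the dead fraction over background
  expect_gt(expected_dead_fraction(ant, 30e-6), 0.02)
  expect_equal(expected_dead_fraction(ant, 1e-6), 0.02)

  expect_error(
    simulate_dose_response_plate(
      dose_response_layout(mod[1, , drop = FALSE], conc[1:4], replicates = 1),
      mod[2, , drop = FALSE], dr_config(), seed = 1),
    "missing")
})

test_that("plate truth is deterministic and records realized fractions", {
  mod <- pparg_reference_compounds()[1, , drop = FALSE]
  layout <- dose_response_layout(mod, dose_concentrations()[c(1, 6, 10, 14)],
                                 replicates = 1, n_fields = 1)
  cfg <- dr_config(cells_per_field = 6,
                   optics = optics_config(field_shape = c(160L, 160L)))
  a <- simulate_dose_response_plate(layout, mod, cfg, seed = 3,
                                    keep_images = FALSE)
  b <- simulate_dose_response_plate(layout, mod, cfg, seed = 3,
                                    keep_images = FALSE)
  expect_identical(a$truth, b$truth)
  expect_true(all(c("expected_fraction", "realized_fraction",
                    "expected_dead") %in% names(a$truth)))
  # the 30 uM well of a toxic antagonist carries extra dead cells
  expect_gt(a$truth$expected_dead[1], 0.02)
})
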