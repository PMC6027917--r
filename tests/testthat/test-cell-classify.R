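test_that("shape features match geometry on synthetic disks and ellipses", {
  m <- matrix(0, 128, 128)
  r <- 20
  m <- paint_disk(m, 64, 64, r, 150)
  seg <- fixed_threshold_segment(matrix_image(m), min_area_um2 = 1)
  rec <- extract_cell_features(matrix_image(m), seg)
  expect_identical(nrow(rec), 1L)
  expect_lt(abs(rec$area_um2 - pi * r^2) / (pi * r^2), 0.05)
  expect_gte(rec$form_factor, 0.95)
  expect_lte(rec$form_factor, 1.1)
  expect_lt(rec$eccentricity, 0.3)

  m2 <- matrix(0, 128, 128)
  m2 <- paint_ellipse(m2, 64, 64, 45, 15, 150)  # 3:1 ellipse
  seg2 <- fixed_threshold_segment(matrix_image(m2), min_area_um2 = 1)
  rec2 <- extract_cell_features(matrix_image(m2), seg2)
  expect_gt(rec2$eccentricity, 0.9)
  expect_lt(rec2$form_factor, rec$form_factor)

  # OPD features on a constant-valued object
  expect_equal(rec$mean_opd_nm, 150)
  expect_equal(rec$integrated_opd, 150 * rec$area_um2 / 1)
})

test_that("phenotype rules encode the size/OPD/roundness definitions", {
  mk <- function(area, opd, ff) {
    data.frame(cell_id = 1, centroid_x = 0, centroid_y = 0, area_um2 = area,
               perimeter_um = 1, form_factor = ff, eccentricity = 0.1,
               mean_opd_nm = opd, integrated_opd = area * opd,
               phenotype = "error", stringsAsFactors = FALSE)
  }
  thr <- rule_thresholds()
  expect_identical(classify_cells_rules(mk(900, 80, 0.9), thr)$phenotype,
                   "undifferentiated")
  expect_identical(classify_cells_rules(mk(900, 250, 0.9), thr)$phenotype,
                   "adipocytic")
  expect_identical(classify_cells_rules(mk(60, 250, 0.95), thr)$phenotype,
                   "dead")
  # small, low-OPD debris falls through to the error bucket
  expect_identical(classify_cells_rules(mk(60, 40, 0.95), thr)$phenotype,
                   "error")
  expect_error(rule_thresholds(area_small_cutoff_um2 = -1), "positive")
})

test_that("rules agree with construction truth on noiseless phantoms", {
  opt <- noiseless_optics(c(320L, 320L))
  agree <- tot <- 0
  for (s in 1:8) {
    ph <- make_phantom_field(14, c(undifferentiated = 0.4, adipocytic = 0.4,
                                   dead = 0.2), optics = opt, seed = s)
    img <- render_phase_image(ph, opt)
    seg <- fixed_threshold_segment(img)
    rec <- classify_cells_rules(extract_cell_features(img, seg))
    truth <- vapply(rec$cell_id, function(id) {
      phantom_truth_majority(ph, seg$label_map, id)
    }, character(1))
    ok <- !is.na(truth)
    agree <- agree + sum(rec$phenotype[ok] == truth[ok])
    tot <- tot + sum(ok)
  }
  expect_gte(agree / tot, 0.99)
})

test_that("trained classifiers recover phenotypes and are deterministic", {
  recs <- labeled_records(1:14)
  expect_gt(nrow(recs), 80)
  n <- nrow(recs)
  split <- seq_len(n) %% 4 != 0  # 75/25 split by record order
  train <- recs[split, ]; test <- recs[!split, ]

  rf <- train_cell_classifier(train, train$truth, "random_forest", seed = 5)
  rf2 <- train_cell_classifier(train, train$truth, "random_forest", seed = 5)
  p1 <- apply_cell_classifier(rf, test)
  p2 <- apply_cell_classifier(rf2, test)
  expect_identical(p1$records$phenotype, p2$records$phenotype)

  # counts over phenotypes partition the records
  expect_identical(sum(p1$counts), nrow(test))

  # held-out macro accuracy beats 0.9 and the majority-class baseline by 30+
  per_class <- vapply(unique(test$truth), function(cl) {
    mean(p1$records$phenotype[test$truth == cl] == cl)
  }, numeric(1))
  expect_gte(mean(per_class), 0.9)
  overall <- mean(p1$records$phenotype == test$truth)
  majority <- max(table(test$truth)) / nrow(test)
  expect_gte(overall - majority, 0.30)

  # resubstitution accuracy is at least the rule-based accuracy
  resub <- apply_cell_classifier(rf, train)
  acc_rf <- mean(resub$records$phenotype == train$truth)
  acc_rules <- mean(classify_cells_rules(train)$phenotype == train$truth)
  expect_gte(acc_rf, acc_rules - 1e-9)

  # 1-NN has perfect resubstitution accuracy
  knn1 <- train_cell_classifier(train, train$truth, "k_neighbors",
                                seed = 5, k = 1)
  expect_identical(apply_cell_classifier(knn1, train)$records$phenotype,
                   as.character(train$truth))

  expect_error(train_cell_classifier(train, rep("dead", nrow(train))),
               ">= 2 classes")

  # serialized round trip predicts identically
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_cell_classifier(rf, tmp)
  rf_back <- load_cell_classifier(tmp)
  expect_identical(apply_cell_classifier(rf_back, test)$records$phenotype,
                   p1$records$phenotype)
})

test_that("dead-only fields classify as all dead", {
  opt <- noiseless_optics(c(256L, 256L))
  ph <- make_phantom_field(10, c(dead = 1), optics = opt, seed = 2)
  img <- render_phase_image(ph, opt)
  seg <- fixed_threshold_segment(img)
  rec <- classify_cells_rules(extract_cell_features(img, seg))
  expect_true(all(rec$phenotype == "dead"))
  expect_equal(as.numeric(dead_fraction(rec)), 1.0)
})

test_that("dead_fraction handles the edge cases", {
  mk <- function(phens) {
    data.frame(cell_id = seq_along(phens), phenotype = phens,
               stringsAsFactors = FALSE)
  }
  expect_equal(dead_fraction(mk(c(rep("dead", 2), rep("adipocytic", 8)))),
               0.2)
  expect_equal(dead_fraction(mk(rep("undifferentiated", 5))), 0)
  v <- dead_fraction(mk(character(0)))
  expect_true(is.nan(v) && isTRUE(attr(v, "flagged")))
  v2 <- dead_fraction(mk(rep("error", 3)))
  expect_true(is.nan(v2))
})
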