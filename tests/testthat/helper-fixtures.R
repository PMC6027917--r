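# Small, fast imaging settings shared across tests.
test_optics <- function(shape = c(256L, 256L), noise = 4, drift = 8) {
  optics_config(field_shape = shape, opd_noise_sd_nm = noise,
                background_drift_nm = drift)
}

noiseless_optics <- function(shape = c(256L, 256L)) {
  test_optics(shape, noise = 0, drift = 0)
}

# A bare phase_image around a plain matrix (pixel size 1 um unless given).
matrix_image <- function(m, pixel_size_um = 1) {
  structure(
    list(opd_nm = m,
         optics = optics_config(pixel_size_um = pixel_size_um,
                                field_shape = dim(m), opd_noise_sd_nm = 0,
                                background_drift_nm = 0),
         provenance = "test fixture"),
    class = "phase_image")
}

# Paint a filled disk of the given value onto a matrix.
paint_disk <- function(m, cx, cy, r, value) {
  xs <- pmax(1, floor(cx - r)):pmin(ncol(m), ceiling(cx + r))
  ys <- pmax(1, floor(cy - r)):pmin(nrow(m), ceiling(cy + r))
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  sub <- m[ys, xs, drop = FALSE]
  sub[(dx^2 + dy^2) <= r^2] <- value
  m[ys, xs] <- sub
  m
}

# Paint a filled axis-ratio ellipse.
paint_ellipse <- function(m, cx, cy, rx, ry, value) {
  xs <- pmax(1, floor(cx - rx)):pmin(ncol(m), ceiling(cx + rx))
  ys <- pmax(1, floor(cy - ry)):pmin(nrow(m), ceiling(cy + ry))
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  sub <- m[ys, xs, drop = FALSE]
  sub[(dx / rx)^2 + (dy / ry)^2 <= 1] <- value
  m[ys, xs] <- sub
  m
}

# Independent brute-force intermeans oracle: enumerate every cut between
# consecutive distinct levels of a weighted histogram and return all fixed
# points, i.e. cuts whose class-mean average falls back into the same gap.
intermeans_fixed_points <- function(levels, weights) {
  ord <- order(levels)
  lv <- levels[ord]; w <- weights[ord]
  n <- length(lv)
  fps <- numeric(0)
  for (k in 1:(n - 1)) {
    lo <- seq_len(k)
    m0 <- sum(lv[lo] * w[lo]) / sum(w[lo])
    m1 <- sum(lv[-lo] * w[-lo]) / sum(w[-lo])
    t <- (m0 + m1) / 2
    if (t >= lv[k] && t < lv[k + 1]) fps <- c(fps, t)
  }
  fps
}

# Match segmented objects to truth cells by majority label overlap and
# report per-truth-cell IoU.
truth_iou <- function(phantom, mask) {
  tl <- phantom$truth_label
  sl <- mask$label_map
  out <- numeric(nrow(phantom$truth_cells))
  for (i in seq_len(nrow(phantom$truth_cells))) {
    id <- phantom$truth_cells$cell_id[i]
    tpix <- tl == id
    if (!any(tpix)) { out[i] <- 0; next }
    labs <- sl[tpix]
    labs <- labs[labs > 0]
    if (!length(labs)) { out[i] <- 0; next }
    best <- as.integer(names(which.max(table(labs))))
    spix <- sl == best
    out[i] <- sum(tpix & spix) / sum(tpix | spix)
  }
  out
}

# Simulated toxicity series: wells spanning a range of true dead fractions,
# quantified by both the phase (rule-based dead fraction) and fluorescence
# (Et-HD positive fraction) branches.
simulate_toxicity_wells <- function(n_wells, seed, n_fields = 2,
                                    optics = test_optics(c(512L, 512L)),
                                    cells_per_field = 16) {
  geometry <- phantom_geometry()
  stain <- stain_config()
  rules <- rule_thresholds()
  out <- vector("list", n_wells)
  for (w in seq_len(n_wells)) {
    dead_true <- 0.05 + 0.5 * (w - 1) / max(1, n_wells - 1)
    mix <- c(undifferentiated = (1 - dead_true) * 0.8,
             adipocytic = (1 - dead_true) * 0.2, dead = dead_true)
    dhm <- numeric(0); ethd <- numeric(0); truth <- numeric(0)
    recs <- list()
    for (k in seq_len(n_fields)) {
      ph <- make_phantom_field(cells_per_field, mix, geometry, optics,
                               seed = k + 1000 * w + seed, sample_mix = TRUE)
      img <- render_phase_image(ph)
      m <- fixed_threshold_segment(img)
      recs[[k]] <- classify_cells_rules(extract_cell_features(img, m), rules)
      fl <- render_fluor_channels(ph, stain)
      nucc <- correct_illumination(fl$nuclear,
                                   pixel_size_um = optics$pixel_size_um)
      dc <- correct_illumination(fl$death + 1,
                                 pixel_size_um = optics$pixel_size_um)
      nuclei <- detect_nuclei(nucc, optics$pixel_size_um)
      ethd <- c(ethd, ethd_positive_fraction(dc, nuclei,
                                             pixel_size_um =
                                               optics$pixel_size_um))
      truth <- c(truth, mean(ph$truth_cells$phenotype == "dead"))
    }
    rec <- do.call(rbind, recs)
    out[[w]] <- data.frame(
      well = w,
      dead_dhm = as.numeric(dead_fraction(rec)),
      dead_ethd = mean(ethd, na.rm = TRUE),
      dead_truth = mean(truth)
    )
  }
  do.call(rbind, out)
}

# Build feature records + truth labels from seeded default-noise fields.
labeled_records <- function(seeds, mix = c(undifferentiated = 0.45,
                                           adipocytic = 0.40, dead = 0.15),
                            optics = test_optics(c(320L, 320L)),
                            n_cells = 16) {
  recs <- list()
  for (s in seeds) {
    ph <- make_phantom_field(n_cells, mix, optics = optics, seed = s)
    img <- render_phase_image(ph)
    m <- fixed_threshold_segment(img)
    r <- extract_cell_features(img, m)
    if (nrow(r) == 0) next
    # truth label by majority overlap through the truth label map
    lab <- m$label_map
    r$truth <- vapply(r$cell_id, function(id) {
      tl <- phantom_truth_majority(ph, lab, id)
      tl
    }, character(1))
    recs[[length(recs) + 1L]] <- r[!is.na(r$truth), ]
  }
  do.call(rbind, recs)
}

phantom_truth_majority <- function(phantom, label_map, id) {
  sel <- label_map == id
  tl <- phantom$truth_label[sel]
  tl <- tl[tl > 0]
  if (!length(tl)) return(NA_character_)
  best <- as.integer(names(which.max(table(tl))))
  phantom$truth_cells$phenotype[phantom$truth_cells$cell_id == best]
}
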