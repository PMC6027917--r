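#' Extract per-cell morphological and OPD features
#'
#' Computes one record per non-border segmented object: centroid, area,
#' perimeter, form factor, eccentricity, and OPD statistics. The perimeter
#' is the crack-boundary length (count of pixel edges between the object and
#' anything else) scaled by `pi/4`, which is unbiased for convex digitized
#' shapes (Cauchy-Crofton); the form factor is `4 * pi * area / perimeter^2`
#' (1 for a circle); eccentricity comes from the second central moments of
#' the pixel coordinates. Border-touching objects are excluded here because
#' their shape and area are truncated by the field of view.
#'
#' @param image A `phase_image` or numeric matrix (nm).
#' @param mask The [fixed_threshold_segment()] result for the same image.
#' @return A data frame of class `cell_records`, one row per non-border
#'   object: `cell_id`, `centroid_x`, `centroid_y` (px), `area_um2`,
#'   `perimeter_um`, `form_factor`, `eccentricity`, `mean_opd_nm`,
#'   `integrated_opd` (nm um^2), `phenotype` (initialized to `"error"`).
#' @export
extract_cell_features <- function(image, mask) {
  opd <- as_opd_matrix(image)
  stopifnot(inherits(mask, "labeled_mask"))
  lab <- mask$label_map
  if (!all(dim(opd) == dim(lab))) stop("shape mismatch")
  px <- mask$pixel_size_um
  n <- mask$n_objects
  keep <- setdiff(seq_len(n), mask$border_excluded_ids)
  if (n == 0L || length(keep) == 0L) return(empty_records())

  idx <- which(lab > 0L)
  li <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L

  area_px <- tabulate(li, nbins = n)
  sum_opd <- rowsum_by(opd[idx], li, n)
  sx <- rowsum_by(cols, li, n)
  sy <- rowsum_by(rows, li, n)
  sxx <- rowsum_by(cols^2, li, n)
  syy <- rowsum_by(rows^2, li, n)
  sxy <- rowsum_by(cols * rows, li, n)

  crack <- crack_length(lab, n)

  cx <- sx / area_px
  cy <- sy / area_px
  # central second moments (+1/12 pixel-integration term)
  mxx <- sxx / area_px - cx^2 + 1 / 12
  myy <- syy / area_px - cy^2 + 1 / 12
  mxy <- sxy / area_px - cx * cy
  tr <- mxx + myy
  det2 <- sqrt(pmax((mxx - myy)^2 + 4 * mxy^2, 0))
  l1 <- (tr + det2) / 2
  l2 <- (tr - det2) / 2
  ecc <- sqrt(pmax(1 - l2 / pmax(l1, .Machine$double.eps), 0))

  per_um <- crack * (pi / 4) * px
  area_um2 <- area_px * px^2
  ff <- 4 * pi * area_um2 / pmax(per_um^2, .Machine$double.eps)

  out <- data.frame(
    cell_id = keep,
    centroid_x = cx[keep], centroid_y = cy[keep],
    area_um2 = area_um2[keep],
    perimeter_um = per_um[keep],
    form_factor = ff[keep],
    eccentricity = ecc[keep],
    mean_opd_nm = (sum_opd / area_px)[keep],
    integrated_opd = (sum_opd * px^2)[keep],
    phenotype = "error",
    stringsAsFactors = FALSE
  )
  class(out) <- c("cell_records", "data.frame")
  out
}

empty_records <- function() {
  out <- data.frame(cell_id = integer(0), centroid_x = numeric(0),
                    centroid_y = numeric(0), area_um2 = numeric(0),
                    perimeter_um = numeric(0), form_factor = numeric(0),
                    eccentricity = numeric(0), mean_opd_nm = numeric(0),
                    integrated_opd = numeric(0), phenotype = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_records", "data.frame")
  out
}

rowsum_by <- function(v, g, n) {
  out <- numeric(n)
  rs <- rowsum(as.numeric(v), g)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

# Per-label count of exposed pixel edges (4-neighborhood crack boundary).
crack_length <- function(lab, n) {
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
  cnt <- numeric(n)
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  for (sh in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- pad[(2L + sh[1]):(nr + 1L + sh[1]), (2L + sh[2]):(nc + 1L + sh[2])]
    m <- core > 0L & nb != core
    if (any(m)) {
      t <- tabulate(core[m], nbins = n)
      cnt <- cnt + t
    }
  }
  cnt
}

#' Phenotype rule thresholds
#'
#' Cutoffs for the rule-based phenotype assignment. A cell is "small" below
#' `area_small_cutoff_um2`, "round" above `roundness_cutoff` (form factor),
#' and "high OPD" above `opd_high_cutoff_nm`. The OPD cutoff default (135
#' nm) was calibrated once from simulator truth as the midpoint between the
#' mean per-cell OPD of cytoplasm-only and droplet-bearing cells at default
#' geometry; the area and roundness defaults separate the small round dead
#' cells from the large spread live ones.
#'
#' @param area_small_cutoff_um2 Area below which a cell counts as small.
#' @param opd_high_cutoff_nm Mean OPD above which a cell counts as high-OPD.
#' @param roundness_cutoff Form factor above which a cell counts as round.
#' @return An object of class `rule_thresholds`.
#' @export
rule_thresholds <- function(area_small_cutoff_um2 = 200,
                            opd_high_cutoff_nm = 135,
                            roundness_cutoff = 0.85) {
  if (area_small_cutoff_um2 <= 0 || opd_high_cutoff_nm <= 0 ||
      roundness_cutoff <= 0) {
    stop("all rule thresholds must be positive")
  }
  structure(list(area_small_cutoff_um2 = area_small_cutoff_um2,
                 opd_high_cutoff_nm = opd_high_cutoff_nm,
                 roundness_cutoff = roundness_cutoff),
            class = "rule_thresholds")
}

#' Rule-based phenotype classification
#'
#' Encodes the qualitative phenotype definitions: dead cells are small and
#' round with high OPD; adipocytic cells are large with high OPD;
#' undifferentiated cells are large with low OPD. Objects matching none of
#' the three conjunctions (e.g. small low-OPD debris) are labeled `"error"`.
#'
#' @param records A [extract_cell_features()] data frame.
#' @param thresholds A [rule_thresholds()].
#' @return `records` with the `phenotype` column filled.
#' @export
classify_cells_rules <- function(records, thresholds = rule_thresholds()) {
  stopifnot(inherits(thresholds, "rule_thresholds"))
  if (nrow(records) == 0) return(records)
  small <- records$area_um2 < thresholds$area_small_cutoff_um2
  round_ <- records$form_factor > thresholds$roundness_cutoff
  high <- records$mean_opd_nm > thresholds$opd_high_cutoff_nm
  ph <- rep("error", nrow(records))
  dead <- small & round_ & high
  ph[dead] <- "dead"
  ph[!dead & !small & high] <- "adipocytic"
  ph[!dead & !small & !high] <- "undifferentiated"
  records$phenotype <- ph
  records
}

#' Dead-cell fraction of a record set
#'
#' @param records Classified cell records.
#' @return Dead cells divided by all non-error cells, in `[0, 1]`; `NaN`
#'   with a `flagged` attribute when there are no usable records.
#' @export
dead_fraction <- function(records) {
  if (nrow(records) == 0) {
    return(structure(NaN, flagged = TRUE))
  }
  usable <- records$phenotype != "error"
  if (!any(usable)) return(structure(NaN, flagged = TRUE))
  sum(records$phenotype == "dead") / sum(usable)
}
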