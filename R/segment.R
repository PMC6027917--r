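#' Segment a phase image with a robust fixed threshold
#'
#' Estimates the background level and spread robustly (median and
#' MAD-derived SD, `1.4826 * MAD`) from the whole image, thresholds at
#' `background + offset_sd * sd` ("slightly higher than the background", so
#' noisy pixels do not contribute), labels 8-connected components, removes
#' components below a minimum physical area, and flags components touching
#' the image edge for border exclusion downstream.
#'
#' @param image A `phase_image` (or bare numeric matrix in nm).
#' @param offset_sd Threshold offset in robust-SD units above background.
#' @param min_area_um2 Minimum object area in um^2; smaller components are
#'   dropped as noise.
#' @param pixel_size_um Pixel size; taken from `image$optics` when present.
#'
#' @return An object of class `labeled_mask`: `label_map` (integer matrix,
#'   0 = background, labels contiguous), `n_objects`,
#'   `border_excluded_ids`, `threshold_nm`, `pixel_size_um`. An
#'   all-background result is returned with `n_objects = 0`, not an error.
#' @export
fixed_threshold_segment <- function(image, offset_sd = 3,
                                    min_area_um2 = 20,
                                    pixel_size_um = NULL) {
  opd <- as_opd_matrix(image)
  if (!all(is.finite(opd))) stop("image must be finite")
  if (is.null(pixel_size_um)) {
    pixel_size_um <- if (inherits(image, "phase_image")) {
      image$optics$pixel_size_um
    } else 1
  }
  bg <- stats::median(opd)
  s <- stats::mad(opd)  # 1.4826 * MAD by default
  thr <- bg + offset_sd * s
  fg <- opd > thr
  lab <- EBImage::bwlabel(fg)
  lab <- matrix(as.integer(lab), nrow(opd), ncol(opd))
  min_px <- max(1L, ceiling(min_area_um2 / pixel_size_um^2))
  n0 <- max(lab)
  if (n0 > 0) {
    areas <- tabulate(lab[lab > 0L], nbins = n0)
    keep <- which(areas >= min_px)
    remap <- integer(n0)
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  n <- max(lab)
  border <- integer(0)
  if (n > 0) {
    edge <- c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])
    border <- sort(unique(edge[edge > 0L]))
  }
  structure(
    list(label_map = lab, n_objects = n, border_excluded_ids = border,
         threshold_nm = thr, pixel_size_um = pixel_size_um),
    class = "labeled_mask"
  )
}

as_opd_matrix <- function(image) {
  if (inherits(image, "phase_image")) image$opd_nm
  else if (is.matrix(image)) image
  else stop("expected a phase_image or numeric matrix")
}

#' Ridler-Calvard (iterative intermeans) threshold
#'
#' Computes the classic iterative-intermeans threshold: starting from the
#' midrange, the threshold is updated to the average of the means of the two
#' classes it induces, `t <- (mean(x[x <= t]) + mean(x[x > t])) / 2`, until
#' it moves by less than `tol`. The result is a fixed point of the
#' intermeans map.
#'
#' @param image A `phase_image`, matrix, or numeric vector of values.
#' @param tol Convergence tolerance on the threshold, in value units.
#' @param max_iter Iteration cap.
#' @return The threshold (numeric scalar), in the units of the input.
#' @export
ridler_calvard_threshold <- function(image, tol = 1e-8, max_iter = 200L) {
  x <- if (inherits(image, "phase_image")) as.numeric(image$opd_nm)
       else as.numeric(image)
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) {
    stop("degenerate histogram: image must have >= 2 distinct values")
  }
  t <- (min(x) + max(x)) / 2
  for (i in seq_len(max_iter)) {
    lo <- x <= t
    m0 <- mean(x[lo])
    m1 <- mean(x[!lo])
    if (!is.finite(m1)) m1 <- m0  # all values below t
    t_new <- (m0 + m1) / 2
    if (abs(t_new - t) <= tol) return(t_new)
    t <- t_new
  }
  t
}

#' Mean OPD within segmented cells
#'
#' Pooled arithmetic mean of the OPD map over all pixels with a positive
#' label. All segmented objects contribute, including border-touching ones
#' (border exclusion applies to counting and classification, not to the
#' pooled OPD average). An empty mask yields `NaN` with a `flagged`
#' attribute rather than a silent 0.
#'
#' @param image A `phase_image` or numeric matrix (nm).
#' @param mask A [fixed_threshold_segment()] result.
#' @return Mean OPD in nm; `NaN` with `attr(, "flagged") = TRUE` when the
#'   mask has no foreground pixels.
#' @export
mean_opd <- function(image, mask) {
  opd <- as_opd_matrix(image)
  stopifnot(inherits(mask, "labeled_mask"))
  if (!all(dim(opd) == dim(mask$label_map))) stop("shape mismatch")
  sel <- mask$label_map > 0L
  if (!any(sel)) {
    return(structure(NaN, flagged = TRUE))
  }
  mean(opd[sel])
}

#' Count cells, excluding border-touching objects
#'
#' @param mask A [fixed_threshold_segment()] result.
#' @return Number of labeled objects not touching the image border.
#' @export
count_cells <- function(mask) {
  stopifnot(inherits(mask, "labeled_mask"))
  mask$n_objects - length(mask$border_excluded_ids)
}

#' Aggregate field measurements into a well measurement
#'
#' Averages the per-field mean OPD over the fields of a well (the four
#' images per well are averaged into the quantified value) and sums cell
#' counts. Fields with an empty mask (`NaN` OPD) are dropped before
#' averaging; if every field is empty the well is flagged as no-cells,
#' mirroring the removal of images without cells from analysis.
#'
#' @param field_opds Numeric vector of per-field mean OPD (nm); `NaN` marks
#'   an empty field.
#' @param field_counts Optional integer vector of per-field cell counts.
#' @param well_id Optional well identifier carried through.
#' @return An object of class `well_measurement`: `well_id`, `field_opds`,
#'   `mean_opd` (nm), `cell_count`, `n_fields_used`, `no_cells` flag.
#' @export
aggregate_well <- function(field_opds, field_counts = NULL, well_id = NA) {
  if (length(field_opds) < 1L) stop("need >= 1 field")
  ok <- is.finite(field_opds)
  no_cells <- !any(ok)
  structure(
    list(
      well_id = well_id,
      field_opds = field_opds,
      mean_opd = if (no_cells) NaN else mean(field_opds[ok]),
      cell_count = if (is.null(field_counts)) NA_integer_
                   else as.integer(sum(field_counts, na.rm = TRUE)),
      n_fields_used = sum(ok),
      no_cells = no_cells
    ),
    class = "well_measurement"
  )
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf(
    "labeled_mask: %d objects (%d border-excluded), threshold %.2f nm\n",
    x$n_objects, length(x$border_excluded_ids), x$threshold_nm))
  invisible(x)
}

#' @export
print.well_measurement <- function(x, ...) {
  cat(sprintf(
    "well %s: mean OPD %.2f nm over %d field(s), %s cells%s\n",
    as.character(x$well_id), x$mean_opd, x$n_fields_used,
    ifelse(is.na(x$cell_count), "NA", as.character(x$cell_count)),
    if (x$no_cells) " [no cells]" else ""))
  invisible(x)
}
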