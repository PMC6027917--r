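#' Correct uneven illumination by division
#'
#' Divides a fluorescence channel by a heavily Gaussian-smoothed version of
#' itself (smoothing scale far above the cell diameter, so only the
#' illumination gradient survives the blur) and rescales so the global
#' median is preserved. The large-scale blur is computed on a block-averaged
#' pyramid level for speed and upsampled back bilinearly. The normalized
#' correction field is clipped to `[1/max_factor, max_factor]`: real
#' illumination gradients are bounded, and on sparse dark-background
#' channels an unclipped estimate is dominated by the cells themselves,
#' which would suppress signal in crowded regions.
#'
#' @param channel Numeric matrix of intensities.
#' @param smoothing_scale_um Gaussian sigma of the background estimate, um.
#' @param pixel_size_um Pixel size, um.
#' @param max_factor Cap on the relative correction factor.
#' @return Corrected matrix with the same dimensions and global median.
#' @export
correct_illumination <- function(channel, smoothing_scale_um = 100,
                                 pixel_size_um = 0.65, max_factor = 1.5) {
  stopifnot(is.matrix(channel))
  sigma_px <- smoothing_scale_um / pixel_size_um
  ds <- max(1L, floor(sigma_px / 8))
  small <- if (ds > 1L) {
    EBImage::resize(channel, w = max(8L, ceiling(nrow(channel) / ds)),
                    h = max(8L, ceiling(ncol(channel) / ds)))
  } else channel
  sig_s <- sigma_px / ds
  # the Gaussian support can exceed the field; blur on a replicate-padded
  # frame so the kernel always fits and edges are not wrapped
  pad <- as.integer(ceiling(3 * sig_s) + 1L)
  # intensities are non-negative; clamp the extrapolated frame accordingly
  padded <- pmax(pad_linear(as.matrix(small), pad), 0)
  blurred <- as.matrix(EBImage::gblur(padded, sigma = sig_s))
  core <- blurred[(pad + 1):(pad + nrow(small)),
                  (pad + 1):(pad + ncol(small)), drop = FALSE]
  smooth <- if (ds > 1L) {
    as.matrix(EBImage::resize(core, w = nrow(channel), h = ncol(channel)))
  } else core
  med_s <- stats::median(smooth)
  if (med_s <= 0) {
    stop("smoothed background contains non-positive values; ",
         "cannot divide (channel too dark for illumination correction)")
  }
  fac <- pmin(pmax(smooth / med_s, 1 / max_factor), max_factor)
  corrected <- channel / fac
  med <- stats::median(corrected)
  if (med > 0) corrected <- corrected * stats::median(channel) / med
  corrected
}

# Odd (antisymmetric) reflection padding: p[-i] = 2 p[1] - p[1+i].
# Continues linear trends across the boundary, so the heavy blur does not
# flatten an illumination gradient at the field edges.
pad_linear <- function(m, pad) {
  nr <- nrow(m); nc <- ncol(m)
  pad_axis <- function(mat) {
    n <- nrow(mat)
    top <- 2 * mat[rep(1L, pad), , drop = FALSE] -
      mat[pmin(1L + (pad:1), n), , drop = FALSE]
    bot <- 2 * mat[rep(n, pad), , drop = FALSE] -
      mat[pmax(n - (1:pad), 1L), , drop = FALSE]
    rbind(top, mat, bot)
  }
  out <- pad_axis(m)
  t(pad_axis(t(out)))
}

#' Detect nuclei in a nuclear-stain channel
#'
#' Automatic (iterative intermeans) threshold, 8-connected labeling, and a
#' minimum-area filter; one centroid per surviving blob.
#'
#' @param channel Nuclear-stain matrix (illumination-corrected).
#' @param pixel_size_um Pixel size, um.
#' @param min_area_um2 Minimum nuclear blob area.
#' @return An object of class `nucleus_set`: `centroids` (matrix with
#'   columns `x`, `y` in pixels) and `count`.
#' @export
detect_nuclei <- function(channel, pixel_size_um = 0.65, min_area_um2 = 10) {
  stopifnot(is.matrix(channel))
  if (length(unique(as.numeric(channel))) < 2L) {
    return(structure(list(centroids = matrix(numeric(0), 0, 2,
                                             dimnames = list(NULL,
                                                             c("x", "y"))),
                          count = 0L), class = "nucleus_set"))
  }
  # intermeans threshold, floored at a robust background ceiling so a
  # signal-free channel (noise only) does not get split within its noise
  thr <- max(ridler_calvard_threshold(channel),
             stats::median(channel) + 3 * stats::mad(channel))
  lab <- EBImage::bwlabel(channel > thr)
  lab <- matrix(as.integer(lab), nrow(channel), ncol(channel))
  n <- max(lab)
  cents <- matrix(numeric(0), 0, 2)
  if (n > 0) {
    min_px <- max(1L, ceiling(min_area_um2 / pixel_size_um^2))
    idx <- which(lab > 0L)
    li <- lab[idx]
    areas <- tabulate(li, nbins = n)
    keep <- which(areas >= min_px)
    if (length(keep)) {
      rows <- (idx - 1L) %% nrow(lab) + 1L
      cols <- (idx - 1L) %/% nrow(lab) + 1L
      cx <- rowsum_by(cols, li, n) / areas
      cy <- rowsum_by(rows, li, n) / areas
      cents <- cbind(x = cx[keep], y = cy[keep])
    }
  }
  structure(list(centroids = cents, count = nrow(cents)),
            class = "nucleus_set")
}

# Median of a channel within a disk around (cx, cy); NA when empty.
disk_median <- function(channel, cx, cy, r_px) {
  nr <- nrow(channel); nc <- ncol(channel)
  x0 <- max(1L, floor(cx - r_px)); x1 <- min(nc, ceiling(cx + r_px))
  y0 <- max(1L, floor(cy - r_px)); y1 <- min(nr, ceiling(cy + r_px))
  if (x0 > x1 || y0 > y1) return(NA_real_)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  sub <- channel[ys, xs, drop = FALSE]
  v <- sub[(dx^2 + dy^2) <= r_px^2]
  if (!length(v)) return(NA_real_)
  stats::median(v)
}

#' Nucleus-anchored lipid intensity (LipidTox-style readout)
#'
#' For each detected nucleus, the median lipid-channel intensity within a
#' disk of the given radius (20 um by default) around the nucleus centroid;
#' the field summary is the median over cells. Nuclei closer than the
#' radius to the image edge get a clipped disk and are flagged.
#'
#' @param channel Lipid-stain matrix (illumination-corrected).
#' @param nuclei A [detect_nuclei()] result.
#' @param radius_um Measurement disk radius, um.
#' @param pixel_size_um Pixel size, um.
#' @return List with `per_cell` (data frame: `x`, `y`, `median_intensity`,
#'   `clipped`) and `field_median` (`NaN`, flagged, when there are no
#'   nuclei).
#' @export
lipid_intensity_per_nucleus <- function(channel, nuclei, radius_um = 20,
                                        pixel_size_um = 0.65) {
  stopifnot(inherits(nuclei, "nucleus_set"), radius_um > 0)
  r_px <- radius_um / pixel_size_um
  if (nuclei$count == 0L) {
    return(list(per_cell = data.frame(x = numeric(0), y = numeric(0),
                                      median_intensity = numeric(0),
                                      clipped = logical(0)),
                field_median = structure(NaN, flagged = TRUE)))
  }
  vals <- numeric(nuclei$count)
  clipped <- logical(nuclei$count)
  for (i in seq_len(nuclei$count)) {
    cx <- nuclei$centroids[i, "x"]
    cy <- nuclei$centroids[i, "y"]
    vals[i] <- disk_median(channel, cx, cy, r_px)
    clipped[i] <- (cx - r_px) < 1 || (cx + r_px) > ncol(channel) ||
                  (cy - r_px) < 1 || (cy + r_px) > nrow(channel)
  }
  list(per_cell = data.frame(x = nuclei$centroids[, "x"],
                             y = nuclei$centroids[, "y"],
                             median_intensity = vals, clipped = clipped),
       field_median = stats::median(vals, na.rm = TRUE))
}

#' Nile Red droplet quantification through a cytoplasm mask
#'
#' Builds a cytoplasm mask from the faint membrane staining (a robust
#' background-anchored threshold, median + 3 x 1.4826 MAD of the whole
#' channel floored at the detector noise level — the mask must capture
#' every cell's faint cytoplasm, so it is anchored to the background
#' rather than split between cell brightness classes; a minimum-area
#' filter keeps isolated noise pixels from counting as cells), finds the
#' droplet
#' threshold within the mask by intermeans, and reports the field median
#' over all cells of the per-cell median droplet intensity. A cell with no
#' pixels above the droplet threshold contributes the median of its mask
#' pixels (its faint cytoplasm level), so droplet-free cells pull the
#' field median down rather than dropping out of it. A field whose mask
#' contains no cell-sized component is flagged, reproducing the failure
#' mode of an unsuccessful staining round.
#'
#' @param channel Nile Red matrix (illumination-corrected).
#' @param pixel_size_um Pixel size, um.
#' @param min_cell_area_um2 Minimum mask component area to count as a cell.
#' @param min_intensity Detector noise floor: mask pixels must also exceed
#'   this absolute intensity, so a stain-free channel cannot produce a
#'   cytoplasm mask out of noise.
#' @return List with `value` (field median droplet intensity; `NaN` when
#'   flagged), `flagged`, `reason`, `n_cells`.
#' @export
nile_red_quant <- function(channel, pixel_size_um = 0.65,
                           min_cell_area_um2 = 50, min_intensity = 5) {
  stopifnot(is.matrix(channel))
  if (max(channel) - min(channel) <= 0) {
    return(list(value = NaN, flagged = TRUE,
                reason = "no dynamic range", n_cells = 0L))
  }
  thr <- max(stats::median(channel) + 3 * stats::mad(channel),
             min_intensity)
  lab <- EBImage::bwlabel(channel > thr)
  lab <- matrix(as.integer(lab), nrow(channel), ncol(channel))
  n <- max(lab)
  if (n == 0L) {
    return(list(value = NaN, flagged = TRUE,
                reason = "empty cytoplasm mask", n_cells = 0L))
  }
  min_px <- max(1L, ceiling(min_cell_area_um2 / pixel_size_um^2))
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(areas >= min_px)
  if (!length(keep)) {
    return(list(value = NaN, flagged = TRUE,
                reason = "empty cytoplasm mask", n_cells = 0L))
  }
  sel <- lab %in% keep
  droplet_thr <- tryCatch(ridler_calvard_threshold(channel[sel]),
                          error = function(e) NA_real_)
  if (!is.finite(droplet_thr)) {
    return(list(value = NaN, flagged = TRUE,
                reason = "degenerate droplet histogram",
                n_cells = length(keep)))
  }
  per_cell <- vapply(keep, function(id) {
    v <- channel[lab == id]
    vd <- v[v > droplet_thr]
    if (length(vd)) stats::median(vd) else stats::median(v)
  }, numeric(1))
  list(value = stats::median(per_cell), flagged = FALSE,
       reason = NA_character_, n_cells = length(keep))
}

#' Ethidium-homodimer positive cell fraction
#'
#' A cell is positive when the median death-channel intensity within a
#' small disk around its nucleus exceeds the fixed cutoff; the returned
#' value is positives over total nuclei. Per-well values average the four
#' per-field ratios upstream.
#'
#' @param channel Death-stain matrix (illumination-corrected).
#' @param nuclei A [detect_nuclei()] result.
#' @param fixed_cutoff Positivity cutoff intensity; the default (50) sits
#'   far above negative-control intensities and far below dead-cell signal
#'   under the default stain model (see [calibrate_ethd_cutoff()]).
#' @param radius_um Per-nucleus measurement disk radius, um.
#' @param pixel_size_um Pixel size, um.
#' @return Fraction in `[0, 1]`; `NaN` with a `flagged` attribute when
#'   there are no nuclei.
#' @export
ethd_positive_fraction <- function(channel, nuclei, fixed_cutoff = 50,
                                   radius_um = 6, pixel_size_um = 0.65) {
  stopifnot(inherits(nuclei, "nucleus_set"), fixed_cutoff > 0)
  if (nuclei$count == 0L) return(structure(NaN, flagged = TRUE))
  med <- vapply(seq_len(nuclei$count), function(i) {
    disk_median(channel, nuclei$centroids[i, "x"], nuclei$centroids[i, "y"],
                radius_um / pixel_size_um)
  }, numeric(1))
  mean(med > fixed_cutoff, na.rm = TRUE)
}

#' Calibrate the Et-HD positivity cutoff from negative controls
#'
#' Sets the fixed cutoff from the upper quantile of negative-control
#' (toxin-free) death-channel intensities, times a safety margin.
#'
#' @param channels List of negative-control death-channel matrices.
#' @param quantile_p Quantile of the pooled intensities (default 99.9th
#'   percentile).
#' @param margin Multiplicative safety margin above the quantile.
#' @return Cutoff intensity (numeric scalar).
#' @export
calibrate_ethd_cutoff <- function(channels, quantile_p = 0.999, margin = 3) {
  if (is.matrix(channels)) channels <- list(channels)
  pooled <- unlist(lapply(channels, as.numeric))
  as.numeric(stats::quantile(pooled, quantile_p)) * margin
}
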