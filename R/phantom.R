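#' Generate a ground-truthed phantom field of adherent cells
#'
#' Places `n_cells` synthetic cells of three phenotypes on an empty field and
#' returns the per-pixel thickness and refractive-index maps from which a
#' phase image can be rendered, together with a per-cell truth table and a
#' truth label map. Undifferentiated cells are large, moderately thick
#' elliptical caps at cytoplasmic index; adipocytic cells are large caps that
#' additionally contain circular lipid-droplet inclusions at elevated index;
#' dead cells are small, round, thick caps at a condensed (elevated) index.
#'
#' Cell thickness follows a spherical-cap profile
#' `t(r) = t_max * sqrt(1 - r^2)` in normalized elliptical radius. Cells are
#' placed by rejection sampling under a minimum centroid-separation
#' constraint (`geometry$min_sep_factor`); when a field is too crowded to
#' satisfy it the constraint is waived for the remaining cells, so dense
#' fields contain touching cells, as in a confluent monolayer.
#'
#' @param n_cells Number of cells to place (>= 0).
#' @param phenotype_mix Named numeric vector of fractions over
#'   `c("undifferentiated", "adipocytic", "dead")`; must sum to 1. Missing
#'   names count as 0.
#' @param geometry A [phantom_geometry()] object.
#' @param optics An [optics_config()] object (field shape and pixel size).
#' @param seed Integer seed; generation is bitwise-reproducible given it.
#' @param sample_mix If `FALSE` (default) phenotype counts are the exact
#'   deterministic apportionment of `n_cells * phenotype_mix`; if `TRUE` they
#'   are a multinomial draw, as appropriate when the mix is itself an
#'   expected fraction.
#'
#' @return An object of class `phantom_field` with elements `thickness_nm`
#'   and `refindex` (matrices), `medium_index`, `truth_label` (integer
#'   matrix, 0 = background), `truth_cells` (data frame: `cell_id`,
#'   `phenotype`, `x`, `y` in pixels, `rx_um`, `ry_um`, `theta`, `tmax_um`,
#'   `area_um2`, `droplet_volume_fraction`, `border`), plus the `geometry`
#'   and `optics` used.
#' @export
make_phantom_field <- function(n_cells,
                               phenotype_mix = c(undifferentiated = 1),
                               geometry = phantom_geometry(),
                               optics = optics_config(),
                               seed = 1L,
                               sample_mix = FALSE) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 0 ||
      n_cells != round(n_cells)) {
    stop("'n_cells' must be a non-negative integer")
  }
  mix <- numeric(length(PHENOTYPES))
  names(mix) <- PHENOTYPES
  if (is.null(names(phenotype_mix)) ||
      !all(names(phenotype_mix) %in% PHENOTYPES)) {
    stop("'phenotype_mix' must be named with phenotypes among: ",
         paste(PHENOTYPES, collapse = ", "))
  }
  mix[names(phenotype_mix)] <- phenotype_mix
  if (abs(sum(mix) - 1) > 1e-6) stop("'phenotype_mix' must sum to 1")

  nr <- optics$field_shape[1]
  nc <- optics$field_shape[2]
  px <- optics$pixel_size_um
  thick <- matrix(0, nr, nc)
  rindex <- matrix(geometry$medium_index, nr, nc)
  label <- matrix(0L, nr, nc)

  local_seed(seed, {
    counts <- if (n_cells == 0) {
      integer(length(PHENOTYPES))
    } else if (sample_mix) {
      as.integer(stats::rmultinom(1, n_cells, mix))
    } else {
      apportion(n_cells, mix)
    }
    phenos <- rep(PHENOTYPES, counts)
    if (length(phenos) > 1L) phenos <- sample(phenos)

    placed <- vector("list", length(phenos))
    centers <- matrix(numeric(0), ncol = 2)
    outer_r <- numeric(0)

    for (i in seq_along(phenos)) {
      ph <- phenos[i]
      if (ph == "dead") {
        r_um <- stats::runif(1, geometry$dead_radius_um[1],
                             geometry$dead_radius_um[2])
        rx <- ry <- r_um
        theta <- 0
        tmax <- stats::runif(1, geometry$dead_thickness_um[1],
                             geometry$dead_thickness_um[2])
        idx_val <- geometry$dead_index
      } else {
        rx <- stats::runif(1, geometry$live_radius_um[1],
                           geometry$live_radius_um[2])
        ar <- stats::runif(1, geometry$live_axis_ratio[1],
                           geometry$live_axis_ratio[2])
        ry <- rx / ar
        theta <- stats::runif(1, 0, pi)
        trange <- if (ph == "adipocytic") geometry$adipo_thickness_um
                  else geometry$live_thickness_um
        tmax <- stats::runif(1, trange[1], trange[2])
        idx_val <- geometry$cytoplasm_index
      }
      rout <- max(rx, ry) / px

      ok <- FALSE
      for (a in seq_len(geometry$max_place_attempts)) {
        cx <- stats::runif(1, 1, nc)
        cy <- stats::runif(1, 1, nr)
        if (nrow(centers) == 0) { ok <- TRUE; break }
        d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        if (all(d >= geometry$min_sep_factor * (outer_r + rout))) {
          ok <- TRUE
          break
        }
      }
      # constraint waived after max attempts: keep last candidate
      centers <- rbind(centers, c(cx, cy))
      outer_r <- c(outer_r, rout)

      cell <- cell_patch(c(nr, nc), cx, cy, rx / px, ry / px, theta,
                         tmax * 1000)
      area_px <- 0L
      if (!is.null(cell)) {
        sub_t <- thick[cell$ys, cell$xs, drop = FALSE]
        win <- cell$tloc > sub_t  # later cells win where strictly thicker
        if (any(win)) {
          sub_t[win] <- cell$tloc[win]
          thick[cell$ys, cell$xs] <- sub_t
          sub_r <- rindex[cell$ys, cell$xs, drop = FALSE]
          sub_r[win] <- idx_val
          rindex[cell$ys, cell$xs] <- sub_r
          sub_l <- label[cell$ys, cell$xs, drop = FALSE]
          sub_l[win] <- i
          label[cell$ys, cell$xs] <- sub_l
        }
        area_px <- sum(win)
      }

      dvf <- 0
      if (ph == "adipocytic" && area_px > 0) {
        target <- stats::runif(1, geometry$droplet_area_fraction[1],
                               geometry$droplet_area_fraction[2])
        droplet_px <- 0L
        for (k in 1:60) {
          if (droplet_px >= target * area_px) break
          dp <- droplet_patch(c(nr, nc), cx, cy, rx / px, ry / px, theta,
                              geometry, px)
          if (is.null(dp)) next
          sub_r <- rindex[dp$ys, dp$xs, drop = FALSE]
          sub_l <- label[dp$ys, dp$xs, drop = FALSE]
          hit <- dp$circ & (sub_l == i) &
                 (sub_r < geometry$droplet_index)
          if (any(hit)) {
            sub_r[hit] <- geometry$droplet_index
            rindex[dp$ys, dp$xs] <- sub_r
            droplet_px <- droplet_px + sum(hit)
          }
        }
        dvf <- droplet_px / area_px
      }

      placed[[i]] <- data.frame(
        cell_id = i, phenotype = ph, x = cx, y = cy,
        rx_um = rx, ry_um = ry, theta = theta, tmax_um = tmax,
        area_um2 = area_px * px^2,
        droplet_volume_fraction = dvf,
        border = (cx - rout) < 1 || (cx + rout) > nc ||
                 (cy - rout) < 1 || (cy + rout) > nr,
        stringsAsFactors = FALSE
      )
    }
    truth <- if (length(placed)) do.call(rbind, placed) else empty_truth()
    truth
  }) -> truth_cells

  structure(
    list(
      thickness_nm = thick, refindex = rindex,
      medium_index = geometry$medium_index,
      truth_label = label, truth_cells = truth_cells,
      geometry = geometry, optics = optics, seed = as.integer(seed)
    ),
    class = "phantom_field"
  )
}

empty_truth <- function() {
  data.frame(cell_id = integer(0), phenotype = character(0),
             x = numeric(0), y = numeric(0), rx_um = numeric(0),
             ry_um = numeric(0), theta = numeric(0), tmax_um = numeric(0),
             area_um2 = numeric(0), droplet_volume_fraction = numeric(0),
             border = logical(0), stringsAsFactors = FALSE)
}

# Largest-remainder apportionment of n over fractions (deterministic).
apportion <- function(n, frac) {
  raw <- n * frac
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Rasterize one spherical-cap cell as a local patch (indices + thickness);
# the caller assigns it into the field maps in place.
cell_patch <- function(shape, cx, cy, rx_px, ry_px, theta, tmax_nm) {
  nr <- shape[1]; nc <- shape[2]
  rout <- max(rx_px, ry_px)
  x0 <- max(1L, floor(cx - rout)); x1 <- min(nc, ceiling(cx + rout))
  y0 <- max(1L, floor(cy - rout)); y1 <- min(nr, ceiling(cy + rout))
  if (x0 > x1 || y0 > y1) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  ct <- cos(theta); st <- sin(theta)
  u <- (dx * ct + dy * st) / rx_px
  v <- (-dx * st + dy * ct) / ry_px
  e <- u^2 + v^2
  tloc <- matrix(0, length(ys), length(xs))
  inside <- e < 1
  tloc[inside] <- tmax_nm * sqrt(1 - e[inside])
  list(xs = xs, ys = ys, tloc = tloc)
}

# One candidate circular droplet inclusion, as a local patch mask.
droplet_patch <- function(shape, cx, cy, rx_px, ry_px, theta, geometry, px) {
  nr <- shape[1]; nc <- shape[2]
  r_um <- stats::runif(1, geometry$droplet_radius_um[1],
                       geometry$droplet_radius_um[2])
  r_px <- min(r_um / px, 0.5 * min(rx_px, ry_px))
  # droplet center inside the inner 75% of the ellipse
  repeat {
    uu <- stats::runif(1, -0.75, 0.75)
    vv <- stats::runif(1, -0.75, 0.75)
    if (uu^2 + vv^2 < 0.75^2) break
  }
  ct <- cos(theta); st <- sin(theta)
  dcx <- cx + uu * rx_px * ct - vv * ry_px * st
  dcy <- cy + uu * rx_px * st + vv * ry_px * ct
  x0 <- max(1L, floor(dcx - r_px)); x1 <- min(nc, ceiling(dcx + r_px))
  y0 <- max(1L, floor(dcy - r_px)); y1 <- min(nr, ceiling(dcy + r_px))
  if (x0 > x1 || y0 > y1) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - dcx)
  dy <- outer(ys - dcy, rep(1, length(xs)))
  list(xs = xs, ys = ys, circ = (dx^2 + dy^2) <= r_px^2)
}

#' Render a phase image from a phantom field
#'
#' Computes the per-pixel optical path difference
#' `OPD(x, y) = d(x, y) * (n_c(x, y) - n_m)` in nm, where `d` is the cell
#' thickness map, `n_c` the z-integrated intracellular refractive index, and
#' `n_m` the medium index, then applies additive Gaussian OPD noise
#' (`optics$opd_noise_sd_nm`) and a smooth random low-order polynomial
#' background drift (`optics$background_drift_nm` peak amplitude). With both
#' set to 0 the returned map is exactly the noiseless product.
#'
#' @param phantom A [make_phantom_field()] result.
#' @param optics An [optics_config()]; its `field_shape` must match the
#'   phantom maps.
#' @param seed Optional integer seed for the noise draw; if `NULL`, the
#'   phantom's own seed is used, so rendering is reproducible by default.
#'
#' @return An object of class `phase_image`: list with `opd_nm` (matrix),
#'   `optics`, and `provenance`.
#' @export
render_phase_image <- function(phantom, optics = phantom$optics, seed = NULL) {
  stopifnot(inherits(phantom, "phantom_field"))
  if (!all(dim(phantom$thickness_nm) == optics$field_shape)) {
    stop("phantom maps do not match optics$field_shape")
  }
  opd <- phantom$thickness_nm * (phantom$refindex - phantom$medium_index)
  if (is.null(seed)) seed <- sub_seed(phantom$seed, 101L)
  if (optics$opd_noise_sd_nm > 0 || optics$background_drift_nm > 0) {
    opd <- local_seed(seed, {
      out <- opd
      if (optics$background_drift_nm > 0) {
        out <- out + poly_drift(dim(opd), optics$background_drift_nm)
      }
      if (optics$opd_noise_sd_nm > 0) {
        out <- out + matrix(stats::rnorm(length(opd), 0,
                                         optics$opd_noise_sd_nm),
                            nrow(opd), ncol(opd))
      }
      out
    })
  }
  structure(
    list(opd_nm = opd, optics = optics,
         provenance = sprintf("synthetic phantom seed=%d", phantom$seed)),
    class = "phase_image"
  )
}

# Random second-order polynomial surface, scaled to peak amplitude, zero
# median: the smooth background drift left by imperfect flat-field reference.
poly_drift <- function(shape, amplitude) {
  xs <- seq(-1, 1, length.out = shape[2])
  ys <- seq(-1, 1, length.out = shape[1])
  cf <- stats::runif(5, -1, 1)
  X <- outer(rep(1, shape[1]), xs)
  Y <- outer(ys, rep(1, shape[2]))
  s <- cf[1] * X + cf[2] * Y + cf[3] * X * Y + cf[4] * X^2 + cf[5] * Y^2
  s <- s - stats::median(s)
  m <- max(abs(s))
  if (m < .Machine$double.eps) return(matrix(0, shape[1], shape[2]))
  s * (amplitude / m)
}

#' @export
print.phantom_field <- function(x, ...) {
  cat(sprintf("phantom_field: %d cells (%s), %dx%d px @ %.3f um/px\n",
              nrow(x$truth_cells),
              paste(sprintf("%s=%d", PHENOTYPES,
                            tabulate(factor(x$truth_cells$phenotype,
                                            PHENOTYPES),
                                     length(PHENOTYPES))), collapse = ", "),
              nrow(x$thickness_nm), ncol(x$thickness_nm),
              x$optics$pixel_size_um))
  invisible(x)
}

#' @export
print.phase_image <- function(x, ...) {
  cat(sprintf("phase_image: %dx%d px, OPD range [%.1f, %.1f] nm (%s)\n",
              nrow(x$opd_nm), ncol(x$opd_nm), min(x$opd_nm), max(x$opd_nm),
              x$provenance))
  invisible(x)
}
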