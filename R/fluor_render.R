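#' Staining model settings for synthetic fluorescence channels
#'
#' Intensity constants (arbitrary units) for the three emulated stains: a
#' nuclear stain (Hoechst-like), a neutral-lipid stain (LipidTox / Nile Red
#' -like: faint cytoplasm, a diffuse component proportional to the cell's
#' droplet content, and bright resolved droplets), and a dead-cell stain
#' (ethidium-homodimer-like, bright only over dead cells). A smooth
#' multiplicative illumination gradient and additive detector noise are
#' applied to all channels; `stain_failure` rescales the lipid channel by a
#' global factor to emulate a failed staining round.
#'
#' @param nuclear_amp,nuclear_sigma_um Peak intensity and Gaussian width of
#'   nuclear blobs.
#' @param lipid_cyto,lipid_diffuse_slope,lipid_droplet_amp Cytoplasmic
#'   baseline, slope of the diffuse component per unit droplet volume
#'   fraction, and resolved-droplet intensity scale of the lipid channel.
#'   Droplet pixels render at `lipid_droplet_amp * (0.4 + 1.2 * dvf)` for a
#'   cell with droplet volume fraction `dvf`: the stain signal integrates
#'   over z, so bigger droplet loads yield brighter droplet pixels, not
#'   just more of them.
#' @param death_amp,death_live_leak Dead-cell footprint intensity and the
#'   faint nonspecific signal over live cells.
#' @param noise_sd Additive Gaussian detector noise SD (all channels).
#' @param illumination_amplitude Peak relative amplitude of the smooth
#'   multiplicative illumination gradient (0 disables it).
#' @param stain_failure_scale Global lipid-channel factor applied when a
#'   field is rendered with `stain_failure = TRUE`.
#' @return An object of class `stain_config`.
#' @export
stain_config <- function(nuclear_amp = 800, nuclear_sigma_um = 3,
                         lipid_cyto = 10, lipid_diffuse_slope = 400,
                         lipid_droplet_amp = 1000,
                         death_amp = 600, death_live_leak = 2,
                         noise_sd = 2,
                         illumination_amplitude = 0.3,
                         stain_failure_scale = 0.15) {
  structure(as.list(environment()), class = "stain_config")
}

#' Render synthetic fluorescence channels for a phantom field
#'
#' Produces the three-channel fluorescence counterpart of a phantom: one
#' nuclear blob per cell (live or dead), a lipid channel whose per-cell
#' intensity increases monotonically with the cell's droplet volume
#' fraction, and a death channel bright only over dead cells. All channels
#' share the phantom's field shape and receive the same multiplicative
#' illumination gradient.
#'
#' @param phantom A [make_phantom_field()] result.
#' @param stain A [stain_config()].
#' @param seed Integer seed for gradient and noise draws.
#' @param stain_failure If `TRUE`, the lipid channel is globally rescaled by
#'   `stain$stain_failure_scale` (a failed lipid stain); all other structure
#'   is identical to the `FALSE` rendering under the same seed.
#'
#' @return An object of class `fluorescence_field`: matrices `nuclear`,
#'   `lipid`, `death`, the applied `illumination` field, `stain_failure`
#'   flag, and the `optics` used.
#' @export
render_fluor_channels <- function(phantom, stain = stain_config(),
                                  seed = NULL, stain_failure = FALSE) {
  stopifnot(inherits(phantom, "phantom_field"))
  if (is.null(seed)) seed <- sub_seed(phantom$seed, 202L)
  optics <- phantom$optics
  nr <- optics$field_shape[1]; nc <- optics$field_shape[2]
  px <- optics$pixel_size_um
  truth <- phantom$truth_cells
  lab <- phantom$truth_label

  nuclear <- matrix(0, nr, nc)
  lipid <- matrix(0, nr, nc)
  death <- matrix(0, nr, nc)

  if (nrow(truth) > 0) {
    # phenotype and droplet fraction looked up per pixel through the label map
    pheno <- truth$phenotype[match(seq_len(max(truth$cell_id)),
                                   truth$cell_id)]
    dvf <- truth$droplet_volume_fraction[match(seq_len(max(truth$cell_id)),
                                               truth$cell_id)]
    inside <- lab > 0
    lab_in <- lab[inside]
    live_in <- pheno[lab_in] != "dead"
    lp <- numeric(sum(inside))
    lp[live_in] <- stain$lipid_cyto +
      stain$lipid_diffuse_slope * dvf[lab_in[live_in]]
    lipid[inside] <- lp
    droplet_pix <- phantom$refindex >= phantom$geometry$droplet_index - 1e-12 &
      inside
    lipid[droplet_pix] <- stain$lipid_droplet_amp *
      (0.4 + 1.2 * dvf[lab[droplet_pix]])
    dd <- numeric(sum(inside))
    dd[live_in] <- stain$death_live_leak
    dd[!live_in] <- stain$death_amp
    death[inside] <- dd

    for (i in seq_len(nrow(truth))) {
      sg <- if (truth$phenotype[i] == "dead") 0.6 * stain$nuclear_sigma_um
            else stain$nuclear_sigma_um
      nuclear <- add_blob(nuclear, truth$x[i], truth$y[i], sg / px,
                          stain$nuclear_amp)
    }
  }

  local_seed(seed, {
    illum <- matrix(1, nr, nc)
    if (stain$illumination_amplitude > 0) {
      illum <- 1 + poly_drift(c(nr, nc), stain$illumination_amplitude)
      illum <- pmax(illum, 0.2)
    }
    if (stain_failure) lipid <- lipid * stain$stain_failure_scale
    noise <- function(m) {
      pmax(m + matrix(stats::rnorm(nr * nc, 0, stain$noise_sd), nr, nc), 0)
    }
    nuclear <- noise(nuclear * illum)
    lipid <- noise(lipid * illum)
    death <- noise(death * illum)
    list(nuclear = nuclear, lipid = lipid, death = death, illum = illum)
  }) -> ch

  structure(
    list(nuclear = ch$nuclear, lipid = ch$lipid, death = ch$death,
         illumination = ch$illum, stain_failure = stain_failure,
         optics = optics),
    class = "fluorescence_field"
  )
}

# Additive truncated Gaussian blob (nuclear stain point spread proxy).
add_blob <- function(img, cx, cy, sigma_px, amp) {
  nr <- nrow(img); nc <- ncol(img)
  r <- ceiling(3 * sigma_px)
  x0 <- max(1L, floor(cx - r)); x1 <- min(nc, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(nr, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  img[ys, xs] <- img[ys, xs] + amp * exp(-(dx^2 + dy^2) / (2 * sigma_px^2))
  img
}
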