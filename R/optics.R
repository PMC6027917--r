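#' Optical configuration for phase imaging
#'
#' Bundles the imaging constants needed to interpret an optical path
#' difference (OPD) map: laser wavelength, lateral pixel size, field shape,
#' and the noise model applied when rendering synthetic fields. The default
#' wavelength matches the 684 nm source of a transmission digital holographic
#' microscope; the pixel sizes correspond to the 10x/0.3 NA (0.65 um/px) and
#' 20x/0.4 NA (0.325 um/px) objectives.
#'
#' @param wavelength_nm Laser wavelength in nm.
#' @param pixel_size_um Lateral size of one pixel in micrometers.
#' @param field_shape Integer vector of length 2, image rows and columns.
#' @param opd_noise_sd_nm Standard deviation of additive Gaussian OPD noise,
#'   in nm. Set to 0 for noiseless rendering.
#' @param background_drift_nm Peak amplitude of the smooth low-order
#'   polynomial background drift, in nm. Set to 0 to disable.
#' @param objective Convenience switch: `"10x"` or `"20x"` presets the pixel
#'   size; ignored when `pixel_size_um` is given explicitly.
#'
#' @return An object of class `optics_config`.
#' @export
#' @examples
#' optics_config()
#' optics_config(objective = "20x", field_shape = c(256, 256))
optics_config <- function(wavelength_nm = 684,
                          pixel_size_um = NULL,
                          field_shape = c(512L, 512L),
                          opd_noise_sd_nm = 4,
                          background_drift_nm = 8,
                          objective = c("10x", "20x")) {
  objective <- match.arg(objective)
  if (is.null(pixel_size_um)) {
    pixel_size_um <- if (objective == "10x") 0.65 else 0.325
  }
  stopif_not_scalar_num(wavelength_nm, "wavelength_nm", positive = TRUE)
  stopif_not_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  stopif_not_scalar_num(opd_noise_sd_nm, "opd_noise_sd_nm")
  if (opd_noise_sd_nm < 0) stop("'opd_noise_sd_nm' must be >= 0")
  field_shape <- as.integer(field_shape)
  if (length(field_shape) != 2L || any(field_shape < 8L)) {
    stop("'field_shape' must be two integers >= 8")
  }
  structure(
    list(
      wavelength_nm = wavelength_nm,
      pixel_size_um = pixel_size_um,
      field_shape = field_shape,
      opd_noise_sd_nm = opd_noise_sd_nm,
      background_drift_nm = background_drift_nm,
      objective = objective
    ),
    class = "optics_config"
  )
}

#' Cell geometry and refractive-index settings for the phantom generator
#'
#' Controls the morphology of the three simulated phenotypes and the
#' refractive indices that give them their OPD contrast. Defaults encode the
#' qualitative phenotype definitions used throughout the package:
#' undifferentiated cells are large and flat with cytoplasmic index only;
#' adipocytic cells are large with high-index lipid droplet inclusions; dead
#' cells are small, round, condensed caps with elevated index. Indices are
#' literature-typical: culture medium 1.337, cytoplasm 1.365, lipid droplet
#' 1.470, condensed dead-cell cytoplasm 1.390.
#'
#' @param medium_index Refractive index of the culture medium (n_m).
#' @param cytoplasm_index z-integrated intracellular index of live cytoplasm.
#' @param droplet_index Index of lipid droplet inclusions (must exceed
#'   `cytoplasm_index` to reproduce the strong droplet contrast).
#' @param dead_index Index of condensed dead cells.
#' @param live_radius_um Range (min, max) of live-cell semi-major axis, um.
#' @param live_thickness_um Range of undifferentiated peak thickness, um.
#' @param adipo_thickness_um Range of adipocytic peak thickness, um.
#' @param live_axis_ratio Range of live-cell ellipse axis ratio (>= 1).
#' @param dead_radius_um Range of dead-cell radius, um.
#' @param dead_thickness_um Range of dead-cell peak thickness, um.
#' @param droplet_radius_um Range of droplet inclusion radius, um.
#' @param droplet_area_fraction Range of per-cell droplet area fraction
#'   targeted for adipocytic cells.
#' @param min_sep_factor Minimum allowed centroid distance between two cells,
#'   as a multiple of the sum of their outer radii. Values >= 1 prevent
#'   overlap; smaller values allow cells to touch or partially occlude.
#' @param max_place_attempts Rejection-sampling attempts per cell before the
#'   separation constraint is waived (keeps dense fields possible).
#'
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(medium_index = 1.337,
                             cytoplasm_index = 1.365,
                             droplet_index = 1.470,
                             dead_index = 1.390,
                             live_radius_um = c(15, 30),
                             live_thickness_um = c(3, 6),
                             adipo_thickness_um = c(4, 6),
                             live_axis_ratio = c(1, 1.5),
                             dead_radius_um = c(4, 7),
                             dead_thickness_um = c(6, 10),
                             droplet_radius_um = c(1, 5),
                             droplet_area_fraction = c(0.25, 0.45),
                             min_sep_factor = 1.05,
                             max_place_attempts = 40L) {
  if (droplet_index <= cytoplasm_index) {
    stop("'droplet_index' must exceed 'cytoplasm_index'")
  }
  if (cytoplasm_index < medium_index || dead_index < medium_index) {
    stop("intracellular indices must be >= 'medium_index'")
  }
  structure(
    list(
      medium_index = medium_index,
      cytoplasm_index = cytoplasm_index,
      droplet_index = droplet_index,
      dead_index = dead_index,
      live_radius_um = live_radius_um,
      live_thickness_um = live_thickness_um,
      adipo_thickness_um = adipo_thickness_um,
      live_axis_ratio = live_axis_ratio,
      dead_radius_um = dead_radius_um,
      dead_thickness_um = dead_thickness_um,
      droplet_radius_um = droplet_radius_um,
      droplet_area_fraction = droplet_area_fraction,
      min_sep_factor = min_sep_factor,
      max_place_attempts = as.integer(max_place_attempts)
    ),
    class = "phantom_geometry"
  )
}

PHENOTYPES <- c("undifferentiated", "adipocytic", "dead")
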