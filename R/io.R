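# 32-bit float TIFF writers clamp samples to [0, 1]; on-disk images
# therefore use a fixed affine encoding inverted on read. The range
# [-16384, 49152] covers any OPD (nm) or intensity this package produces.
TIFF_SCALE <- 65536
TIFF_OFFSET <- 0.25

encode_tiff <- function(m) m / TIFF_SCALE + TIFF_OFFSET
decode_tiff <- function(m) (m - TIFF_OFFSET) * TIFF_SCALE

#' Write and read phase images as 32-bit float TIFF
#'
#' One single-plane float TIFF per field, OPD in nm under a fixed affine
#' on-disk encoding (documented in the source) so that negative noise
#' values survive the writer's `[0, 1]` clamp. `read_phase_tiff` inverts
#' the encoding and restores a `phase_image`.
#'
#' @param image A `phase_image`.
#' @param path Output file path (conventionally ending in `_opd.tif`).
#' @return `write_phase_tiff` returns `path` invisibly; `read_phase_tiff`
#'   returns a `phase_image`.
#' @export
write_phase_tiff <- function(image, path) {
  stopifnot(inherits(image, "phase_image"))
  tiff::writeTIFF(encode_tiff(image$opd_nm), path, bits.per.sample = 32,
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_phase_tiff
#' @param optics The [optics_config()] to attach to the restored image.
#' @export
read_phase_tiff <- function(path, optics = NULL) {
  m <- decode_tiff(tiff::readTIFF(path))
  if (is.null(optics)) {
    optics <- optics_config(field_shape = dim(m), opd_noise_sd_nm = 0,
                            background_drift_nm = 0)
  }
  structure(list(opd_nm = m, optics = optics,
                 provenance = sprintf("read from %s", path)),
            class = "phase_image")
}

#' Write and read fluorescence channels as float TIFFs
#'
#' Writes the three channels of a `fluorescence_field` next to each other
#' using the channel suffix convention `_nuc`, `_lip`, `_dead` (and `_opd`
#' for the matching phase image written separately).
#'
#' @param field A `fluorescence_field`.
#' @param prefix Path prefix; `<prefix>_nuc.tif` etc. are created.
#' @return `write_fluor_tiffs` returns the three paths invisibly;
#'   `read_fluor_tiffs` returns a `fluorescence_field` (without the
#'   generative illumination/stain metadata).
#' @export
write_fluor_tiffs <- function(field, prefix) {
  stopifnot(inherits(field, "fluorescence_field"))
  paths <- paste0(prefix, c("_nuc.tif", "_lip.tif", "_dead.tif"))
  tiff::writeTIFF(encode_tiff(field$nuclear), paths[1],
                  bits.per.sample = 32, reduce = FALSE)
  tiff::writeTIFF(encode_tiff(field$lipid), paths[2],
                  bits.per.sample = 32, reduce = FALSE)
  tiff::writeTIFF(encode_tiff(field$death), paths[3],
                  bits.per.sample = 32, reduce = FALSE)
  invisible(paths)
}

#' @rdname write_fluor_tiffs
#' @export
read_fluor_tiffs <- function(prefix) {
  nuc <- decode_tiff(tiff::readTIFF(paste0(prefix, "_nuc.tif")))
  lip <- decode_tiff(tiff::readTIFF(paste0(prefix, "_lip.tif")))
  dea <- decode_tiff(tiff::readTIFF(paste0(prefix, "_dead.tif")))
  structure(list(nuclear = nuc, lipid = lip, death = dea,
                 illumination = NULL, stain_failure = NA, optics = NULL),
            class = "fluorescence_field")
}

#' Serializable run configuration
#'
#' Bundles every tunable of a pipeline run (seed, optics, generator,
#' segmentation and rule thresholds) into one JSON-serializable object so
#' a run's configuration can be embedded in its outputs and replayed.
#'
#' @param seed Integer master seed.
#' @param optics,geometry,stain,timecourse,dr Component settings.
#' @param offset_sd,rules,ethd_cutoff Quantification thresholds.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, optics = optics_config(),
                       geometry = phantom_geometry(),
                       stain = stain_config(),
                       timecourse = timecourse_config(),
                       dr = dr_config(),
                       offset_sd = 3, rules = rule_thresholds(),
                       ethd_cutoff = 50) {
  structure(list(schema_version = 1L, seed = as.integer(seed),
                 optics = optics, geometry = geometry, stain = stain,
                 timecourse = timecourse, dr = dr, offset_sd = offset_sd,
                 rules = rules, ethd_cutoff = ethd_cutoff),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(strip_classes(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dr_optics <- do.call(optics_config,
                       raw$dr$optics[setdiff(names(raw$dr$optics),
                                             "objective")])
  run_config(
    seed = raw$seed,
    optics = do.call(optics_config,
                     raw$optics[setdiff(names(raw$optics), "objective")]),
    geometry = do.call(phantom_geometry, raw$geometry),
    stain = do.call(stain_config, raw$stain),
    timecourse = do.call(timecourse_config, raw$timecourse),
    dr = run_config_dr(raw$dr, dr_optics),
    offset_sd = raw$offset_sd,
    rules = do.call(rule_thresholds, raw$rules),
    ethd_cutoff = raw$ethd_cutoff
  )
}

run_config_dr <- function(raw_dr, optics) {
  dr_config(cells_per_field = raw_dr$cells_per_field,
            noise_frac = raw_dr$noise_frac,
            base_dead = raw_dr$base_dead,
            optics = optics,
            geometry = do.call(phantom_geometry, raw_dr$geometry))
}

#' Write and read result tables as CSV
#'
#' Thin wrappers that keep the write-read round trip exact for the
#' package's table schemas.
#'
#' @param df Data frame.
#' @param path CSV path.
#' @return `write_table_csv` returns `path` invisibly; `read_table_csv`
#'   the data frame.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
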