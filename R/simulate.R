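#' Time-course simulation settings
#'
#' Conditions of the simulated six-day differentiation experiment: induced
#' wells follow a saturating adipocytic-fraction curve
#' `f(day) = baseline + (plateau - baseline) * (1 - exp(-rate * (day - 1)))`
#' that starts at the spontaneous baseline on day 1 and plateaus around day
#' 4-5; non-induced wells stay at the baseline. Around 5% of cells
#' differentiate spontaneously without induction, which sets the default
#' baseline.
#'
#' @param days Number of simulated days.
#' @param baseline_fraction Spontaneous adipocytic fraction.
#' @param plateau_fraction Induced plateau adipocytic fraction.
#' @param rate_per_day Saturation rate of the induced curve.
#' @param dead_fraction Background dead-cell fraction per well.
#' @param cells_per_field Mean number of cells per imaging field.
#' @param n_fields Imaging fields per well (four images per well).
#' @param well_sd_fraction Well-to-well SD added to the expected adipocytic
#'   fraction (biological variability).
#' @param wells_per_arm Wells per treatment arm in [run_timecourse()].
#' @return An object of class `timecourse_config`.
#' @export
timecourse_config <- function(days = 6,
                              baseline_fraction = 0.05,
                              plateau_fraction = 0.70,
                              rate_per_day = 0.8,
                              dead_fraction = 0.02,
                              cells_per_field = 30,
                              n_fields = 4,
                              well_sd_fraction = 0.02,
                              wells_per_arm = 6) {
  structure(as.list(environment()), class = "timecourse_config")
}

#' Expected adipocytic fraction over a differentiation time course
#'
#' @param day Day index (1-based) vector.
#' @param induced Logical; induced wells follow the saturating curve,
#'   non-induced wells stay at the baseline.
#' @param config A [timecourse_config()].
#' @return Numeric vector of expected adipocytic fractions.
#' @export
adipocytic_fraction_curve <- function(day, induced, config = timecourse_config()) {
  base <- config$baseline_fraction
  if (!induced) return(rep(base, length(day)))
  base + (config$plateau_fraction - base) *
    (1 - exp(-config$rate_per_day * (pmax(day, 1) - 1)))
}

#' Simulate one well of a differentiation time course
#'
#' Generates, for each day, `config$n_fields` phantom fields whose phenotype
#' mix follows the expected adipocytic fraction for the arm, renders their
#' phase images and (optionally) fluorescence channels, and records the
#' per-day truth.
#'
#' @param days Number of days (>= 1).
#' @param induced Logical treatment arm flag.
#' @param config A [timecourse_config()].
#' @param optics,geometry,stain Imaging, phantom and stain settings.
#' @param seed Integer seed; output is bitwise-reproducible given it.
#' @param render_fluor If `FALSE`, skip fluorescence channels (faster).
#' @param keep_phantoms If `TRUE`, retain the phantom objects (memory-heavy).
#'
#' @return List with `truth` (data frame: `day`, `expected_fraction`,
#'   `well_fraction`, `n_cells`, `n_adipocytic`, `n_dead`) and `days`, a list
#'   whose element `d` holds the list of fields for that day; each field is a
#'   list with `phase`, `fluor` (or `NULL`), and optionally `phantom`.
#' @export
simulate_timecourse <- function(days = 6, induced = TRUE,
                                config = timecourse_config(),
                                optics = optics_config(),
                                geometry = phantom_geometry(),
                                stain = stain_config(),
                                seed = 1L,
                                render_fluor = TRUE,
                                keep_phantoms = FALSE) {
  if (days < 1) stop("'days' must be >= 1")
  out_days <- vector("list", days)
  truth <- vector("list", days)
  for (d in seq_len(days)) {
    f_exp <- adipocytic_fraction_curve(d, induced, config)
    sd_day <- sub_seed(seed, d)
    f_well <- local_seed(sd_day, {
      min(max(f_exp + stats::rnorm(1, 0, config$well_sd_fraction), 0), 1)
    })
    dead <- config$dead_fraction
    mix <- c(undifferentiated = (1 - f_well) * (1 - dead),
             adipocytic = f_well * (1 - dead),
             dead = dead)
    fields <- vector("list", config$n_fields)
    n_tot <- n_adip <- n_dead <- 0L
    for (k in seq_len(config$n_fields)) {
      ph <- make_phantom_field(config$cells_per_field, mix,
                               geometry = geometry, optics = optics,
                               seed = sub_seed(sd_day, k),
                               sample_mix = TRUE)
      tc <- ph$truth_cells
      n_tot <- n_tot + nrow(tc)
      n_adip <- n_adip + sum(tc$phenotype == "adipocytic")
      n_dead <- n_dead + sum(tc$phenotype == "dead")
      fields[[k]] <- list(
        phase = render_phase_image(ph),
        fluor = if (render_fluor) render_fluor_channels(ph, stain) else NULL,
        phantom = if (keep_phantoms) ph else NULL
      )
    }
    out_days[[d]] <- fields
    truth[[d]] <- data.frame(day = d, expected_fraction = f_exp,
                             well_fraction = f_well, n_cells = n_tot,
                             n_adipocytic = n_adip, n_dead = n_dead)
  }
  list(truth = do.call(rbind, truth), days = out_days,
       induced = induced, seed = as.integer(seed))
}

#' Reference PPARgamma modulator panel
#'
#' The six-compound truth set used by the dose-response simulations: three
#' PPARgamma antagonists tested on induced wells and three agonists tested on
#' non-induced wells, with generating potencies set to the established
#' half-maximal concentrations of each compound (T0070907 1.49 uM, GW9662
#' 4.49 uM, BADGE beyond the tested range, rosiglitazone 19.5 nM,
#' pioglitazone 1.23 uM, indomethacin 2.77 uM). Antagonists become toxic
#' above 10 uM; the BADGE truth midpoint (250 uM) lies beyond the 100 uM top
#' concentration so its fits are expected to censor.
#'
#' @return A `response_model` data frame with columns `compound`,
#'   `direction`, `true_ec50_m`, `hill_slope`, `baseline_fraction`,
#'   `max_fraction`, `toxicity_threshold_m`.
#' @export
pparg_reference_compounds <- function() {
  response_model(data.frame(
    compound = c("T0070907", "GW9662", "BADGE",
                 "rosiglitazone", "pioglitazone", "indomethacin"),
    direction = c("antagonist", "antagonist", "antagonist",
                  "agonist", "agonist", "agonist"),
    true_ec50_m = c(1.49e-6, 4.49e-6, 2.5e-4, 19.5e-9, 1.23e-6, 2.77e-6),
    hill_slope = 1,
    baseline_fraction = 0.05,
    max_fraction = c(0.70, 0.70, 0.70, 0.85, 0.85, 0.85),
    toxicity_threshold_m = c(1e-5, 1e-5, 1e-5, Inf, Inf, Inf),
    stringsAsFactors = FALSE
  ))
}

#' Validate a compound response model table
#'
#' @param df Data frame with one row per compound; see
#'   [pparg_reference_compounds()] for the columns.
#' @return The validated data frame with class `response_model`.
#' @export
response_model <- function(df) {
  need <- c("compound", "direction", "true_ec50_m", "hill_slope",
            "baseline_fraction", "max_fraction", "toxicity_threshold_m")
  if (!all(need %in% names(df))) {
    stop("response model needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$true_ec50_m <= 0)) stop("true_ec50_m must be > 0")
  if (!all(df$direction %in% c("agonist", "antagonist"))) {
    stop("direction must be 'agonist' or 'antagonist'")
  }
  if (any(df$baseline_fraction < 0 | df$baseline_fraction > df$max_fraction |
          df$max_fraction > 1)) {
    stop("need 0 <= baseline_fraction <= max_fraction <= 1")
  }
  class(df) <- c("response_model", "data.frame")
  df
}

#' Standard 14-point dose series
#'
#' Geometric series of 14 concentrations spanning 100 uM down to 4.6 nM
#' (the dilution ratio is fixed by the endpoints).
#'
#' @param n Number of concentrations.
#' @param max_m,min_m Top and bottom concentrations in molar.
#' @return Decreasing numeric vector of molar concentrations.
#' @export
dose_concentrations <- function(n = 14, max_m = 1e-4, min_m = 4.6e-9) {
  exp(seq(log(max_m), log(min_m), length.out = n))
}

#' Build a dose-response plate layout
#'
#' One well row per compound x concentration x replicate. Antagonists are
#' plated with the differentiation cocktail (induced), agonists without.
#'
#' @param model A [response_model()] table.
#' @param concentrations Molar dose series, default [dose_concentrations()].
#' @param replicates Wells per concentration.
#' @param n_fields Imaging fields per well.
#' @return Data frame of class `plate_layout` with columns `well_id`,
#'   `compound`, `concentration_m`, `induced`, `n_fields`.
#' @export
dose_response_layout <- function(model = pparg_reference_compounds(),
                                 concentrations = dose_concentrations(),
                                 replicates = 4, n_fields = 4) {
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  rows <- list()
  for (i in seq_len(nrow(model))) {
    for (ci in seq_along(concentrations)) {
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          well_id = sprintf("%s_c%02d_r%d", model$compound[i], ci, r),
          compound = model$compound[i],
          concentration_m = concentrations[ci],
          induced = model$direction[i] == "antagonist",
          n_fields = n_fields,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(well_id = character(0), compound = character(0),
               concentration_m = numeric(0), induced = logical(0),
               n_fields = integer(0), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$well_id)) stop("well_ids must be unique")
  class(out) <- c("plate_layout", "data.frame")
  out
}

#' Expected adipocytic fraction under a compound dose
#'
#' Hill curve in concentration: agonists rise from the spontaneous baseline
#' toward `max_fraction`; antagonists fall from the induced plateau
#' (`max_fraction`) back toward the baseline. At the midpoint concentration
#' the expected fraction is exactly halfway between baseline and plateau.
#'
#' @param model_row One row of a [response_model()].
#' @param conc_m Molar concentration vector.
#' @return Expected adipocytic fraction(s).
#' @export
expected_dose_fraction <- function(model_row, conc_m) {
  h <- model_row$hill_slope
  occ <- conc_m^h / (conc_m^h + model_row$true_ec50_m^h)
  base <- model_row$baseline_fraction
  top <- model_row$max_fraction
  if (model_row$direction == "agonist") base + (top - base) * occ
  else top - (top - base) * occ
}

#' Expected dead-cell fraction under a compound dose
#'
#' Background dead fraction plus a toxicity term that grows with the log of
#' the concentration above the compound's toxicity threshold.
#'
#' @param model_row One row of a [response_model()].
#' @param conc_m Molar concentration vector.
#' @param base_dead Background dead fraction.
#' @return Expected dead fraction(s), capped at 0.6.
#' @export
expected_dead_fraction <- function(model_row, conc_m, base_dead = 0.02) {
  extra <- ifelse(conc_m > model_row$toxicity_threshold_m,
                  0.25 * log10(conc_m / model_row$toxicity_threshold_m), 0)
  pmin(base_dead + extra, 0.6)
}

#' Dose-response simulation settings
#'
#' Desk-scale imaging settings for plate simulations: a reduced 256x256 px
#' field with ~9 cells (about 40% confluence, as in the full-size fields)
#' keeps whole-plate simulation tractable while preserving the pooled-OPD
#' readout; the response noise SD is 5% of the dynamic range of the
#' expected adipocytic fraction, applied at the well level before per-field
#' multinomial sampling.
#'
#' @param cells_per_field Cells per simulated field.
#' @param noise_frac Well-level Gaussian noise SD as a fraction of the
#'   compound's dynamic range (`max_fraction - baseline_fraction`).
#' @param base_dead Background dead fraction.
#' @param optics,geometry Imaging and phantom settings for plate fields.
#' @return An object of class `dr_config`.
#' @export
dr_config <- function(cells_per_field = 9,
                      noise_frac = 0.05,
                      base_dead = 0.02,
                      optics = optics_config(field_shape = c(256L, 256L)),
                      geometry = phantom_geometry()) {
  structure(as.list(environment()), class = "dr_config")
}

# Simulate and return the rendered phase fields for a single well.
simulate_dr_well <- function(model_row, conc_m, n_fields, config, seed) {
  f_exp <- expected_dose_fraction(model_row, conc_m)
  d_exp <- expected_dead_fraction(model_row, conc_m, config$base_dead)
  span <- model_row$max_fraction - model_row$baseline_fraction
  f_real <- local_seed(seed, {
    min(max(f_exp + stats::rnorm(1, 0, config$noise_frac * span), 0), 1)
  })
  mix <- c(undifferentiated = (1 - f_real) * (1 - d_exp),
           adipocytic = f_real * (1 - d_exp),
           dead = d_exp)
  fields <- lapply(seq_len(n_fields), function(k) {
    ph <- make_phantom_field(config$cells_per_field, mix,
                             geometry = config$geometry,
                             optics = config$optics,
                             seed = sub_seed(seed, k), sample_mix = TRUE)
    list(phase = render_phase_image(ph), phantom = ph)
  })
  list(fields = fields,
       truth = data.frame(expected_fraction = f_exp,
                          realized_fraction = f_real,
                          expected_dead = d_exp))
}

#' Simulate a full dose-response plate
#'
#' For every well of the layout, draws the well-level realized adipocytic
#' fraction from the compound's Hill curve plus Gaussian response noise,
#' adds toxicity-driven dead cells above the compound's toxicity threshold,
#' and renders the phase fields.
#'
#' @param layout A [dose_response_layout()].
#' @param model A [response_model()] covering every compound in the layout.
#' @param config A [dr_config()].
#' @param seed Integer seed.
#' @param keep_images If `FALSE`, only the truth table is returned (the
#'   streaming quantification in [run_dose_response()] regenerates wells on
#'   the fly instead).
#'
#' @return List with `truth` (one row per well: layout columns plus
#'   `expected_fraction`, `realized_fraction`, `expected_dead`) and `wells`
#'   (named list of per-well field lists, or `NULL`).
#' @export
simulate_dose_response_plate <- function(layout, model, config = dr_config(),
                                         seed = 1L, keep_images = TRUE) {
  missing <- setdiff(layout$compound, model$compound)
  if (length(missing)) {
    stop("compounds missing from response model: ",
         paste(missing, collapse = ", "))
  }
  wells <- if (keep_images) vector("list", nrow(layout)) else NULL
  truth <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    mr <- model[model$compound == layout$compound[i], , drop = FALSE]
    sim <- simulate_dr_well(mr, layout$concentration_m[i],
                            layout$n_fields[i], config, sub_seed(seed, i))
    truth[[i]] <- cbind(layout[i, , drop = FALSE], sim$truth,
                        row.names = NULL)
    if (keep_images) wells[[i]] <- sim$fields
  }
  truth <- do.call(rbind, truth)
  if (keep_images) names(wells) <- layout$well_id
  list(truth = truth, wells = wells)
}
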