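#' Quantify one well from its phase fields
#'
#' Runs the phase chain on each field of a well: robust fixed-threshold
#' segmentation, pooled mean OPD, border-excluded cell count, feature
#' extraction and rule-based phenotyping; then aggregates fields into a
#' well measurement.
#'
#' @param fields List of `phase_image` objects (the well's imaging fields).
#' @param offset_sd Segmentation threshold offset (robust SD units).
#' @param rules A [rule_thresholds()] for phenotyping.
#' @param well_id Carried into the result.
#' @return List with `well` (a [aggregate_well()] result), `dead_fraction`
#'   (pooled over fields), `counts` (per-phenotype totals), and `records`
#'   (per-cell data frame with a `field` column).
#' @export
quantify_phase_well <- function(fields, offset_sd = 3,
                                rules = rule_thresholds(), well_id = NA) {
  opds <- numeric(length(fields))
  counts <- integer(length(fields))
  recs <- vector("list", length(fields))
  for (k in seq_along(fields)) {
    img <- fields[[k]]
    m <- fixed_threshold_segment(img, offset_sd = offset_sd)
    opds[k] <- mean_opd(img, m)
    counts[k] <- count_cells(m)
    r <- classify_cells_rules(extract_cell_features(img, m), rules)
    if (nrow(r)) r$field <- k
    recs[[k]] <- r
  }
  records <- do.call(rbind, recs)
  ph_counts <- table(factor(records$phenotype,
                            levels = c(PHENOTYPES, "error")))
  list(well = aggregate_well(opds, counts, well_id = well_id),
       dead_fraction = dead_fraction(records),
       counts = stats::setNames(as.integer(ph_counts), names(ph_counts)),
       records = records)
}

#' Run the differentiation time-course experiment end to end
#'
#' Simulates induced and non-induced wells over the configured number of
#' days (four fields per well), quantifies each day's phase images (well
#' mean OPD, rule-based dead fraction) and, optionally, the fluorescence
#' branch (illumination-corrected nucleus-anchored lipid readout and Nile
#' Red droplet median), then computes the per-day Z-prime between arms and
#' the correlation between the phase and fluorescence lipid readouts.
#'
#' @param config A [timecourse_config()].
#' @param optics,geometry,stain Imaging settings.
#' @param seed Integer seed; the whole run is reproducible given it.
#' @param fluor If `FALSE`, skip the fluorescence branch (faster).
#' @param rules,offset_sd Quantification settings.
#' @param nile_red_failure_day Optional day index on which the Nile Red
#'   stain is rendered as failed in every well (emulates a failed staining
#'   round); `NA` disables it.
#' @return List with `wells` (data frame: one row per well x day),
#'   `zprime_by_day` (data frame `day`, `z_prime`), `correlations` (list
#'   with OLS summaries of lipid and Nile Red readouts against OPD), and
#'   the `config` used.
#' @export
run_timecourse <- function(config = timecourse_config(),
                           optics = optics_config(),
                           geometry = phantom_geometry(),
                           stain = stain_config(),
                           seed = 1L, fluor = TRUE,
                           rules = rule_thresholds(), offset_sd = 3,
                           nile_red_failure_day = NA) {
  rows <- list()
  arms <- c(induced = TRUE, non_induced = FALSE)
  for (arm_i in seq_along(arms)) {
    for (w in seq_len(config$wells_per_arm)) {
      wseed <- sub_seed(seed, arm_i * 1000L + w)
      sim <- simulate_timecourse(config$days, arms[arm_i], config,
                                 optics, geometry, stain, seed = wseed,
                                 render_fluor = fluor)
      for (d in seq_len(config$days)) {
        fields <- sim$days[[d]]
        q <- quantify_phase_well(lapply(fields, `[[`, "phase"),
                                 offset_sd = offset_sd, rules = rules,
                                 well_id = sprintf("%s_w%d",
                                                   names(arms)[arm_i], w))
        lipid_med <- nile_med <- NA_real_
        if (fluor) {
          lv <- nv <- numeric(0)
          for (k in seq_along(fields)) {
            fl <- fields[[k]]$fluor
            failed <- identical(d, as.integer(nile_red_failure_day))
            lip <- if (failed) {
              fl$lipid * stain$stain_failure_scale
            } else fl$lipid
            nucc <- correct_illumination(fl$nuclear,
                                         pixel_size_um = optics$pixel_size_um)
            lipc <- correct_illumination(lip + 1,
                                         pixel_size_um = optics$pixel_size_um)
            nuclei <- detect_nuclei(nucc, optics$pixel_size_um)
            lr <- lipid_intensity_per_nucleus(lipc, nuclei,
                                              pixel_size_um =
                                                optics$pixel_size_um)
            lv <- c(lv, lr$field_median)
            nr <- nile_red_quant(lipc, optics$pixel_size_um)
            nv <- c(nv, if (nr$flagged) NA_real_ else nr$value)
          }
          lipid_med <- mean(lv, na.rm = TRUE)
          nile_med <- if (all(is.na(nv))) NA_real_ else mean(nv, na.rm = TRUE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          arm = names(arms)[arm_i], well = w, day = d,
          mean_opd_nm = q$well$mean_opd,
          cell_count = q$well$cell_count,
          dead_fraction_dhm = as.numeric(q$dead_fraction),
          lipid_median = lipid_med,
          nile_red_median = nile_med,
          truth_fraction = sim$truth$well_fraction[d],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  wells <- do.call(rbind, rows)

  zp <- do.call(rbind, lapply(seq_len(config$days), function(d) {
    p <- wells$mean_opd_nm[wells$arm == "induced" & wells$day == d]
    n <- wells$mean_opd_nm[wells$arm == "non_induced" & wells$day == d]
    z <- zprime(p, n)
    data.frame(day = d, z_prime = z$z_prime, mean_induced = z$mean_pos,
               mean_non_induced = z$mean_neg)
  }))

  correlations <- NULL
  if (fluor) {
    ok <- is.finite(wells$lipid_median)
    correlations <- list(
      lipidtox = linear_fit_r2(wells$mean_opd_nm[ok], wells$lipid_median[ok])
    )
    okn <- is.finite(wells$nile_red_median)
    if (sum(okn) >= 3) {
      correlations$nile_red <- linear_fit_r2(wells$mean_opd_nm[okn],
                                             wells$nile_red_median[okn])
    }
  }

  list(wells = wells, zprime_by_day = zp, correlations = correlations,
       config = config, seed = as.integer(seed))
}

#' Run a dose-response plate end to end
#'
#' Streams through the plate layout well by well (simulate, segment,
#' quantify, classify, discard images), then fits a four-parameter logistic
#' to each compound's well responses (mean OPD in nm against molar
#' concentration). Compounds with fewer than four distinct concentrations
#' are skipped with a warning. Per-well QC columns carry the rule-based
#' dead fraction and the number of contributing fields.
#'
#' @param layout A [dose_response_layout()] (may be empty).
#' @param model A [response_model()] covering the layout's compounds.
#' @param config A [dr_config()].
#' @param seed Integer seed.
#' @param rules,offset_sd Quantification settings.
#' @return List with `wells` (per-well quantification and truth), `fits`
#'   (one row per fitted compound), and the `config` used.
#' @export
run_dose_response <- function(layout, model, config = dr_config(),
                              seed = 1L, rules = rule_thresholds(),
                              offset_sd = 3) {
  if (nrow(layout) == 0) {
    return(list(wells = data.frame(), fits = data.frame(), config = config))
  }
  missing <- setdiff(layout$compound, model$compound)
  if (length(missing)) {
    stop("compounds missing from response model: ",
         paste(missing, collapse = ", "))
  }
  rows <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    mr <- model[model$compound == layout$compound[i], , drop = FALSE]
    sim <- simulate_dr_well(mr, layout$concentration_m[i],
                            layout$n_fields[i], config, sub_seed(seed, i))
    q <- quantify_phase_well(lapply(sim$fields, `[[`, "phase"),
                             offset_sd = offset_sd, rules = rules,
                             well_id = layout$well_id[i])
    rows[[i]] <- data.frame(
      well_id = layout$well_id[i], compound = layout$compound[i],
      concentration_m = layout$concentration_m[i],
      mean_opd_nm = q$well$mean_opd,
      cell_count = q$well$cell_count,
      dead_fraction = as.numeric(q$dead_fraction),
      n_fields_used = q$well$n_fields_used,
      truth_fraction = sim$truth$realized_fraction,
      truth_dead = sim$truth$expected_dead,
      stringsAsFactors = FALSE
    )
  }
  wells <- do.call(rbind, rows)

  fits <- list()
  for (cmp in unique(wells$compound)) {
    wc <- wells[wells$compound == cmp & is.finite(wells$mean_opd_nm), ]
    if (length(unique(wc$concentration_m)) < 4L) {
      warning(sprintf("compound %s has < 4 concentrations; skipped", cmp))
      next
    }
    f <- fit_4pl(wc$concentration_m, wc$mean_opd_nm)
    fits[[length(fits) + 1L]] <- data.frame(
      compound = cmp, direction = f$direction, top = f$top,
      bottom = f$bottom, hill_slope = f$hill_slope, ic50_m = f$ic50_m,
      ic50_label = f$ic50_label, r_squared = f$r_squared,
      censored = f$censored, converged = f$converged,
      n_points = f$n_points, stringsAsFactors = FALSE
    )
  }
  fits <- if (length(fits)) do.call(rbind, fits) else data.frame()
  list(wells = wells, fits = fits, config = config, seed = as.integer(seed))
}

#' Monte-Carlo IC50 parameter-recovery study
#'
#' Repeats the full simulate-segment-quantify-fit chain `n_reps` times for
#' one compound and tabulates estimated against generating potencies. Each
#' replicate uses the standard 14-point dose series with the given number
#' of replicate wells per concentration.
#'
#' @param model_row One-row [response_model()] (or a row index into one).
#' @param n_reps Number of independent simulated experiments.
#' @param seed Integer seed.
#' @param config A [dr_config()]; `noise_frac` can be overridden.
#' @param noise_frac Optional override of the well-level response noise.
#' @param concentrations Dose series, default [dose_concentrations()].
#' @param replicates Wells per concentration.
#' @return List with `table` (per-rep `true_ec50_m`, `est_ic50_m`,
#'   `censored`) and `summary` (median estimate, bias, RMSE on log10
#'   scale, fraction censored).
#' @export
recovery_study <- function(model_row, n_reps = 20, seed = 1L,
                           config = dr_config(), noise_frac = NULL,
                           concentrations = dose_concentrations(),
                           replicates = 4) {
  stopifnot(n_reps >= 1)
  if (!is.null(noise_frac)) config$noise_frac <- noise_frac
  model <- response_model(as.data.frame(model_row))
  layout <- dose_response_layout(model, concentrations,
                                 replicates = replicates)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    res <- run_dose_response(layout, model, config,
                             seed = sub_seed(seed, 37L + r))
    f <- res$fits[1, ]
    out[[r]] <- data.frame(rep = r, true_ec50_m = model$true_ec50_m,
                           est_ic50_m = f$ic50_m, censored = f$censored,
                           r_squared = f$r_squared)
  }
  tab <- do.call(rbind, out)
  est <- tab$est_ic50_m[!tab$censored & is.finite(tab$est_ic50_m)]
  summary <- list(
    median_est_m = stats::median(est),
    true_m = model$true_ec50_m,
    log10_bias = mean(log10(est)) - log10(model$true_ec50_m),
    log10_rmse = sqrt(mean((log10(est) - log10(model$true_ec50_m))^2)),
    frac_censored = mean(tab$censored)
  )
  list(table = tab, summary = summary)
}
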