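#' Z-prime screening-window coefficient
#'
#' `Z' = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|`. Values above
#' 0.5 indicate an excellent assay window; negative values indicate
#' overlapping control distributions.
#'
#' @param pos_values,neg_values Numeric vectors (>= 2 values each) of
#'   positive- and negative-control measurements.
#' @return An object of class `zprime_result`: `mean_pos`, `sd_pos`,
#'   `mean_neg`, `sd_neg`, `z_prime` (always <= 1; `NaN` with a `flagged`
#'   element when the arm means coincide).
#' @export
zprime <- function(pos_values, neg_values) {
  if (length(pos_values) < 2L || length(neg_values) < 2L) {
    stop("need >= 2 values per arm")
  }
  mp <- mean(pos_values); mn <- mean(neg_values)
  sp <- stats::sd(pos_values); sn <- stats::sd(neg_values)
  flagged <- mp == mn
  z <- if (flagged) NaN else 1 - 3 * (sp + sn) / abs(mp - mn)
  structure(list(mean_pos = mp, sd_pos = sp, mean_neg = mn, sd_neg = sn,
                 z_prime = z, flagged = flagged),
            class = "zprime_result")
}

#' @export
print.zprime_result <- function(x, ...) {
  cat(sprintf("Z' = %.3f  (pos %.3g +/- %.3g, neg %.3g +/- %.3g)\n",
              x$z_prime, x$mean_pos, x$sd_pos, x$mean_neg, x$sd_neg))
  invisible(x)
}

#' Ordinary least squares fit with R-squared
#'
#' Simple linear regression `y ~ x` with `R^2 = 1 - SS_res / SS_tot` and a
#' two-sided t test on the slope.
#'
#' @param x,y Numeric vectors (>= 3 points; `x` must vary).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
linear_fit_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 finite points")
  if (stats::sd(x) == 0) stop("'x' must not be constant")
  if (stats::sd(y) == 0) {
    # no variance to explain: slope 0, R^2 defined as 0
    return(list(slope = 0, intercept = y[1], r_squared = 0, p_value = 1,
                n = length(x)))
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       n = length(x))
}

#' Predict from four-parameter logistic parameters
#'
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (log10(x) - log10(ic50))))`.
#' With `hill > 0` the curve decreases with concentration (antagonist
#' orientation); `hill < 0` increases (agonist orientation).
#'
#' @param conc Molar concentration vector.
#' @param top,bottom,hill,log10_ic50 4PL parameters.
#' @return Predicted responses.
#' @export
predict_4pl <- function(conc, top, bottom, hill, log10_ic50) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - log10_ic50)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Bounded least squares in log10 concentration (Levenberg-Marquardt via
#' \pkg{minpack.lm}), multi-started from three deterministic
#' initializations of the midpoint (lower quartile, median, upper quartile
#' of the tested log-concentration range) with the hill sign chosen from
#' the empirical top-vs-bottom trend; the best-SSE fit wins. The reported
#' parameters are canonicalized to `top >= bottom` (the 4PL family is
#' symmetric under swapping asymptotes and negating the hill), so `top` is
#' the larger asymptote and a positive hill means response falls with
#' concentration. The fit is censored when the fitted midpoint lies
#' outside the tested concentration range — above it ("> max tested",
#' including the flat-curve case where the fitted dynamic range is
#' indistinguishable from noise) or below it ("< min tested", a curve
#' claimed to saturate before the lowest dose); a censored IC50 is
#' returned as `NA` with `ic50_label` carrying the inequality statement.
#'
#' @param concentrations Molar concentrations (>= 4 distinct values).
#' @param responses Finite responses, same length.
#' @param flat_sd_mult Flatness rule: censor when
#'   `|top - bottom| < flat_sd_mult * residual SD`.
#' @return An object of class `dose_response_fit`: `top`, `bottom`,
#'   `hill_slope`, `ic50_m`, `ic50_label`, `log10_ic50`, `r_squared`,
#'   `censored`, `converged`, `n_points`, `direction`, `message`.
#' @export
fit_4pl <- function(concentrations, responses, flat_sd_mult = 2) {
  if (length(concentrations) != length(responses)) {
    stop("lengths differ")
  }
  ok <- is.finite(concentrations) & is.finite(responses) & concentrations > 0
  x <- concentrations[ok]; y <- responses[ok]
  if (length(unique(x)) < 4L) stop("need >= 4 distinct concentrations")
  L <- log10(x)
  lo <- min(L); hi <- max(L)

  # empirical orientation: hill > 0 when response falls with concentration
  y_lo <- mean(y[L <= stats::quantile(L, 0.25)])
  y_hi <- mean(y[L >= stats::quantile(L, 0.75)])
  hill0 <- if (y_hi < y_lo) 1 else -1
  starts <- lapply(stats::quantile(L, c(0.25, 0.5, 0.75)), function(m0) {
    c(top = max(y), bottom = min(y), hill = hill0, m = unname(m0))
  })

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(hill * (L - m))),
        start = as.list(st),
        lower = c(top = -Inf, bottom = -Inf, hill = -10, m = lo - 3),
        upper = c(top = Inf, bottom = Inf, hill = 10, m = hi + 3),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }

  if (is.null(best)) {
    return(structure(
      list(top = NA_real_, bottom = NA_real_, hill_slope = NA_real_,
           ic50_m = NA_real_, ic50_label = NA_character_,
           log10_ic50 = NA_real_, r_squared = NA_real_, censored = FALSE,
           converged = FALSE, n_points = length(y), direction = NA_character_,
           message = "optimizer failed from all starts"),
      class = "dose_response_fit"))
  }

  cf <- stats::coef(best$fit)
  # canonical orientation: (top, bottom, hill) and (bottom, top, -hill)
  # describe the same curve; report with top >= bottom
  if (cf["top"] < cf["bottom"]) {
    tmp <- cf["top"]; cf["top"] <- cf["bottom"]; cf["bottom"] <- tmp
    cf["hill"] <- -cf["hill"]
  }
  rss <- best$sse
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  resid_sd <- sqrt(rss / max(1, length(y) - 4))
  span <- abs(cf["top"] - cf["bottom"])
  flat <- unname(span < flat_sd_mult * resid_sd)
  above <- unname(cf["m"] > hi)
  below <- !flat && !above && unname(cf["m"] < lo)
  censored <- flat || above || below
  direction <- if (unname(cf["hill"]) >= 0) "antagonist" else "agonist"

  label <- if (flat || above) sprintf("> %.3g M", max(x))
           else if (below) sprintf("< %.3g M", min(x))
           else sprintf("%.3g M", unname(10^cf["m"]))
  structure(
    list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
         hill_slope = unname(cf["hill"]),
         ic50_m = if (censored) NA_real_ else unname(10^cf["m"]),
         ic50_label = label,
         log10_ic50 = unname(cf["m"]),
         r_squared = r2, censored = censored, converged = TRUE,
         n_points = length(y), direction = direction,
         message = if (flat) "flat response within noise"
                   else if (above) "midpoint beyond tested range"
                   else if (below) "midpoint below tested range"
                   else NA_character_),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit (%s, n=%d): IC50 %s, hill %.2f, top %.3g, bottom %.3g, R2 %.3f%s\n",
    x$direction, x$n_points, x$ic50_label, x$hill_slope, x$top, x$bottom,
    x$r_squared, if (x$censored) " [censored]" else ""))
  invisible(x)
}
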