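#' Isotope-dilution calibration curve
#'
#' Ordinary least-squares line of the analyte/internal-standard response
#' ratio on known concentration, as used for extracellular glucose and
#' lactate quantitation with stable-isotope-labeled analogs as internal
#' standards.
#'
#' @param points Data frame with columns `concentration` and
#'   `response_ratio` (>= 3 distinct concentrations; duplicate
#'   concentrations are allowed and enter the fit).
#' @param analyte Analyte name carried for labeling.
#' @return Object of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared` and `conc_range`.
#' @export
fit_calibration <- function(points, analyte = NA_character_) {
  if (!is.data.frame(points) ||
      !all(c("concentration", "response_ratio") %in% names(points))) {
    abort("points must have columns concentration and response_ratio",
          class = "ppptrace_calibration_error")
  }
  conc <- points$concentration
  ratio <- points$response_ratio
  if (length(unique(conc)) < 3L) {
    abort("calibration needs at least 3 distinct concentrations",
          class = "ppptrace_calibration_error")
  }
  fit <- lm(ratio ~ conc)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((ratio - mean(ratio))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    abort("calibration slope must be positive",
          class = "ppptrace_calibration_error")
  }
  structure(
    list(analyte = analyte, slope = slope,
         intercept = unname(coef(fit)[1]), r_squared = r2,
         conc_range = range(conc)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s: ratio = %.5g * conc + %.5g, R^2 = %.5f, range [%g, %g]\n",
    x$analyte, x$slope, x$intercept, x$r_squared,
    x$conc_range[1], x$conc_range[2]))
  invisible(x)
}

#' Quantify a response ratio against a calibration curve
#'
#' Inverts the calibration line: concentration =
#' (ratio - intercept) / slope. Ratios outside the calibrated range trigger
#' an extrapolation warning; negative computed concentrations floor at 0
#' with a warning (evaporation/matrix effects), rather than erroring.
#'
#' @param ratio Numeric vector of response ratios.
#' @param curve A [fit_calibration()] result.
#' @return Numeric vector of concentrations in the calibration's units.
#' @export
quantify <- function(ratio, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (ratio - curve$intercept) / curve$slope
  if (any(conc < curve$conc_range[1] - 1e-12) ||
      any(conc > curve$conc_range[2] + 1e-12)) {
    warn("quantified concentration outside the calibrated range (extrapolation)")
  }
  if (any(conc < -1e-9 * max(1, abs(curve$conc_range[2])))) {
    warn("negative computed concentration floored at 0")
  }
  pmax(conc, 0)
}

#' Consumption or production rate per microgram protein
#'
#' `consumption = (blank - sample) / hours / protein_ug` (positive when the
#' cells consumed the analyte, the glucose convention);
#' `production = (sample - blank) / hours / protein_ug` (positive when the
#' cells released it, the lactate convention). Units follow the inputs
#' (e.g. mM h^-1 ug^-1).
#'
#' @param sample_conc,blank_conc Supernatant and medium-blank concentrations.
#' @param hours Incubation time (> 0).
#' @param protein_ug Protein content for normalization (> 0).
#' @param kind `"consumption"` or `"production"`.
#' @return Numeric rate(s).
#' @export
consumption_production <- function(sample_conc, blank_conc, hours, protein_ug,
                                   kind = c("consumption", "production")) {
  kind <- match.arg(kind)
  if (any(hours <= 0)) {
    abort("hours must be positive", class = "ppptrace_invalid_input")
  }
  if (any(protein_ug <= 0)) {
    abort("protein_ug must be positive",
          class = "ppptrace_invalid_normalization")
  }
  delta <- if (kind == "consumption") blank_conc - sample_conc
           else sample_conc - blank_conc
  delta / hours / protein_ug
}

#' ECAR trace for the glycolysis stress test
#'
#' Timestamped extracellular acidification rates with the three annotated
#' injections (glucose, oligomycin, 2-deoxy-D-glucose) that delimit the four
#' assay phases.
#'
#' @param times Strictly increasing measurement times (minutes).
#' @param values ECAR values (mpH/min, arbitrary consistent units).
#' @param injections Three ordered injection times partitioning `times`.
#' @return Object of class `ecar_trace` with a derived `phase` per point.
#' @export
ecar_trace <- function(times, values, injections) {
  if (length(times) != length(values)) {
    abort("times and values must have equal length",
          class = "ppptrace_invalid_input")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("times must be strictly increasing",
          class = "ppptrace_invalid_input")
  }
  if (length(injections) != 3L || is.unsorted(injections, strictly = TRUE)) {
    abort("injections must be three ordered times (glucose, oligomycin, 2-DG)",
          class = "ppptrace_invalid_input")
  }
  phase_levels <- c("pre_glucose", "post_glucose", "post_oligomycin", "post_2dg")
  phase <- phase_levels[findInterval(times, injections) + 1L]
  structure(
    list(times = times, values = values, injections = injections,
         phase = factor(phase, levels = phase_levels)),
    class = "ecar_trace"
  )
}

#' @export
print.ecar_trace <- function(x, ...) {
  cat(sprintf("<ecar_trace> %d points over %g-%g min, injections at %s\n",
              length(x$times), min(x$times), max(x$times),
              paste(x$injections, collapse = ", ")))
  invisible(x)
}

#' Glycolysis-stress-test metrics from an ECAR trace
#'
#' Standard glycolysis-stress-test conventions (the assay names the
#' quantities but does not define them; this is the package's stated
#' convention choice):
#' * `non_glycolytic` = mean pre-glucose ECAR;
#' * `glycolysis` = mean post-glucose ECAR - non_glycolytic;
#' * `glycolytic_capacity` = mean post-oligomycin ECAR - non_glycolytic;
#' * `glycolytic_reserve` = capacity - glycolysis (exactly, by definition).
#'
#' Post-2-DG values below baseline are reported, not errored.
#'
#' @param trace An [ecar_trace()] with at least one measurement per phase.
#' @param method `"mean"` (all measurements between injections, default) or
#'   `"last"` (last point of each phase).
#' @return Named list with the four metrics.
#' @export
glycolysis_stress_metrics <- function(trace, method = c("mean", "last")) {
  stopifnot(inherits(trace, "ecar_trace"))
  method <- match.arg(method)
  by_phase <- split(trace$values, trace$phase)
  if (any(lengths(by_phase) == 0L)) {
    missing <- names(by_phase)[lengths(by_phase) == 0L]
    abort(paste("incomplete trace: no measurements in phase(s)",
                paste(missing, collapse = ", ")),
          class = "ppptrace_incomplete_trace")
  }
  level <- if (method == "mean") vapply(by_phase, mean, numeric(1))
           else vapply(by_phase, function(v) v[length(v)], numeric(1))
  non_glycolytic <- level[["pre_glucose"]]
  glycolysis <- level[["post_glucose"]] - non_glycolytic
  capacity <- level[["post_oligomycin"]] - non_glycolytic
  list(non_glycolytic = non_glycolytic,
       glycolysis = glycolysis,
       glycolytic_capacity = capacity,
       glycolytic_reserve = capacity - glycolysis)
}

#' Baseline-normalized fold change of treated over control
#'
#' Each series is divided by its own baseline value (the 0 h measurement),
#' then the treated series is divided by the control series at matched
#' times: the "fold change metformin/control" convention. Values below 1
#' indicate net loss relative to control; a normalized value below 1 within
#' a series indicates signal below its 0 h starting point.
#'
#' @param treated,control Numeric series at matched times.
#' @param baseline_index Index of the baseline (0 h) measurement, default 1.
#' @return Numeric vector of fold changes, same length as the series.
#' @export
fold_change <- function(treated, control, baseline_index = 1L) {
  if (length(treated) != length(control)) {
    abort("series must have equal length", class = "ppptrace_invalid_input")
  }
  if (baseline_index < 1L || baseline_index > length(treated)) {
    abort("baseline_index out of range", class = "ppptrace_invalid_input")
  }
  if (treated[baseline_index] <= 0 || control[baseline_index] <= 0) {
    abort("baseline values must be positive",
          class = "ppptrace_normalization_error")
  }
  (treated / treated[baseline_index]) / (control / control[baseline_index])
}
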