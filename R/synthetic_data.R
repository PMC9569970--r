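#' Default synthetic cell-line panel
#'
#' Mirrors the study's core set: two proneural brain-tumor-initiating-cell
#' (BTIC) lines with high PPP usage and low glucose turnover, and two
#' mesenchymal lines with the opposite profile; `include_tc = TRUE` adds
#' differentiated tumor-cell (TC) counterparts with the same parameters.
#' Rates are in mM per hour of culture medium; `protein_ug` is the protein
#' content used for per-microgram normalization.
#'
#' @param include_tc Add TC counterparts of each line.
#' @return Tibble with columns `line_id`, `subtype`, `f_ppp`,
#'   `glucose_consumption_rate`, `lactate_production_rate`, `protein_ug`.
#' @export
default_lines <- function(include_tc = FALSE) {
  btic <- tibble::tibble(
    line_id = c("BTIC8L", "BTIC18L", "BTIC11L", "BTIC13L"),
    subtype = c("proneural", "proneural", "mesenchymal", "mesenchymal"),
    f_ppp = c(0.3, 0.3, 0.1, 0.1),
    glucose_consumption_rate = c(0.08, 0.07, 0.25, 0.22),
    lactate_production_rate = c(0.12, 0.10, 0.40, 0.36),
    protein_ug = 100
  )
  if (!include_tc) return(btic)
  tc <- btic
  tc$line_id <- sub("^BTIC", "TC", tc$line_id)
  dplyr::bind_rows(btic, tc)
}

#' Default treatment arms
#'
#' Metformin arms as used in the study (0.01, 1 and 10 mM); by default only
#' control and the 1 mM arm are generated. Metformin lowers the PPP fraction
#' and raises glucose consumption and lactate production.
#'
#' @param full Include the 0.01 and 10 mM arms.
#' @return Tibble with `name`, `metformin_mM`, `f_ppp_shift`,
#'   `glucose_rate_multiplier`.
#' @export
default_treatments <- function(full = FALSE) {
  arms <- tibble::tibble(
    name = c("control", "metformin_0.01mM", "metformin_1mM", "metformin_10mM"),
    metformin_mM = c(0, 0.01, 1, 10),
    f_ppp_shift = c(0, 0, -0.05, -0.08),
    glucose_rate_multiplier = c(1, 1.05, 1.3, 1.5)
  )
  if (full) arms else arms[arms$name %in% c("control", "metformin_1mM"), ]
}

#' Simulation configuration
#'
#' Bundles the cell-line panel, treatment arms, replication, noise level,
#' tracer specification and seed that every simulator consumes. All
#' simulators are pure functions of `(config, seed)`.
#'
#' @param lines Tibble as returned by [default_lines()].
#' @param treatments Tibble as returned by [default_treatments()].
#' @param n_replicates Replicates per line x treatment (>= 1; the study's
#'   assays were run in triplicate).
#' @param noise_cv Multiplicative coefficient of variation of intensity /
#'   response noise (>= 0; default 0.05 for GC-MS peak areas).
#' @param tracer A [tracer_spec()].
#' @param seed Integer seed.
#' @param hours Incubation time for exometabolome sampling (default 48).
#' @param blank_glucose_mM,blank_lactate_mM Medium-blank concentrations.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(lines = default_lines(),
                              treatments = default_treatments(),
                              n_replicates = 3, noise_cv = 0.05,
                              tracer = tracer_spec(), seed = 1,
                              hours = 48, blank_glucose_mM = 25,
                              blank_lactate_mM = 0) {
  stopifnot(is.data.frame(lines), is.data.frame(treatments),
            inherits(tracer, "tracer_spec"))
  need <- c("line_id", "subtype", "f_ppp", "glucose_consumption_rate",
            "lactate_production_rate", "protein_ug")
  if (!all(need %in% names(lines))) {
    abort(paste("lines must have columns:", paste(need, collapse = ", ")),
          class = "ppptrace_invalid_input")
  }
  if (any(lines$f_ppp < 0 | lines$f_ppp > 1)) {
    abort("line f_ppp values must lie in [0, 1]",
          class = "ppptrace_invalid_input")
  }
  if (n_replicates < 1) {
    abort("n_replicates must be >= 1", class = "ppptrace_invalid_input")
  }
  if (noise_cv < 0) {
    abort("noise_cv must be >= 0", class = "ppptrace_invalid_input")
  }
  structure(
    list(lines = tibble::as_tibble(lines),
         treatments = tibble::as_tibble(treatments),
         n_replicates = as.integer(n_replicates), noise_cv = noise_cv,
         tracer = tracer, seed = as.integer(seed), hours = hours,
         blank_glucose_mM = blank_glucose_mM,
         blank_lactate_mM = blank_lactate_mM),
    class = "simulation_config"
  )
}

# log-normal multiplicative noise with unit mean and given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulate a [1,2-13C2]glucose tracing dataset
#'
#' For each line x treatment x replicate and each registry fragment
#' (lactate full ion, lactate C2-C3 fragment, pyruvate full ion):
#' the tracer-label MID from [expected_mid()] at the line's (shifted) PPP
#' fraction is convolved through the correction operator (natural abundance
#' plus tracer impurity), scaled to a random total ion intensity, and
#' perturbed by multiplicative log-normal noise per bin. Ground truth is
#' returned as a sidecar table so recovery tests never parse it from the
#' intensity table.
#'
#' @param config A [simulation_config()].
#' @return List with `intensities` (long tibble: `sample_id`, `line_id`,
#'   `subtype`, `treatment`, `replicate`, `analyte`, `fragment_id`, `mz`,
#'   `isotopologue`, `intensity`), `truth` (one row per sample x fragment
#'   with `f_ppp_true`), and `config`.
#' @export
simulate_tracing_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  frags <- default_fragments()
  cms <- lapply(frags, build_correction_matrix, tracer = config$tracer)

  withr::with_seed(config$seed, {
    rows <- list()
    truth <- list()
    grid <- tidyr::expand_grid(
      line = seq_len(nrow(config$lines)),
      trt = seq_len(nrow(config$treatments)),
      replicate = seq_len(config$n_replicates)
    )
    for (g in seq_len(nrow(grid))) {
      ln <- config$lines[grid$line[g], ]
      tr <- config$treatments[grid$trt[g], ]
      rep_i <- grid$replicate[g]
      p_true <- clamp01(ln$f_ppp + tr$f_ppp_shift)
      sample_id <- sprintf("%s_%s_r%d", ln$line_id, tr$name, rep_i)
      for (fid in names(frags)) {
        frag <- frags[[fid]]
        x <- expected_mid(p_true, frag, tracer_spec(purity = 1))
        y <- convolve_forward(x, cms[[fid]])
        total <- rlnorm(1, meanlog = log(1e6), sdlog = 0.2)
        nb <- length(y$fractions)
        inten <- total * y$fractions * rlnorm_cv(nb, config$noise_cv)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample_id = sample_id, line_id = ln$line_id, subtype = ln$subtype,
          treatment = tr$name, replicate = rep_i, analyte = frag$analyte,
          fragment_id = fid, mz = frag$base_mz + 0:(nb - 1L),
          isotopologue = 0:(nb - 1L), intensity = inten
        )
        truth[[length(truth) + 1L]] <- tibble::tibble(
          sample_id = sample_id, line_id = ln$line_id, subtype = ln$subtype,
          treatment = tr$name, replicate = rep_i, fragment_id = fid,
          f_ppp_true = p_true
        )
      }
    }
    list(intensities = dplyr::bind_rows(rows),
         truth = dplyr::bind_rows(truth),
         config = config)
  })
}

# True calibration curves used by the exometabolome simulator; recovery
# tests read these from the returned truth table, not from here.
EXO_TRUE_CURVES <- tibble::tibble(
  analyte = c("glucose", "lactate"),
  slope = c(0.05, 0.08),
  intercept = c(0.002, 0.001)
)

#' Simulate an exometabolome quantitation experiment
#'
#' Generates isotope-dilution calibration points (analyte/internal-standard
#' response ratio linear in concentration, multiplicative noise) and
#' supernatant samples whose concentrations follow each line's consumption
#' or production rate over the configured incubation: glucose =
#' blank - rate x hours (floored at 0 with a warning), lactate =
#' blank + rate x hours. Treatment multiplies both rates.
#'
#' @param config A [simulation_config()].
#' @param cal_cv CV of calibration / sample response noise (default 0.02).
#' @return List with `calibration` (`analyte`, `concentration`,
#'   `response_ratio`), `samples` (`sample_id`, `line_id`, `subtype`,
#'   `treatment`, `replicate`, `analyte`, `response_ratio`, `protein_ug`,
#'   `hours`), and `truth` (true curves and true concentrations).
#' @export
simulate_exometabolome <- function(config = simulation_config(), cal_cv = 0.02) {
  stopifnot(inherits(config, "simulation_config"))
  conc_points <- list(glucose = c(0, 1, 2.5, 5, 10, 25),
                      lactate = c(0, 0.5, 1, 2.5, 5, 10, 20))
  withr::with_seed(config$seed + 1L, {
    cal <- list()
    for (i in seq_len(nrow(EXO_TRUE_CURVES))) {
      cv <- EXO_TRUE_CURVES[i, ]
      conc <- conc_points[[cv$analyte]]
      ratio <- (cv$slope * conc + cv$intercept) * rlnorm_cv(length(conc), cal_cv)
      cal[[i]] <- tibble::tibble(analyte = cv$analyte, concentration = conc,
                                 response_ratio = ratio)
    }
    calibration <- dplyr::bind_rows(cal)

    grid <- tidyr::expand_grid(
      line = seq_len(nrow(config$lines)),
      trt = seq_len(nrow(config$treatments)),
      replicate = seq_len(config$n_replicates)
    )
    samp <- list(); tru <- list()
    floored <- FALSE
    for (g in seq_len(nrow(grid))) {
      ln <- config$lines[grid$line[g], ]
      tr <- config$treatments[grid$trt[g], ]
      rep_i <- grid$replicate[g]
      sample_id <- sprintf("%s_%s_r%d", ln$line_id, tr$name, rep_i)
      gluc <- config$blank_glucose_mM -
        ln$glucose_consumption_rate * tr$glucose_rate_multiplier * config$hours
      if (gluc < 0) { floored <- TRUE; gluc <- 0 }
      lact <- config$blank_lactate_mM +
        ln$lactate_production_rate * tr$glucose_rate_multiplier * config$hours
      for (an in c("glucose", "lactate")) {
        conc <- if (an == "glucose") gluc else lact
        cv <- EXO_TRUE_CURVES[EXO_TRUE_CURVES$analyte == an, ]
        ratio <- (cv$slope * conc + cv$intercept) * rlnorm_cv(1, cal_cv)
        samp[[length(samp) + 1L]] <- tibble::tibble(
          sample_id = sample_id, line_id = ln$line_id, subtype = ln$subtype,
          treatment = tr$name, replicate = rep_i, analyte = an,
          response_ratio = ratio, protein_ug = ln$protein_ug,
          hours = config$hours
        )
        tru[[length(tru) + 1L]] <- tibble::tibble(
          sample_id = sample_id, analyte = an, concentration_true = conc
        )
      }
    }
    if (floored) {
      warn("simulated glucose consumption exceeded the medium blank; concentration floored at 0")
    }
    list(calibration = calibration, samples = dplyr::bind_rows(samp),
         truth = list(curves = EXO_TRUE_CURVES,
                      concentrations = dplyr::bind_rows(tru)))
  })
}

#' Simulate a survival cohort with a continuous expression covariate
#'
#' Event times are exponential with a hazard scaled by expression group:
#' subjects with expression above the population median (0) have hazard
#' `base_hazard * hazard_ratio`, the rest `base_hazard`. Each subject is
#' independently censored with probability `censor_rate` at a uniform
#' fraction of its event time. Exactly `n_per_group` subjects fall on each
#' side of the population median so that a sample median split recovers the
#' groups with high probability.
#'
#' @param n_per_group Subjects per expression side.
#' @param hazard_ratio Hazard multiplier for the high-expression side
#'   (1 = null).
#' @param censor_rate Independent censoring probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param base_hazard Baseline exponential hazard (events per time unit).
#' @return Tibble with `time`, `event` (1 = death observed, 0 = censored)
#'   and `expression`.
#' @export
simulate_survival <- function(n_per_group = 100, hazard_ratio = 1,
                              censor_rate = 0.2, seed = 1, base_hazard = 0.05) {
  stopifnot(n_per_group >= 2, hazard_ratio > 0,
            censor_rate >= 0, censor_rate < 1)
  withr::with_seed(as.integer(seed), {
    expression <- c(abs(rnorm(n_per_group)), -abs(rnorm(n_per_group)))
    high <- expression > 0
    rate <- base_hazard * ifelse(high, hazard_ratio, 1)
    t_event <- rexp(2 * n_per_group, rate)
    cens <- runif(2 * n_per_group) < censor_rate
    time <- ifelse(cens, t_event * runif(2 * n_per_group), t_event)
    tibble::tibble(time = time, event = as.integer(!cens),
                   expression = expression)
  })
}

#' Simulate a glycolysis-stress-test ECAR trace
#'
#' Piecewise-constant extracellular acidification rate over the four assay
#' phases (pre-glucose, post-glucose, post-oligomycin, post-2-DG) with
#' additive Gaussian noise and annotated injection times.
#'
#' @param basal,post_glucose,post_oligomycin,post_2dg Phase mean ECAR levels
#'   (mpH/min, arbitrary consistent units).
#' @param noise Additive Gaussian noise SD (default 0).
#' @param seed Integer seed.
#' @param n_per_phase Measurements per phase (default 3).
#' @param dt Minutes between measurements (default 6).
#' @return An [ecar_trace()].
#' @export
simulate_ecar_trace <- function(basal = 10, post_glucose = 40,
                                post_oligomycin = 70, post_2dg = 8,
                                noise = 0, seed = 1, n_per_phase = 3, dt = 6) {
  stopifnot(n_per_phase >= 1)
  levels <- c(basal, post_glucose, post_oligomycin, post_2dg)
  withr::with_seed(as.integer(seed), {
    values <- rep(levels, each = n_per_phase) +
      rnorm(4 * n_per_phase, sd = noise)
    times <- dt * seq_len(4 * n_per_phase)
    injections <- dt * n_per_phase * (1:3) + dt / 2
    ecar_trace(times, values, injections)
  })
}
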