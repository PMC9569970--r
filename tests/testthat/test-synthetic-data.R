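small_config <- function(seed = 1, noise_cv = 0.05, tracer = tracer_spec(),
                         treatments = default_treatments()[1, ],
                         n_replicates = 2) {
  simulation_config(lines = default_lines()[c(1, 3), ],
                    treatments = treatments, n_replicates = n_replicates,
                    noise_cv = noise_cv, tracer = tracer, seed = seed)
}

test_that("tracing simulation is a pure function of config and seed", {
  a <- simulate_tracing_dataset(small_config(seed = 5))
  b <- simulate_tracing_dataset(small_config(seed = 5))
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$truth, b$truth)
  c <- simulate_tracing_dataset(small_config(seed = 6))
  expect_false(identical(a$intensities$intensity, c$intensities$intensity))
})

test_that("noiseless, pure, abundance-free intensities are proportional to the model MID", {
  cfg <- small_config(noise_cv = 0,
                      tracer = tracer_spec(purity = 1, nat_abund_13C = 0))
  sim <- simulate_tracing_dataset(cfg)
  part <- dplyr::filter(sim$intensities,
                        sample_id == sim$intensities$sample_id[1],
                        fragment_id == "lactate_c23")
  truth <- sim$truth$f_ppp_true[sim$truth$sample_id == part$sample_id[1]][1]
  expect_equal(part$intensity / sum(part$intensity),
               expected_mid(truth, frags$lactate_c23, pure_tracer)$fractions,
               tolerance = 1e-12)
})

test_that("simulated tables pass the reader validation and carry all fragments", {
  sim <- simulate_tracing_dataset(small_config())
  expect_silent(validate_tracing_table(sim$intensities))
  expect_setequal(unique(sim$intensities$fragment_id),
                  c("lactate_full", "lactate_c23", "pyruvate_full"))
  c23 <- sim$intensities[sim$intensities$fragment_id == "lactate_c23", ]
  expect_setequal(unique(c23$mz), c(117, 118, 119))
  # 2 lines x 1 treatment x 2 replicates x (4 + 3 + 4) bins
  expect_equal(nrow(sim$intensities), 2 * 1 * 2 * 11)
})

test_that("metformin arms shift the simulated PPP fraction down", {
  cfg <- small_config(treatments = default_treatments(), noise_cv = 0)
  sim <- simulate_tracing_dataset(cfg)
  tr <- dplyr::distinct(sim$truth, line_id, treatment, f_ppp_true)
  wide <- tidyr::pivot_wider(tr, names_from = treatment,
                             values_from = f_ppp_true)
  expect_true(all(wide$metformin_1mM < wide$control))
})

test_that("exometabolome quantitation recovers true concentrations without noise", {
  cfg <- small_config(seed = 3)
  exo <- simulate_exometabolome(cfg, cal_cv = 0)
  for (an in c("glucose", "lactate")) {
    cal <- exo$calibration[exo$calibration$analyte == an, ]
    curve <- fit_calibration(cal, analyte = an)
    expect_equal(curve$r_squared, 1, tolerance = 1e-12)
    samp <- exo$samples[exo$samples$analyte == an, ]
    conc <- quantify(samp$response_ratio, curve)
    truth <- exo$truth$concentrations
    truth <- truth[truth$analyte == an, ]
    truth <- truth$concentration_true[match(samp$sample_id, truth$sample_id)]
    expect_equal(conc, truth, tolerance = 1e-9)
  }
})

test_that("noisy calibration at 2% CV still fits with R^2 above 0.99", {
  exo <- simulate_exometabolome(small_config(seed = 4), cal_cv = 0.02)
  for (an in c("glucose", "lactate")) {
    cal <- exo$calibration[exo$calibration$analyte == an, ]
    expect_gt(fit_calibration(cal, analyte = an)$r_squared, 0.99)
  }
})

test_that("glucose consumption beyond the blank floors at zero with a warning", {
  lines <- default_lines()[3, ]
  lines$glucose_consumption_rate <- 1  # 48 mM over 48 h > 25 mM blank
  cfg <- simulation_config(lines = lines,
                           treatments = default_treatments()[1, ],
                           n_replicates = 1, seed = 1)
  expect_warning(exo <- simulate_exometabolome(cfg, cal_cv = 0),
                 "floored")
  gl <- exo$truth$concentrations
  expect_true(all(gl$concentration_true[gl$analyte == "glucose"] == 0))
})

test_that("survival simulation honors censoring and the null is calibrated", {
  d0 <- simulate_survival(50, hazard_ratio = 2, censor_rate = 0, seed = 1)
  expect_true(all(d0$event == 1))
  expect_equal(nrow(d0), 100)

  # null: log-rank p approximately uniform across seeded datasets
  ps <- vapply(1:150, function(s) {
    d <- simulate_survival(40, hazard_ratio = 1, censor_rate = 0.2, seed = s)
    logrank_test(d$time, d$event, median_split(d$expression))$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a strong hazard ratio is detected by the median-split log-rank test", {
  hits <- vapply(1:40, function(s) {
    d <- simulate_survival(100, hazard_ratio = 3, censor_rate = 0.2, seed = s)
    logrank_test(d$time, d$event, median_split(d$expression))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ECAR traces reproduce their phase levels and are seed-deterministic", {
  tr <- simulate_ecar_trace(10, 40, 70, 8, noise = 0, seed = 1)
  m <- glycolysis_stress_metrics(tr)
  expect_equal(m$glycolysis, 30)
  expect_equal(m$glycolytic_capacity, 60)
  expect_equal(m$glycolytic_reserve, 30)

  flat <- simulate_ecar_trace(20, 20, 20, 20, noise = 0, seed = 1)
  mf <- glycolysis_stress_metrics(flat)
  expect_equal(mf$glycolytic_reserve, 0)
  expect_equal(mf$glycolysis, 0)

  n1 <- simulate_ecar_trace(10, 40, 70, 8, noise = 2, seed = 42)
  n2 <- simulate_ecar_trace(10, 40, 70, 8, noise = 2, seed = 42)
  expect_identical(n1$values, n2$values)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_replicates = 0),
               class = "ppptrace_invalid_input")
  expect_error(simulation_config(noise_cv = -0.1),
               class = "ppptrace_invalid_input")
  bad_lines <- default_lines()
  bad_lines$f_ppp[1] <- 1.5
  expect_error(simulation_config(lines = bad_lines),
               class = "ppptrace_invalid_input")
})
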