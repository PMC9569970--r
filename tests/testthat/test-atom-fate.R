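iso_table <- function(isos) {
  data.frame(
    pattern = vapply(isos, function(x) {
      paste(which(x$carbon_labels), collapse = ",")
    }, character(1)),
    weight = vapply(isos, function(x) x$weight, numeric(1))
  )
}

test_that("pure glycolysis yields one [2,3-13C2] and one unlabeled lactate per glucose", {
  tab <- iso_table(forward_isotopomers(0, pure_tracer))
  expect_equal(tab$weight[tab$pattern == "2,3"], 1)
  expect_equal(tab$weight[tab$pattern == ""], 1)
  expect_equal(sum(tab$weight), 2)
})

test_that("pure PPP yields 1+1+3 lactate carrying three labels per three glucose", {
  isos <- forward_isotopomers(1, pure_tracer)
  tab <- iso_table(isos)
  expect_equal(3 * tab$weight[tab$pattern == "1,3"], 1)
  expect_equal(3 * tab$weight[tab$pattern == "3"], 1)
  expect_equal(3 * tab$weight[tab$pattern == ""], 3)
  # mass balance: five molecules, three labeled carbons, per three glucose
  w <- vapply(isos, function(x) x$weight, numeric(1))
  k <- vapply(isos, function(x) sum(x$carbon_labels), numeric(1))
  expect_equal(3 * sum(w), 5)
  expect_equal(3 * sum(w * k), 3)
})

test_that("glycolysis mass balance holds: two lactate, two labels per glucose", {
  isos <- forward_isotopomers(0, pure_tracer)
  w <- vapply(isos, function(x) x$weight, numeric(1))
  k <- vapply(isos, function(x) sum(x$carbon_labels), numeric(1))
  expect_equal(sum(w), 2)
  expect_equal(sum(w * k), 2)
})

test_that("an unlabeled tracer yields only unlabeled product", {
  tab <- iso_table(forward_isotopomers(0, tracer_spec(purity = 0)))
  expect_identical(unique(tab$pattern), "")
  expect_equal(sum(tab$weight), 2)
})

test_that("expected MIDs match the closed forms", {
  expect_equal(expected_mid(1, frags$lactate_full, pure_tracer)$fractions,
               c(0.6, 0.2, 0.2, 0))
  expect_equal(expected_mid(0, frags$lactate_c23, pure_tracer)$fractions,
               c(0.5, 0, 0.5))
  expect_equal(expected_mid(0.5, frags$lactate_c23, pure_tracer)$fractions,
               c(6, 2, 3) / 11)
  for (p in seq(0, 1, by = 0.1)) {
    expect_equal(expected_mid(p, frags$lactate_full, pure_tracer)$fractions,
                 c(3, p, 3 - 2 * p, 0) / (6 - p), tolerance = 1e-12)
    expect_equal(expected_mid(p, frags$lactate_c23, pure_tracer)$fractions,
                 c(3, 2 * p, 3 - 3 * p) / (6 - p), tolerance = 1e-12)
  }
})

test_that("fragment m+1 rises and m+2 falls strictly with the PPP fraction", {
  ps <- seq(0, 1, by = 0.05)
  mids <- vapply(ps, function(p) {
    expected_mid(p, frags$lactate_c23, pure_tracer)$fractions
  }, numeric(3))
  expect_true(all(diff(mids[2, ]) > 0))
  expect_true(all(diff(mids[3, ]) < 0))
})

test_that("the ratio estimator inverts the forward model exactly", {
  expect_equal(estimate_fppp_ratio(mid(c(6, 2, 3) / 11),
                                   frags$lactate_c23)$f_ppp, 0.5,
               tolerance = 1e-12)
  expect_equal(estimate_fppp_ratio(mid(c(0.5, 0, 0.5)),
                                   frags$lactate_c23)$f_ppp, 0)
  expect_equal(estimate_fppp_ratio(mid(c(0.6, 0.2, 0.2)),
                                   frags$lactate_full)$f_ppp, 1,
               tolerance = 1e-12)
})

test_that("estimators round-trip on a dense grid for both ion modes", {
  for (frag in list(frags$lactate_full, frags$lactate_c23)) {
    for (p in seq(0, 1, by = 0.05)) {
      m <- expected_mid(p, frag, pure_tracer)
      expect_equal(estimate_fppp_ratio(m, frag)$f_ppp, p, tolerance = 1e-9)
      expect_equal(estimate_fppp_lsq(m, frag)$f_ppp, p, tolerance = 1e-6)
    }
  }
})

test_that("degenerate and out-of-range MIDs are flagged, not errored", {
  d1 <- estimate_fppp_ratio(mid(c(0.6, 0.4, 0)), frags$lactate_c23)
  expect_equal(d1$f_ppp, 1)
  expect_true("degenerate" %in% d1$flags)

  d0 <- estimate_fppp_ratio(mid(c(1, 0, 0)), frags$lactate_c23)
  expect_equal(d0$f_ppp, 0)
  expect_true("degenerate" %in% d0$flags)

  # m1/m2 beyond the invertible range clamps to 1 with a flag
  cl <- estimate_fppp_ratio(mid(c(0.1, 0.8, 0.1)), frags$lactate_full)
  expect_true("clamped" %in% cl$flags || cl$f_ppp <= 1)
  expect_gte(cl$f_ppp, 0)
  expect_lte(cl$f_ppp, 1)

  expect_error(estimate_fppp_ratio(mid(c(0.5, 0.5)), frags$lactate_c23),
               class = "ppptrace_invalid_input")
  expect_error(forward_isotopomers(1.2, pure_tracer),
               class = "ppptrace_domain_error")
  expect_error(estimate_fppp_lsq(list(), frags$lactate_c23),
               class = "ppptrace_invalid_input")
})

test_that("flux partition carries complement, triose share and bounds", {
  fp <- flux_partition(0.4, "ratio")
  expect_equal(fp$f_glycolysis, 0.6)
  expect_equal(fp$ppp_triose_share, 5 * 0.4 / (6 - 0.4))
  expect_error(flux_partition(1.5, "ratio"), class = "ppptrace_domain_error")
  expect_error(flux_partition(0.5, "ratio", ci_low = 0.6, ci_high = 0.9),
               class = "ppptrace_invalid_input")
})

test_that("least-squares estimation recovers the truth from noisy replicates", {
  for (p in c(0.05, 0.2, 0.5, 0.8)) {
    reps <- make_noisy_mids(p, frags$lactate_c23, cv = 0.05, n = 3,
                            seed = round(1000 * p))
    est <- estimate_fppp_lsq(reps, frags$lactate_c23)
    expect_lt(abs(est$f_ppp - p), 0.05)
  }
})

test_that("bootstrap intervals are seed-deterministic and collapse without variance", {
  reps <- make_noisy_mids(0.3, frags$lactate_c23, cv = 0, n = 4, seed = 1)
  ci <- bootstrap_ci(reps, frags$lactate_c23, n_boot = 200, seed = 9)
  expect_equal(ci$ci_low, ci$f_ppp)
  expect_equal(ci$ci_high, ci$f_ppp)

  noisy <- make_noisy_mids(0.5, frags$lactate_c23, cv = 0.05, n = 6, seed = 2)
  a <- bootstrap_ci(noisy, frags$lactate_c23, n_boot = 200, seed = 11)
  b <- bootstrap_ci(noisy, frags$lactate_c23, n_boot = 200, seed = 11)
  expect_identical(a$ci_low, b$ci_low)
  expect_identical(a$ci_high, b$ci_high)
  expect_lt(a$ci_low, a$f_ppp)
  expect_gt(a$ci_high, a$f_ppp)

  expect_error(bootstrap_ci(noisy[1], frags$lactate_c23, n_boot = 200, seed = 1),
               class = "ppptrace_insufficient_replicates")
  expect_error(bootstrap_ci(noisy, frags$lactate_c23, n_boot = 50, seed = 1),
               class = "ppptrace_invalid_input")
})

test_that("bootstrap interval covers the truth at its small-sample rate", {
  # Percentile intervals over n = 6 replicates undercover somewhat; the
  # check pins behavior at fixed seeds rather than asserting nominal 95%.
  cover <- 0
  for (s in 1:40) {
    reps <- make_noisy_mids(0.5, frags$lactate_c23, cv = 0.05, n = 6, seed = s)
    ci <- bootstrap_ci(reps, frags$lactate_c23, n_boot = 300, seed = s + 500)
    if (ci$ci_low <= 0.5 && 0.5 <= ci$ci_high) cover <- cover + 1
  }
  expect_gte(cover / 40, 0.75)
})

test_that("the least-squares objective is unimodal on a grid", {
  mbar <- expected_mid(0.35, frags$lactate_c23, pure_tracer)$fractions
  ps <- seq(0, 1, by = 0.01)
  obj <- vapply(ps, function(p) {
    f <- c(3, 2 * p, 3 - 3 * p) / (6 - p)
    sum((f - mbar)^2)
  }, numeric(1))
  signs <- sign(diff(obj))
  expect_lte(sum(diff(signs[signs != 0]) != 0), 1)
})

test_that("tracer impurity shifts signal toward lower isotopologues", {
  impure <- expected_mid(0.3, frags$lactate_c23, tracer_spec(purity = 0.9))
  pure <- expected_mid(0.3, frags$lactate_c23, pure_tracer)
  expect_gt(impure$fractions[1], pure$fractions[1])
  expect_lt(impure$fractions[3], pure$fractions[3])
  expect_equal(sum(impure$fractions), 1, tolerance = 1e-12)
})
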