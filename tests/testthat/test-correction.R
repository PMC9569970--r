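test_that("correction matrix columns follow the binomial expansion", {
  a <- 0.0107
  frag2 <- fragment_spec("lactate", "c23", c(2, 3), 117)
  cm <- build_correction_matrix(frag2, tracer_spec(purity = 1,
                                                   nat_abund_13C = a))
  expect_equal(cm$matrix[, 1], c((1 - a)^2, 2 * a * (1 - a), a^2),
               tolerance = 1e-12)
  # fully labeled column: no unlabeled carbons remain
  expect_equal(cm$matrix[, 3], c(0, 0, 1))
  # no isotopes to correct: identity
  cm_id <- build_correction_matrix(frag2, tracer_spec(purity = 1,
                                                      nat_abund_13C = 0))
  expect_equal(cm_id$matrix, diag(3))
})

test_that("carbon-only matrices are column-stochastic and lower-triangular at purity 1", {
  for (frag in frags) {
    cm <- build_correction_matrix(frag, tracer_spec(purity = 1))
    expect_true(all(colSums(cm$matrix) <= 1 + 1e-9))
    expect_true(all(colSums(cm$matrix) >= 1 - 1e-9))
    expect_true(all(cm$matrix[upper.tri(cm$matrix)] == 0))
    # impurity introduces apparent label loss (upper entries)
    cmp <- build_correction_matrix(frag, tracer_spec(purity = 0.95))
    expect_true(any(cmp$matrix[upper.tri(cmp$matrix)] > 0))
  }
})

test_that("forward convolution matches the matrix columns and normalizes", {
  a <- 0.0107
  frag2 <- fragment_spec("lactate", "c23", c(2, 3), 117)
  cm <- build_correction_matrix(frag2, tracer_spec(purity = 1,
                                                   nat_abund_13C = a))
  out <- convolve_forward(mid(c(1, 0, 0)), cm)
  expect_equal(out$fractions, c((1 - a)^2, 2 * a * (1 - a), a^2),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:10) {
    x <- random_mid(3)
    expect_equal(sum(convolve_forward(x, cm)$fractions), 1, tolerance = 1e-12)
  }
  cm_id <- build_correction_matrix(frag2, tracer_spec(purity = 1,
                                                      nat_abund_13C = 0))
  x <- mid(c(0.2, 0.3, 0.5))
  expect_equal(convolve_forward(x, cm_id)$fractions, x$fractions)
})

test_that("correction inverts the forward convolution to 1e-8 for all registry fragments", {
  set.seed(11)
  for (frag in frags) {
    cm <- build_correction_matrix(frag, tracer_spec())
    nb <- length(frag$retained_carbons) + 1L
    for (i in 1:100) {
      x <- random_mid(nb)
      y <- convolve_forward(x, cm)
      back <- correct_mid(y, cm)
      expect_equal(back$fractions, x$fractions, tolerance = 1e-8)
    }
  }
})

test_that("a pure unlabeled measurement corrects to m+0 and noise stays non-negative", {
  a <- 0.0107
  frag2 <- fragment_spec("lactate", "c23", c(2, 3), 117)
  cm <- build_correction_matrix(frag2, tracer_spec(purity = 1,
                                                   nat_abund_13C = a))
  meas <- mid(c((1 - a)^2, 2 * a * (1 - a), a^2))
  expect_equal(correct_mid(meas, cm)$fractions, c(1, 0, 0), tolerance = 1e-10)

  # measured slightly under the natural-abundance envelope: NNLS floors at 0
  noisy <- mid(c(0.99, 0.008, 0.002))
  corr <- correct_mid(noisy, cm)
  expect_true(all(corr$fractions >= 0))
  expect_equal(sum(corr$fractions), 1, tolerance = 1e-12)
})

test_that("corrected m+1 separates high-PPP from low-PPP samples in every noiseless run", {
  cm <- build_correction_matrix(frags$lactate_c23, tracer_spec())
  for (pair in list(c(0.3, 0.1), c(0.5, 0.2), c(0.2, 0.05))) {
    hi <- correct_mid(convolve_forward(
      expected_mid(pair[1], frags$lactate_c23, pure_tracer), cm), cm)
    lo <- correct_mid(convolve_forward(
      expected_mid(pair[2], frags$lactate_c23, pure_tracer), cm), cm)
    expect_gt(hi$fractions[2], lo$fractions[2])
  }
})

test_that("full-formula mode corrects heteroatoms and validates its inputs", {
  frag_f <- fragment_spec("lactate", "c23_tms", c(2, 3), 117,
                          formula = "C5H13O2Si")
  cm_f <- build_correction_matrix(frag_f, tracer_spec(purity = 1),
                                  mode = "full_formula")
  cm_c <- build_correction_matrix(frag_f, tracer_spec(purity = 1))
  # heavy heteroatoms push more unlabeled signal into m+1/m+2
  expect_lt(cm_f$matrix[1, 1], cm_c$matrix[1, 1])
  expect_gt(cm_f$matrix[2, 1], cm_c$matrix[2, 1])
  expect_true(all(abs(colSums(cm_f$matrix) - 1) < 1e-9))
  # round trip still holds
  x <- mid(c(0.5, 0.3, 0.2))
  expect_equal(correct_mid(convolve_forward(x, cm_f), cm_f)$fractions,
               x$fractions, tolerance = 1e-8)

  no_formula <- fragment_spec("lactate", "bare", c(2, 3), 117)
  expect_error(build_correction_matrix(no_formula, tracer_spec(),
                                       mode = "full_formula"),
               class = "ppptrace_configuration_error")
  bad <- fragment_spec("lactate", "bad", c(2, 3), 117, formula = "C1Xx3")
  expect_error(build_correction_matrix(bad, tracer_spec(),
                                       mode = "full_formula"),
               class = "ppptrace_configuration_error")
})

test_that("dimension mismatches and audit dumps behave", {
  cm <- build_correction_matrix(frags$lactate_c23, tracer_spec())
  expect_error(convolve_forward(mid(c(0.25, 0.25, 0.25, 0.25)), cm),
               class = "ppptrace_invalid_input")
  expect_error(correct_mid(mid(c(0.25, 0.25, 0.25, 0.25)), cm),
               class = "ppptrace_invalid_input")
  tab <- correction_matrix_table(cm)
  expect_equal(dim(tab), c(3L, 4L))
  expect_equal(tab$labels_0, cm$matrix[, 1])
})
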