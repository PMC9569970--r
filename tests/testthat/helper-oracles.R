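# Shared fixtures and independent oracles, built in code at test time.

frags <- default_fragments()
pure_tracer <- tracer_spec(purity = 1)

# Noisy replicate MIDs around the model expectation: per-bin multiplicative
# log-normal noise at the given CV, renormalized.
make_noisy_mids <- function(p, fragment, cv, n, seed) {
  withr::with_seed(seed, {
    f <- expected_mid(p, fragment, pure_tracer)$fractions
    lapply(seq_len(n), function(i) {
      v <- f * stats::rlnorm(length(f), 0, sqrt(log(1 + cv^2)))
      mid(v / sum(v))
    })
  })
}

# Random valid MID (uniform on the simplex via exponential spacings).
random_mid <- function(n_bins) {
  v <- stats::rexp(n_bins)
  mid(v / sum(v))
}

# Balanced two-factor dataset with configurable effects.
make_balanced <- function(a, b, n, seed, effect_a = 0, effect_b = 0,
                          interaction = 0, sd = 1) {
  withr::with_seed(seed, {
    grid <- expand.grid(A = paste0("a", seq_len(a)),
                        B = paste0("b", seq_len(b)),
                        rep = seq_len(n))
    mu <- effect_a * as.integer(factor(grid$A)) +
      effect_b * as.integer(factor(grid$B)) +
      interaction * as.integer(factor(grid$A)) * as.integer(factor(grid$B))
    grid$value <- mu + stats::rnorm(nrow(grid), sd = sd)
    grid
  })
}

# Brute-force textbook two-way ANOVA oracle: explicit loops over levels,
# no vectorized shortcuts shared with the implementation.
oracle_two_way_anova <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  a <- nlevels(A); b <- nlevels(B)
  n <- sum(A == levels(A)[1] & B == levels(B)[1])
  N <- length(y)
  grand <- sum(y) / N
  ss_a <- 0
  for (i in levels(A)) ss_a <- ss_a + b * n * (mean(y[A == i]) - grand)^2
  ss_b <- 0
  for (j in levels(B)) ss_b <- ss_b + a * n * (mean(y[B == j]) - grand)^2
  ss_ab <- 0
  for (i in levels(A)) for (j in levels(B)) {
    cell <- mean(y[A == i & B == j])
    ss_ab <- ss_ab + n * (cell - mean(y[A == i]) - mean(y[B == j]) + grand)^2
  }
  ss_res <- 0
  for (i in levels(A)) for (j in levels(B)) {
    sel <- A == i & B == j
    ss_res <- ss_res + sum((y[sel] - mean(y[sel]))^2)
  }
  df <- c(a - 1, b - 1, (a - 1) * (b - 1), N - a * b)
  ms <- c(ss_a, ss_b, ss_ab, ss_res) / df
  f <- ms[1:3] / ms[4]
  p <- stats::pf(f, df[1:3], df[4], lower.tail = FALSE)
  list(ss = c(ss_a, ss_b, ss_ab, ss_res), df = df, f = f, p = p,
       ss_total = sum((y - grand)^2))
}
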