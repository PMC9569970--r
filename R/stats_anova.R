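#' Balanced two-way fixed-effects ANOVA
#'
#' Classical sum-of-squares decomposition for a balanced two-factor design
#' with replication, computed from first principles (marginal and cell
#' means): SS_A, SS_B, SS_AB, SS_resid, with SS_total conserved exactly and
#' degrees of freedom summing to N - 1. p-values come from the F
#' distribution. Unbalanced designs are refused explicitly rather than
#' silently switching among Type-I/II/III sums of squares; the study's
#' designs are triplicate and balanced.
#'
#' A zero residual mean square (all replicates identical within cells) is
#' reported as degenerate with the convention F = 0, p = 1 when the means
#' are equal too.
#'
#' @param data Data frame.
#' @param value Name of the numeric response column.
#' @param factor_a,factor_b Names of the two factor columns.
#' @return Object of class `anova_result`: a tibble with one row per effect
#'   (`factor_a`, `factor_b`, `interaction`, `residual`, `total`) and columns
#'   `effect`, `ss`, `df`, `ms`, `f`, `p`; attributes `cell_means`, `mse`,
#'   `df_resid`, `n_per_cell`, `degenerate`.
#' @export
two_way_anova <- function(data, value = "value", factor_a = "factor_a",
                          factor_b = "factor_b") {
  if (!all(c(value, factor_a, factor_b) %in% names(data))) {
    abort("data must contain the value and factor columns",
          class = "ppptrace_invalid_input")
  }
  y <- data[[value]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  if (anyNA(y) || anyNA(A) || anyNA(B)) {
    abort("missing values are not supported", class = "ppptrace_invalid_input")
  }
  a <- nlevels(A); b <- nlevels(B)
  if (a < 2L || b < 2L) {
    abort("each factor needs at least 2 levels",
          class = "ppptrace_invalid_input")
  }
  counts <- table(A, B)
  n <- counts[1, 1]
  if (any(counts != n) || n < 2L) {
    abort("unsupported design: two_way_anova requires a balanced design with >= 2 replicates per cell",
          class = "ppptrace_unbalanced_design")
  }
  N <- length(y)
  grand <- mean(y)
  mean_a <- tapply(y, A, mean)
  mean_b <- tapply(y, B, mean)
  mean_ab <- tapply(y, list(A, B), mean)

  ss_a <- b * n * sum((mean_a - grand)^2)
  ss_b <- a * n * sum((mean_b - grand)^2)
  ss_cells <- n * sum((mean_ab - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  fitted_cell <- mean_ab[cbind(as.integer(A), as.integer(B))]
  ss_res <- sum((y - fitted_cell)^2)
  ss_tot <- sum((y - grand)^2)

  df_a <- a - 1L; df_b <- b - 1L; df_ab <- df_a * df_b
  df_res <- N - a * b
  mse <- ss_res / df_res
  degenerate <- mse <= .Machine$double.eps * max(1, ss_tot)

  eff_ss <- c(ss_a, ss_b, ss_ab)
  eff_df <- c(df_a, df_b, df_ab)
  eff_ms <- eff_ss / eff_df
  if (degenerate) {
    fstat <- ifelse(eff_ss <= .Machine$double.eps * max(1, ss_tot), 0, Inf)
    pval <- ifelse(fstat == 0, 1, 0)
  } else {
    fstat <- eff_ms / mse
    pval <- pf(fstat, eff_df, df_res, lower.tail = FALSE)
  }
  tab <- tibble::tibble(
    effect = c("factor_a", "factor_b", "interaction", "residual", "total"),
    term = c(factor_a, factor_b, paste(factor_a, factor_b, sep = ":"),
             "residual", "total"),
    ss = c(eff_ss, ss_res, ss_tot),
    df = c(eff_df, df_res, N - 1L),
    ms = c(eff_ms, mse, NA_real_),
    f = c(fstat, NA_real_, NA_real_),
    p = c(pval, NA_real_, NA_real_)
  )
  structure(tab, class = c("anova_result", class(tab)),
            cell_means = mean_ab, mse = mse, df_resid = df_res,
            n_per_cell = as.integer(n), degenerate = degenerate)
}

# Studentized range distribution function P(Q <= q) for k groups and df
# residual degrees of freedom, by nested numerical integration
# (quadrature tolerance 1e-8). Internal; Tukey p = 1 - this.
ptukey_range <- function(q, k, df) {
  if (q <= 0) return(0)
  range_cdf <- function(u) {
    if (u <= 0) return(0)
    k * integrate(function(z) dnorm(z) * (pnorm(z) - pnorm(z - u))^(k - 1),
                  lower = -Inf, upper = Inf, rel.tol = 1e-10)$value
  }
  if (is.infinite(df)) return(range_cdf(q))
  # s = sqrt(chi^2_df / df); integrate the scale mixture over its density
  log_c <- (df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2)
  f_s <- function(s) exp(log_c + (df - 1) * log(s) - df * s^2 / 2)
  integrand <- Vectorize(function(s) f_s(s) * range_cdf(q * s))
  integrate(integrand, lower = 0, upper = Inf, rel.tol = 1e-8)$value
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range statistic \eqn{q = |\bar y_i - \bar y_j| /
#' \sqrt{MSE/n}} for every pair of cell means, with adjusted p from the
#' studentized range distribution for `k` means and the residual degrees of
#' freedom (computed by numerical integration, quadrature tolerance 1e-8).
#'
#' @param means Named vector of group/cell means.
#' @param mse Residual mean square from the ANOVA.
#' @param df_resid Residual degrees of freedom.
#' @param n_per_cell Replicates behind each mean.
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble with `group_1`, `group_2`, `diff`, `q`, `p_adj`,
#'   `significant`, `stars`; attribute `degenerate` when `mse <= 0`.
#' @export
tukey_hsd <- function(means, mse, df_resid, n_per_cell, alpha = 0.05) {
  if (length(means) < 2L) {
    abort("need at least 2 means", class = "ppptrace_invalid_input")
  }
  if (is.null(names(means))) names(means) <- seq_along(means)
  k <- length(means)
  pairs <- combn(names(means), 2)
  degenerate <- !(is.finite(mse) && mse > 0)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    d <- means[[g1]] - means[[g2]]
    if (degenerate) {
      q <- if (d == 0) 0 else Inf
      p <- if (d == 0) 1 else NA_real_
    } else {
      q <- abs(d) / sqrt(mse / n_per_cell)
      p <- 1 - ptukey_range(q, k, df_resid)
      p <- min(max(p, 0), 1)
    }
    tibble::tibble(group_1 = g1, group_2 = g2, diff = d, q = q, p_adj = p)
  })
  out <- dplyr::bind_rows(res)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$stars <- significance_stars(out$p_adj)
  structure(out, class = class(out), degenerate = degenerate)
}

#' Significance stars
#'
#' The study's star mapping: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001; `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.0001 ~ "****",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
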