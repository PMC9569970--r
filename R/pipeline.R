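TRACING_COLUMNS <- c("sample_id", "analyte", "fragment_id", "isotopologue",
                     "intensity")

#' Read and validate a long-format tracing intensity table
#'
#' Expected columns: `sample_id`, `analyte`, `fragment_id`, `isotopologue`
#' (integer m+k), `intensity` (non-negative); extra columns (e.g. `mz`,
#' `line_id`, `subtype`, `treatment`, `replicate`) pass through. Schema
#' violations are reported with row numbers.
#'
#' @param path CSV file path.
#' @return Validated tibble.
#' @export
read_tracing_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_tracing_table(df)
}

#' @rdname read_tracing_csv
#' @param df A data frame already in memory.
#' @export
validate_tracing_table <- function(df) {
  missing_cols <- setdiff(TRACING_COLUMNS, names(df))
  if (length(missing_cols)) {
    abort(paste("tracing table missing column(s):",
                paste(missing_cols, collapse = ", ")),
          class = "ppptrace_schema_error")
  }
  bad <- which(is.na(df$intensity) | df$intensity < 0)
  if (length(bad)) {
    abort(paste("negative or missing intensity at row(s):",
                paste(head(bad, 10), collapse = ", ")),
          class = "ppptrace_schema_error")
  }
  bad <- which(is.na(df$isotopologue) | df$isotopologue < 0 |
                 df$isotopologue != round(df$isotopologue))
  if (length(bad)) {
    abort(paste("isotopologue must be a non-negative integer; bad row(s):",
                paste(head(bad, 10), collapse = ", ")),
          class = "ppptrace_schema_error")
  }
  bad <- which(!df$analyte %in% names(BACKBONE_CARBONS))
  if (length(bad)) {
    abort(paste("unknown analyte at row(s):",
                paste(head(bad, 10), collapse = ", ")),
          class = "ppptrace_schema_error")
  }
  tibble::as_tibble(df)
}

# Collapse a long intensity table into one mid per sample x fragment.
mids_from_table <- function(df, fragments = default_fragments()) {
  split_keys <- interaction(df$sample_id, df$fragment_id, drop = TRUE)
  parts <- split(df, split_keys)
  lapply(parts, function(part) {
    frag <- fragments[[part$fragment_id[1]]]
    if (is.null(frag)) {
      abort(sprintf("fragment_id '%s' not in registry", part$fragment_id[1]),
            class = "ppptrace_invalid_fragment")
    }
    part <- part[order(part$isotopologue), ]
    n <- n_fragment_carbons(frag)
    raw <- numeric(n + 1L)
    raw[part$isotopologue + 1L] <- part$intensity
    list(sample_id = part$sample_id[1],
         fragment_id = part$fragment_id[1],
         meta = part[1, setdiff(names(part),
                                c("isotopologue", "intensity", "mz")), drop = FALSE],
         mid = normalize_intensities(raw, analyte = frag$analyte,
                                     fragment_id = frag$fragment_id))
  })
}

#' End-to-end tracing analysis
#'
#' Chains the full workflow: simulate (or accept a measured long-format
#' table) -> normalize intensities -> correct each MID for natural
#' abundance and tracer impurity -> estimate the PPP fraction per sample
#' with both the closed-form ratio estimator and the bounded least-squares
#' estimator -> compare groups. When the sample metadata carry `subtype`
#' and `treatment` with a balanced design, a two-way ANOVA of the
#' per-sample ratio estimates (C2-C3 fragment) with Tukey HSD is included.
#'
#' @param config A [simulation_config()]; used to simulate when
#'   `intensities` is `NULL`, and for the tracer specification always.
#' @param intensities Optional measured long-format table (see
#'   [read_tracing_csv()]); when supplied, no simulation happens.
#' @param n_boot Bootstrap resamples for per-group confidence intervals on
#'   the pooled least-squares estimate; 0 (default) skips the bootstrap.
#' @param out_dir Optional directory; when given, `estimates.csv`,
#'   `group_estimates.csv` and (if computed) `anova.csv` / `tukey.csv` are
#'   written there.
#' @return List with `estimates` (tidy per-sample tibble: sample_id,
#'   analyte, fragment_id, estimator, f_ppp, ci_low, ci_high, flags),
#'   `group_estimates` (pooled per line x treatment x fragment), `anova`,
#'   `tukey`, and `corrected` (list of corrected [mid()]s).
#' @export
run_tracing <- function(config = simulation_config(), intensities = NULL,
                        n_boot = 0, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- NULL
  if (is.null(intensities)) {
    sim <- simulate_tracing_dataset(config)
    intensities <- sim$intensities
    truth <- sim$truth
  } else {
    intensities <- validate_tracing_table(intensities)
  }
  fragments <- default_fragments()
  cms <- lapply(fragments, build_correction_matrix, tracer = config$tracer)

  entries <- mids_from_table(intensities, fragments)
  est_rows <- list()
  corrected <- list()
  for (e in entries) {
    cm <- cms[[e$fragment_id]]
    corr <- correct_mid(e$mid, cm)
    corrected[[paste(e$sample_id, e$fragment_id, sep = "|")]] <- corr
    frag <- fragments[[e$fragment_id]]
    for (est in list(estimate_fppp_ratio(corr, frag),
                     estimate_fppp_lsq(corr, frag))) {
      est_rows[[length(est_rows) + 1L]] <- dplyr::bind_cols(
        e$meta,
        tibble::tibble(estimator = est$estimator, f_ppp = est$f_ppp,
                       ci_low = est$ci_low, ci_high = est$ci_high,
                       flags = paste(est$flags, collapse = ";"))
      )
    }
  }
  estimates <- dplyr::bind_rows(est_rows)

  # pooled per-group estimates (replicates of one line x treatment x fragment)
  grp_cols <- intersect(c("line_id", "subtype", "treatment", "fragment_id"),
                        names(estimates))
  group_estimates <- NULL
  if (all(c("line_id", "treatment") %in% grp_cols)) {
    keys <- estimates[estimates$estimator == "least_squares", grp_cols]
    keys <- dplyr::distinct(keys)
    g_rows <- list()
    for (i in seq_len(nrow(keys))) {
      key <- keys[i, ]
      ids <- estimates$estimator == "least_squares"
      for (col in grp_cols) ids <- ids & estimates[[col]] == key[[col]]
      samp_ids <- unique(estimates$sample_id[ids])
      mids <- corrected[paste(samp_ids, key$fragment_id, sep = "|")]
      frag <- fragments[[key$fragment_id]]
      est <- if (n_boot >= 100 && length(mids) >= 2) {
        bootstrap_ci(unname(mids), frag, n_boot = n_boot, seed = config$seed)
      } else {
        estimate_fppp_lsq(unname(mids), frag)
      }
      g_rows[[length(g_rows) + 1L]] <- dplyr::bind_cols(
        key,
        tibble::tibble(n_replicates = length(mids), f_ppp = est$f_ppp,
                       ci_low = est$ci_low, ci_high = est$ci_high)
      )
    }
    group_estimates <- dplyr::bind_rows(g_rows)
  }

  # two-way ANOVA of ratio estimates on the disambiguating fragment
  anova_res <- NULL; tukey_res <- NULL
  av_data <- estimates[estimates$estimator == "ratio" &
                         estimates$fragment_id == "lactate_c23", ]
  if (all(c("subtype", "treatment") %in% names(av_data)) &&
      nrow(av_data) > 0 &&
      length(unique(av_data$subtype)) >= 2 &&
      length(unique(av_data$treatment)) >= 2) {
    counts <- table(av_data$subtype, av_data$treatment)
    if (all(counts == counts[1, 1]) && counts[1, 1] >= 2) {
      anova_res <- two_way_anova(av_data, value = "f_ppp",
                                 factor_a = "subtype", factor_b = "treatment")
      cm_means <- attr(anova_res, "cell_means")
      means <- setNames(as.vector(cm_means),
                        as.vector(outer(rownames(cm_means), colnames(cm_means),
                                        paste, sep = ":")))
      tukey_res <- tukey_hsd(means, attr(anova_res, "mse"),
                             attr(anova_res, "df_resid"),
                             attr(anova_res, "n_per_cell"))
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(estimates, file.path(out_dir, "estimates.csv"),
                     row.names = FALSE)
    if (!is.null(group_estimates)) {
      utils::write.csv(group_estimates,
                       file.path(out_dir, "group_estimates.csv"),
                       row.names = FALSE)
    }
    if (!is.null(anova_res)) {
      utils::write.csv(as.data.frame(anova_res),
                       file.path(out_dir, "anova.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(tukey_res),
                       file.path(out_dir, "tukey.csv"), row.names = FALSE)
    }
  }
  list(estimates = estimates, group_estimates = group_estimates,
       anova = anova_res, tukey = tukey_res, corrected = corrected,
       truth = truth)
}

#' End-to-end survival comparison
#'
#' Median-splits a continuous expression covariate into high/low groups,
#' builds Kaplan-Meier curves per group, and tests the difference with the
#' log-rank (Mantel-Cox) test.
#'
#' @param data Tibble with columns `time`, `event`, `expression`
#'   (e.g. from [simulate_survival()]).
#' @param out_dir Optional directory for `km_curves.csv` and
#'   `logrank.csv`.
#' @return List with `groups`, `km` (tibble of both curves with a `group`
#'   column), `logrank`, and a one-line `summary` string with the star
#'   annotation.
#' @export
run_survival <- function(data, out_dir = NULL) {
  if (!all(c("time", "event", "expression") %in% names(data))) {
    abort("data must have columns time, event, expression",
          class = "ppptrace_schema_error")
  }
  groups <- median_split(data$expression)
  km <- dplyr::bind_rows(lapply(levels(groups), function(g) {
    sel <- groups == g
    dplyr::bind_cols(tibble::tibble(group = g),
                     km_curve(data$time[sel], data$event[sel]))
  }))
  lr <- logrank_test(data$time, data$event, groups)
  summary_line <- sprintf(
    "log-rank chi-square = %.4f, p = %.4g (%s); n_low = %d, n_high = %d",
    lr$statistic, lr$p, significance_stars(lr$p), lr$n[1], lr$n[2])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(km, file.path(out_dir, "km_curves.csv"),
                     row.names = FALSE)
    utils::write.csv(
      tibble::tibble(statistic = lr$statistic, p = lr$p,
                     observed = lr$observed, expected = lr$expected),
      file.path(out_dir, "logrank.csv"), row.names = FALSE)
  }
  list(groups = groups, km = km, logrank = lr, summary = summary_line)
}
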