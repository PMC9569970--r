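#' Positional isotopomer of a backbone-carbon metabolite
#'
#' A positional isotopomer records *which* backbone carbons of a metabolite
#' carry \eqn{^{13}}C, together with a relative molar weight. Isotopologues
#' (mass shifts m+0, m+1, ...) only count labels; positional isotopomers keep
#' their location, which is what lets a sub-fragment ion disambiguate labeling
#' routes that share a total label count.
#'
#' Carbon positions are 1-based throughout the package: C1 is the carboxyl
#' carbon of lactate/pyruvate and the aldehyde carbon of glucose.
#'
#' @param analyte One of `"lactate"`, `"pyruvate"`, `"glucose"`.
#' @param labeled_positions Integer vector of backbone positions carrying
#'   \eqn{^{13}}C (possibly empty).
#' @param weight Non-negative relative molar amount.
#' @return An object of class `positional_isotopomer`.
#' @examples
#' positional_isotopomer("lactate", c(1, 3))   # [1,3-13C2]lactate
#' positional_isotopomer("lactate", integer()) # unlabeled [12C3]lactate
#' @export
positional_isotopomer <- function(analyte, labeled_positions, weight = 1) {
  analyte <- match.arg(analyte, names(BACKBONE_CARBONS))
  n <- BACKBONE_CARBONS[[analyte]]
  labeled_positions <- as.integer(sort(unique(labeled_positions)))
  if (length(labeled_positions) &&
      (min(labeled_positions) < 1L || max(labeled_positions) > n)) {
    abort(
      sprintf("labeled positions must lie in 1..%d for %s", n, analyte),
      class = "ppptrace_invalid_input"
    )
  }
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) || weight < 0) {
    abort("weight must be a single non-negative number",
          class = "ppptrace_invalid_input")
  }
  carbon_labels <- rep(FALSE, n)
  carbon_labels[labeled_positions] <- TRUE
  structure(
    list(analyte = analyte, carbon_labels = carbon_labels, weight = weight),
    class = "positional_isotopomer"
  )
}

#' @export
format.positional_isotopomer <- function(x, ...) {
  pos <- which(x$carbon_labels)
  lab <- if (length(pos) == 0L) {
    sprintf("[12C%d]", length(x$carbon_labels))
  } else {
    sprintf("[13C%d-%s]", length(pos), paste(pos, collapse = ","))
  }
  sprintf("%s%s (weight %.6g)", lab, x$analyte, x$weight)
}

#' @export
print.positional_isotopomer <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' GC-MS fragment-ion specification
#'
#' Describes which backbone carbons a measured ion retains, its nominal
#' unlabeled m/z, and optionally the full elemental formula of the ion
#' (needed only for full-formula isotope correction).
#'
#' @param analyte Analyte name (`"lactate"`, `"pyruvate"`, `"glucose"`).
#' @param fragment_id Short identifier, unique within the registry.
#' @param retained_carbons Integer vector of backbone positions present in
#'   the ion; must be non-empty and within the backbone range.
#' @param base_mz Nominal m/z of the unlabeled ion (> 0).
#' @param formula Optional elemental formula string of the ion,
#'   e.g. `"C6H13O3Si"`, used by full-formula correction.
#' @param label Free-text description.
#' @return An object of class `fragment_spec`.
#' @seealso [default_fragments()] for the shipped registry.
#' @export
fragment_spec <- function(analyte, fragment_id, retained_carbons, base_mz,
                          formula = NULL, label = fragment_id) {
  analyte <- match.arg(analyte, names(BACKBONE_CARBONS))
  n <- BACKBONE_CARBONS[[analyte]]
  retained_carbons <- as.integer(sort(unique(retained_carbons)))
  if (length(retained_carbons) == 0L ||
      min(retained_carbons) < 1L || max(retained_carbons) > n) {
    abort(
      sprintf("retained_carbons must be a non-empty subset of 1..%d for %s",
              n, analyte),
      class = "ppptrace_invalid_fragment"
    )
  }
  if (!is.numeric(base_mz) || length(base_mz) != 1L || base_mz <= 0) {
    abort("base_mz must be a single positive number",
          class = "ppptrace_invalid_fragment")
  }
  structure(
    list(analyte = analyte, fragment_id = fragment_id,
         retained_carbons = retained_carbons, base_mz = base_mz,
         formula = formula, label = label),
    class = "fragment_spec"
  )
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat(sprintf("<fragment_spec> %s / %s: carbons {%s}, base m/z %g\n",
              x$analyte, x$fragment_id,
              paste(x$retained_carbons, collapse = ","), x$base_mz))
  invisible(x)
}

n_fragment_carbons <- function(fragment) length(fragment$retained_carbons)

#' Tracer specification for [1,2-13C2]glucose
#'
#' Records which glucose carbons the tracer nominally labels, the per-position
#' isotopic purity (probability that a nominally labeled position actually
#' carries \eqn{^{13}}C), and the natural \eqn{^{13}}C abundance used for
#' correction.
#'
#' @param labeled_positions Glucose carbons labeled by the tracer
#'   (default `c(1, 2)`).
#' @param purity Per-position label probability in `[0, 1]` (default 0.99).
#' @param nat_abund_13C Natural \eqn{^{13}}C abundance in `[0, 0.5)`
#'   (default 0.0107).
#' @return An object of class `tracer_spec`.
#' @export
tracer_spec <- function(labeled_positions = c(1L, 2L), purity = 0.99,
                        nat_abund_13C = 0.0107) {
  labeled_positions <- as.integer(sort(unique(labeled_positions)))
  if (length(labeled_positions) == 0L || min(labeled_positions) < 1L ||
      max(labeled_positions) > BACKBONE_CARBONS[["glucose"]]) {
    abort("labeled_positions must be glucose carbons in 1..6",
          class = "ppptrace_invalid_input")
  }
  if (!is.numeric(purity) || length(purity) != 1L || purity < 0 || purity > 1) {
    abort("purity must be a single value in [0, 1]",
          class = "ppptrace_invalid_input")
  }
  if (!is.numeric(nat_abund_13C) || nat_abund_13C < 0 || nat_abund_13C >= 0.5) {
    abort("nat_abund_13C must lie in [0, 0.5)",
          class = "ppptrace_invalid_input")
  }
  structure(
    list(labeled_positions = labeled_positions, purity = purity,
         nat_abund_13C = nat_abund_13C),
    class = "tracer_spec"
  )
}

MID_SUM_TOL <- 1e-9

#' Mass-isotopologue distribution (MID)
#'
#' Fractional abundances of the m+0 ... m+n isotopologues of one analyte
#' fragment ion, where n is the number of backbone carbons the ion retains.
#' Fractions must be non-negative and sum to 1 (tolerance 1e-9); the
#' constructor renormalizes exact inputs but rejects vectors that are not
#' already close to a distribution.
#'
#' @param fractions Numeric vector of length n+1 over m+0 ... m+n.
#' @param analyte Analyte name.
#' @param fragment_id Fragment identifier.
#' @return An object of class `mid`.
#' @export
mid <- function(fractions, analyte = NA_character_, fragment_id = NA_character_) {
  if (!is.numeric(fractions) || length(fractions) < 1L || anyNA(fractions)) {
    abort("fractions must be a numeric vector without NAs",
          class = "ppptrace_invalid_input")
  }
  if (any(fractions < -MID_SUM_TOL)) {
    abort("MID fractions must be non-negative",
          class = "ppptrace_invalid_input")
  }
  fractions <- pmax(fractions, 0)
  s <- sum(fractions)
  if (abs(s - 1) > 1e-6) {
    abort(sprintf("MID fractions must sum to 1 (got %.8g)", s),
          class = "ppptrace_invalid_input")
  }
  fractions <- fractions / s
  stopifnot(abs(sum(fractions) - 1) <= MID_SUM_TOL)
  structure(
    list(fractions = as.numeric(fractions), analyte = analyte,
         fragment_id = fragment_id),
    class = "mid"
  )
}

#' @export
print.mid <- function(x, digits = 4, ...) {
  labs <- paste0("m+", seq_along(x$fractions) - 1L)
  cat(sprintf("<mid> %s / %s\n",
              x$analyte %||% NA, x$fragment_id %||% NA))
  print(setNames(round(x$fractions, digits), labs))
  invisible(x)
}

#' Project weighted positional isotopomers onto a fragment-ion MID
#'
#' Each isotopomer contributes its weight to the isotopologue bin equal to
#' the number of labeled carbons among the carbons the fragment retains;
#' the result is normalized to sum 1. This is how the C2-C3 lactate fragment
#' separates PPP-derived \[1,3-13C2\] (m+1 in the fragment) from glycolytic
#' \[2,3-13C2\] (m+2 in the fragment) although both are m+2 on the full ion.
#'
#' @param isotopomers List of [positional_isotopomer()] objects sharing the
#'   fragment's analyte, with total weight > 0.
#' @param fragment A [fragment_spec()].
#' @return A [mid()] with n+1 bins, n = number of retained carbons.
#' @examples
#' frag <- fragment_spec("lactate", "c23", c(2, 3), 117)
#' positional_to_mid(list(positional_isotopomer("lactate", c(1, 3))), frag)
#' @export
positional_to_mid <- function(isotopomers, fragment) {
  stopifnot(inherits(fragment, "fragment_spec"))
  if (!is.list(isotopomers) || length(isotopomers) == 0L) {
    abort("isotopomers must be a non-empty list",
          class = "ppptrace_invalid_input")
  }
  ok <- vapply(isotopomers, inherits, logical(1), "positional_isotopomer")
  if (!all(ok)) {
    abort("all elements must be positional_isotopomer objects",
          class = "ppptrace_invalid_input")
  }
  analytes <- vapply(isotopomers, function(x) x$analyte, character(1))
  if (!all(analytes == fragment$analyte)) {
    abort("all isotopomers must share the fragment's analyte",
          class = "ppptrace_invalid_input")
  }
  weights <- vapply(isotopomers, function(x) x$weight, numeric(1))
  total <- sum(weights)
  if (total <= 0) {
    abort("total isotopomer weight must be positive",
          class = "ppptrace_invalid_input")
  }
  n <- n_fragment_carbons(fragment)
  bins <- numeric(n + 1L)
  for (iso in isotopomers) {
    k <- sum(iso$carbon_labels[fragment$retained_carbons])
    bins[k + 1L] <- bins[k + 1L] + iso$weight
  }
  mid(bins / total, analyte = fragment$analyte,
      fragment_id = fragment$fragment_id)
}

#' Normalize raw isotopologue intensities to a MID
#'
#' Converts integrated extracted-ion-chromatogram intensities for the
#' m+0 ... m+n ions of one analyte fragment into fractional abundances.
#'
#' @param raw Non-negative intensity vector ordered m+0 ... m+n, with at
#'   least one strictly positive entry.
#' @inheritParams mid
#' @return A [mid()].
#' @export
normalize_intensities <- function(raw, analyte = NA_character_,
                                  fragment_id = NA_character_) {
  if (!is.numeric(raw) || length(raw) < 1L || anyNA(raw)) {
    abort("raw must be a numeric vector without NAs",
          class = "ppptrace_invalid_intensity")
  }
  if (any(raw < 0)) {
    abort("intensities must be non-negative",
          class = "ppptrace_invalid_intensity")
  }
  if (sum(raw) <= 0) {
    abort("all-zero intensity vector: degenerate sample",
          class = "ppptrace_degenerate_sample")
  }
  mid(raw / sum(raw), analyte = analyte, fragment_id = fragment_id)
}

#' Shipped fragment registry
#'
#' The three ions the tracing workflow measures for derivatized pyruvate and
#' lactate: the full-backbone \[M-CH3\]+ ions (all of C1-C3) and the lactate
#' fragment retaining only C2-C3 (m/z 117/118/119 for m+0/m+1/m+2). Full-ion
#' base m/z values are nominal registry configuration for reporting only; the
#' carbon-only isotope correction never uses them.
#'
#' @return Named list of [fragment_spec()] objects with entries
#'   `lactate_full`, `lactate_c23`, `pyruvate_full`.
#' @export
default_fragments <- function() {
  list(
    lactate_full = fragment_spec("lactate", "lactate_full", 1:3, 219,
                                 label = "lactate [M-CH3]+ full backbone C1-C3"),
    lactate_c23 = fragment_spec("lactate", "lactate_c23", 2:3, 117,
                                label = "lactate fragment retaining C2-C3"),
    pyruvate_full = fragment_spec("pyruvate", "pyruvate_full", 1:3, 174,
                                  label = "pyruvate [M-CH3]+ full backbone C1-C3")
  )
}
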