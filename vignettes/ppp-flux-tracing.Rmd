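---
title: "Partitioning glucose catabolism with [1,2-13C2]glucose: model, correction and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning glucose catabolism with [1,2-13C2]glucose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppptrace)
```

## The tracing problem

Cultured cells fed [1,2-^13^C~2~]glucose route the tracer through two
competing catabolic branches. Glycolysis cleaves fructose 1,6-bisphosphate
into two trioses; the triose carrying glucose carbons C1–C3 keeps both
labels, so one labeled glucose yields one [2,3-^13^C~2~]lactate (m+2) and one
unlabeled lactate. The oxidative pentose phosphate pathway (PPP)
decarboxylates glucose C1 — destroying one of the two labels — and the
non-oxidative branch reassembles three pentoses into trioses, so three
glucose molecules passing the PPP yield one [1,3-^13^C~2~]lactate, one
[3-^13^C~1~]lactate (m+1) and three unlabeled lactate. The m+1 share of
pyruvate/lactate therefore reports PPP activity while m+2 reports
glycolysis.

A complication: [1,3-^13^C~2~]lactate from the PPP is *also* m+2 on the full
backbone ion, indistinguishable from glycolytic [2,3-^13^C~2~]lactate by
mass alone. A GC-MS fragment ion of the lactate derivative that retains only
carbons C2–C3 (m/z 117/118/119 for m+0/1/2) resolves this: the PPP
isotopomer loses its C1 label and registers m+1, the glycolytic isotopomer
keeps both labels and stays m+2. The shipped fragment registry
(`default_fragments()`) carries exactly these ions; full-ion base m/z values
are nominal configuration because the derivatization chemistry is not
modeled.

## The forward model and its assumptions

`forward_isotopomers(f_ppp, tracer)` mixes the two branch stoichiometries at
the glucose fraction `f_ppp` entering the PPP. It is deliberately
**single-pass**: no recycling of PPP-derived fructose 6-phosphate back into
the PPP, no reverse non-oxidative exchange, and no relabeling through TCA or
pyruvate cycling. These are real phenomena in long labeling experiments; the
package models the product stoichiometry above and nothing more, and
estimates from data where recycling matters will be biased accordingly.

With tracer purity 1, composing the branch outputs with the fragment
projection gives closed forms in `p = f_ppp`:

* full C1–C3 ion: `(m0, m1, m2) = (3, p, 3 - 2p) / (6 - p)`
* C2–C3 fragment: `(m0, m1, m2) = (3, 2p, 3 - 3p) / (6 - p)`

`f_ppp` is parameterized as the fraction of glucose *molecules* entering the
oxidative PPP. Because one glucose yields 2 trioses by glycolysis but only
5/3 by a single PPP pass, the share of triose products that saw the PPP is
the derived quantity `5p/(6 - p)`, exposed read-only on every
`flux_partition`. Lactate and pyruvate share one labeling distribution (the
same carbon map); imperfect tracer purity is modeled per labeled position as
independent Bernoulli events, so each product label is present with the
probability of the glucose carbon it derives from.

```{r forward}
expected_mid(0.5, default_fragments()$lactate_c23, tracer_spec(purity = 1))
```

## Isotope correction

Measured MIDs convolve the tracer signal with ~1.07% natural ^13^C on
unlabeled carbons and with tracer impurity. `build_correction_matrix()`
constructs the operator column by column: column *j* is the measured
distribution of a molecule with exactly *j* tracer-derived labels (each
retained with probability `purity`, the remaining carbons heavy at the
natural abundance). The default `carbon_only` mode corrects backbone ^13^C
and impurity; `full_formula` mode additionally convolves the natural
heavy-isotope distributions of every other atom in a user-supplied ion
formula (H, N, O, Si, S). It is off by default because the derivative — and
hence the true ion formula — is not part of the model; both behaviors are
available and neither is asserted as "the" setting used upstream.

Correction solves the non-negative least-squares problem
min‖Mx − y‖², x ≥ 0 (via `pracma::lsqnonneg`) and renormalizes, rather than
inverting M directly: inversion of these near-triangular operators amplifies
measurement noise into negative bins, while NNLS guarantees a distribution.
Distributions are truncated to the observed n+1 bins and renormalized —
the instrument records only those masses — which introduces a small bias
that grows with natural abundance and ion size; at 3-carbon ions it is
negligible. Forward-then-inverse round trips are identities to 1e-8, tested
for 100 random MIDs per registry fragment.

## Estimating the PPP fraction

Two estimators act on *corrected* MIDs (tracer-label space, so the purity-1
closed forms apply):

* `estimate_fppp_ratio()` inverts the closed forms through `r = m1/m2`:
  `p = 3r/(2 + 3r)` (fragment) or `p = 3r/(1 + 2r)` (full ion). Degenerate
  inputs are flagged, not errored: `m2 = 0, m1 > 0` reports `p = 1`;
  `m1 = m2 = 0` reports `p = 0`; out-of-range inversions (possible after
  correcting noisy data) clamp to [0, 1] with a `clamped` flag.
* `estimate_fppp_lsq()` minimizes the squared distance between the mean
  replicate MID and the model over `p` in [0, 1] by bounded scalar
  minimization (tolerance 1e-10, endpoints polished). The objective is
  unimodal on [0, 1] for these fragments (asserted on a grid in the tests),
  so no multi-start is needed. On noiseless input the two estimators agree
  to 1e-6.

`bootstrap_ci()` resamples replicates with replacement and reports the
percentile (2.5/97.5) interval of the least-squares estimate, deterministic
given its seed. **Limitation:** with the triplicate-to-sextuplicate
replication typical of these assays, percentile intervals undercover —
at 6 replicates and 5% noise the interval contains the truth in roughly
84% of repeats rather than 95%. The interval is reported as a resampling
summary, not an exact confidence procedure; the unit tests pin this behavior
rather than asserting nominal coverage.

## What the synthetic generator emulates — and what it does not

`simulate_tracing_dataset()` generates, for each line × treatment ×
replicate and each registry ion, the model MID at the line's PPP fraction,
convolves it through the correction operator (natural abundance plus
impurity), scales to a log-normal total intensity, and applies
multiplicative log-normal noise per bin. Log-normal noise was chosen because
GC-MS peak areas are positive with roughly concentration-stable CV; the
default CV is 5%. Ground truth goes to a sidecar table so recovery analyses
cannot accidentally read it.

The default panel mirrors the study design it emulates: two proneural-like
lines at `f_ppp = 0.3` with low glucose turnover and two mesenchymal-like
lines at `f_ppp = 0.1` with high turnover, triplicate, with metformin arms
(0.01/1/10 mM as metadata) that lower `f_ppp` and raise glucose consumption
and lactate output. Where the emulated study prints no quantitative value
(the PPP fractions themselves, rates, noise), the defaults are one-time
choices of values a metabolomics practitioner would call realistic for
glioblastoma stem-like cultures; they are fixed study conditions, not tuning
knobs.

What the generator does **not** emulate: chromatographic peak shape and
integration error, retention-time drift, detector saturation, carry-over,
cross-contamination of fragment windows, metabolite recycling, or
between-batch effects. Passing recovery tests therefore show that the
estimator chain is correct *under the model's own noise assumptions*, not
that real instruments are this well behaved.

Sister simulators cover the supporting assays: `simulate_exometabolome()`
(linear isotope-dilution calibration, concentrations from consumption /
production rates over 48 h, glucose floored at the physical zero),
`simulate_survival()` (exponential event times, hazard scaled by expression
side, independent censoring at a uniform fraction of the event time), and
`simulate_ecar_trace()` (piecewise-constant phase means with additive
noise).

## Inferential statistics

The study-style inference layer is implemented from first principles and
cross-checked in the tests against independent routes (`aov`, `ptukey`,
`survdiff`, `survfit`):

* `two_way_anova()` — classical balanced fixed-effects decomposition.
  Unbalanced input raises an explicit error instead of silently choosing
  among Type-I/II/III sums of squares; the emulated designs are triplicate
  and balanced, so this restriction costs nothing and avoids a silent
  modeling decision. Zero residual variance is reported as degenerate with
  the convention F = 0, p = 1 for equal means.
* `tukey_hsd()` — studentized-range statistic with p-values from the range
  distribution computed by nested numerical quadrature (tolerance 1e-8).
* `median_split()` — values strictly above the median are "high"; ties go
  to "low", a deterministic rule chosen because "above versus below the
  median" leaves the tie case undefined.
* `logrank_test()` / `km_curve()` — Mantel–Cox statistic from hypergeometric
  moments at each event time; product-limit survival.
* Stars follow the convention `*` p<0.05, `**` p<0.01, `***` p<0.001,
  `****` p<0.0001.

## Problem sizes and numerical choices

The test suite and acceptance script use: dense estimator grids at 0.01
spacing; 100 random MIDs per fragment for correction round trips; 100 seeded
panel runs (4 lines × 3 replicates, 5% CV) for parameter recovery; 1000
seeded null cohorts of 50 + 50 subjects for log-rank type-I calibration; and
scaled-down property checks elsewhere (150 null datasets for the
uniformity KS check, 40 repeats × 300 resamples for bootstrap behavior).
These sizes were chosen as the smallest that make the Monte-Carlo bands
stable; all are fixed-seed and deterministic.

Tolerances: MID sum-to-1 at 1e-9 after normalization; correction round trip
1e-8; ratio-estimator round trip 1e-9; optimizer tolerance 1e-10; quadrature
1e-8. Ties, degenerate inputs and clamping behaviors are described above
where they arise.

## Known limitations

* Single-pass atom fate: recycling, exchange and compartmentation biases
  are out of scope by design.
* Percentile bootstrap undercoverage at small replicate counts (above).
* Truncation/renormalization of the correction operator at m+n is a small
  high-abundance bias.
* The unit system of the assay layer is deliberately agnostic: rates carry
  whatever concentration unit the calibration was built in.
* Survival comparisons are univariate median splits — no adjustment for
  covariates, so they inherit every caveat of marginal survival contrasts.
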