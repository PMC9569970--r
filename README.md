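# ppptrace

Partitioning glucose catabolism between glycolysis and the oxidative
pentose phosphate pathway (PPP) from [1,2-¹³C₂]glucose stable-isotope
tracing, with the supporting assay computations a metabolic phenotyping
study needs: isotopologue correction, isotope-dilution quantitation,
glycolysis-stress metrics, balanced two-way ANOVA with Tukey HSD, and
median-split survival comparison. A synthetic-data module generates every
input the pipeline consumes, so the whole chain is testable without
instrument data.

## Who this is for

Metabolomics and cancer-metabolism researchers who run [1,2-¹³C₂]glucose
tracing on cultured cells (e.g. glioblastoma stem-like cells of proneural
vs. mesenchymal character) and want a scripted, reproducible route from
integrated GC-MS isotopologue intensities to a PPP/glycolysis flux
partition with uncertainty and group statistics.

## The model

Feeding [1,2-¹³C₂]glucose, the two branches leave distinct fingerprints on
pyruvate/lactate:

* **Glycolysis** — one glucose → one [2,3-¹³C₂]lactate (m+2) + one
  unlabeled lactate.
* **Oxidative PPP** — glucose C1 (one label) is lost as CO₂; three glucose
  → one [1,3-¹³C₂]lactate + one [3-¹³C₁]lactate (m+1) + three unlabeled
  lactate.

With *p* the fraction of glucose entering the PPP, the expected
mass-isotopologue distribution (MID) of the lactate C2–C3 fragment ion
(m/z 117/118/119) is

    (m0, m1, m2) = (3, 2p, 3 − 3p) / (6 − p)

and of the full C1–C3 ion `(3, p, 3 − 2p) / (6 − p)`. The C2–C3 fragment is
what disambiguates the two m+2 isotopomers: PPP-derived [1,3-¹³C₂]lactate
drops to m+1 in the fragment while glycolytic [2,3-¹³C₂]lactate stays m+2.
Measured MIDs are corrected for natural ¹³C abundance and tracer impurity
by non-negative least squares against a correction operator built per
fragment; *p* is then recovered by closed-form ratio inversion
(`p = 3r/(2+3r)`, `r = m1/m2`, fragment mode) or bounded least squares,
with bootstrap percentile intervals over replicates.

## Worked example

Simulate the default panel (two proneural-like lines at f_PPP = 0.3, two
mesenchymal-like at 0.1, triplicate, 5% CV), correct, estimate and compare:

```r
library(ppptrace)
cfg <- simulation_config(treatments = default_treatments(full = TRUE),
                         seed = 20260901)
res <- run_tracing(cfg, n_boot = 500)
subset(res$group_estimates,
       fragment_id == "lactate_c23" & treatment == "control")
```

```
  line_id subtype      f_ppp ci_low ci_high
1 BTIC18L proneural   0.289  0.260    0.312
2 BTIC8L  proneural   0.282  0.266    0.298
3 BTIC13L mesenchymal 0.112  0.0817   0.135
4 BTIC11L mesenchymal 0.0979 0.0819   0.120
```

The pooled estimates recover the simulated PPP fractions (0.3 / 0.1) within
a few hundredths and the proneural > mesenchymal ordering; `res$anova`
holds the two-way ANOVA of the per-sample estimates (subtype × treatment;
subtype F ≈ 2798, p ≈ 1e-38 on this seed) and `res$tukey` the pairwise
Tukey comparisons with star annotations. The numbered scripts under
`analysis/` run the same steps as a narrative workflow — `01` simulates,
`02` corrects/estimates, `03` quantifies extracellular glucose/lactate and
converts them to per-µg-protein rates, `04` computes glycolysis-stress
metrics, `05` runs the median-split survival comparison — writing their
tables under `results/`.

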