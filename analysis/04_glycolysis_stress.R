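#!/usr/bin/env Rscript
# Glycolysis stress test on simulated ECAR traces: a mesenchymal-like
# profile with high glycolytic capacity versus a proneural-like profile
# with modest capacity. Computes glycolysis, glycolytic capacity and
# glycolytic reserve from the phase means.

suppressPackageStartupMessages(library(ppptrace))

profiles <- list(
  proneural_like   = list(basal = 8,  glucose = 25, oligo = 33, dg2 = 6),
  mesenchymal_like = list(basal = 12, glucose = 45, oligo = 80, dg2 = 9)
)

rows <- list()
for (nm in names(profiles)) {
  pr <- profiles[[nm]]
  for (rep_i in 1:3) {
    trace <- simulate_ecar_trace(pr$basal, pr$glucose, pr$oligo, pr$dg2,
                                 noise = 1.5, seed = 100 * rep_i + match(nm, names(profiles)))
    m <- glycolysis_stress_metrics(trace)
    rows[[length(rows) + 1L]] <- data.frame(
      profile = nm, replicate = rep_i,
      non_glycolytic = m$non_glycolytic, glycolysis = m$glycolysis,
      glycolytic_capacity = m$glycolytic_capacity,
      glycolytic_reserve = m$glycolytic_reserve)
  }
}
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
utils::write.csv(tab, "results/glycolysis_stress_metrics.csv",
                 row.names = FALSE)
agg <- aggregate(cbind(glycolysis, glycolytic_capacity, glycolytic_reserve)
                 ~ profile, tab, mean)
print(agg, digits = 3)
cat("\nThe mesenchymal-like profile shows the higher ECAR and glycolytic reserve.\n")
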