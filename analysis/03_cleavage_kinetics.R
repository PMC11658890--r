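#!/usr/bin/env Rscript
# Cleavage kinetics track: simulate single-turnover time courses at the
# rate constants measured for the four enzyme variants on the
# DNA-melting substrates (nine-point schedule, Gaussian noise, n = 3),
# fit Y = Ymax (1 - exp(-k t)) per condition, and compare substrates by
# rate fold change. The headline comparison: on the suboptimal
# 5'-N4GAAA PAM the wild-type enzyme needs the 2-bp-mismatch (melted)
# substrate to reach the fast regime (~5-fold over its linear-substrate
# rate), while the WED-mutant enzymes are fast on the linear substrate.

library(pamkin)

conditions <- list(
  # enzyme, substrate, true k (min^-1), Ymax
  list(id = "WT_linear_GAAA",   k = 0.04, ymax = 0.85),
  list(id = "R1_linear_GAAA",   k = 0.05, ymax = 0.85),
  list(id = "iGeo_linear_GAAA", k = 0.40, ymax = 0.90),
  list(id = "KGR_linear_GAAA",  k = 0.30, ymax = 0.90),
  list(id = "WT_mm_GAAA",       k = 0.20, ymax = 0.90),
  list(id = "WT_linear_CAAA",   k = 0.30, ymax = 0.90),
  list(id = "iGeo_linear_CAAA", k = 0.40, ymax = 0.90))

tab <- do.call(rbind, lapply(seq_along(conditions), function(i) {
  cc <- conditions[[i]]
  tc <- simulate_cleavage_timecourse(cc$k, cc$ymax, noise_sd = 0.02,
                                     n_replicates = 3, seed = 300L + i)
  cbind(condition = cc$id, as.data.frame(tc))
}))

report <- run_kinetics_pipeline(
  tab, output_dir = file.path("results", "cleavage_kinetics"),
  model = "cleavage",
  fold_requests = list(c("WT_mm_GAAA", "WT_linear_GAAA"),
                       c("iGeo_linear_GAAA", "WT_linear_GAAA")))

for (cc in conditions) {
  r <- report$conditions[[cc$id]]
  cat(sprintf("%-18s true k = %.2f  fitted k = %.3f min^-1\n",
              cc$id, cc$k, r$mean_k))
}
for (nm in names(report$fold_changes)) {
  cat(sprintf("fold change %s: %.2f\n", nm, report$fold_changes[[nm]]))
}
cat("tables: results/cleavage_kinetics/fit_summary.tsv, fit_report.json\n")
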