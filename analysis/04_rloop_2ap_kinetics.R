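#!/usr/bin/env Rscript
# R-loop formation track: simulate 2-aminopurine unwinding traces under
# magnesium-restricted conditions (0.1 mM MgCl2), where early R-loop
# formation is similar for both enzymes (~0.03 s^-1) but the wild type
# slows ~3.3-fold at the mid stage and stalls at the late stage, while
# the engineered enzyme keeps 0.03 s^-1 throughout. Traces are sampled
# every 20 s; fits are per replicate with Y0 fixed to the blank, then
# averaged (mean +/- SD, n = 3); a late-stage amplitude below the 100 AU
# floor is reported as nd.

library(pamkin)

conditions <- list(
  list(id = "WT_early",   k = 0.030, ymax = 3500),
  list(id = "iGeo_early", k = 0.030, ymax = 3500),
  list(id = "WT_mid",     k = 0.009, ymax = 3000),
  list(id = "iGeo_mid",   k = 0.030, ymax = 3000),
  list(id = "WT_late",    k = 0.005, ymax = 50),    # stalled: nd amplitude
  list(id = "iGeo_late",  k = 0.030, ymax = 2500))

tab <- do.call(rbind, lapply(seq_along(conditions), function(i) {
  cc <- conditions[[i]]
  s <- simulate_2ap_trace(cc$k, cc$ymax, y0 = 500, duration = 600,
                          noise_sd = 15, n_replicates = 3,
                          seed = 400L + i)
  cbind(condition = cc$id, as.data.frame(s$trace),
        blank = attr(s$trace, "blank_mean"))
}))

report <- run_kinetics_pipeline(
  tab, output_dir = file.path("results", "rloop_2ap"),
  model = "two_ap", time_unit = "second",
  fold_requests = list(c("iGeo_mid", "WT_mid")))

for (cc in conditions) {
  r <- report$conditions[[cc$id]]
  k <- if (identical(r$mean_k, "nd")) "nd"
       else sprintf("%.4f +/- %.4f s^-1 (n=%d)", r$mean_k, r$sd_k, r$n)
  cat(sprintf("%-10s true k = %.3f  fitted k_obs = %s\n", cc$id, cc$k, k))
}
cat(sprintf("mid-stage fold change iGeo vs WT: %.2f\n",
            report$fold_changes[["iGeo_mid vs WT_mid"]]))
cat("tables: results/rloop_2ap/fit_summary.tsv, fit_report.json\n")
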