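#!/usr/bin/env Rscript
# Run the depletion track end to end on the simulated libraries:
# extract PAMs -> depth-normalize -> log2FC vs untreated -> threshold from
# the non-targeting controls (99.9999% one-sided bound) -> significant set
# -> logo -> IUPAC consensus. Expect the constricted experiment to call
# {CAAA, CTAA} with consensus CWAA and the relaxed one to call the 64
# C-initial PAMs with consensus CNNN.

library(pamkin)

for (name in c("constricted", "relaxed")) {
  manifest <- file.path("results", paste0("manifest_", name, ".tsv"))
  if (!file.exists(manifest)) {
    stop("run analysis/01_simulate_depletion_libraries.R first")
  }
  report <- run_pam_pipeline(manifest,
                             output_dir = file.path("results",
                                                    paste0("pam_", name)))
  res <- report$samples$targeting
  cat(sprintf("%s: threshold = %.3f, %d significant PAMs, consensus %s\n",
              name, report$threshold, res$n_significant, res$consensus))
}
cat("tables: results/pam_*/depletion_targeting.tsv, logo_targeting.tsv\n")
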