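#!/usr/bin/env Rscript
# Simulate the two PAM depletion experiments the depletion track analyzes:
# a constricted recognizer that fully cleaves 5'-N4CWAA-3' PAMs (the
# wild-type enzyme's behavior) and a relaxed recognizer cleaving all
# C-initial PAMs (the engineered variant). Each experiment has one
# untreated library, three non-targeting controls and one targeting
# sample. FASTQ goes to scratch/ (bulky); manifests and ground truth to
# results/.

library(pamkin)

reads_per_sample <- 50000L
lib <- default_pam_library()
samples <- data.frame(
  sample_id = c("untreated", "ntc1", "ntc2", "ntc3", "targeting"),
  role = c("untreated", rep("non_targeting", 3), "targeting"))

dir.create("results", showWarnings = FALSE)
for (exp in list(list(name = "constricted", pattern = "CWAA", seed = 101L),
                 list(name = "relaxed", pattern = "CNNN", seed = 202L))) {
  model <- recognition_model(list(list(pattern = exp$pattern,
                                       probability = 1)))
  plan <- simulation_plan(lib, model, reads_per_sample, samples,
                          seed = exp$seed)
  out <- file.path("scratch", "analysis", exp$name)
  sim <- simulate_pam_library_reads(plan, out)
  manifest <- data.frame(sample_id = names(sim$files),
                         role = samples$role, path = unname(sim$files))
  write.table(manifest,
              file.path("results", paste0("manifest_", exp$name, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d samples x %d reads, planted pattern %s -> %s\n",
              exp$name, nrow(samples), reads_per_sample, exp$pattern, out))
}
cat("done: manifests in results/, reads + ground truth in scratch/analysis/\n")
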