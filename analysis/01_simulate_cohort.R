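#!/usr/bin/env Rscript
# Simulate the 10-patient synthetic cohort and write every sample's raw
# inputs as plain text: junction BEDPE, binned read-depth BED, SNP
# allele-count TSV, mutation TSV and the per-patient ground-truth JSON.
# The cohort is a pure function of the seed, so later scripts regenerate it
# deterministically instead of reading intermediate state.

library(svlineage)

seed <- 20
out <- "results/cohort_data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- toy_genome()
cfg <- sim_config()
cohort <- run_simulated_cohort(cfg, genome, n_patients = 10, seed = seed)

n_samples <- 0
for (pid in names(cohort$simulations)) {
  sim <- cohort$simulations[[pid]]
  pdir <- file.path(out, pid)
  dir.create(pdir, showWarnings = FALSE)
  for (s in names(sim$call_sets)) {
    write_junction_bedpe(sim$call_sets[[s]]$junctions,
                         file.path(pdir, paste0(s, ".junctions.bedpe")))
    write_depth_bed(sim$depth_profiles[[s]],
                    file.path(pdir, paste0(s, ".depth.bed")))
    write_allele_tsv(sim$allele_profiles[[s]],
                     file.path(pdir, paste0(s, ".alleles.tsv")))
    write_mutation_tsv(sim$mutation_tables[[s]],
                       file.path(pdir, paste0(s, ".mutations.tsv")))
    n_samples <- n_samples + 1
  }
  write_ground_truth_json(sim$truth, file.path(pdir, "ground_truth.json"))
}

cat(sprintf("Simulated %d patients (%d samples) under %s\n",
            length(cohort$simulations), n_samples, out))
cat("Components per patient:\n")
for (pid in names(cohort$simulations)) {
  m <- cohort$simulations[[pid]]$truth$meta
  cat(sprintf("  %s: %s\n", pid, paste(m$histology, collapse = ", ")))
}
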