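#!/usr/bin/env Rscript
# Arm-level aneuploidy across the synthetic cohort: per-sample karyotypes,
# the samples x arms aneuploidy matrix, 12p-gain detection per histology and
# shared gains/losses between components of the same patient.

library(svlineage)

seed <- 20
out <- "results/cnv"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- toy_genome()
cohort <- run_simulated_cohort(sim_config(), genome, n_patients = 10,
                               seed = seed)

arms <- chrom_arms(genome)$arm
mat <- NULL
i12p_rows <- NULL
for (pid in names(cohort$patients)) {
  res <- cohort$patients[[pid]]
  for (s in names(res$karyotypes)) {
    mat <- rbind(mat, data.frame(sample_id = s,
                                 histology = res$filtered[[s]]$histology,
                                 t(res$karyotypes[[s]]$states),
                                 check.names = FALSE))
  }
  i12p_rows <- rbind(i12p_rows,
                     cbind(res$i12p,
                           histology = vapply(res$filtered[res$i12p$sample_id],
                                              `[[`, "", "histology")))
  write.table(res$cnv_comparison, file.path(out, paste0(pid, "_shared_cnv.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(mat, file.path(out, "aneuploidy_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(i12p_rows, file.path(out, "i12p_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("12p gain by histology (fraction of components with state >= 3N):\n")
print(aggregate(gain_12p ~ histology, i12p_rows, mean))
inv <- !(i12p_rows$histology %in% c("normal", "GCNIS"))
cat(sprintf("\n12p gain in %d/%d invasive components (states %s)\n",
            sum(i12p_rows$gain_12p[inv]), sum(inv),
            paste(sort(unique(i12p_rows$state_12p[inv])), collapse = "-")))
cat(sprintf("12p gain in %d/%d GCNIS/normal components\n",
            sum(i12p_rows$gain_12p[!inv]), sum(!inv)))
cat(sprintf("\nArtefacts written under %s/\n", out))
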