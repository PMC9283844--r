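#!/usr/bin/env Rscript

# Cell-type deconvolution of the simulated cohort: parses each sample's
# stranded methylation BED, collapses strands onto probes, runs NNLS
# against the reference atlas over the marker-probe union, and compares
# the estimated celltype_E ("tumor") fraction with the simulated truth.
# Run analysis/01_simulate_cohort.R first.

suppressMessages(library(cfmix))

sim_dir <- "scratch/sim"
cohort <- read.table("results/cohort_truth.tsv", header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
atlas <- read_atlas(file.path(sim_dir, "atlas.csv"))
probe_map <- read_probe_map(file.path(sim_dir, "probe_map.tsv"))
mk <- marker_union(atlas, 50)

rows <- lapply(cohort$sample, function(s) {
  calls <- parse_modbed(file.path(sim_dir, paste0(s, ".meth.bed")))
  pb <- collapse_strands(calls, probe_map)
  fit <- nnls_fractions(setNames(pb$beta, pb$probe_id), atlas, mk)
  data.frame(sample = s, component = names(fit$fractions),
             fraction = unname(fit$fractions),
             n_probes = fit$n_probes_used, stringsAsFactors = FALSE)
})
fractions <- do.call(rbind, rows)
write.table(fractions, "results/deconvolution_fractions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

est <- fractions$fraction[fractions$component == "celltype_E"]
err <- est - cohort$tumor_fraction
message(sprintf(
  "tumor-component fraction: truth vs estimate MAE = %.4f (max %.4f)",
  mean(abs(err)), max(abs(err))))
summary_df <- data.frame(cohort, estimated_tumor_fraction = est,
                         error = err)
write.table(summary_df, "results/deconvolution_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/deconvolution_fractions.tsv and ",
        "results/deconvolution_summary.tsv")
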