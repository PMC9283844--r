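#!/usr/bin/env Rscript

# Fragmentomics of the simulated cohort: filters fragment tables with
# the standard cfDNA predicates, computes short mono-/dinucleosome
# ratios and length histograms per sample, and runs the differential
# 4-mer end-motif test (healthy vs cancer) on per-sample frequencies.
# Run analysis/01_simulate_cohort.R first.

suppressMessages(library(cfmix))

sim_dir <- "scratch/sim"
cohort <- read.table("results/cohort_truth.tsv", header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)

ratio_rows <- list()
motif_tabs <- list()
hist_rows <- list()
for (i in seq_len(nrow(cohort))) {
  s <- cohort$sample[i]
  frags <- read_fragments(file.path(sim_dir,
                                    paste0(s, ".fragments.tsv")))
  frags <- suppressMessages(filter_fragments(frags))
  ratio_rows[[i]] <- data.frame(
    sample = s, group = cohort$group[i],
    short_mono_ratio = short_mono_ratio(frags$length),
    short_di_ratio = short_di_ratio(frags$length),
    n_fragments = nrow(frags), stringsAsFactors = FALSE)
  h <- length_histogram(frags$length)
  h$sample <- s
  hist_rows[[i]] <- h[h$count > 0, ]
  motif_tabs[[s]] <- motif_frequencies(
    readLines(file.path(sim_dir, paste0(s, ".motifs.txt"))))
}
ratios <- do.call(rbind, ratio_rows)
write.table(ratios, "results/fragment_ratios.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, hist_rows), "results/length_histograms.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

by_group <- split(ratios$short_mono_ratio, ratios$group)
message(sprintf(
  "short mono ratio: healthy mean %.3f, cancer mean %.3f (t p = %.3g)",
  mean(by_group$healthy), mean(by_group$cancer),
  t_test(by_group$cancer, by_group$healthy, "greater")$p_value))

healthy_tabs <- motif_tabs[cohort$sample[cohort$group == "healthy"]]
cancer_tabs <- motif_tabs[cohort$sample[cohort$group == "cancer"]]
diff_tbl <- motif_differential(healthy_tabs, cancer_tabs)
write.table(diff_tbl, "results/motif_differential.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("top differential end motif: ", diff_tbl$motif[1],
        sprintf(" (p = %.3g, q = %.3g)", diff_tbl$p_value[1],
                diff_tbl$q_value[1]))
message("wrote results/fragment_ratios.tsv, results/length_histograms.tsv, ",
        "results/motif_differential.tsv")
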