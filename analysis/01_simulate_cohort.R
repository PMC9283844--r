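#!/usr/bin/env Rscript

# Simulates a small plasma cfDNA cohort (4 healthy donors, 3 lung-cancer
# patients) with known ground truth and writes every input dialect the
# downstream analyses consume: reference atlas CSV, probe map TSV,
# per-sample stranded methylation BED (modbam2bed dialect), fragment
# tables, and the ground-truth manifest. Raw simulated inputs go under
# scratch/sim/ (regenerated on demand); summary truth tables under
# results/.

suppressMessages(library(cfmix))

seed <- 20260101
sim_dir <- "scratch/sim"
dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

## Reference atlas with planted cell-type markers
sa <- simulate_atlas(n_components = 5, seed = seed)
write_atlas(sa$atlas, file.path(sim_dir, "atlas.csv"))

## Cohort design: tumor-bearing samples carry celltype_E (the "tumor"
## methylome) at increasing fractions on top of a leukocyte-dominated
## background; healthy samples have none.
cohort <- data.frame(
  sample = c(paste0("H", 1:4), paste0("C", 1:3)),
  group = rep(c("healthy", "cancer"), c(4, 3)),
  tumor_fraction = c(0, 0, 0, 0, 0.1, 0.2, 0.35),
  stringsAsFactors = FALSE
)
base_w <- c(0.55, 0.25, 0.12, 0.08, 0)  # plasma-like background

probe_map <- NULL
for (i in seq_len(nrow(cohort))) {
  tf <- cohort$tumor_fraction[i]
  w <- c(base_w[1:4] * (1 - tf), tf)
  mx <- simulate_mixture_calls(sa$atlas, w, coverage = 30,
                               seed = seed + i)
  write_modbed(mx$calls, file.path(sim_dir,
                                   paste0(cohort$sample[i], ".meth.bed")))
  probe_map <- mx$probe_map
}
write.table(probe_map, file.path(sim_dir, "probe_map.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## Fragment tables: tumor fraction drives the short-fragment shift and
## the CCCA end-motif depletion.
for (i in seq_len(nrow(cohort))) {
  sf <- simulate_fragments(20000, tumor_prop = cohort$tumor_fraction[i],
                           seed = seed + 100 + i)
  write_fragments(sf$fragments,
                  file.path(sim_dir, paste0(cohort$sample[i],
                                            ".fragments.tsv")))
  writeLines(sf$truth$motif,
             file.path(sim_dir, paste0(cohort$sample[i], ".motifs.txt")))
}

write.table(cohort, "results/cohort_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("simulated ", nrow(cohort), " samples into ", sim_dir,
        "; ground truth in results/cohort_truth.tsv")
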