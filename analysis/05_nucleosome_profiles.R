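#!/usr/bin/env Rscript

# Nucleosome positioning around CTCF-like sites: simulates phased
# mononucleosome fragments, builds an RPGC-normalized coverage track,
# and extracts the reference-point metaplot. Reports where the profile
# minima/maxima fall relative to the simulated nucleosome grid.

suppressMessages(library(cfmix))
dir.create("results", showWarnings = FALSE)

sim <- simulate_ctcf_coverage(n_sites = 100, background_per_kb = 5,
                              seed = 20260105)
frags <- select_nucleosomal(sim$fragments)
track <- rpgc_normalize(compute_coverage(frags, sim$chrom_sizes),
                        effective_genome_size = sim$chrom_sizes)
rpm <- reference_point_matrix(track, sim$sites)

profile <- data.frame(bin_center = rpm$bin_center,
                      fold_change = rpm$mean_profile)
write.table(profile, "results/ctcf_metaprofile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

min_at <- profile$bin_center[which.min(profile$fold_change)]
peaks <- vapply(c(-570, -380, -190, 190, 380, 570), function(target) {
  win <- abs(profile$bin_center - target) <= 90
  profile$bin_center[win][which.max(profile$fold_change[win])]
}, numeric(1))
message("central depletion minimum at ", min_at, " bp; phased peaks at ",
        paste(peaks, collapse = ", "),
        " bp (simulated nucleosome grid: multiples of ",
        sim$truth$spacing, " bp)")
message("wrote results/ctcf_metaprofile.tsv")
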