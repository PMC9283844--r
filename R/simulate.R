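# Truth-known synthetic cfDNA generators. Each emits the exact dialects
# the analysis consumes plus a `truth` element used as the test oracle.
# All draws are reproducible given `seed`.

#' Simulate a reference methylation atlas with planted markers
#'
#' Each component receives `markers_per_component` hypomethylated
#' markers (target beta ~0.1, other components ~0.5) and as many
#' hypermethylated markers (target ~0.9); remaining probes are
#' background (~0.5 everywhere). Gaussian noise is added and betas are
#' clipped to [0, 1].
#'
#' @param n_components number of cell types
#' @param n_probes total probes (must fit all markers)
#' @param markers_per_component markers per direction per component
#' @param noise_sd beta noise standard deviation (0 for the noiseless
#'   limit)
#' @param beta_hypo,beta_hyper,beta_bg center betas for hypomethylated
#'   markers, hypermethylated markers and background probes
#' @param seed RNG seed
#' @return list with `atlas` ([ref_atlas]) and `truth` (probe_id,
#'   marker_type, component)
#' @export
simulate_atlas <- function(n_components = 5, n_probes = 2000,
                           markers_per_component = 50, noise_sd = 0.03,
                           beta_hypo = 0.1, beta_hyper = 0.9,
                           beta_bg = 0.5, seed = 1) {
  stopifnot(2 * n_components * markers_per_component <= n_probes)
  with_seed(seed, {
    probe_ids <- sprintf("cg%06d", seq_len(n_probes))
    comps <- paste0("celltype_", LETTERS[seq_len(n_components)])
    betas <- matrix(beta_bg, nrow = n_probes, ncol = n_components,
                    dimnames = list(probe_ids, comps))
    truth <- data.frame(probe_id = probe_ids, marker_type = "background",
                        component = NA_character_,
                        stringsAsFactors = FALSE)
    idx <- 1L
    for (k in seq_len(n_components)) {
      hypo <- idx:(idx + markers_per_component - 1L)
      hyper <- (idx + markers_per_component):
        (idx + 2L * markers_per_component - 1L)
      betas[hypo, k] <- beta_hypo
      betas[hyper, k] <- beta_hyper
      truth$marker_type[hypo] <- "hypo"
      truth$marker_type[hyper] <- "hyper"
      truth$component[c(hypo, hyper)] <- comps[k]
      idx <- idx + 2L * markers_per_component
    }
    if (noise_sd > 0) {
      betas <- clip01(betas + rnorm(length(betas), sd = noise_sd))
    }
    list(atlas = ref_atlas(betas), truth = truth)
  })
}

#' Simulate stranded CpG calls for a plasma mixture of atlas components
#'
#' Per probe, read depth is Poisson(`coverage`), each read comes from
#' component k with probability `fractions[k]` and is methylated with
#' that component's probe beta (so the methylated count is binomial with
#' the mixture beta). Reads are split randomly across the two strands of
#' the CpG, exercising strand collapsing downstream.
#'
#' @param atlas `ref_atlas`
#' @param fractions simplex weight vector over atlas components
#' @param coverage mean reads per CpG
#' @param seed RNG seed
#' @return list with `calls` (stranded CpG call data frame),
#'   `probe_map`, and `truth` (the input fractions)
#' @export
simulate_mixture_calls <- function(atlas, fractions, coverage = 30,
                                   seed = 1) {
  b <- atlas$betas
  stopifnot(length(fractions) == ncol(b),
            abs(sum(fractions) - 1) < 1e-8)
  with_seed(seed, {
    p_mix <- as.numeric(b %*% fractions)
    n_probe <- nrow(b)
    n <- rpois(n_probe, coverage)
    n_fwd <- rbinom(n_probe, n, 0.5)
    n_rev <- n - n_fwd
    m_fwd <- rbinom(n_probe, n_fwd, p_mix)
    m_rev <- rbinom(n_probe, n_rev, p_mix)
    pos_fwd <- 10L * seq_len(n_probe)
    probe_map <- data.frame(probe_id = rownames(b), chrom = "chrS",
                            pos = pos_fwd, stringsAsFactors = FALSE)
    calls <- rbind(
      data.frame(chrom = "chrS", pos = pos_fwd, strand = "+",
                 n_reads = n_fwd, beta = ifelse(n_fwd > 0, m_fwd / n_fwd, NA),
                 stringsAsFactors = FALSE),
      data.frame(chrom = "chrS", pos = pos_fwd + 1L, strand = "-",
                 n_reads = n_rev, beta = ifelse(n_rev > 0, m_rev / n_rev, NA),
                 stringsAsFactors = FALSE)
    )
    calls <- sort_genomic(calls[calls$n_reads > 0L, , drop = FALSE])
    rownames(calls) <- NULL
    list(calls = calls, probe_map = probe_map,
         truth = setNames(fractions, colnames(b)))
  })
}

#' Simulate a PMD genome: solo-WCGW CpG calls, bins and CN segments
#'
#' The genome is divided into 10-Mbp bins, each carrying one copy-number
#' state for the tumor (1 = loss, 2 = neutral, 3 = gain). The local
#' tumor-DNA proportion in a bin with tumor copy number c is
#' `p = c*tf / (c*tf + 2*(1-tf))`, which skews the solo-WCGW methylation
#' mixture `(1-p)*beta_healthy_pmd + p*beta_tumor_pmd`. Background CpGs
#' (methylation unaffected by the tumor, as for CpGs outside PMDs)
#' dominate the genome-wide mean. CN segments carry
#' `log2ratio = log2((c*tf + 2*(1-tf)) / 2)`.
#'
#' @param tumor_fraction cfDNA tumor fraction in [0, 1]
#' @param n_bins number of 10-Mbp bins
#' @param cn_states integer tumor copy number per bin (default: equal
#'   thirds of 1, 2 and 3)
#' @param solo_per_bin solo-WCGW CpGs per bin
#' @param bg_per_bin background CpGs per bin
#' @param beta_healthy_pmd,beta_tumor_pmd solo-WCGW betas in healthy and
#'   tumor DNA
#' @param beta_bg background CpG beta
#' @param coverage mean reads per CpG
#' @param seed RNG seed
#' @return list with `calls`, `solo_wcgw`, `bins`, `segments`, and
#'   `truth` (per-bin copy number and local tumor proportion)
#' @export
simulate_pmd_genome <- function(tumor_fraction = 0.3, n_bins = 150,
                                cn_states = NULL, solo_per_bin = 300,
                                bg_per_bin = 5700,
                                beta_healthy_pmd = 0.8,
                                beta_tumor_pmd = 0.4, beta_bg = 0.8,
                                coverage = 1, seed = 1) {
  tf <- tumor_fraction
  stopifnot(tf >= 0, tf <= 1)
  if (is.null(cn_states)) {
    stopifnot(n_bins %% 3 == 0)
    cn_states <- rep(c(1L, 2L, 3L), each = n_bins %/% 3)
  }
  stopifnot(length(cn_states) == n_bins)
  with_seed(seed, {
    bin_size <- 1e7
    bins <- data.frame(chrom = "chrP",
                       start = as.numeric((seq_len(n_bins) - 1L) * bin_size),
                       end = as.numeric(seq_len(n_bins) * bin_size),
                       stringsAsFactors = FALSE)
    p_local <- cn_states * tf / (cn_states * tf + 2 * (1 - tf))
    solo_beta_true <- (1 - p_local) * beta_healthy_pmd +
      p_local * beta_tumor_pmd
    solo_pos <- unlist(lapply(seq_len(n_bins), function(i) {
      bins$start[i] + round(seq(1e5, bin_size - 1e5,
                                length.out = solo_per_bin))
    }))
    bg_pos <- unlist(lapply(seq_len(n_bins), function(i) {
      bins$start[i] + round(seq(1e5 + 7, bin_size - 1e5 - 7,
                                length.out = bg_per_bin))
    }))
    beta_true <- c(rep(solo_beta_true, each = solo_per_bin),
                   rep(beta_bg, n_bins * bg_per_bin))
    pos <- c(solo_pos, bg_pos)
    n <- rpois(length(pos), coverage)
    keep <- n > 0L
    m <- rbinom(sum(keep), n[keep], beta_true[keep])
    calls <- data.frame(chrom = "chrP", pos = pos[keep], strand = "+",
                        n_reads = n[keep], beta = m / n[keep],
                        stringsAsFactors = FALSE)
    calls <- sort_genomic(calls)
    rownames(calls) <- NULL
    mix_copy <- cn_states * tf + 2 * (1 - tf)
    segments <- data.frame(chrom = "chrP", start = bins$start,
                           end = bins$end,
                           log2ratio = log2(mix_copy / 2),
                           stringsAsFactors = FALSE)
    list(calls = calls,
         solo_wcgw = data.frame(chrom = "chrP", pos = solo_pos,
                                stringsAsFactors = FALSE),
         bins = bins, segments = segments,
         truth = data.frame(bin = seq_len(n_bins), cn = cn_states,
                            p_local = p_local,
                            solo_beta = solo_beta_true))
  })
}

# Class-specific 4-mer end-motif multinomial: uniform base with the
# CCCA mass set explicitly and the remainder spread evenly.
motif_multinomial <- function(ccca = 0.025) {
  probs <- rep((1 - ccca) / 255, 256)
  names(probs) <- all_4mers()
  probs["CCCA"] <- ccca
  probs
}

#' Simulate cfDNA fragments from a healthy/tumor mixture
#'
#' Fragment lengths come from a mono/dinucleosome normal mixture whose
#' modes are shorter for tumor-derived fragments; each fragment's 4-mer
#' end motif is drawn from its class multinomial. With
#' `build_reference = TRUE` fragments are placed at non-overlapping
#' positions on a synthetic chromosome whose sequence is constructed so
#' that [end_motif()] re-derives exactly the drawn motif (plus strand:
#' motif planted at the fragment start; minus strand: its reverse
#' complement planted at the fragment end).
#'
#' @param n_fragments number of fragments
#' @param tumor_prop proportion of tumor-derived fragments
#' @param mono_weight probability a fragment is mononucleosomal
#' @param mono_healthy,di_healthy,mono_tumor,di_tumor `c(mode, sd)`
#'   length parameters per class
#' @param motif_probs_healthy,motif_probs_tumor named 256-vectors of
#'   motif probabilities (default: CCCA at 0.025 in healthy and 0.015 in
#'   tumor, the depletion direction seen in cancer plasma)
#' @param build_reference also emit the synthetic reference chromosome
#' @param seed RNG seed
#' @return list with `fragments`, `reference`
#'   ([Biostrings::DNAStringSet] or `NULL`) and `truth` (class,
#'   nucleosome class and drawn motif per fragment)
#' @export
simulate_fragments <- function(n_fragments = 20000, tumor_prop = 0,
                               mono_weight = 0.85,
                               mono_healthy = c(167, 12),
                               di_healthy = c(335, 25),
                               mono_tumor = c(147, 12),
                               di_tumor = c(305, 25),
                               motif_probs_healthy = motif_multinomial(0.025),
                               motif_probs_tumor = motif_multinomial(0.015),
                               build_reference = FALSE, seed = 1) {
  with_seed(seed, {
    is_tumor <- runif(n_fragments) < tumor_prop
    is_mono <- runif(n_fragments) < mono_weight
    mode <- ifelse(is_tumor,
                   ifelse(is_mono, mono_tumor[1], di_tumor[1]),
                   ifelse(is_mono, mono_healthy[1], di_healthy[1]))
    sd <- ifelse(is_tumor,
                 ifelse(is_mono, mono_tumor[2], di_tumor[2]),
                 ifelse(is_mono, mono_healthy[2], di_healthy[2]))
    len <- pmin(700L, pmax(60L, as.integer(round(rnorm(n_fragments,
                                                       mode, sd)))))
    motifs <- all_4mers()
    motif <- character(n_fragments)
    motif[is_tumor] <- sample(motifs, sum(is_tumor), replace = TRUE,
                              prob = motif_probs_tumor)
    motif[!is_tumor] <- sample(motifs, sum(!is_tumor), replace = TRUE,
                               prob = motif_probs_healthy)
    spacing <- 710L
    start <- (seq_len(n_fragments) - 1L) * spacing + 50L
    strand <- rep(c("+", "-"), length.out = n_fragments)
    frags <- data.frame(
      chrom = "chrF", start = start, end = start + len, length = len,
      mapq = 60L, strand = strand, cigar = paste0(len, "M"),
      is_primary = TRUE, softclip_start = FALSE, softclip_end = FALSE,
      barcode_both_ends = TRUE, stringsAsFactors = FALSE)
    reference <- NULL
    if (build_reference) {
      glen <- max(frags$end) + 100L
      bases <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
      plus <- strand == "+"
      motif_chars <- matrix(unlist(strsplit(motif, "")), nrow = 4L)
      for (j in 0:3) {
        # plant at [start, start+4) for plus, revcomp at [end-4, end) for minus
        bases[frags$start[plus] + 1L + j] <- motif_chars[j + 1L, plus]
        bases[frags$end[!plus] - j] <-
          chartr("ACGT", "TGCA", motif_chars[j + 1L, !plus])
      }
      reference <- Biostrings::DNAStringSet(
        setNames(paste(bases, collapse = ""), "chrF"))
    }
    list(fragments = frags, reference = reference,
         truth = data.frame(is_tumor = is_tumor,
                            nucleosome = ifelse(is_mono, "mono", "di"),
                            motif = motif, stringsAsFactors = FALSE))
  })
}

#' Simulate phased-nucleosome fragment coverage around CTCF-like sites
#'
#' Bound CTCF ejects the central nucleosome and phases `n_phased`
#' nucleosomes at multiples of `spacing` on either side. Fragments of
#' mononucleosomal length are drawn centered on each phased nucleosome
#' (with positional jitter) over a uniform background; background
#' fragments whose centers fall within +/-80 bp of a site are thinned by
#' `depletion`.
#'
#' @param n_sites number of sites
#' @param spacing nucleosome repeat length (bp)
#' @param n_phased phased nucleosomes per side
#' @param frags_per_nucleosome fragments drawn per phased nucleosome
#' @param background_per_kb background fragments per kb of genome
#' @param depletion probability a central background fragment is removed
#' @param jitter_sd positional jitter of nucleosome-bound fragments (bp)
#' @param len_mean,len_sd fragment length distribution (clamped to the
#'   130-155 bp nucleosomal band)
#' @param seed RNG seed
#' @return list with `fragments`, `sites`, `chrom_sizes` and `truth`
#'   (nucleosome center offsets)
#' @export
simulate_ctcf_coverage <- function(n_sites = 30, spacing = 190,
                                   n_phased = 10,
                                   frags_per_nucleosome = 40,
                                   background_per_kb = 2, depletion = 1,
                                   jitter_sd = 20, len_mean = 142,
                                   len_sd = 6, seed = 1) {
  with_seed(seed, {
    site_gap <- 6000L
    centers <- site_gap %/% 2L + site_gap * (seq_len(n_sites) - 1L)
    glen <- site_gap * n_sites + site_gap
    offsets <- if (n_phased > 0) {
      spacing * c(-(n_phased:1), 1:n_phased)
    } else integer()
    nuc_centers <- as.vector(outer(offsets, centers, `+`))
    n_nuc_frags <- length(nuc_centers) * frags_per_nucleosome
    nuc_mid <- rep(nuc_centers, each = frags_per_nucleosome) +
      round(rnorm(n_nuc_frags, 0, jitter_sd))
    n_bg <- round(background_per_kb * glen / 1000)
    bg_mid <- round(runif(n_bg, 1, glen))
    near_site <- vapply(bg_mid, function(m)
      any(abs(m - centers) <= 80), logical(1))
    drop_bg <- near_site & runif(n_bg) < depletion
    mid <- c(nuc_mid, bg_mid[!drop_bg])
    n <- length(mid)
    len <- pmin(155L, pmax(130L, as.integer(round(rnorm(n, len_mean,
                                                        len_sd)))))
    start <- pmax(0L, pmin(as.integer(mid - len %/% 2L),
                           as.integer(glen) - len))
    frags <- data.frame(
      chrom = "chrC", start = start, end = start + len, length = len,
      mapq = 60L, strand = sample(c("+", "-"), n, replace = TRUE),
      is_primary = TRUE, softclip_start = FALSE, softclip_end = FALSE,
      barcode_both_ends = TRUE, stringsAsFactors = FALSE)
    list(fragments = frags,
         sites = data.frame(chrom = "chrC", center = centers,
                            stringsAsFactors = FALSE),
         chrom_sizes = c(chrC = glen),
         truth = list(nucleosome_offsets = offsets, spacing = spacing))
  })
}

#' Simulate CpG methylation around TF binding sites
#'
#' CpGs are laid every `cpg_spacing` bp across +/-`half_window` of each
#' site; within +/-`effect_halfwidth` of the center the true beta is the
#' mixture `(1-f)*beta_bg + f*beta_low` (bound TF footprints are
#' demethylated in the signal-carrying cell population), elsewhere
#' `beta_bg`. Reads are Poisson/binomial sampled.
#'
#' @param n_sites number of sites
#' @param f signal fraction (e.g. tumor or lung fraction) in [0, 1]
#' @param beta_bg,beta_low background and fully-demethylated betas
#' @param coverage mean reads per CpG
#' @param cpg_spacing CpG spacing (bp)
#' @param half_window window half-width (bp)
#' @param effect_halfwidth demethylation half-width around the center
#' @param seed RNG seed
#' @return list with `calls`, `sites` and `truth` (expected center and
#'   flank betas)
#' @export
simulate_tfbs_methylation <- function(n_sites = 50, f = 0.3,
                                      beta_bg = 0.85, beta_low = 0.05,
                                      coverage = 30, cpg_spacing = 20,
                                      half_window = 1000,
                                      effect_halfwidth = 200, seed = 1) {
  with_seed(seed, {
    site_gap <- 2L * half_window + 2000L
    centers <- site_gap %/% 2L + site_gap * (seq_len(n_sites) - 1L)
    rel <- seq(-half_window + cpg_spacing %/% 2L,
               half_window - cpg_spacing %/% 2L, by = cpg_spacing)
    pos <- as.vector(outer(rel, centers, `+`))
    dist <- rep(rel, times = n_sites)
    beta_center <- (1 - f) * beta_bg + f * beta_low
    beta_true <- ifelse(abs(dist) <= effect_halfwidth, beta_center,
                        beta_bg)
    n <- rpois(length(pos), coverage)
    keep <- n > 0L
    m <- rbinom(sum(keep), n[keep], beta_true[keep])
    calls <- data.frame(chrom = "chrT", pos = pos[keep], strand = "+",
                        n_reads = n[keep], beta = m / n[keep],
                        stringsAsFactors = FALSE)
    calls <- sort_genomic(calls)
    rownames(calls) <- NULL
    list(calls = calls,
         sites = data.frame(chrom = "chrT", center = centers,
                            stringsAsFactors = FALSE),
         truth = list(beta_center = beta_center, beta_flank = beta_bg,
                      expected_fold_change = beta_center / beta_bg))
  })
}
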