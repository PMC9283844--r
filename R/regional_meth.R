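#' Pick the highest-scoring motif hit per peak
#'
#' Each peak containing at least one motif hit contributes exactly one
#' binding site: the hit with the highest match score, ties resolved to
#' the leftmost hit. Peaks without hits are dropped. The site center is
#' the midpoint of the winning hit interval.
#'
#' @param motif_hits data frame with `chrom`, `start`, `end`, `score`
#'   and optionally `strand` (0-based half-open intervals)
#' @param peaks data frame with `chrom`, `start`, `end`
#' @return data frame of sites with `chrom`, `center`, `strand`, `score`
#' @export
highest_score_motif_per_peak <- function(motif_hits, peaks) {
  if (nrow(motif_hits) == 0L || nrow(peaks) == 0L) {
    return(data.frame(chrom = character(), center = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  hit_gr <- GenomicRanges::GRanges(
    motif_hits$chrom,
    IRanges::IRanges(motif_hits$start + 1L, motif_hits$end))
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
  ov <- GenomicRanges::findOverlaps(hit_gr, peak_gr)
  if (length(ov) == 0L) {
    return(data.frame(chrom = character(), center = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  h <- S4Vectors::queryHits(ov)
  p <- S4Vectors::subjectHits(ov)
  # best hit per peak: max score, then leftmost start
  o <- order(p, -motif_hits$score[h], motif_hits$start[h])
  first <- !duplicated(p[o])
  win <- h[o][first]
  strand <- if ("strand" %in% names(motif_hits)) motif_hits$strand[win]
  else rep("+", length(win))
  out <- data.frame(
    chrom = motif_hits$chrom[win],
    center = as.integer(motif_hits$start[win] +
                          (motif_hits$end[win] - motif_hits$start[win]) %/% 2L),
    strand = strand,
    score = motif_hits$score[win],
    stringsAsFactors = FALSE
  )
  out[order(out$chrom, out$center, method = "radix"), , drop = FALSE]
}

#' Flank-normalized methylation metaplot around binding sites
#'
#' Pools every CpG within `half_window` of a site center into
#' signed-distance bins, averages betas per bin across all sites, and
#' normalizes by the mean over the flanking bins (distance 800-1000 bp on
#' either side), giving a fold change relative to the regional baseline.
#' Bins with no CpGs are reported missing, not zero.
#'
#' @param calls CpG call data frame (`chrom`, `pos`, `beta`)
#' @param sites data frame with `chrom`, `center`
#' @param half_window window half-width in bp
#' @param bin_width bin width in bp
#' @return data frame of class `meta_profile` with `bin_center`,
#'   `n_cpgs`, `mean_beta`, `fold_change`; the flank mean is attached as
#'   attribute `flank_mean`
#' @export
tfbs_meta_profile <- function(calls, sites, half_window = 1000,
                              bin_width = 20) {
  stopifnot(nrow(sites) > 0L)
  call_gr <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$pos + 1L, calls$pos + 1L))
  win_gr <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(pmax(sites$center - half_window + 1L, 1L),
                     sites$center + half_window))
  ov <- GenomicRanges::findOverlaps(call_gr, win_gr)
  ci <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  d <- calls$pos[ci] - sites$center[si]          # signed distance
  keep <- d >= -half_window & d < half_window
  d <- d[keep]; ci <- ci[keep]
  n_bins <- as.integer(2 * half_window / bin_width)
  bin <- floor((d + half_window) / bin_width) + 1L
  centers <- -half_window + bin_width * (seq_len(n_bins) - 0.5)
  n_cpgs <- tabulate(bin, nbins = n_bins)
  sum_beta <- rep(0, n_bins)
  agg <- tapply(calls$beta[ci], bin, sum)
  sum_beta[as.integer(names(agg))] <- agg
  mean_beta <- ifelse(n_cpgs > 0, sum_beta / n_cpgs, NA_real_)
  flank <- abs(centers) >= 800 & abs(centers) <= 1000
  flank_vals <- mean_beta[flank & n_cpgs > 0]
  flank_mean <- if (length(flank_vals)) mean(flank_vals) else NA_real_
  if (is.na(flank_mean) || flank_mean == 0) {
    warning("flank mean unavailable; fold change undefined")
    fc <- rep(NA_real_, n_bins)
  } else {
    fc <- mean_beta / flank_mean
  }
  out <- data.frame(bin_center = centers, n_cpgs = n_cpgs,
                    mean_beta = mean_beta, fold_change = fc)
  attr(out, "flank_mean") <- flank_mean
  class(out) <- c("meta_profile", "data.frame")
  out
}

#' Solo-WCGW methylation deltas in 10-Mbp PMD bins
#'
#' For each pre-defined genomic bin overlapping a common partially
#' methylated domain, averages the betas of the solo-WCGW CpGs it
#' contains and reports the difference from the genome-wide mean beta
#' over ALL CpG calls (not only solo-WCGW), so hypomethylated bins get
#' negative deltas. Bins with fewer than `min_cpgs` covered solo-WCGW
#' CpGs are emitted with a missing delta.
#'
#' @param calls CpG call data frame (`chrom`, `pos`, `beta`)
#' @param solo_wcgw data frame of solo-WCGW CpG positions (`chrom`,
#'   `pos`)
#' @param bins data frame of bins (`chrom`, `start`, `end`, 0-based
#'   half-open)
#' @param min_cpgs minimum covered solo-WCGW CpGs for a defined delta
#' @return data frame with bin coordinates, `n_cpgs`, `bin_beta`,
#'   `delta`; genome mean attached as attribute `genome_mean`
#' @export
pmd_bin_deltas <- function(calls, solo_wcgw, bins, min_cpgs = 10) {
  if (nrow(solo_wcgw) == 0L) stop("empty solo-WCGW CpG set", call. = FALSE)
  genome_mean <- mean(calls$beta)
  key <- paste0(solo_wcgw$chrom, ":", solo_wcgw$pos)
  solo <- calls[paste0(calls$chrom, ":", calls$pos) %in% key, , drop = FALSE]
  solo_gr <- GenomicRanges::GRanges(
    solo$chrom, IRanges::IRanges(solo$pos + 1L, solo$pos + 1L))
  bin_gr <- GenomicRanges::GRanges(
    bins$chrom, IRanges::IRanges(bins$start + 1L, bins$end))
  ov <- GenomicRanges::findOverlaps(solo_gr, bin_gr)
  bi <- S4Vectors::subjectHits(ov)
  n_cpgs <- tabulate(bi, nbins = nrow(bins))
  sums <- rep(0, nrow(bins))
  agg <- tapply(solo$beta[S4Vectors::queryHits(ov)], bi, sum)
  sums[as.integer(names(agg))] <- agg
  bin_beta <- ifelse(n_cpgs > 0, sums / n_cpgs, NA_real_)
  delta <- ifelse(n_cpgs >= min_cpgs, bin_beta - genome_mean, NA_real_)
  out <- data.frame(chrom = bins$chrom, start = bins$start,
                    end = bins$end, n_cpgs = n_cpgs,
                    bin_beta = bin_beta, delta = delta,
                    stringsAsFactors = FALSE)
  attr(out, "genome_mean") <- genome_mean
  out
}

#' Assign copy-number status to genomic bins from segment calls
#'
#' Each bin's log2 ratio is the overlap-length-weighted mean of the
#' overlapping segments' log2 ratios; status is gain above `gain_cut`,
#' loss below `loss_cut`, otherwise neutral; bins with no overlapping
#' segment get `NA`.
#'
#' @param bins data frame with `chrom`, `start`, `end`
#' @param segments data frame with `chrom`, `start`, `end`, `log2ratio`
#'   (non-overlapping within a sample)
#' @param gain_cut,loss_cut log2-ratio thresholds
#' @return `bins` with added `log2ratio` and `cn_status` columns
#' @export
assign_cn_status <- function(bins, segments, gain_cut = 0.10,
                             loss_cut = -0.10) {
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom, IRanges::IRanges(segments$start + 1L, segments$end))
  if (length(seg_gr) &&
      sum(IRanges::width(GenomicRanges::reduce(seg_gr))) <
        sum(IRanges::width(seg_gr))) {
    stop("segments overlap within the sample", call. = FALSE)
  }
  bin_gr <- GenomicRanges::GRanges(
    bins$chrom, IRanges::IRanges(bins$start + 1L, bins$end))
  ov <- GenomicRanges::findOverlaps(bin_gr, seg_gr)
  bi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(bin_gr)[bi], IRanges::ranges(seg_gr)[si]))
  num <- rep(0, nrow(bins)); den <- rep(0, nrow(bins))
  aggn <- tapply(w * segments$log2ratio[si], bi, sum)
  aggd <- tapply(w, bi, sum)
  num[as.integer(names(aggn))] <- aggn
  den[as.integer(names(aggd))] <- aggd
  l2r <- ifelse(den > 0, num / den, NA_real_)
  status <- ifelse(is.na(l2r), NA_character_,
                   ifelse(l2r > gain_cut, "gain",
                          ifelse(l2r < loss_cut, "loss", "neutral")))
  bins$log2ratio <- l2r
  bins$cn_status <- status
  bins
}

#' One-sided Wilcoxon comparison of bin deltas between groups
#'
#' Hypomethylation in cancer is a directional hypothesis, so the test is
#' one-sided by design; the direction is always an explicit argument.
#'
#' @param group_a_deltas,group_b_deltas numeric delta vectors (NAs
#'   dropped)
#' @param alternative direction of group A relative to group B
#' @return p-value
#' @export
compare_bins <- function(group_a_deltas, group_b_deltas,
                         alternative = "less") {
  a <- group_a_deltas[!is.na(group_a_deltas)]
  b <- group_b_deltas[!is.na(group_b_deltas)]
  stopifnot(length(a) > 0, length(b) > 0)
  wilcoxon_test(a, b, alternative = alternative)$p_value
}

#' Zero out unstable tumor-fraction estimates
#'
#' When copy-number alterations cover less than 15% of the genome the
#' tumor-fraction estimate is considered unstable and set to 0.
#'
#' @param tf_estimate non-negative tumor-fraction estimate
#' @param segments data frame with `chrom`, `start`, `end` and either a
#'   `cn_status` column or a `log2ratio` column (thresholded at +/-0.10)
#' @param genome_size total genome length in bp
#' @param min_altered_frac minimum altered genome fraction to trust the
#'   estimate
#' @return tumor fraction (possibly floored to 0)
#' @export
tumor_fraction_floor <- function(tf_estimate, segments, genome_size,
                                 min_altered_frac = 0.15) {
  stopifnot(tf_estimate >= 0)
  status <- if ("cn_status" %in% names(segments)) segments$cn_status
  else ifelse(segments$log2ratio > 0.10, "gain",
              ifelse(segments$log2ratio < -0.10, "loss", "neutral"))
  altered <- sum((segments$end - segments$start)[!is.na(status) &
                                                   status != "neutral"])
  if (altered / genome_size < min_altered_frac) 0 else tf_estimate
}
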