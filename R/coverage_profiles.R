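#' Select deduplicated mononucleosomal fragments
#'
#' Keeps fragments in the nucleosome-protected size band (130-155 bp by
#' default, inclusive) after collapsing duplicates, defined as identical
#' (chrom, start, end, strand).
#'
#' @param fragments fragment data frame
#' @param min_len,max_len inclusive length bounds (bp)
#' @return filtered fragment data frame
#' @export
select_nucleosomal <- function(fragments, min_len = 130, max_len = 155) {
  if (nrow(fragments) == 0L) return(fragments)
  dup <- duplicated(fragments[, c("chrom", "start", "end", "strand")])
  out <- fragments[!dup & fragments$length >= min_len &
                     fragments$length <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-base fragment coverage track
#'
#' Piles up fragment reference spans into a per-base coverage track
#' (run-length encoded per chromosome).
#'
#' @param fragments fragment data frame with `chrom`, `start`, `end`
#'   (0-based half-open)
#' @param chrom_sizes named integer vector of chromosome lengths
#' @return list of class `coverage_track` with `cov` (RleList),
#'   `total_frag_len`, `normalization`, `effective_genome_size`
#' @export
compute_coverage <- function(fragments, chrom_sizes) {
  gr <- GenomicRanges::GRanges(
    fragments$chrom,
    IRanges::IRanges(fragments$start + 1L, fragments$end),
    seqlengths = chrom_sizes)
  cov <- GenomicRanges::coverage(gr)
  structure(list(cov = cov,
                 total_frag_len = sum(fragments$end - fragments$start),
                 normalization = "raw",
                 effective_genome_size = NA_real_),
            class = "coverage_track")
}

#' Normalize a coverage track to reads per genomic content (RPGC)
#'
#' Multiplies every base by `effective_genome_size / total fragment
#' length`, so the mean coverage over the effective genome equals 1 and
#' the track reads directly as fold change over the genome average.
#'
#' @param track `coverage_track` from [compute_coverage()]
#' @param effective_genome_size mappable genome length in bp; the
#'   default is the standard GRCh38 effective size
#' @return RPGC-normalized `coverage_track`
#' @export
rpgc_normalize <- function(track, effective_genome_size = 2913022398) {
  if (track$total_frag_len <= 0) {
    stop("zero total coverage; cannot normalize", call. = FALSE)
  }
  scale <- effective_genome_size / track$total_frag_len
  track$cov <- track$cov * scale
  track$normalization <- "RPGC"
  track$effective_genome_size <- effective_genome_size
  track
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track (", x$normalization, ") over ",
      length(x$cov), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Coverage matrix around reference points
#'
#' One row per site, one column per signed-distance bin (bin means of
#' the track); positions beyond chromosome bounds are missing. Under
#' RPGC normalization the mean profile is the fold change over the
#' genome-wide average coverage.
#'
#' @param track `coverage_track`
#' @param sites data frame with `chrom`, `center` (0-based)
#' @param half_window half-width of the window (bp)
#' @param bin bin width (bp); must divide `2 * half_window`
#' @return list of class `refpoint_matrix` with `matrix` (sites x
#'   bins), `bin_center` and `mean_profile` (column means ignoring
#'   missing)
#' @export
reference_point_matrix <- function(track, sites, half_window = 1000,
                                   bin = 10) {
  stopifnot(nrow(sites) > 0L, (2 * half_window) %% bin == 0)
  n_bins <- as.integer(2 * half_window / bin)
  mat <- matrix(NA_real_, nrow = nrow(sites), ncol = n_bins)
  for (i in seq_len(nrow(sites))) {
    chr <- sites$chrom[i]
    if (!chr %in% names(track$cov)) next
    rle <- track$cov[[chr]]
    lo <- sites$center[i] - half_window + 1L   # 1-based window start
    hi <- sites$center[i] + half_window
    span_lo <- max(lo, 1L)
    span_hi <- min(hi, length(rle))
    if (span_lo > span_hi) next
    vals <- rep(NA_real_, 2 * half_window)
    vals[(span_lo - lo + 1L):(span_hi - lo + 1L)] <-
      as.numeric(IRanges::Views(rle, span_lo, span_hi)[[1]])
    mat[i, ] <- colMeans(matrix(vals, nrow = bin), na.rm = FALSE)
  }
  centers <- -half_window + bin * (seq_len(n_bins) - 0.5)
  structure(list(matrix = mat, bin_center = centers,
                 mean_profile = colMeans(mat, na.rm = TRUE)),
            class = "refpoint_matrix")
}

#' @export
print.refpoint_matrix <- function(x, ...) {
  cat("refpoint_matrix:", nrow(x$matrix), "sites x", ncol(x$matrix),
      "bins\n")
  invisible(x)
}
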