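#' Parse per-CpG methylation calls in the modbam2bed BED dialect
#'
#' Reads the 11+ column stranded BED produced by modbam2bed for CpG
#' methylation calling. Column 5 is the score, column 6 the strand,
#' column 10 the coverage score and column 11 the percent of reads
#' methylated; the confident read count is reconstructed as
#' `round(col5 * col10 / 1000)`. Positions with zero confident reads are
#' dropped, so a missing beta is encoded as an absent record.
#'
#' @param x path to a BED file (optionally gzipped) or a character vector
#'   of raw lines
#' @return data frame of CpG calls with columns `chrom`, `pos` (0-based
#'   position of the C), `strand`, `n_reads`, `beta`, sorted by
#'   (chrom, pos)
#' @export
parse_modbed <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_calls())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("malformed modbam2bed line ", which(nf < 11L)[1L],
         ": expected >= 11 tab-separated columns, got ", nf[nf < 11L][1L],
         call. = FALSE)
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:11)), ncol = 11L, byrow = TRUE)
  score <- as.numeric(m[, 5L])
  cov <- as.numeric(m[, 10L])
  pct <- as.numeric(m[, 11L])
  bad <- which(is.na(score) | is.na(cov) | is.na(pct))
  if (length(bad)) {
    stop("malformed modbam2bed line ", bad[1L],
         ": non-numeric score/coverage/percent fields", call. = FALSE)
  }
  out_of_range <- which(pct < 0 | pct > 100)
  if (length(out_of_range)) {
    stop("modbam2bed line ", out_of_range[1L],
         ": percent methylated ", pct[out_of_range[1L]],
         " outside [0, 100]", call. = FALSE)
  }
  calls <- data.frame(
    chrom = m[, 1L],
    pos = as.integer(m[, 2L]),
    strand = m[, 6L],
    n_reads = as.integer(round(score * cov / 1000)),
    beta = pct / 100,
    stringsAsFactors = FALSE
  )
  calls <- calls[calls$n_reads > 0L, , drop = FALSE]
  sort_genomic(calls)
}

empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             n_reads = integer(), beta = numeric(), stringsAsFactors = FALSE)
}

#' Collapse stranded CpG calls onto unstranded array probes
#'
#' Each CpG covers two genomic positions (the C on the forward strand and
#' the C of the reverse complement one base downstream). Methylated read
#' counts are reconstructed per strand as `round(beta * n_reads)` and the
#' probe beta is the ratio of summed methylated reads to summed total
#' reads across the two strands; a probe covered on only one strand uses
#' that strand alone, and probes with no covered strand are absent from
#' the output.
#'
#' @param calls CpG call data frame as from [parse_modbed()]
#' @param probe_map data frame with columns `probe_id`, `chrom`, `pos`
#'   where `pos` is the forward-strand C position (the reverse-strand C
#'   sits at `pos + 1`)
#' @return data frame with columns `probe_id`, `beta`, `n_reads`
#' @export
collapse_strands <- function(calls, probe_map) {
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(probe_map)))
  if (anyDuplicated(probe_map$probe_id)) {
    stop("duplicate probe_ids in probe map", call. = FALSE)
  }
  keys <- c(paste0(probe_map$chrom, ":", probe_map$pos),
            paste0(probe_map$chrom, ":", probe_map$pos + 1L))
  if (anyDuplicated(keys)) {
    stop("probe map positions collide across probes", call. = FALSE)
  }
  meth <- round(calls$beta * calls$n_reads)
  call_key <- paste0(calls$chrom, ":", calls$pos)
  idx_fwd <- match(paste0(probe_map$chrom, ":", probe_map$pos), call_key)
  idx_rev <- match(paste0(probe_map$chrom, ":", probe_map$pos + 1L), call_key)
  n_fwd <- ifelse(is.na(idx_fwd), 0L, calls$n_reads[idx_fwd])
  n_rev <- ifelse(is.na(idx_rev), 0L, calls$n_reads[idx_rev])
  m_fwd <- ifelse(is.na(idx_fwd), 0, meth[idx_fwd])
  m_rev <- ifelse(is.na(idx_rev), 0, meth[idx_rev])
  n_tot <- n_fwd + n_rev
  keep <- n_tot > 0L
  data.frame(
    probe_id = probe_map$probe_id[keep],
    beta = (m_fwd[keep] + m_rev[keep]) / n_tot[keep],
    n_reads = as.integer(n_tot[keep]),
    stringsAsFactors = FALSE
  )
}

#' Downsample methylation coverage to a target genome-wide depth
#'
#' Treats every read at every CpG as an independent observation (of which
#' `round(beta * n_reads)` per CpG are methylated) and samples
#' `k = round(target_cov * n_cpgs_genome)` observations uniformly without
#' replacement, then recomputes per-CpG read counts and betas. When `k`
#' is at least the total number of observations the input is returned
#' unchanged.
#'
#' @param calls CpG call data frame
#' @param target_cov desired mean reads per CpG over the genome
#' @param n_cpgs_genome number of CpGs in the genome the coverage refers
#'   to; the default is the GRCh38 CpG count used for plasma downsampling
#' @param seed integer seed; the draw is deterministic given the seed
#' @return CpG call data frame with recomputed `n_reads` and `beta`;
#'   CpGs that receive no observations are dropped
#' @export
downsample_coverage <- function(calls, target_cov,
                                n_cpgs_genome = 28217005, seed = NULL) {
  if (!is.numeric(target_cov) || length(target_cov) != 1L || target_cov <= 0) {
    stop("'target_cov' must be a positive number", call. = FALSE)
  }
  n <- calls$n_reads
  total <- sum(n)
  stopifnot(total >= 1L)
  k <- round(target_cov * n_cpgs_genome)
  if (k >= total) return(calls)
  meth <- round(calls$beta * n)
  offsets <- cumsum(c(0, n))
  with_seed(seed, {
    idx <- sample.int(total, k)
    call_of <- findInterval(idx, offsets + 1)
    within <- idx - offsets[call_of]
    # observations 1..meth within a call are the methylated ones; uniform
    # index sampling makes the within-call label assignment exchangeable
    meth_flag <- within <= meth[call_of]
    new_n <- tabulate(call_of, nbins = nrow(calls))
    new_m <- tabulate(call_of[meth_flag], nbins = nrow(calls))
    out <- calls[new_n > 0L, , drop = FALSE]
    out$n_reads <- as.integer(new_n[new_n > 0L])
    out$beta <- new_m[new_n > 0L] / new_n[new_n > 0L]
    rownames(out) <- NULL
    out
  })
}

#' Write CpG betas as a 4-column bedgraph
#'
#' Emits `chrom  start  start+1  beta` (0-based half-open) with betas at
#' fixed 6-decimal precision so write/read round trips are exact at that
#' precision. Input must already be sorted by (chrom, pos).
#'
#' @param calls data frame with `chrom`, `pos`, `beta`
#' @param path output file path
#' @export
write_bedgraph <- function(calls, path) {
  if (nrow(calls) > 0L && !is_sorted_genomic(calls)) {
    stop("bedgraph input must be sorted by (chrom, pos)", call. = FALSE)
  }
  lines <- if (nrow(calls) == 0L) character() else {
    sprintf("%s\t%d\t%d\t%.6f", calls$chrom, calls$pos, calls$pos + 1L,
            calls$beta)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a 4-column bedgraph of CpG betas
#'
#' @param path bedgraph file path
#' @return data frame with `chrom`, `pos`, `beta`
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      beta = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    stop("malformed bedgraph line ",
         which(lengths(fields) < 4L)[1L], call. = FALSE)
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:4)), ncol = 4L, byrow = TRUE)
  data.frame(chrom = m[, 1L], pos = as.integer(m[, 2L]),
             beta = as.numeric(m[, 4L]), stringsAsFactors = FALSE)
}

#' Read a probe map (probe_id, chrom, pos) TSV
#'
#' @param path TSV path with a header line
#' @return data frame with `probe_id`, `chrom`, `pos`
#' @export
read_probe_map <- function(path) {
  pm <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(pm)))
  pm
}

#' Write CpG calls in the modbam2bed BED dialect
#'
#' Emits the 11-column stranded BED this package parses: score fixed at
#' 1000 so the reconstructed read count equals column 10 exactly, and
#' column 11 carries the percent methylated. Round-trips through
#' [parse_modbed()].
#'
#' @param calls CpG call data frame (`chrom`, `pos`, `strand`,
#'   `n_reads`, `beta`)
#' @param path output file path
#' @export
write_modbed <- function(calls, path) {
  lines <- sprintf("%s\t%d\t%d\tCpG\t1000\t%s\t%d\t%d\t0,0,0\t%d\t%.6g",
                   calls$chrom, calls$pos, calls$pos + 1L, calls$strand,
                   calls$pos, calls$pos + 1L, calls$n_reads,
                   calls$beta * 100)
  writeLines(lines, path)
  invisible(path)
}
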