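#' Fragment (read) length from a CIGAR string
#'
#' Sums the lengths of the query-consuming operations (M, I, =, X), so
#' deletions and skips against the reference do not inflate the molecule
#' length. Clipped reads are expected to be removed upstream; S/H
#' operations are tolerated but not counted.
#'
#' @param cigar character vector of CIGAR strings
#' @return integer vector of lengths
#' @export
fragment_length_from_cigar <- function(cigar) {
  vapply(cigar, function(cg) {
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    if (length(toks) == 0L || nchar(paste(toks, collapse = "")) != nchar(cg)) {
      stop("invalid CIGAR string: '", cg, "'", call. = FALSE)
    }
    n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    op <- substring(toks, nchar(toks))
    sum(n[op %in% c("M", "I", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Default fragment filter configuration
#'
#' Mirrors the standard cfDNA alignment filters: primary alignments
#' only, mapping quality at least 20, length at most 700 bp (longer
#' molecules are not plasma cfDNA), no soft clipping at either end, and
#' sequencing barcodes detected at both ends (guards against chimeric or
#' partially sequenced molecules in multiplexed runs).
#'
#' @param min_mapq minimum mapping quality retained
#' @param max_len maximum fragment length retained (bp)
#' @param require_primary drop secondary/supplementary alignments
#' @param require_double_barcode drop fragments without both barcodes
#' @param drop_softclipped drop fragments soft-clipped at either end
#' @return list of class `filter_config`
#' @export
filter_config <- function(min_mapq = 20, max_len = 700,
                          require_primary = TRUE,
                          require_double_barcode = TRUE,
                          drop_softclipped = TRUE) {
  stopifnot(min_mapq >= 0, max_len > 0)
  structure(list(min_mapq = min_mapq, max_len = max_len,
                 require_primary = require_primary,
                 require_double_barcode = require_double_barcode,
                 drop_softclipped = drop_softclipped),
            class = "filter_config")
}

#' Filter a fragment table
#'
#' Applies the predicates of a [filter_config()]; survivors satisfy
#' every enabled predicate. Removal counts per predicate are attached as
#' attribute `removed` and reported via `message()`.
#'
#' @param fragments fragment data frame with columns `length`, `mapq`,
#'   `is_primary`, `softclip_start`, `softclip_end`, `barcode_both_ends`
#' @param config `filter_config`
#' @return filtered fragment data frame
#' @export
filter_fragments <- function(fragments, config = filter_config()) {
  checks <- list(
    mapq = fragments$mapq >= config$min_mapq,
    length = fragments$length <= config$max_len,
    primary = if (config$require_primary) fragments$is_primary else TRUE,
    barcode = if (config$require_double_barcode)
      fragments$barcode_both_ends else TRUE,
    softclip = if (config$drop_softclipped)
      !(fragments$softclip_start | fragments$softclip_end) else TRUE
  )
  keep <- Reduce(`&`, checks)
  removed <- vapply(checks, function(ok) sum(!(ok | FALSE)), integer(1))
  message("filter_fragments: kept ", sum(keep), "/", nrow(fragments),
          " (removed by predicate: ",
          paste(names(removed), removed, sep = "=", collapse = ", "), ")")
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Short-mononucleosome fragment ratio
#'
#' Fraction of mononucleosomal fragments (100-220 bp, inclusive) that
#' are short (100-150 bp, inclusive). Elevated in samples with more
#' tumor-derived cfDNA.
#'
#' @param lengths fragment lengths in bp
#' @return ratio in [0, 1], or `NA` with a warning when no fragment
#'   falls in the denominator range
#' @export
short_mono_ratio <- function(lengths) {
  denom <- sum(lengths >= 100 & lengths <= 220)
  if (denom == 0L) {
    warning("no mononucleosomal fragments (100-220 bp); ratio undefined")
    return(NA_real_)
  }
  sum(lengths >= 100 & lengths <= 150) / denom
}

#' Short-dinucleosome fragment ratio
#'
#' Fraction of dinucleosomal fragments (275-400 bp, inclusive) that are
#' short (275-325 bp, inclusive).
#'
#' @param lengths fragment lengths in bp
#' @return ratio in [0, 1], or `NA` with a warning when no fragment
#'   falls in the denominator range
#' @export
short_di_ratio <- function(lengths) {
  denom <- sum(lengths >= 275 & lengths <= 400)
  if (denom == 0L) {
    warning("no dinucleosomal fragments (275-400 bp); ratio undefined")
    return(NA_real_)
  }
  sum(lengths >= 275 & lengths <= 325) / denom
}

#' Normalized fragment-length histogram
#'
#' @param lengths fragment lengths in bp
#' @param bin bin width (bp)
#' @param range two-element length range covered by the histogram
#' @return data frame with `length` (bin start), `count`, `density`
#'   (densities sum to 1)
#' @export
length_histogram <- function(lengths, bin = 1, range = c(0, 700)) {
  stopifnot(all(lengths >= range[1]), all(lengths <= range[2]))
  breaks <- seq(range[1], range[2] + bin, by = bin)
  idx <- findInterval(lengths, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  data.frame(length = breaks[-length(breaks)], count = counts,
             density = if (sum(counts) > 0) counts / sum(counts) else
               rep(0, length(counts)))
}

#' Extract 4-mer fragment end motifs from the reference genome
#'
#' The motif is the 4 reference bases at the fragment's sequenced 5' end
#' (end1): for plus-strand fragments the bases at `[start, start+4)`,
#' for minus-strand fragments the reverse complement of `[end-4, end)`
#' (so the motif always reads 5'->3' along the molecule). Bases are
#' taken from the reference, not the read, to avoid basecalling errors.
#' Motifs containing non-ACGT characters are missing.
#'
#' @param fragments fragment data frame with `chrom`, `start`, `end`,
#'   `strand`
#' @param reference named [Biostrings::DNAStringSet] (or path to a FASTA
#'   file) with one entry per chromosome
#' @param revcomp_minus reverse-complement minus-strand motifs (the
#'   molecule-5' convention); `FALSE` reports reference-forward 4-mers
#' @return character vector of 4-mers (`NA` where undefined)
#' @export
end_motif <- function(fragments, reference, revcomp_minus = TRUE) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  n <- nrow(fragments)
  out <- rep(NA_character_, n)
  short <- fragments$end - fragments$start < 4L
  if (any(short)) warning(sum(short), " fragments shorter than 4 bp")
  for (chr in unique(fragments$chrom)) {
    sel <- which(fragments$chrom == chr & !short)
    if (!length(sel)) next
    seq <- reference[[chr]]
    plus <- fragments$strand[sel] != "-"
    st <- ifelse(plus, fragments$start[sel] + 1L, fragments$end[sel] - 3L)
    ok <- st >= 1L & st + 3L <= length(seq)
    views <- Biostrings::extractAt(
      seq, IRanges::IRanges(st[ok], width = 4L))
    mot <- as.character(views)
    flip <- !plus[ok] & revcomp_minus
    if (any(flip)) {
      mot[flip] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(mot[flip])))
    }
    out[sel[ok]] <- mot
  }
  out[!is.na(out) & grepl("[^ACGT]", out)] <- NA_character_
  out
}

#' All 256 4-mers in lexicographic order
#' @return character vector of length 256
#' @export
all_4mers <- function() {
  b <- c("A", "C", "G", "T")
  apply(expand.grid(b, b, b, b)[, 4:1], 1, paste, collapse = "")
}

#' Tabulate 4-mer end-motif frequencies
#'
#' Always returns all 256 4-mers (zero-filled) so motif tables from
#' different samples align. With no motifs the frequencies are
#' undefined (`NA`) and `n_total` is 0.
#'
#' @param motifs character vector of 4-mers (`NA` values are dropped)
#' @return data frame of class `motif_table` with `motif`, `count`,
#'   `frequency` sorted lexicographically; `n_total` as attribute
#' @export
motif_frequencies <- function(motifs) {
  motifs <- motifs[!is.na(motifs)]
  if (length(motifs) && any(!motifs %in% all_4mers())) {
    stop("invalid 4-mer motif(s): ",
         paste(unique(motifs[!motifs %in% all_4mers()]), collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(motifs, levels = all_4mers()))
  n_total <- length(motifs)
  out <- data.frame(motif = all_4mers(), count = as.integer(counts),
                    frequency = if (n_total > 0)
                      as.integer(counts) / n_total else NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "n_total") <- n_total
  class(out) <- c("motif_table", "data.frame")
  out
}

#' Differential end-motif analysis between sample groups
#'
#' Two-tailed Student's t-test per 4-mer on per-sample frequencies (the
#' sample, not the pooled fragment count, is the statistical unit),
#' Benjamini-Hochberg adjustment across the 256 motifs, output sorted by
#' p-value. Motifs with constant frequency in both groups get p = 1.
#'
#' @param group_a_tables,group_b_tables lists of [motif_frequencies()]
#'   tables, one per sample (at least 2 per group)
#' @return data frame with `motif`, `mean_a`, `mean_b`, `delta`,
#'   `p_value`, `q_value`
#' @export
motif_differential <- function(group_a_tables, group_b_tables) {
  stopifnot(length(group_a_tables) >= 2, length(group_b_tables) >= 2)
  fa <- vapply(group_a_tables, function(t) t$frequency, numeric(256))
  fb <- vapply(group_b_tables, function(t) t$frequency, numeric(256))
  p <- vapply(seq_len(256), function(i) {
    a <- fa[i, ]; b <- fb[i, ]
    if (var(a) == 0 && var(b) == 0) {
      # constant in both groups: p = 1 if equal; with unequal means the
      # t statistic is undefined at these group sizes -> not testable
      return(if (mean(a) == mean(b)) 1 else NA_real_)
    }
    t_test(a, b, alternative = "two.sided")$p_value
  }, numeric(1))
  q <- rep(NA_real_, 256)
  q[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  out <- data.frame(motif = all_4mers(),
                    mean_a = rowMeans(fa), mean_b = rowMeans(fb),
                    delta = rowMeans(fa) - rowMeans(fb),
                    p_value = p, q_value = q,
                    stringsAsFactors = FALSE)
  out[order(out$p_value, out$motif), , drop = FALSE]
}

#' Read a fragment table TSV
#'
#' Expected header columns: chrom, start, end, mapq, strand, cigar,
#' is_primary, softclip_start, softclip_end, barcode_both_ends. A
#' `length` column is recomputed from the CIGAR when present, otherwise
#' taken as end - start.
#'
#' @param path TSV path
#' @return fragment data frame with a `length` column
#' @export
read_fragments <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  for (col in c("is_primary", "softclip_start", "softclip_end",
                "barcode_both_ends")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df$length <- if ("cigar" %in% names(df))
    fragment_length_from_cigar(df$cigar) else as.integer(df$end - df$start)
  df
}

#' Convert SAM text lines to a fragment table
#'
#' Minimal single-end adapter: drops unmapped reads (flag 0x4), marks
#' secondary/supplementary alignments (0x100/0x800) as non-primary,
#' derives soft-clip flags from the CIGAR ends, and takes strand from
#' flag 0x10. Barcode status is not encoded in SAM and defaults to TRUE.
#'
#' @param lines character vector of SAM lines (headers ignored)
#' @return fragment data frame
#' @export
fragments_from_sam <- function(lines) {
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), mapq = integer(),
                      strand = character(), cigar = character(),
                      is_primary = logical(), softclip_start = logical(),
                      softclip_end = logical(),
                      barcode_both_ends = logical(), length = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(fields, function(f) as.integer(f[2]), integer(1))
  mapped <- bitwAnd(flag, 0x4) == 0L
  fields <- fields[mapped]; flag <- flag[mapped]
  cigar <- vapply(fields, `[`, character(1), 6L)
  pos <- vapply(fields, function(f) as.integer(f[4]), integer(1))
  ref_len <- vapply(cigar, function(cg) {
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- substring(toks, nchar(toks))
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
  df <- data.frame(
    chrom = vapply(fields, `[`, character(1), 3L),
    start = pos - 1L,
    end = pos - 1L + ref_len,
    mapq = vapply(fields, function(f) as.integer(f[5]), integer(1)),
    strand = ifelse(bitwAnd(flag, 0x10) > 0L, "-", "+"),
    cigar = cigar,
    is_primary = bitwAnd(flag, 0x100) == 0L & bitwAnd(flag, 0x800) == 0L,
    softclip_start = grepl("^[0-9]+S", cigar),
    softclip_end = grepl("[0-9]+S$", cigar),
    barcode_both_ends = TRUE,
    stringsAsFactors = FALSE
  )
  df$length <- fragment_length_from_cigar(df$cigar)
  df
}

#' Write a fragment table TSV
#'
#' @param fragments fragment data frame
#' @param path output file path
#' @export
write_fragments <- function(fragments, path) {
  write.table(fragments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
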