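test_that("CIGAR length sums query-consuming operations", {
  expect_equal(fragment_length_from_cigar("100M"), 100L)
  expect_equal(fragment_length_from_cigar("10M2I10M"), 22L)
  # deletions consume reference, not molecule: oracle is the length of
  # the synthesized query a 50M2D50M alignment implies
  query <- paste(c(strrep("A", 50), strrep("A", 50)), collapse = "")
  expect_equal(fragment_length_from_cigar("50M2D50M"), nchar(query))
  expect_equal(fragment_length_from_cigar(c("5M", "3M1I")), c(5L, 4L))
  expect_error(fragment_length_from_cigar("10M2Q"), "invalid CIGAR")
  expect_error(fragment_length_from_cigar("M10"), "invalid CIGAR")
})

base_frag <- function(n = 1, ...) {
  df <- data.frame(chrom = "chr1", start = 0L, end = 150L, length = 150L,
                   mapq = 60L, strand = "+", is_primary = TRUE,
                   softclip_start = FALSE, softclip_end = FALSE,
                   barcode_both_ends = TRUE)
  df <- df[rep(1, n), , drop = FALSE]
  args <- list(...)
  for (nm in names(args)) df[[nm]] <- args[[nm]]
  rownames(df) <- NULL
  df
}

test_that("fragment filters apply every predicate with strict bounds", {
  frags <- rbind(base_frag(mapq = 19L),                 # removed: mapq
                 base_frag(mapq = 20L),                 # kept (boundary)
                 base_frag(length = 701L),              # removed: length
                 base_frag(length = 700L),              # kept (boundary)
                 base_frag(is_primary = FALSE),         # removed
                 base_frag(softclip_end = TRUE),        # removed
                 base_frag(barcode_both_ends = FALSE))  # removed
  out <- suppressMessages(filter_fragments(frags))
  expect_equal(nrow(out), 2L)
  expect_equal(out$mapq, c(20L, 60L))
  # all predicates passing is the identity
  clean <- base_frag(5)
  expect_equal(suppressMessages(filter_fragments(clean)), clean,
               ignore_attr = TRUE)
})

test_that("filtering is order-independent across predicate subsets", {
  set.seed(71)
  frags <- base_frag(200,
                     mapq = sample(c(10L, 30L), 200, TRUE),
                     length = sample(c(150L, 800L), 200, TRUE),
                     is_primary = sample(c(TRUE, FALSE), 200, TRUE))
  all_at_once <- suppressMessages(filter_fragments(frags))
  # apply predicates one at a time in a different order
  step <- frags
  step <- step[step$is_primary, ]
  step <- step[step$length <= 700, ]
  step <- step[step$mapq >= 20, ]
  rownames(step) <- NULL
  expect_equal(all_at_once, step, ignore_attr = TRUE)
})

test_that("short-fragment ratios match hand counts incl. boundaries", {
  expect_equal(short_mono_ratio(c(120, 140, 160, 200, 230)), 0.5)
  expect_equal(short_mono_ratio(rep(167, 10)), 0)
  # 150 counts in both ranges, 151 only in the denominator
  expect_equal(short_mono_ratio(c(150, 151)), 0.5)
  expect_warning(r <- short_mono_ratio(c(50, 300)), "undefined")
  expect_true(is.na(r))
  expect_equal(short_di_ratio(c(300, 350, 390)), 1 / 3)
  expect_equal(short_di_ratio(c(325, 326)), 0.5)
  expect_warning(r2 <- short_di_ratio(c(167)), "undefined")
  expect_true(is.na(r2))
})

test_that("ratios are order- and duplication-invariant", {
  set.seed(72)
  lengths <- sample(80:500, 300, replace = TRUE)
  r <- short_mono_ratio(lengths)
  expect_equal(short_mono_ratio(sample(lengths)), r)
  expect_equal(short_mono_ratio(rep(lengths, 2)), r)
  d <- short_di_ratio(lengths)
  expect_equal(short_di_ratio(rev(lengths)), d)
  expect_equal(short_di_ratio(c(lengths, lengths)), d)
})

test_that("length histogram is a unit-mass density", {
  h <- length_histogram(167)
  expect_equal(h$density[h$length == 167], 1)
  h10 <- length_histogram(100:109)
  expect_equal(h10$density[h10$length %in% 100:109], rep(0.1, 10))
  set.seed(73)
  hr <- length_histogram(sample(0:700, 500, TRUE))
  expect_equal(sum(hr$density), 1)
  expect_equal(sum(hr$count), 500)
})

test_that("end motifs come from the reference with strand handling", {
  ref <- Biostrings::DNAStringSet(c(chrZ = paste0(
    strrep("A", 100), "CCCAT", strrep("G", 91),
    "TGGG", strrep("A", 100))))
  # plus strand, start 100 (0-based) -> reference CCCA
  plus <- base_frag(start = 100L, end = 250L, chrom = "chrZ")
  expect_equal(end_motif(plus, ref), "CCCA")
  # minus strand, end 200: [196,200) = TGGG -> revcomp CCCA
  minus <- base_frag(start = 60L, end = 200L, strand = "-",
                     chrom = "chrZ")
  expect_equal(end_motif(minus, ref), "CCCA")
  # without reverse-complementing, the reference-forward 4-mer
  expect_equal(end_motif(minus, ref, revcomp_minus = FALSE), "TGGG")
  # N in the window -> missing
  refN <- Biostrings::DNAStringSet(c(chrZ = paste0(
    strrep("A", 100), "CCNA", strrep("G", 100))))
  expect_true(is.na(end_motif(plus, refN)))
  # fragment shorter than 4 bp -> missing with warning
  tiny <- base_frag(start = 100L, end = 102L, chrom = "chrZ")
  expect_warning(m <- end_motif(tiny, ref), "shorter than 4")
  expect_true(is.na(m))
})

test_that("motif frequencies tabulate all 256 4-mers", {
  mt <- motif_frequencies(c("CCCA", "CCCA", "AAAA", "TTTT"))
  expect_equal(nrow(mt), 256L)
  expect_equal(mt$frequency[mt$motif == "CCCA"], 0.5)
  expect_equal(mt$frequency[mt$motif == "AAAA"], 0.25)
  expect_equal(sum(mt$frequency), 1)
  expect_equal(attr(mt, "n_total"), 4L)
  # frequencies times n_total reproduce the counts exactly
  expect_equal(mt$frequency * attr(mt, "n_total"), as.numeric(mt$count))
  single <- motif_frequencies("ACGT")
  expect_equal(single$frequency[single$motif == "ACGT"], 1)
  empty <- motif_frequencies(character())
  expect_equal(attr(empty, "n_total"), 0L)
  expect_true(all(is.na(empty$frequency)))
  expect_error(motif_frequencies("ACGU"), "invalid 4-mer")
})

test_that("a planted CCCA deficit ranks first in the differential test", {
  hits <- vapply(1:20, function(rep) {
    healthy <- lapply(1:4, function(i) {
      sim <- simulate_fragments(n_fragments = 20000, tumor_prop = 0,
                                seed = 1000 * rep + i)
      motif_frequencies(sim$truth$motif)
    })
    tumor <- lapply(1:3, function(i) {
      sim <- simulate_fragments(n_fragments = 20000, tumor_prop = 1,
                                seed = 1000 * rep + 10 + i)
      motif_frequencies(sim$truth$motif)
    })
    motif_differential(healthy, tumor)$motif[1] == "CCCA"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("differential motif test controls type I error and BH order", {
  set.seed(74)
  null_sig <- vapply(1:40, function(rep) {
    tabs <- lapply(1:7, function(i) {
      sim <- simulate_fragments(n_fragments = 3000, tumor_prop = 0,
                                seed = 5000 + 10 * rep + i)
      motif_frequencies(sim$truth$motif)
    })
    res <- motif_differential(tabs[1:4], tabs[5:7])
    any(res$q_value < 0.05, na.rm = TRUE)
  }, logical(1))
  expect_lte(mean(null_sig), 0.1)
  # q-values are non-decreasing in p-rank
  tabs <- lapply(1:4, function(i)
    motif_frequencies(simulate_fragments(3000, seed = 80 + i)$truth$motif))
  res <- motif_differential(tabs[1:2], tabs[3:4])
  q <- res$q_value[!is.na(res$q_value)]
  expect_true(all(diff(q) >= -1e-12))
})

test_that("SAM adapter derives coordinates, strand and clip flags", {
  sam <- c(
    "@HD\tVN:1.6",
    paste("r1", 0, "chr1", 101, 60, "100M", "*", 0, 0, "*", "*",
          sep = "\t"),
    paste("r2", 16, "chr1", 201, 60, "50M2D48M", "*", 0, 0, "*", "*",
          sep = "\t"),
    paste("r3", 256, "chr1", 301, 60, "5S95M", "*", 0, 0, "*", "*",
          sep = "\t"),
    paste("r4", 4, "*", 0, 0, "*", "*", 0, 0, "*", "*", sep = "\t"))
  df <- fragments_from_sam(sam)
  expect_equal(nrow(df), 3L)                 # unmapped dropped
  expect_equal(df$start, c(100L, 200L, 300L))
  expect_equal(df$end[2], 200L + 100L)       # 50M2D48M spans 100 ref bp
  expect_equal(df$length[2], 98L)            # but a 98 bp molecule
  expect_equal(df$strand, c("+", "-", "+"))
  expect_equal(df$is_primary, c(TRUE, TRUE, FALSE))
  expect_equal(df$softclip_start, c(FALSE, FALSE, TRUE))
})
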