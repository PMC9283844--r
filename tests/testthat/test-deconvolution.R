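toy_atlas <- function() {
  b <- matrix(c(0.9, 0.1, 0.5, 0.5, 0.2, 0.8,
                0.1, 0.9, 0.5, 0.5, 0.8, 0.2,
                0.5, 0.5, 0.9, 0.1, 0.5, 0.5),
              nrow = 6, ncol = 3,
              dimnames = list(sprintf("cg%02d", 1:6), c("A", "B", "C")))
  ref_atlas(b)
}

test_that("marker selection matches exhaustive margin enumeration", {
  atlas <- toy_atlas()
  b <- atlas$betas
  margins <- b[, "A"] - rowMeans(b[, c("B", "C")])
  ms <- select_markers(atlas, "A", n_each = 1)
  expect_equal(ms$hyper_probes, names(which.max(margins)))
  expect_equal(ms$hypo_probes, names(which.min(margins)))
  expect_error(select_markers(atlas, "Z"), "not in atlas")
})

test_that("marker ties break lexicographically and saturation returns all", {
  b <- matrix(c(0.9, 0.9, 0.1, 0.1,
                0.1, 0.1, 0.9, 0.9),
              nrow = 4, ncol = 2,
              dimnames = list(c("cgB", "cgA", "cgD", "cgC"),
                              c("T1", "T2")))
  atlas <- ref_atlas(b)
  ms <- select_markers(atlas, "T1", n_each = 1)
  expect_equal(ms$hyper_probes, "cgA")      # tie with cgB -> smaller id
  expect_equal(ms$hypo_probes, "cgC")
  all_of_them <- select_markers(atlas, "T1", n_each = 100)
  expect_length(all_of_them$hyper_probes, 4L)
})

test_that("NNLS recovers identity and exact two-component mixtures", {
  atlas <- toy_atlas()
  b <- atlas$betas
  # sample equals one atlas column
  fit <- nnls_fractions(setNames(b[, "B"], rownames(b)), atlas)
  expect_equal(unname(fit$fractions["B"]), 1, tolerance = 1e-9)
  expect_equal(unname(fit$fractions["A"]), 0, tolerance = 1e-9)
  # exact 0.3 / 0.7 mixture on a separable 2-component atlas
  b2 <- b[, c("A", "B")]
  atlas2 <- ref_atlas(b2)
  y <- setNames(as.numeric(b2 %*% c(0.3, 0.7)), rownames(b2))
  fit2 <- nnls_fractions(y, atlas2)
  expect_equal(unname(fit2$fractions), c(0.3, 0.7), tolerance = 1e-6)
  expect_lt(fit2$residual_norm, 1e-8)
})

test_that("NNLS agrees with a simplex grid-search oracle", {
  atlas <- toy_atlas()
  b2 <- atlas$betas[, c("A", "C")]
  set.seed(11)
  for (rep in 1:5) {
    w <- runif(1)
    y <- as.numeric(b2 %*% c(w, 1 - w)) + rnorm(6, sd = 0.01)
    fit <- nnls_fractions(setNames(y, rownames(b2)), ref_atlas(b2))
    oracle <- grid_nnls_2comp(b2, y)
    expect_equal(unname(fit$fractions), oracle, tolerance = 2e-3)
  }
})

test_that("NNLS errors when fewer usable probes than components", {
  atlas <- toy_atlas()
  y <- setNames(c(0.5, 0.5), rownames(atlas$betas)[1:2])
  expect_error(nnls_fractions(y, atlas), "usable probes")
})

test_that("noiseless simplex mixtures are recovered within 1e-6", {
  sa <- simulate_atlas(n_components = 5, noise_sd = 0, seed = 2)
  b <- sa$atlas$betas
  set.seed(5)
  for (rep in 1:10) {
    w <- as.numeric(rexp(5)); w <- w / sum(w)
    y <- setNames(as.numeric(b %*% w), rownames(b))
    fit <- nnls_fractions(y, sa$atlas)
    expect_lt(max(abs(fit$fractions - w)), 1e-6)
  }
})

test_that("grouping fractions is additive and conserves the total", {
  fr <- c(T = 0.1, B = 0.2, NK = 0.05, Hep = 0.65)
  gm <- data.frame(component = c("T", "B", "NK", "Hep"),
                   group = c("lymphocytes", "lymphocytes",
                             "lymphocytes", "liver"))
  g <- group_fractions(fr, gm)
  expect_equal(unname(g["lymphocytes"]), 0.35)
  expect_equal(sum(g), sum(fr))
  # identity map leaves values unchanged
  id <- data.frame(component = names(fr), group = names(fr))
  expect_equal(group_fractions(fr, id)[names(fr)], fr)
  expect_error(group_fractions(fr, gm[-1, ]), "without a group")
  # conservation on random fractions
  set.seed(8)
  for (rep in 1:200) {
    w <- as.numeric(rexp(4)); w <- w / sum(w)
    expect_equal(sum(group_fractions(setNames(w, names(fr)), gm)), 1)
  }
})

test_that("two-component fraction recovers analytic mixtures", {
  set.seed(21)
  n <- 400
  refs <- data.frame(probe_id = sprintf("cg%04d", 1:n),
                     x1 = runif(n), x2 = runif(n))
  # pure target component
  y1 <- setNames(refs$x1, refs$probe_id)
  expect_equal(two_component_fraction(y1, refs)$fraction, 1.0,
               tolerance = 1e-9)
  # exact 0.25 mixture
  y <- setNames(0.25 * refs$x1 + 0.75 * refs$x2, refs$probe_id)
  expect_equal(two_component_fraction(y, refs)$fraction, 0.25,
               tolerance = 1e-6)
  # monotone in the mixing weight
  fs <- vapply(seq(0, 1, by = 0.1), function(f) {
    yy <- setNames(f * refs$x1 + (1 - f) * refs$x2, refs$probe_id)
    two_component_fraction(yy, refs)$fraction
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("degenerate two-component fits are signalled, not silently 0", {
  refs <- data.frame(probe_id = sprintf("cg%02d", 1:20),
                     x1 = rep(0, 20), x2 = rep(0, 20))
  y <- setNames(rep(0.5, 20), refs$probe_id)
  expect_warning(out <- two_component_fraction(y, refs, warn_below = 0),
                 "undefined")
  expect_true(is.na(out$fraction))
  expect_error(two_component_fraction(y[1:5], refs[1:5, ]),
               "shared probes")
})

test_that("two-component refs require enough valid replicates per probe", {
  tm <- matrix(c(0.8, 0.9, NA,
                 0.7, NA, NA), nrow = 2, byrow = TRUE,
               dimnames = list(c("cg1", "cg2"), NULL))
  pm <- matrix(0.2, nrow = 2, ncol = 3,
               dimnames = list(c("cg1", "cg2"), NULL))
  refs <- two_component_refs(tm, pm, min_valid = 2)
  expect_equal(refs$probe_id, "cg1")        # cg2 has 1 valid target value
  expect_equal(refs$x1, 0.85)
})

test_that("purity correction inverts the mixing equation", {
  expect_equal(purity_correct(0.5, 0.8, 0.5), 0.2)
  expect_equal(purity_correct(0.37, 0.9, 1), 0.37)   # pure-tumor limit
  expect_error(purity_correct(0.5, 0.5, 0), "purity")
  # algebraic round trip on random draws
  set.seed(13)
  cvals <- runif(1000); lvals <- runif(1000)
  pur <- runif(1000, 0.05, 1)
  mixed <- pur * cvals + (1 - pur) * lvals
  expect_equal(purity_correct(mixed, lvals, pur), cvals,
               tolerance = 1e-12)
})

test_that("differential CpG selection recovers planted probes", {
  set.seed(17)
  n_probes <- 1000; n_per <- 20
  ids <- sprintf("cg%04d", 1:n_probes)
  base <- runif(n_probes, 0.3, 0.5)
  tumor <- matrix(rnorm(n_probes * n_per, base, 0.05), n_probes,
                  dimnames = list(ids, NULL))
  plasma <- matrix(rnorm(n_probes * n_per, base, 0.05), n_probes,
                   dimnames = list(ids, NULL))
  planted <- ids[1:50]
  tumor[planted, ] <- tumor[planted, ] + 0.5
  hits <- select_differential_cpgs(clip01(tumor), clip01(plasma))
  expect_gte(sum(planted %in% hits$probe_id), 50)
  expect_lte(sum(!hits$probe_id %in% planted), 1)    # at most 1 FP
})

test_that("differential CpG gates: min_valid and effect size", {
  ids <- c("cgA", "cgB")
  tumor <- matrix(c(0.99, 0.99, 0.99, 0.99,     # cgA: huge separation
                    0.59, NA, NA, NA),          # cgB: 1 valid value
                  nrow = 2, byrow = TRUE, dimnames = list(ids, NULL))
  plasma <- matrix(c(0.01, 0.012, 0.011, 0.013,
                     0.30, 0.31, 0.30, 0.31),
                   nrow = 2, byrow = TRUE, dimnames = list(ids, NULL))
  hits <- select_differential_cpgs(tumor, plasma, fdr_cut = 0.05)
  expect_false("cgB" %in% hits$probe_id)        # not tested
  # an effect below min_delta is excluded even at p ~ 0
  t2 <- matrix(rep(c(0.29, 0.0), each = 6), nrow = 2, byrow = TRUE,
               dimnames = list(ids, NULL))
  t2 <- t2 + matrix(rnorm(12, sd = 1e-4), 2)
  p2 <- matrix(rep(c(0.0, 0.0), each = 6), nrow = 2, byrow = TRUE,
               dimnames = list(ids, NULL))
  p2 <- p2 + matrix(rnorm(12, sd = 1e-4), 2)
  hits2 <- select_differential_cpgs(clip01(t2), clip01(p2),
                                    fdr_cut = 0.05)
  expect_false("cgA" %in% hits2$probe_id)       # delta 0.29 < 0.3
  # exclusion set removes otherwise-significant probes
  hits3 <- select_differential_cpgs(tumor[1, , drop = FALSE],
                                    plasma[1, , drop = FALSE],
                                    exclusion_set = "cgA",
                                    fdr_cut = 0.05)
  expect_equal(nrow(hits3), 0L)
})
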