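#' Construct a reference methylation atlas
#'
#' @param betas numeric matrix of beta values, probes in rows (rownames =
#'   probe ids), components (cell types) in columns; `NA` marks missing
#' @return object of class `ref_atlas`
#' @export
ref_atlas <- function(betas) {
  stopifnot(is.matrix(betas), !is.null(rownames(betas)),
            !is.null(colnames(betas)))
  if (anyDuplicated(rownames(betas))) stop("duplicate probe ids",
                                           call. = FALSE)
  if (anyDuplicated(colnames(betas))) stop("duplicate component names",
                                           call. = FALSE)
  rng <- range(betas, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("atlas betas outside [0,1]",
                                     call. = FALSE)
  keep <- rowSums(!is.na(betas)) >= 1L
  structure(list(betas = betas[keep, , drop = FALSE]), class = "ref_atlas")
}

#' @export
print.ref_atlas <- function(x, ...) {
  cat("Reference methylation atlas:", ncol(x$betas), "components x",
      nrow(x$betas), "probes\n")
  invisible(x)
}

#' Read a reference atlas CSV (MethAtlas dialect)
#'
#' First column holds probe ids, header row holds component names, empty
#' cells are missing values.
#'
#' @param path CSV path
#' @return `ref_atlas`
#' @export
read_atlas <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("", "NA"))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  ref_atlas(m)
}

#' Write a reference atlas CSV (MethAtlas dialect)
#'
#' @param atlas `ref_atlas`
#' @param path output path
#' @export
write_atlas <- function(atlas, path) {
  df <- data.frame(CpGs = rownames(atlas$betas), atlas$betas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Select hyper- and hypomethylated marker probes for one cell type
#'
#' Ranks probes by the one-vs-rest margin, the target component's beta
#' minus the mean beta of all other components, and takes the top
#' `n_each` most hypermethylated (largest margin) and hypomethylated
#' (smallest margin) probes. Probes missing the target beta, or missing
#' all other betas, are excluded. Ties break lexicographically on
#' probe id so selection is deterministic.
#'
#' @param atlas `ref_atlas`
#' @param target component name to select markers for
#' @param n_each number of probes per direction
#' @return list with `target_component`, `hyper_probes`, `hypo_probes`
#' @export
select_markers <- function(atlas, target, n_each = 1000) {
  b <- atlas$betas
  if (!target %in% colnames(b)) {
    stop("component '", target, "' not in atlas", call. = FALSE)
  }
  tgt <- b[, target]
  others <- b[, setdiff(colnames(b), target), drop = FALSE]
  margin <- tgt - rowMeans(others, na.rm = TRUE)
  ok <- !is.na(margin)
  ids <- rownames(b)[ok]
  margin <- margin[ok]
  o_hyper <- order(-margin, ids, method = "radix")
  o_hypo <- order(margin, ids, method = "radix")
  list(
    target_component = target,
    hyper_probes = ids[o_hyper][seq_len(min(n_each, length(ids)))],
    hypo_probes = ids[o_hypo][seq_len(min(n_each, length(ids)))]
  )
}

#' Union of marker probes across all atlas components
#'
#' @param atlas `ref_atlas`
#' @param n_each markers per direction per component
#' @return character vector of probe ids
#' @export
marker_union <- function(atlas, n_each = 1000) {
  sets <- lapply(colnames(atlas$betas), function(comp) {
    ms <- select_markers(atlas, comp, n_each)
    c(ms$hyper_probes, ms$hypo_probes)
  })
  sort(unique(unlist(sets)))
}

#' Estimate cell-type fractions by non-negative least squares
#'
#' Solves `argmin_beta || X beta - Y ||_2, beta >= 0` over the marker
#' probes, where X holds the atlas columns and Y the sample betas, using
#' the Lawson-Hanson algorithm. Only probes with non-missing values in
#' the sample and in every atlas column are used (complete cases).
#' Fractions are the coefficients normalized to sum to one.
#'
#' @param sample_betas named numeric vector of probe betas
#' @param atlas `ref_atlas`
#' @param markers character vector of probe ids to restrict the fit to;
#'   default uses all atlas probes
#' @return list of class `deconv_result` with `coefficients`,
#'   `fractions`, `n_probes_used`, `residual_norm`
#' @export
nnls_fractions <- function(sample_betas, atlas, markers = NULL) {
  b <- atlas$betas
  probes <- if (is.null(markers)) rownames(b) else markers
  probes <- intersect(probes, rownames(b))
  probes <- probes[probes %in% names(sample_betas)]
  y <- sample_betas[probes]
  x <- b[probes, , drop = FALSE]
  ok <- !is.na(y) & complete.cases(x)
  y <- y[ok]
  x <- x[ok, , drop = FALSE]
  k <- ncol(x)
  if (nrow(x) < k) {
    stop("only ", nrow(x), " usable probes for ", k,
         " components; need at least ", k, call. = FALSE)
  }
  fit <- pracma::lsqnonneg(x, as.numeric(y))
  coefs <- setNames(fit$x, colnames(x))
  stopifnot(all(coefs >= 0))
  s <- sum(coefs)
  fractions <- if (s > 0) coefs / s else {
    warning("all NNLS coefficients are zero; fractions undefined")
    setNames(rep(NA_real_, k), colnames(x))
  }
  structure(list(coefficients = coefs, fractions = fractions,
                 n_probes_used = nrow(x),
                 residual_norm = sqrt(fit$resid.norm)),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat("NNLS deconvolution over", x$n_probes_used, "probes\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Collapse component fractions into groups
#'
#' @param fractions named numeric vector of component fractions
#' @param group_map data frame with columns `component`, `group`
#' @return named numeric vector of grouped fractions (sum preserved)
#' @export
group_fractions <- function(fractions, group_map) {
  stopifnot(all(c("component", "group") %in% names(group_map)))
  idx <- match(names(fractions), group_map$component)
  if (anyNA(idx)) {
    stop("components without a group: ",
         paste(names(fractions)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  grp <- group_map$group[idx]
  out <- tapply(fractions, grp, sum)
  setNames(as.numeric(out), names(out))
}

#' Build the two reference methylomes for a two-component fit
#'
#' Averages beta values across replicate samples of the target tissue
#' and of healthy plasma, keeping only probes with at least `min_valid`
#' non-missing values in each group.
#'
#' @param target_mat probes x samples beta matrix for the target tissue
#' @param plasma_mat probes x samples beta matrix for healthy plasma
#'   (same probe order)
#' @param min_valid minimum non-missing values per group per probe
#' @return data frame with `probe_id`, `x1` (target mean), `x2`
#'   (plasma mean)
#' @export
two_component_refs <- function(target_mat, plasma_mat, min_valid = 2) {
  stopifnot(identical(rownames(target_mat), rownames(plasma_mat)))
  ok <- rowSums(!is.na(target_mat)) >= min_valid &
    rowSums(!is.na(plasma_mat)) >= min_valid
  data.frame(
    probe_id = rownames(target_mat)[ok],
    x1 = rowMeans(target_mat[ok, , drop = FALSE], na.rm = TRUE),
    x2 = rowMeans(plasma_mat[ok, , drop = FALSE], na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Two-component tissue-fraction estimate
#'
#' Fits the sample betas as a non-negative combination of a single
#' target-tissue methylome `x1` and a healthy-plasma methylome `x2` and
#' returns `beta1 / (beta1 + beta2)`, the fraction of target-tissue DNA.
#'
#' @param sample_betas named numeric vector of probe betas
#' @param refs data frame from [two_component_refs()] (columns
#'   `probe_id`, `x1`, `x2`)
#' @param min_probes minimum shared non-missing probes required
#' @param warn_below emit a warning when fewer shared probes than this
#'   are available (fits on very few probes are unstable)
#' @return list with `fraction` (`NA` when both coefficients vanish),
#'   `beta1`, `beta2`, `n_probes_used`
#' @export
two_component_fraction <- function(sample_betas, refs, min_probes = 10,
                                   warn_below = 330) {
  stopifnot(all(c("probe_id", "x1", "x2") %in% names(refs)))
  idx <- match(refs$probe_id, names(sample_betas))
  y <- sample_betas[idx]
  ok <- !is.na(y) & !is.na(refs$x1) & !is.na(refs$x2)
  n <- sum(ok)
  if (n < min_probes) {
    stop("only ", n, " shared probes; need at least ", min_probes,
         call. = FALSE)
  }
  if (n < warn_below) {
    warning("two-component fit on only ", n, " shared probes")
  }
  x <- cbind(x1 = refs$x1[ok], x2 = refs$x2[ok])
  fit <- pracma::lsqnonneg(x, as.numeric(y[ok]))
  b1 <- fit$x[1]
  b2 <- fit$x[2]
  frac <- if (b1 + b2 > 0) b1 / (b1 + b2) else {
    warning("both two-component coefficients are zero; fraction undefined")
    NA_real_
  }
  list(fraction = frac, beta1 = b1, beta2 = b2, n_probes_used = n)
}

#' Correct bulk-tumor methylation for non-cancer cell content
#'
#' Inverts the mixing equation `M_m = M_c * purity + M_l * (1 - purity)`
#' to recover the pure cancer-cell methylation `M_c` from the observed
#' bulk mixture `M_m`, the leukocyte methylation `M_l`, and the tumor
#' purity. The result is clipped to the valid beta range.
#'
#' @param m_m observed bulk mixture beta(s)
#' @param m_l leukocyte beta(s)
#' @param purity cancer-cell fraction in (0, 1]
#' @return corrected cancer beta(s) in [0, 1]
#' @export
purity_correct <- function(m_m, m_l, purity) {
  stop_if_not_numeric(m_m, "m_m"); stop_if_not_numeric(m_l, "m_l")
  if (any(purity <= 0) || any(purity > 1)) {
    stop("'purity' must be in (0, 1]", call. = FALSE)
  }
  clip01((m_m - m_l * (1 - purity)) / purity)
}

#' Select differentially methylated probes between tumors and plasma
#'
#' Per-probe Welch two-sample t-test of (purity-corrected) tumor betas
#' against healthy plasma betas, Benjamini-Hochberg adjustment across all
#' tested probes, keeping probes with FDR below `fdr_cut`, absolute mean
#' beta difference at least `min_delta`, and not in the exclusion set.
#' Probes with fewer than `min_valid` non-missing values in either group
#' are not tested.
#'
#' @param tumor_betas probes x samples matrix
#' @param plasma_betas probes x samples matrix (same probe order)
#' @param exclusion_set probe ids to drop regardless of significance
#' @param fdr_cut BH FDR threshold
#' @param min_delta minimum absolute mean beta difference
#' @param min_valid minimum valid values per group
#' @return data frame of selected probes with `probe_id`, `delta`,
#'   `p_value`, `q_value`
#' @export
select_differential_cpgs <- function(tumor_betas, plasma_betas,
                                     exclusion_set = character(),
                                     fdr_cut = 0.001, min_delta = 0.3,
                                     min_valid = 2) {
  stopifnot(identical(rownames(tumor_betas), rownames(plasma_betas)))
  if (ncol(tumor_betas) == 0L || ncol(plasma_betas) == 0L) {
    stop("both groups must contain samples", call. = FALSE)
  }
  n_a <- rowSums(!is.na(tumor_betas))
  n_b <- rowSums(!is.na(plasma_betas))
  testable <- n_a >= min_valid & n_b >= min_valid
  ta <- tumor_betas[testable, , drop = FALSE]
  pb <- plasma_betas[testable, , drop = FALSE]
  mean_a <- rowMeans(ta, na.rm = TRUE)
  mean_b <- rowMeans(pb, na.rm = TRUE)
  var_a <- apply(ta, 1, var, na.rm = TRUE)
  var_b <- apply(pb, 1, var, na.rm = TRUE)
  na <- n_a[testable]; nb <- n_b[testable]
  se2 <- var_a / na + var_b / nb
  tstat <- (mean_a - mean_b) / sqrt(se2)
  df <- se2^2 / ((var_a / na)^2 / (na - 1) + (var_b / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[se2 == 0 & mean_a == mean_b] <- 1
  q <- p.adjust(p, method = "BH")
  delta <- mean_a - mean_b
  keep <- !is.na(q) & q < fdr_cut & abs(delta) >= min_delta &
    !(rownames(ta) %in% exclusion_set)
  out <- data.frame(probe_id = rownames(ta)[keep], delta = delta[keep],
                    p_value = p[keep], q_value = q[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_value, out$probe_id), , drop = FALSE]
}
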