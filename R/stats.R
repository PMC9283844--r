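#' Choose the two-sample test by group size
#'
#' Policy: Student's t-test when either group has fewer than five
#' samples, otherwise the Wilcoxon rank-sum test (small groups give the
#' rank test too little resolution).
#'
#' @param n_a,n_b group sizes (each at least 2)
#' @return `"t"` or `"wilcoxon"`
#' @export
choose_test <- function(n_a, n_b) {
  if (n_a < 2 || n_b < 2) stop("each group needs at least 2 samples",
                               call. = FALSE)
  if (min(n_a, n_b) < 5) "t" else "wilcoxon"
}

#' Two-sample t-test (Student by default)
#'
#' Pooled-variance Student's t-test, with Welch available by flag. When
#' both groups are constant with equal means the p-value is defined as 1.
#' The direction of one-sided alternatives must be given explicitly.
#'
#' @param a,b numeric vectors (each at least 2 values)
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (a vs b)
#' @param var_equal pooled variance (Student) if `TRUE`, Welch otherwise
#' @return list of class `cf_test` with `statistic`, `p_value`,
#'   `alternative`, `method`, `n_a`, `n_b`
#' @export
t_test <- function(a, b, alternative = c("two.sided", "less", "greater"),
                   var_equal = TRUE) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(structure(list(statistic = 0, p_value = 1,
                            alternative = alternative, method = "t",
                            n_a = length(a), n_b = length(b)),
                       class = "cf_test"))
    }
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  ht <- t.test(a, b, alternative = alternative, var.equal = var_equal)
  structure(list(statistic = unname(ht$statistic),
                 p_value = ht$p.value, alternative = alternative,
                 method = "t", n_a = length(a), n_b = length(b)),
            class = "cf_test")
}

#' Wilcoxon rank-sum test with explicit direction
#'
#' Exact enumeration for tie-free samples with both groups below 50,
#' normal approximation with tie correction otherwise.
#'
#' @param a,b numeric vectors
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (a vs b)
#' @return `cf_test` list
#' @export
wilcoxon_test <- function(a, b,
                          alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) >= 1, length(b) >= 1)
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- !has_ties && length(a) < 50 && length(b) < 50
  if (length(unique(c(a, b))) == 1L) {
    warning("all values tied across both groups; p = 1")
    return(structure(list(statistic = length(a) * length(b) / 2,
                          p_value = 1, alternative = alternative,
                          method = "wilcoxon", n_a = length(a),
                          n_b = length(b)), class = "cf_test"))
  }
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = alternative, exact = exact,
                correct = !exact)
  )
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 alternative = alternative, method = "wilcoxon",
                 n_a = length(a), n_b = length(b)), class = "cf_test")
}

#' @export
print.cf_test <- function(x, ...) {
  cat(sprintf("%s test (%s): statistic = %.4g, p = %.4g (n = %d vs %d)\n",
              x$method, x$alternative, x$statistic, x$p_value,
              x$n_a, x$n_b))
  invisible(x)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up FDR adjustment with enforced monotonicity.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return q-values in [0, 1], same order as `p`
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}
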