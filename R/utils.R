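#' @importFrom stats rnorm rpois rbinom runif t.test wilcox.test p.adjust
#'   pt var complete.cases aggregate setNames
#' @importFrom utils read.table write.table head
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

stop_if_not_numeric <- function(x, name) {
  if (!is.numeric(x)) stop("'", name, "' must be numeric", call. = FALSE)
}

# clip to [lo, hi]
clip01 <- function(x, lo = 0, hi = 1) pmax(pmin(x, hi), lo)

#' Order a CpG call or interval table by (chrom, position)
#'
#' Canonical ordering used throughout: chromosome lexicographic, then
#' numeric position. Keeps diffs between runs reproducible.
#'
#' @param df data frame with `chrom` and a position column
#' @param pos_col name of the position column
#' @return reordered data frame
#' @export
sort_genomic <- function(df, pos_col = "pos") {
  df[order(df$chrom, df[[pos_col]], method = "radix"), , drop = FALSE]
}

is_sorted_genomic <- function(df, pos_col = "pos") {
  o <- order(df$chrom, df[[pos_col]], method = "radix")
  identical(o, seq_len(nrow(df)))
}
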