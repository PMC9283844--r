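# Independent brute-force oracles used to check the fast implementations.

clip01 <- function(x) pmax(pmin(x, 1), 0)

# Two-component NNLS by grid search: sweep simplex weight s (step 0.001),
# optimize the overall scale analytically for each direction, return the
# weight pair minimizing the residual.
grid_nnls_2comp <- function(x, y, step = 0.001) {
  s_grid <- seq(0, 1, by = step)
  resid <- vapply(s_grid, function(s) {
    v <- x %*% c(s, 1 - s)
    scale <- max(0, sum(v * y) / sum(v * v))
    sum((y - scale * v)^2)
  }, numeric(1))
  s <- s_grid[which.min(resid)]
  c(s, 1 - s)
}

# Exact rank-sum p-value by exhaustive enumeration of all group-A
# assignments (tie-free data).
perm_wilcoxon_p <- function(a, b, alternative = "less") {
  pooled <- c(a, b)
  na <- length(a)
  ranks <- rank(pooled)
  obs <- sum(ranks[seq_len(na)])
  combos <- combn(length(pooled), na)
  stats <- apply(combos, 2, function(idx) sum(ranks[idx]))
  switch(alternative,
         less = mean(stats <= obs),
         greater = mean(stats >= obs),
         two.sided = min(1, 2 * min(mean(stats <= obs),
                                    mean(stats >= obs))))
}

# Step-up FDR by its definition: q_(i) = min over j >= i of m * p_(j) / j.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * p[o][i:m] / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Monte-Carlo permutation p-value for the difference in means.
perm_t_p <- function(a, b, n_perm = 1e5, seed = 1) {
  pooled <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  cfmix:::with_seed(seed, {
    stats <- replicate(n_perm, {
      idx <- sample(length(pooled), na)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    })
    mean(stats >= obs - 1e-12)
  })
}

# Build probe betas keyed by probe id from simulated stranded calls.
probe_betas_from_mixture <- function(mix) {
  pb <- collapse_strands(mix$calls, mix$probe_map)
  setNames(pb$beta, pb$probe_id)
}
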