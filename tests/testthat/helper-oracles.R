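# Independent oracles, deliberately naive: these re-derive expected values
# by brute force or textbook formulas and must stay free of package code.

# count length-k walks from any seed to every node by depth-first
# enumeration of neighbor sequences
dfs_walk_counts <- function(adj, seeds, max_step) {
  r <- nrow(adj)
  counts <- matrix(0, max_step, r)
  recurse <- function(node, depth) {
    if (depth > 0) counts[depth, node] <<- counts[depth, node] + 1
    if (depth == max_step) return(invisible())
    for (nb in which(adj[node, ] == 1)) recurse(nb, depth + 1)
  }
  for (s in seeds) recurse(s, 0)
  counts
}

# textbook partial correlation from the plain inverse of the sample
# covariance of z-scored columns
naive_partial_correlation <- function(x) {
  z <- scale(x)
  p <- solve(cov(z))
  r <- matrix(0, ncol(x), ncol(x))
  for (i in seq_len(ncol(x))) {
    for (j in seq_len(ncol(x))) {
      if (i != j) r[i, j] <- -p[i, j] / sqrt(p[i, i] * p[j, j])
    }
  }
  r
}

# hand-applied BH step-up: q_(i) = min_{j>=i}(p_(j) * m / j), clipped at 1
stepup_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    q_sorted[i] <- min(running, 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# two-pass Pearson correlation
two_pass_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random symmetric 0/1 graph with zero diagonal
random_graph <- function(r, density = 0.4) {
  a <- matrix(0L, r, r)
  a[upper.tri(a)] <- as.integer(runif(r * (r - 1) / 2) < density)
  a + t(a)
}

# small quick cohort config for structural tests
quick_config <- function(...) {
  args <- utils::modifyList(list(n_subjects = 24, n_regions = 28,
                                 n_timepoints = 60, n_true_seeds = 8),
                            list(...))
  do.call(sim_config, args)
}
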