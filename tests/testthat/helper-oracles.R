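# Independent oracles used to cross-check the package's implementations.
# These are deliberately naive (loops, enumeration) and share no code with
# the functions they validate.

# Benjamini-Hochberg step-up, computed literally from the definition:
# adj p of the i-th ranked p value is min over j >= i of n*p_(j)/j, capped.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(n * ranked[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# assignments of the pooled values to the first group.
mwu_enum_oracle <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  picks <- utils::combn(length(pooled), n1)
  us <- apply(picks, 2L, function(idx) u_stat(pooled[idx], pooled[-idx]))
  p_low <- mean(us <= u_obs)
  p_high <- mean(us >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Brute-force UPGMA (average linkage, Euclidean): at each step merge the two
# clusters with the smallest mean pairwise distance. Returns merge heights
# and the member set created at each merge.
upgma_oracle <- function(m) {
  D <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    best_d <- Inf
    best <- c(NA, NA)
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    heights <- c(heights, best_d)
    merges <- c(merges, list(merged))
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, merges = merges)
}

# Member sets created at each merge of an hclust tree, for comparison with
# the brute-force oracle.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    sets[[k]] <- sort(unlist(lapply(hc$merge[k, ], function(x) {
      if (x < 0) -x else sets[[x]]
    })))
  }
  sets
}
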