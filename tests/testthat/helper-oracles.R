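# Independent oracles, implemented with no reference to the package internals
# beyond the shared problem definitions.

# Exact optimal contiguous K-partition of weighted 1-D points minimising the
# weighted L1 deviation from each segment's weighted (lower-middle) median,
# in the same distance space as the clustering. Dynamic programming over
# segment ends.
dp_kmedians_objective <- function(x, w, K = 3, n = 1,
                                  transformed = TRUE) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  tx <- if (transformed) log2(x + n) else x
  m <- length(x)
  seg_cost <- matrix(Inf, m, m)
  for (i in 1:m) for (j in i:m) {
    xs <- x[i:j]; ws <- w[i:j]
    cw <- cumsum(ws)
    med <- xs[which(cw >= ceiling(sum(ws) / 2))[1]]
    tmed <- if (transformed) log2(med + n) else med
    seg_cost[i, j] <- sum(ws * abs(tx[i:j] - tmed))
  }
  dp <- matrix(Inf, K, m)
  dp[1, ] <- seg_cost[1, ]
  if (K > 1) for (k in 2:K) for (j in k:m)
    dp[k, j] <- min(dp[k - 1, (k - 1):(j - 1)] + seg_cost[k:j, j])
  dp[K, m]
}

# Exact two-sided signed-rank p-value by brute-force enumeration of all 2^n
# sign assignments (usable for n <= 12 or so).
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  Ws <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  p_le <- mean(Ws <= W_obs + 1e-9)
  p_ge <- mean(Ws >= W_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force background threshold: scan every candidate.
brute_background_threshold <- function(pos, neg) {
  cand <- sort(unique(c(0, pos, neg)))
  d <- vapply(cand, function(t) {
    fpr <- sum(neg > t) / length(neg)
    fnr <- sum(pos <= t) / length(pos)
    abs(fpr - fnr)
  }, numeric(1))
  cand[which.min(d)]
}

# Naive average-linkage agglomeration over a distance matrix, recording the
# merge order (sets merged at each step) for small n.
brute_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dist_ab <- mean(d[clusters[[a]], clusters[[b]]])
      if (dist_ab < best_d - 1e-12) { best_d <- dist_ab; best <- c(a, b) }
    }
    merges[[length(merges) + 1]] <-
      list(members = sort(c(clusters[[best[1]]], clusters[[best[2]]])),
           height = best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}
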