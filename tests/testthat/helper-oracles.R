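# Independent brute-force oracles used to verify the vectorized metric
# implementations, plus small fixture builders. These deliberately use plain
# double loops / double sums so they share no code path with the package.

oracle_within_between <- function(z, ids, own, scope) {
  # z: full matrix with NA diagonal; own/scope: node id vectors
  i <- match(own, ids); j <- match(scope, ids)
  ws <- 0; wc <- 0
  for (a in seq_along(i)) for (b in seq_along(i)) {
    if (a < b) { ws <- ws + z[i[a], i[b]]; wc <- wc + 1 }
  }
  bs <- 0; bc <- 0
  for (a in i) for (b in j) { bs <- bs + z[a, b]; bc <- bc + 1 }
  c(Z_w = ws / wc, Z_b = bs / bc)
}

oracle_pc <- function(W, memb) {
  # W: weight matrix with zero diagonal
  p <- nrow(W)
  out <- numeric(p)
  for (i in seq_len(p)) {
    k <- sum(W[i, ])
    if (k == 0) { out[i] <- 0; next }
    s2 <- 0
    for (m in unique(memb)) s2 <- s2 + (sum(W[i, memb == m]) / k)^2
    out[i] <- 1 - s2
  }
  out
}

oracle_q <- function(W, memb, gamma = 1) {
  p <- nrow(W)
  m2 <- sum(W)
  k <- rowSums(W)
  q <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (memb[i] == memb[j])
      q <- q + (W[i, j] - gamma * k[i] * k[j] / m2) / m2
  }
  unname(q)
}

# enumerate all set partitions of n elements as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) { out[[length(out) + 1]] <<- prefix; return() }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

oracle_best_q <- function(W, gamma = 1) {
  parts <- all_partitions(nrow(W))
  best <- -Inf
  k <- rowSums(W); m2 <- sum(W)
  for (memb in parts) {
    same <- outer(memb, memb, `==`)
    q <- sum(W[same]) / m2 - gamma * sum(tapply(k, memb, sum)^2) / m2^2
    if (q > best) best <- q
  }
  best
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# random positive weighted conn_matrix (masked) plus an atlas covering it
rand_masked_fixture <- function(p, n_networks, seed) {
  set.seed(seed)
  W <- matrix(runif(p * p), p, p)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  ids <- sprintf("v%02d", seq_len(p))
  dimnames(W) <- list(ids, ids)
  net <- paste0("N", rep_len(seq_len(n_networks), p))
  sys <- ifelse(as.integer(sub("N", "", net)) <= ceiling(n_networks / 2),
                "association", "sensory-motor")
  atlas <- node_atlas(ids, net, sys)
  x <- conn_matrix(W, node_ids = ids, masked = TRUE)
  list(x = x, atlas = atlas, W = W, memb = net)
}

# varimax criterion (raw, no Kaiser normalization): sum of column variances
# of squared loadings
varimax_criterion <- function(L) {
  sum(apply(L^2, 2, function(col) mean((col - mean(col))^2)))
}
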