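make_toy_conn <- function(z, ids, masked = TRUE) {
  dimnames(z) <- list(ids, ids)
  conn_matrix(z, node_ids = ids, masked = masked)
}

test_that("within/between means match hand arithmetic and the loop oracle", {
  ids <- c("a1", "a2", "b1", "b2")
  atlas <- node_atlas(ids, c("A", "A", "B", "B"), rep("association", 4))

  # constant matrix: both means equal the constant
  zc <- matrix(0.3, 4, 4)
  x <- make_toy_conn(zc, ids)
  wb <- within_between_means(x, atlas, "A", c("b1", "b2"))
  expect_equal(unname(wb), c(0.3, 0.3))

  # 2+2 toy: within z {0.4, 0.6}, between all 0.2
  z <- matrix(0.2, 4, 4)
  z[1, 2] <- z[2, 1] <- 0.4
  z[3, 4] <- z[4, 3] <- 0.6
  x <- make_toy_conn(z, ids)
  expect_equal(unname(within_between_means(x, atlas, "A", c("b1", "b2"))),
               c(0.4, 0.2))
  expect_equal(unname(within_between_means(x, atlas, "B", c("a1", "a2"))),
               c(0.6, 0.2))

  # random 20-node fixture vs brute-force double loop
  fx <- rand_masked_fixture(20, 4, seed = 10)
  for (net in unique(fx$atlas$network)) {
    own <- fx$atlas$node_id[fx$atlas$network == net]
    scope <- setdiff(fx$atlas$node_id, own)
    expect_equal(within_between_means(fx$x, fx$atlas, net, scope),
                 oracle_within_between(fx$x$z, fx$x$node_ids, own, scope),
                 tolerance = 1e-12)
  }

  expect_error(within_between_means(x, atlas, "A", character(0)), "scope")
  single <- node_atlas(ids, c("A", "B", "B", "B"), rep("association", 4))
  expect_error(within_between_means(x, single, "A", c("b1")), "fewer than 2")
})

test_that("segregation follows (Zw - Zb)/Zw with its limits", {
  expect_equal(segregation(0.1, 0.05), 0.5)
  expect_equal(segregation(0.7, 0), 1)
  expect_equal(segregation(0.4, 0.4), 0)
  expect_error(segregation(0, 0.1), "Z_w")
  expect_error(segregation(-0.2, 0.1), "Z_w")
})

test_that("network segregation uses the right scope and hits its limits", {
  # association network with no positive between edges is fully segregated
  ids <- sprintf("v%d", 1:6)
  atlas <- node_atlas(ids, c("A", "A", "B", "B", "S", "S"),
                      c(rep("association", 4), rep("sensory-motor", 2)))
  z <- matrix(-0.2, 6, 6)
  z[1, 2] <- z[2, 1] <- 0.5
  z[3, 4] <- z[4, 3] <- 0.5
  z[5, 6] <- z[6, 5] <- 0.5
  z[1, 5] <- z[5, 1] <- 0.9  # assoc-to-SM edge: must be ignored by scope
  xp <- positive_part(make_toy_conn(z, ids, masked = FALSE))
  expect_equal(network_segregation(xp, atlas, "A"), 1)
  # with scope = "all" the strong assoc-SM edge enters and lowers segregation
  expect_lt(network_segregation(xp, atlas, "A", scope = "all"), 1)

  # system segregation is the unweighted mean over member networks
  fx <- rand_masked_fixture(20, 4, seed = 21)
  nets <- system_networks(fx$atlas, "association")
  manual <- mean(vapply(nets, function(n)
    network_segregation(fx$x, fx$atlas, n), numeric(1)))
  expect_equal(system_segregation(fx$x, fx$atlas, "association"), manual,
               tolerance = 1e-12)
  # pooled-pair variant exists and differs in general
  expect_true(is.finite(system_segregation(fx$x, fx$atlas, pooled = TRUE)))
})

test_that("increasing a between-network weight never increases segregation", {
  fx <- rand_masked_fixture(20, 4, seed = 33)
  base <- system_segregation(fx$x, fx$atlas, "association")
  a <- fx$atlas
  i <- which(a$network == "N1")[1]
  j <- which(a$network == "N2")[1]
  z <- fx$x$z
  for (bump in c(0.1, 0.5, 2)) {
    z2 <- z
    z2[i, j] <- z2[j, i] <- z[i, j] + bump
    x2 <- conn_matrix(z2, fx$x$node_ids, masked = TRUE)
    expect_lte(system_segregation(x2, a, "association"), base + 1e-12)
  }
})

test_that("segregation, PC and Q are invariant to uniform positive scaling", {
  fx <- rand_masked_fixture(20, 4, seed = 8)
  xs <- conn_matrix(fx$x$z * 3.7, fx$x$node_ids, masked = TRUE)
  expect_equal(system_segregation(xs, fx$atlas),
               system_segregation(fx$x, fx$atlas), tolerance = 1e-12)
  expect_equal(participation_coefficient(xs, fx$atlas)$node,
               participation_coefficient(fx$x, fx$atlas)$node,
               tolerance = 1e-12)
  expect_equal(modularity_q(xs, fx$atlas), modularity_q(fx$x, fx$atlas),
               tolerance = 1e-12)
})

test_that("participation coefficient matches its definition and bounds", {
  ids <- c("a1", "a2", "b1", "b2")
  atlas <- node_atlas(ids, c("A", "A", "B", "B"), rep("association", 4))
  # all weight inside the node's own network -> 0
  z <- matrix(0, 4, 4); z[1, 2] <- z[2, 1] <- 0.8
  x <- make_toy_conn(z, ids)
  expect_equal(participation_coefficient(x, atlas)$node[["a1"]], 0)
  # isolated node (zero strength) -> 0 by convention
  expect_equal(participation_coefficient(x, atlas)$node[["b1"]], 0)
  # strength split equally across two networks -> 1 - 2*(1/2)^2 = 0.5
  z[1, 3] <- z[3, 1] <- 0.8
  x <- make_toy_conn(z, ids)
  expect_equal(participation_coefficient(x, atlas)$node[["a1"]], 0.5)

  # loop oracle + bounds on a random fixture with M = 5 communities
  fx <- rand_masked_fixture(20, 5, seed = 14)
  pc <- participation_coefficient(fx$x, fx$atlas)
  W <- fx$x$z; diag(W) <- 0
  expect_equal(unname(pc$node), oracle_pc(W, fx$memb), tolerance = 1e-12)
  expect_true(all(pc$node >= 0 & pc$node <= 1 - 1 / 5 + 1e-12))
})

test_that("modularity matches closed forms, the double-sum oracle and igraph", {
  # two equal disconnected cliques, partitioned by component: Q = 0.5
  ids <- sprintf("v%d", 1:6)
  atlas <- node_atlas(ids, rep(c("A", "B"), each = 3), rep("association", 6))
  z <- matrix(0, 6, 6)
  z[1:3, 1:3] <- 1; z[4:6, 4:6] <- 1; diag(z) <- 0
  x <- make_toy_conn(z, ids)
  expect_equal(modularity_q(x, atlas), 0.5)
  # a single community covering everything: Q = 0
  one <- stats::setNames(rep(1, 6), ids)
  expect_equal(modularity_q(x, atlas, partition = one), 0)

  # random 8-node weighted graph vs direct double-sum oracle, gamma 1 and 1.3
  fx <- rand_masked_fixture(8, 3, seed = 6)
  W <- fx$x$z; diag(W) <- 0
  for (g in c(1, 1.3)) {
    expect_equal(modularity_q(fx$x, fx$atlas, gamma = g),
                 oracle_q(W, fx$memb, gamma = g), tolerance = 1e-12)
  }
  # independent implementation cross-check
  gr <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  expect_equal(modularity_q(fx$x, fx$atlas),
               igraph::modularity(gr, as.integer(factor(fx$memb)),
                                  weights = igraph::E(gr)$weight),
               tolerance = 1e-12)
  expect_error(modularity_q(make_toy_conn(matrix(0, 4, 4), ids[1:4]),
                            node_atlas(ids[1:4], rep("A", 4),
                                       rep("association", 4))),
               "zero-weight")
})

test_that("louvain recovers separable and planted community structure", {
  # two disconnected cliques -> the two components
  ids <- sprintf("v%d", 1:8)
  atlas <- node_atlas(ids, rep(c("A", "B"), each = 4), rep("association", 8))
  z <- matrix(0, 8, 8)
  z[1:4, 1:4] <- 1; z[5:8, 5:8] <- 1; diag(z) <- 0
  x <- make_toy_conn(z, ids)
  lp <- louvain_partition(x, atlas, gamma = 1, seed = 1)
  expect_equal(adjusted_rand(lp$membership, rep(1:2, each = 4)), 1)

  # planted 5-block matrix: labels recovered up to relabeling (ARI = 1)
  nets <- rep(paste0("N", 1:5), each = 6)
  a5 <- node_atlas(sprintf("n%02d", 1:30), nets, rep("association", 30))
  S <- make_block_covariance(a5, 0.5, 0.05)
  ts <- simulate_subject_timeseries(S, 2000, seed = 12)
  xp <- positive_part(connectivity(ts))
  lp5 <- louvain_partition(xp, a5, gamma = 1.2, seed = 4)
  expect_equal(adjusted_rand(lp5$membership, nets), 1)

  # best-Q restart policy is deterministic under a fixed seed
  lp5b <- louvain_partition(xp, a5, gamma = 1.2, seed = 4)
  expect_identical(lp5$membership, lp5b$membership)
})

test_that("unassigned nodes are excluded from every metric", {
  base <- default_atlas()
  aug <- default_atlas(n_unassigned = 5)
  S <- make_block_covariance(aug, 0.45, 0.1)
  ts <- simulate_subject_timeseries(S, 300, seed = 2)
  x_aug <- connectivity(ts)
  x_base <- connectivity(ts[, base$node_id])
  m_aug <- compute_metrics(x_aug, aug, "s")
  m_base <- compute_metrics(x_base, base, "s")
  expect_equal(m_aug, m_base, tolerance = 1e-12)
})

test_that("subject segregation and atlas-partition Q are positively coupled", {
  sp <- cohort_spec(n_subjects = 30, n_frames = 120, seed = 15)
  co <- simulate_cohort(sp)
  mt <- metrics_table(co)
  expect_gt(cor(mt$system_segregation, mt$modularity_Q), 0)
})
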