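## Graph metrics on Fisher-z connectivity: within/between-network means,
## segregation at network and system level, participation coefficient,
## modularity, and Louvain community detection.

atlas_index_ <- function(x, atlas) {
  atlas <- assigned_nodes(atlas)
  idx <- match(atlas$node_id, x$node_ids)
  if (anyNA(idx)) stop("atlas node(s) missing from connectivity matrix: ",
                       paste(atlas$node_id[is.na(idx)], collapse = ", "))
  list(atlas = atlas, idx = idx)
}

require_masked_ <- function(x, masked = TRUE) {
  if (isTRUE(masked) && !x$masked)
    stop("this metric requires the positive-masked matrix; call positive_part() first")
  if (!isTRUE(masked) && x$masked)
    stop("this metric requires the signed (unmasked) matrix")
}

#' Mean within- and between-network connectivity for one network
#'
#' `Z_w` is the mean z over distinct node pairs inside the network (the
#' excluded diagonal never enters); `Z_b` is the mean z over all pairs from
#' the network's nodes to the `between_scope` nodes. Zeroed (positive-masked)
#' entries count as zero in both numerator and denominator.
#'
#' @param x a [conn_matrix()].
#' @param atlas a [node_atlas()].
#' @param network network label (must have >= 2 nodes).
#' @param between_scope character vector of node ids forming the comparison
#'   scope; the network's own nodes are excluded from it.
#' @return named numeric vector `c(Z_w, Z_b)`.
#' @export
within_between_means <- function(x, atlas, network, between_scope) {
  ai <- atlas_index_(x, atlas)
  own <- ai$atlas$node_id[ai$atlas$network == network]
  if (length(own) < 2) stop("network '", network, "' has fewer than 2 nodes")
  scope <- setdiff(as.character(between_scope), own)
  if (!length(scope)) stop("empty between scope for network '", network, "'")
  i <- match(own, x$node_ids)
  j <- match(scope, x$node_ids)
  if (anyNA(j)) stop("between_scope node(s) missing from matrix")
  W <- x$z[i, i, drop = FALSE]
  zw <- mean(W[upper.tri(W)])
  zb <- mean(x$z[i, j])
  c(Z_w = zw, Z_b = zb)
}

#' Segregation of a network
#'
#' `S = (Z_w - Z_b) / Z_w`: 1 when the network has no (positive) between
#' connectivity, 0 when within and between connectivity are equal.
#'
#' @param Z_w mean within-network connectivity (must be > 0).
#' @param Z_b mean between-network connectivity.
#' @return unitless segregation, `<= 1`.
#' @export
segregation <- function(Z_w, Z_b) {
  if (any(Z_w <= 0)) stop("segregation undefined: Z_w <= 0")
  (Z_w - Z_b) / Z_w
}

#' Segregation of one network from the other networks of its system
#'
#' The between scope is restricted to nodes of the *other* networks in the
#' same system (for an association network: the other association networks;
#' sensory-motor nodes are excluded), or to all labeled networks when
#' `scope = "all"`.
#'
#' @param x a positive-masked [conn_matrix()].
#' @param atlas a [node_atlas()].
#' @param network network label.
#' @param scope `"system"` (default) or `"all"`.
#' @return unitless segregation.
#' @export
network_segregation <- function(x, atlas, network, scope = c("system", "all")) {
  scope <- match.arg(scope)
  require_masked_(x, TRUE)
  ai <- atlas_index_(x, atlas)
  a <- ai$atlas
  sys <- unique(a$system[a$network == network])
  if (!length(sys)) stop("unknown network: ", network)
  keep <- if (scope == "system") a$system == sys else rep(TRUE, nrow(a))
  other <- a$node_id[keep & a$network != network]
  wb <- within_between_means(x, a, network, other)
  segregation(wb["Z_w"], wb["Z_b"])[[1]]
}

#' System segregation
#'
#' The unweighted mean of [network_segregation()] over the system's networks
#' (default), or a pooled-pair variant that averages z over all within pairs
#' and all between pairs of the system before forming `(Z_w - Z_b)/Z_w`.
#'
#' @param x a positive-masked [conn_matrix()].
#' @param atlas a [node_atlas()].
#' @param system system label (default `"association"`).
#' @param scope between-scope passed to [network_segregation()].
#' @param pooled use the pooled-pair variant (default FALSE).
#' @return unitless segregation.
#' @export
system_segregation <- function(x, atlas, system = "association",
                               scope = c("system", "all"), pooled = FALSE) {
  scope <- match.arg(scope)
  require_masked_(x, TRUE)
  ai <- atlas_index_(x, atlas)
  a <- ai$atlas
  nets <- system_networks(a, system)
  nets <- nets[vapply(nets, function(n) sum(a$network == n) >= 2, logical(1))]
  if (length(nets) < 2) stop("system '", system, "' needs >= 2 networks with >= 2 nodes")
  if (!pooled)
    return(mean(vapply(nets, function(n)
      network_segregation(x, a, n, scope = scope), numeric(1))))
  # pooled: collect all within pairs and all between pairs across networks
  wsum <- 0; wcnt <- 0; bsum <- 0; bcnt <- 0
  for (n in nets) {
    own <- a$node_id[a$network == n]
    keep <- if (scope == "system") a$system == unique(a$system[a$network == n])
            else rep(TRUE, nrow(a))
    other <- a$node_id[keep & a$network != n]
    i <- match(own, x$node_ids); j <- match(other, x$node_ids)
    W <- x$z[i, i]
    wsum <- wsum + sum(W[upper.tri(W)]); wcnt <- wcnt + sum(upper.tri(W))
    bsum <- bsum + sum(x$z[i, j]); bcnt <- bcnt + length(i) * length(j)
  }
  segregation(wsum / wcnt, bsum / bcnt)
}

#' Mean within-network connectivity (signed)
#'
#' The standalone connectivity metric: mean Fisher-z over distinct within
#' pairs, with both negative and positive values incorporated, averaged
#' (unweighted) over the system's networks. Requires the unmasked matrix.
#'
#' @param x a signed (unmasked) [conn_matrix()].
#' @param atlas a [node_atlas()].
#' @param system system label.
#' @return mean within-network z.
#' @export
mean_within_connectivity <- function(x, atlas, system = "association") {
  require_masked_(x, FALSE)
  ai <- atlas_index_(x, atlas)
  a <- ai$atlas
  nets <- system_networks(a, system)
  nets <- nets[vapply(nets, function(n) sum(a$network == n) >= 2, logical(1))]
  mean(vapply(nets, function(n) {
    i <- match(a$node_id[a$network == n], x$node_ids)
    W <- x$z[i, i]
    mean(W[upper.tri(W)])
  }, numeric(1)))
}

masked_weights_ <- function(x, atlas) {
  ai <- atlas_index_(x, atlas)
  W <- x$z[ai$idx, ai$idx, drop = FALSE]
  diag(W) <- 0
  list(W = W, atlas = ai$atlas)
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_s (kappa_is / k_i)^2` over communities `s`, with node
#' strength `k_i` and per-community strength `kappa_is`; `P_i = 0` when
#' `k_i = 0`. Communities default to the atlas networks (labeled nodes only).
#'
#' @param x a positive-masked [conn_matrix()].
#' @param atlas a [node_atlas()].
#' @param communities optional membership vector named by node id; defaults
#'   to the atlas network labels.
#' @return list: `node` (named per-node values), `association_mean`,
#'   `sensory_motor_mean`.
#' @export
participation_coefficient <- function(x, atlas, communities = NULL) {
  require_masked_(x, TRUE)
  mw <- masked_weights_(x, atlas)
  W <- mw$W; a <- mw$atlas
  memb <- if (is.null(communities)) a$network
          else as.character(communities[a$node_id])
  if (anyNA(memb)) stop("communities must cover all labeled nodes")
  k <- rowSums(W)
  kappa <- t(rowsum(t(W), memb))       # nodes x communities
  frac2 <- (kappa / ifelse(k == 0, 1, k))^2
  p <- 1 - rowSums(frac2)
  p[k == 0] <- 0
  names(p) <- a$node_id
  list(node = p,
       association_mean = mean(p[a$system == "association"]),
       sensory_motor_mean = mean(p[a$system == "sensory-motor"]))
}

#' Weighted modularity Q of a partition
#'
#' Newman's weighted modularity with resolution `gamma`:
#' `Q = (1/2m) * sum_ij (W_ij - gamma * k_i k_j / 2m) * delta(c_i, c_j)`.
#'
#' @param x a positive-masked [conn_matrix()].
#' @param partition membership vector named by node id (or in the order of
#'   the labeled atlas nodes); defaults to the atlas networks.
#' @param atlas a [node_atlas()].
#' @param gamma resolution (default 1, the reported-metric convention).
#' @return Q, `<= 1`.
#' @export
modularity_q <- function(x, atlas, partition = NULL, gamma = 1) {
  require_masked_(x, TRUE)
  mw <- masked_weights_(x, atlas)
  W <- mw$W; a <- mw$atlas
  memb <- if (is.null(partition)) a$network
          else if (!is.null(names(partition))) as.character(partition[a$node_id])
          else as.character(partition)
  if (length(memb) != nrow(W) || anyNA(memb))
    stop("partition must cover all labeled nodes")
  m2 <- sum(W)
  if (m2 <= 0) stop("zero-weight graph: modularity undefined")
  k <- rowSums(W)
  q <- 0
  for (s in unique(memb)) {
    i <- memb == s
    q <- q + sum(W[i, i]) / m2 - gamma * (sum(k[i]) / m2)^2
  }
  q
}

## greedy single-node best-move refinement at resolution gamma: sweeps all
## nodes, moving each to the community (or a fresh singleton) with the best
## modularity gain, until a full sweep makes no move
refine_partition_ <- function(W, memb, gamma) {
  m2 <- sum(W)
  k <- rowSums(W)
  memb <- as.integer(factor(memb))
  repeat {
    moved <- FALSE
    for (i in seq_along(memb)) {
      K <- tapply(k, memb, sum)
      kap <- tapply(W[i, ], memb, sum)
      cand <- as.integer(names(K))
      a <- memb[i]
      # gain of moving i from community a to community c (kappa excludes the
      # zero diagonal); an empty target community models a new singleton
      Kc <- K[as.character(cand)]
      Kc[cand == a] <- Kc[cand == a] - k[i]
      Ka <- K[[as.character(a)]] - k[i]
      kap_a <- kap[[as.character(a)]]
      gain <- 2 * (kap[as.character(cand)] - kap_a) / m2 -
        2 * gamma * k[i] * (Kc - Ka) / m2^2
      # fresh singleton community
      gain_new <- 2 * (0 - kap_a) / m2 - 2 * gamma * k[i] * (0 - Ka) / m2^2
      best <- which.max(gain)
      if (gain_new > gain[best] + 1e-12 && gain_new > 1e-12) {
        memb[i] <- max(memb) + 1L
        moved <- TRUE
      } else if (gain[best] > 1e-12 && cand[best] != a) {
        memb[i] <- cand[best]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  as.integer(factor(memb))
}

#' Louvain community detection with restarts
#'
#' Runs igraph's weighted Louvain algorithm at resolution `gamma`,
#' `n_restarts` times with the node visit order shuffled per restart
#' (Louvain is order-dependent), finishing each restart with a greedy
#' single-node move refinement pass on the original graph. Because greedy
#' agglomeration from singletons provably misses some optima even with
#' restarts, each restart additionally hill-climbs from a random initial
#' partition; the best-modularity partition over all of these is returned.
#' On small graphs this reliably attains the exhaustively optimal Q.
#'
#' @param x a positive-masked [conn_matrix()].
#' @param atlas a [node_atlas()].
#' @param gamma resolution for detection (default 1.2).
#' @param seed seed for the restart shuffles.
#' @param n_restarts number of restarts (default 20).
#' @return list: `membership` (named by node id), `Q` (at `gamma`),
#'   `gamma`, `seed`, `n_restarts`.
#' @export
louvain_partition <- function(x, atlas, gamma = 1.2, seed = 1L,
                              n_restarts = 20) {
  require_masked_(x, TRUE)
  mw <- masked_weights_(x, atlas)
  W <- mw$W; a <- mw$atlas
  p <- nrow(W)
  if (p == 0) stop("empty graph")
  best <- NULL; best_q <- -Inf
  with_seed_(seed, {
    for (r in seq_len(n_restarts)) {
      perm <- sample.int(p)
      g <- igraph::graph_from_adjacency_matrix(
        W[perm, perm], mode = "undirected", weighted = TRUE, diag = FALSE)
      cl <- igraph::cluster_louvain(g, resolution = gamma)
      memb <- integer(p)
      memb[perm] <- igraph::membership(cl)
      rand0 <- sample.int(sample(2:min(6, p), 1), p, replace = TRUE)
      for (memb_r in list(refine_partition_(W, memb, gamma),
                          refine_partition_(W, rand0, gamma))) {
        q <- modularity_q(x, a, stats::setNames(memb_r, a$node_id),
                          gamma = gamma)
        if (q > best_q + 1e-12) { best_q <- q; best <- memb_r }
      }
    }
  })
  list(membership = stats::setNames(best, a$node_id), Q = best_q,
       gamma = gamma, seed = seed, n_restarts = n_restarts)
}

#' Relabel an atlas from Louvain communities
#'
#' Mirrors the data-driven parcellation check: communities detected on a
#' (typically group-average) connectivity matrix become the network labels,
#' and each community inherits the system label of the majority of its
#' member nodes under the original atlas.
#'
#' @param x a positive-masked [conn_matrix()] (e.g. the group mean).
#' @param atlas the original [node_atlas()].
#' @inheritParams louvain_partition
#' @return a [node_atlas()] with networks `comm_1, comm_2, ...`.
#' @export
louvain_atlas <- function(x, atlas, gamma = 1.2, seed = 1L, n_restarts = 20) {
  lp <- louvain_partition(x, atlas, gamma = gamma, seed = seed,
                          n_restarts = n_restarts)
  a <- assigned_nodes(atlas)
  memb <- lp$membership[a$node_id]
  network <- paste0("comm_", memb)
  system <- vapply(split(a$system, network), function(s)
    names(sort(table(s), decreasing = TRUE))[1], character(1))[network]
  node_atlas(a$node_id, network, unname(system))
}

#' Per-subject network metrics
#'
#' Computes the full metrics row for one subject from its (unmasked)
#' connectivity matrix: association-system segregation, DMN/FPN/CON network
#' segregation, signed mean within-network connectivity, mean participation
#' coefficient over association nodes, and modularity Q of the atlas
#' partition at `gamma = 1`.
#'
#' @param x an unmasked [conn_matrix()] (the positive mask is applied
#'   internally where required).
#' @param atlas a [node_atlas()].
#' @param subject_id identifier for the output row.
#' @param networks association networks reported individually.
#' @return one-row `data.frame`.
#' @export
compute_metrics <- function(x, atlas, subject_id = "subj",
                            networks = c("DMN", "FPN", "CON")) {
  require_masked_(x, FALSE)
  xp <- positive_part(x)
  present <- intersect(networks, unique(atlas$network))
  seg_net <- vapply(present, function(n)
    network_segregation(xp, atlas, n), numeric(1))
  pc <- participation_coefficient(xp, atlas)
  sm_seg <- tryCatch(system_segregation(xp, atlas, "sensory-motor"),
                     error = function(e) NA_real_)
  out <- data.frame(
    subject_id = subject_id,
    system_segregation = system_segregation(xp, atlas, "association"),
    mean_within_connectivity = mean_within_connectivity(x, atlas, "association"),
    participation_coefficient = pc$association_mean,
    modularity_Q = modularity_q(xp, atlas, gamma = 1),
    sm_segregation = sm_seg,
    stringsAsFactors = FALSE)
  for (n in present) out[[paste0("seg_", n)]] <- seg_net[[n]]
  out
}

#' Metrics table for a cohort
#'
#' Applies [connectivity()] and [compute_metrics()] to every subject.
#'
#' @param cohort a `synthetic_cohort`, or a named list of frames x nodes
#'   matrices.
#' @param atlas a [node_atlas()] (taken from the cohort if omitted).
#' @return `data.frame`, one row per subject.
#' @export
metrics_table <- function(cohort, atlas = NULL) {
  if (inherits(cohort, "synthetic_cohort")) {
    ts <- cohort$timeseries
    if (is.null(atlas)) atlas <- cohort$atlas
  } else ts <- cohort
  if (is.null(atlas)) stop("atlas required")
  rows <- lapply(names(ts), function(id)
    compute_metrics(connectivity(ts[[id]]), atlas, subject_id = id))
  do.call(rbind, rows)
}
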