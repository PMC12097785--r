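#' Construct a node atlas
#'
#' A node atlas assigns every node of a parcellation to a functional network
#' (e.g. default mode, fronto-parietal) and every named network to a system
#' (`"association"` or `"sensory-motor"`). Nodes that belong to no labeled
#' network carry `system = "unassigned"` and are dropped before any metric is
#' computed.
#'
#' @param node_id character or integer vector of unique node identifiers.
#' @param network character vector, one network label per node. Unlabeled
#'   nodes use `NA` or `"unassigned"`.
#' @param system character vector, one of `"association"`,
#'   `"sensory-motor"`, `"unassigned"` per node. Every named network must map
#'   to exactly one system.
#' @return A `data.frame` of class `node_atlas` with columns `node_id`,
#'   `network`, `system`.
#' @export
node_atlas <- function(node_id, network, system) {
  node_id <- as.character(node_id)
  if (anyDuplicated(node_id)) stop("node_id values must be unique")
  if (length(network) != length(node_id) || length(system) != length(node_id))
    stop("node_id, network, system must have equal length")
  network <- as.character(network)
  network[is.na(network)] <- "unassigned"
  system <- as.character(system)
  system[network == "unassigned"] <- "unassigned"
  ok <- c("association", "sensory-motor", "unassigned")
  if (!all(system %in% ok))
    stop("system labels must be one of: ", paste(ok, collapse = ", "))
  # a named network may not straddle systems
  map <- unique(data.frame(network = network, system = system))
  dup <- map$network[duplicated(map$network)]
  if (length(dup))
    stop("network(s) mapped to more than one system: ",
         paste(unique(dup), collapse = ", "))
  out <- data.frame(node_id = node_id, network = network, system = system,
                    stringsAsFactors = FALSE)
  class(out) <- c("node_atlas", "data.frame")
  out
}

#' Default 90-node test atlas
#'
#' A compact parcellation used throughout the synthetic cohorts: five
#' association networks (DMN, FPN, CON, DA, VA; 50 nodes) and four
#' sensory-motor networks (visual, auditory, somatomotor hand and mouth;
#' 40 nodes), mirroring the nine-network association/sensory-motor layout of
#' typical cortical parcellations at a size that keeps simulations fast.
#'
#' @param n_unassigned number of additional unlabeled nodes to append
#'   (default 0); useful for testing that unassigned nodes are excluded.
#' @return a [node_atlas()].
#' @export
default_atlas <- function(n_unassigned = 0) {
  assoc <- c(DMN = 12, FPN = 10, CON = 10, DA = 9, VA = 9)
  sm <- c(visual = 12, auditory = 8, smhand = 12, smmouth = 8)
  network <- c(rep(names(assoc), assoc), rep(names(sm), sm),
               rep("unassigned", n_unassigned))
  system <- c(rep("association", sum(assoc)), rep("sensory-motor", sum(sm)),
              rep("unassigned", n_unassigned))
  node_atlas(sprintf("n%03d", seq_along(network)), network, system)
}

#' Drop unassigned nodes from an atlas
#' @param atlas a [node_atlas()].
#' @return the atlas restricted to labeled nodes.
#' @export
assigned_nodes <- function(atlas) {
  out <- atlas[atlas$system != "unassigned", , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("node_atlas", "data.frame")
  out
}

#' Networks belonging to a system
#' @param atlas a [node_atlas()].
#' @param system system label.
#' @return character vector of network labels.
#' @export
system_networks <- function(atlas, system = "association") {
  unique(atlas$network[atlas$system == system])
}
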