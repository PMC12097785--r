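#' Connectivity matrix container
#'
#' Holds a symmetric node-by-node matrix of Fisher z-transformed correlations.
#' The diagonal is stored as `NA` and treated as excluded: no within- or
#' between-network mean ever includes it. The `masked` flag records whether
#' negative edges have been zeroed ([positive_part()]); metrics that are
#' defined on positive edges (segregation, participation coefficient,
#' modularity) refuse unmasked input, and the signed mean within-network
#' connectivity metric refuses masked input.
#'
#' @param z numeric nodes x nodes matrix (Fisher z units).
#' @param node_ids node identifiers, in matrix order.
#' @param masked logical, `TRUE` if negatives have been zeroed.
#' @return an object of class `conn_matrix`.
#' @export
conn_matrix <- function(z, node_ids = colnames(z), masked = FALSE) {
  z <- as.matrix(z)
  if (nrow(z) != ncol(z)) stop("z must be square")
  if (is.null(node_ids)) node_ids <- sprintf("n%03d", seq_len(ncol(z)))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != ncol(z)) stop("node_ids length must match z")
  diag(z) <- NA_real_
  off <- z[upper.tri(z) | lower.tri(z)]
  if (any(!is.finite(off))) stop("non-finite off-diagonal entries in z")
  if (max(abs(z - t(z)), na.rm = TRUE) > 1e-12) stop("z must be symmetric")
  dimnames(z) <- list(node_ids, node_ids)
  structure(list(z = z, node_ids = node_ids, masked = isTRUE(masked)),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix: %d nodes, %s>\n", length(x$node_ids),
              if (x$masked) "positive-masked" else "signed"))
  invisible(x)
}

#' Pearson correlation matrix of node time courses
#'
#' Correlates each node's time course with every other node's.
#'
#' @param ts frames x nodes numeric matrix (column names = node ids), or a
#'   list with elements `data` and `node_ids`.
#' @return nodes x nodes Pearson r matrix with unit diagonal.
#' @export
correlation_matrix <- function(ts) {
  if (is.list(ts) && !is.data.frame(ts)) {
    m <- ts$data
    if (!is.null(ts$node_ids)) colnames(m) <- ts$node_ids
  } else m <- as.matrix(ts)
  if (nrow(m) < 2) stop("need at least 2 frames")
  if (anyNA(m)) stop("time series contains missing values")
  v <- apply(m, 2, stats::var)
  if (any(v <= 0)) {
    bad <- colnames(m)[v <= 0]
    if (is.null(bad)) bad <- which(v <= 0)
    stop("zero-variance node(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(m)
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Fisher z transform of a correlation matrix
#'
#' Applies `atanh` elementwise off the diagonal. Correlations with magnitude
#' at or beyond `clip` are clipped first so duplicated node time courses
#' (r = 1) do not produce infinities.
#'
#' @param r correlation matrix with `|r| <= 1`.
#' @param clip magnitude bound applied before `atanh` (default `1 - 1e-6`).
#' @param node_ids optional node identifiers (default from `colnames(r)`).
#' @return a [conn_matrix()] (unmasked).
#' @export
fisher_z <- function(r, clip = 1 - 1e-6, node_ids = colnames(r)) {
  r <- as.matrix(r)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  z <- atanh(r)
  conn_matrix(z, node_ids = node_ids, masked = FALSE)
}

#' Retain only positive connectivity
#'
#' Zeroes negative edges, keeping the matrix shape stable; zeroed entries
#' still count (as zero) in the denominators of pairwise means. Idempotent.
#'
#' @param x a [conn_matrix()].
#' @return a positive-masked [conn_matrix()].
#' @export
positive_part <- function(x) {
  stopifnot(inherits(x, "conn_matrix"))
  z <- x$z
  z[!is.na(z) & z < 0] <- 0
  diag(z) <- 0  # placeholder; conn_matrix() re-sets it to NA
  conn_matrix(z, node_ids = x$node_ids, masked = TRUE)
}

#' Connectivity from a time-series matrix in one step
#' @inheritParams correlation_matrix
#' @inheritParams fisher_z
#' @return a [conn_matrix()] (unmasked, Fisher z units).
#' @export
connectivity <- function(ts, clip = 1 - 1e-6) {
  fisher_z(correlation_matrix(ts), clip = clip)
}

#' Read a delimited node time-series file
#'
#' Expects a tab-delimited file, frames in rows, one column per node, header
#' row of node ids.
#' @param path file path.
#' @return frames x nodes numeric matrix with node ids as column names.
#' @export
read_timeseries <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  as.matrix(d)
}

#' Write a connectivity matrix as delimited text
#' @param x a [conn_matrix()].
#' @param path output path.
#' @export
write_connectivity <- function(x, path) {
  stopifnot(inherits(x, "conn_matrix"))
  d <- as.data.frame(x$z)
  d <- cbind(node_id = x$node_ids, d)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a connectivity matrix written by [write_connectivity()]
#' @param path file path.
#' @param masked logical flag to attach (the file does not store it).
#' @return a [conn_matrix()].
#' @export
read_connectivity <- function(path, masked = FALSE) {
  d <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(d$node_id)
  z <- as.matrix(d[, -1, drop = FALSE])
  conn_matrix(z, node_ids = ids, masked = masked)
}
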