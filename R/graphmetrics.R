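#' Global metrics of directed thresholded connectivity graphs
#'
#' All metrics are computed on the binarised graph: topological distance is
#' the minimum number of edges from one node to another (respecting edge
#' direction), so retained correlation weights play no role in the metrics
#' themselves.
#'
#' Conventions:
#' * Per-node total degree is the number of distinct neighbours (an edge in
#'   either direction). On graphs produced by [direct_and_threshold()] —
#'   which carry at most one direction per pair — this is identically
#'   `k_in + k_out`, and the mean equals `2 |E| / N`; on graphs with
#'   reciprocal edges it keeps the mean degree bounded by `N - 1` and makes
#'   the complete graph a fixed point of all four metrics.
#' * Clustering uses the undirected projection (edge present iff either
#'   direction exists): `C_i = 2 t_i / (k_i (k_i - 1))` with `t_i` the number
#'   of triangles through node i, and `C_i = 0` when `k_i < 2`. With at most
#'   one directed edge per pair the projection is lossless for triangle
#'   counting.
#' * Unreachable ordered pairs have infinite distance and contribute 0 to the
#'   efficiency sums.
#'
#' @name graphmetrics
NULL

as_adjacency <- function(graph) {
  if (inherits(graph, "tep_graph")) {
    a <- graph$adjacency
  } else if (is.matrix(graph)) {
    a <- graph
  } else {
    stop_invalid("`graph` must be a tep_graph or a square binary matrix.")
  }
  if (nrow(a) != ncol(a)) stop_invalid("Adjacency must be square.")
  a <- (a != 0) * 1L
  diag(a) <- 0L
  a
}

#' Node degrees
#'
#' @param graph A `tep_graph` or binary adjacency matrix (rows = source).
#' @return A list with `per_node` (tibble of `node`, `k_in`, `k_out`,
#'   `degree` = distinct neighbours) and `mean_degree`.
#' @export
degrees <- function(graph) {
  a <- as_adjacency(graph)
  u <- pmax(a, t(a))
  per <- tibble::new_tibble(list(
    node = rownames(a) %||% as.character(seq_len(nrow(a))),
    k_in = unname(colSums(a)),
    k_out = unname(rowSums(a)),
    degree = unname(rowSums(u))
  ), nrow = nrow(a))
  list(per_node = per, mean_degree = mean(per$degree))
}

#' Clustering coefficients
#'
#' @inheritParams degrees
#' @return A list with `per_node` (tibble of `node`, `k`, `triangles`, `C`)
#'   and `mean_clustering` (unweighted mean over all nodes).
#' @export
clustering_coef <- function(graph) {
  a <- as_adjacency(graph)
  u <- pmax(a, t(a))
  k <- rowSums(u)
  tri <- diag(u %*% u %*% u) / 2
  ci <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  per <- tibble::new_tibble(list(
    node = rownames(a) %||% as.character(seq_len(nrow(a))),
    k = unname(k), triangles = unname(tri), C = unname(ci)
  ), nrow = nrow(a))
  list(per_node = per, mean_clustering = mean(ci))
}

#' Directed shortest-path lengths
#'
#' Breadth-first topological distances respecting edge direction;
#' `Inf` for unreachable ordered pairs, 0 on the diagonal.
#'
#' @inheritParams degrees
#' @return An N x N numeric matrix of distances.
#' @export
shortest_path_lengths <- function(graph) {
  a <- as_adjacency(graph)
  d <- spl_adj(a)
  dimnames(d) <- dimnames(a)
  d
}

# simultaneous BFS from all sources via boolean matrix powers: reach[s, j]
# becomes positive once j is reachable from s in <= level steps
spl_adj <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  if (n == 0 || sum(a) == 0) return(d)
  storage.mode(a) <- "double"
  reach <- a
  level <- 1
  repeat {
    new <- reach > 0 & is.infinite(d)
    if (!any(new)) break
    d[new] <- level
    level <- level + 1
    if (level > n) break
    reach <- reach %*% a
  }
  d
}

ge_adj <- function(a) {
  n <- nrow(a)
  if (n < 2) return(0)
  inv <- 1 / spl_adj(a)
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs (diagonal
#' excluded), with `1 / Inf = 0`; lies in `[0, 1]` and equals 1 only when
#' every ordered pair is directly connected.
#'
#' @inheritParams degrees
#' @return A single number.
#' @export
global_efficiency <- function(graph) {
  ge_adj(as_adjacency(graph))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the directed subgraph induced on
#' its neighbourhood (nodes linked to it in either direction, the node itself
#' removed); 0 for nodes with fewer than 2 neighbours. If all neighbours of a
#' node are mutually linked in both directions its local efficiency is 1,
#' mirroring the maximal-clustering limit.
#'
#' @inheritParams degrees
#' @return A list with `per_node` (tibble of `node`, `n_neighbors`, `LE`) and
#'   `local_efficiency` (mean over all nodes).
#' @export
local_efficiency <- function(graph) {
  a <- as_adjacency(graph)
  u <- pmax(a, t(a))
  n <- nrow(a)
  le <- numeric(n)
  nn <- integer(n)
  for (i in seq_len(n)) {
    nb <- which(u[i, ] == 1L)
    nn[i] <- length(nb)
    le[i] <- if (length(nb) < 2) 0 else ge_adj(a[nb, nb, drop = FALSE])
  }
  per <- tibble::new_tibble(list(
    node = rownames(a) %||% as.character(seq_len(nrow(a))),
    n_neighbors = nn, LE = le
  ), nrow = nrow(a))
  list(per_node = per, local_efficiency = mean(le))
}

#' All four global network metrics
#'
#' Mean degree, mean clustering coefficient, local efficiency and global
#' efficiency of one thresholded graph, the per-participant-per-condition
#' quantities entering the group statistics.
#'
#' @inheritParams degrees
#' @param symmetrize Compute distances on the undirected projection instead
#'   of respecting edge direction (degree and clustering are unaffected).
#' @return A `tep_metrics` object; use [tidy()] for the per-node table and
#'   `as_tibble()`/`glance()`-style access via `$` for the four global values.
#' @export
network_metrics <- function(graph, symmetrize = FALSE) {
  a <- as_adjacency(graph)
  ad <- if (symmetrize) pmax(a, t(a)) else a
  deg <- degrees(a)
  cl <- clustering_coef(a)
  le <- local_efficiency(ad)
  ge <- global_efficiency(ad)
  per <- deg$per_node
  per$C <- cl$per_node$C
  per$LE <- le$per_node$LE
  structure(
    list(
      mean_degree = deg$mean_degree,
      mean_clustering = cl$mean_clustering,
      local_efficiency = le$local_efficiency,
      global_efficiency = ge,
      per_node = per,
      symmetrized = symmetrize
    ),
    class = "tep_metrics"
  )
}

#' @export
print.tep_metrics <- function(x, ...) {
  cat(sprintf(
    "<tep_metrics> mean degree %.3f | clustering %.3f | LE %.3f | GE %.3f\n",
    x$mean_degree, x$mean_clustering, x$local_efficiency, x$global_efficiency
  ))
  invisible(x)
}
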