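#' Network measures on daily interaction matrices
#'
#' All binary measures (edge density, components, degree, local
#' clustering) treat a dyad as connected iff it recorded at least one
#' interaction; no weight threshold is applied. Weighted information is
#' used only by [filter_by_mean_degree()] (a visualization aid) and
#' [average_matrices()] (block averaging for temporal comparisons).
#'
#' @name netmetrics
NULL

# symmetric matrix (NA diagonal allowed) -> igraph binary graph
as_binary_graph <- function(matrix) {
  m <- as.matrix(matrix)
  diag(m) <- 0
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (any(m[!is.na(m)] < 0)) stop("counts must be non-negative")
  m[is.na(m)] <- 0
  adj <- (m >= 1) * 1
  if (!isSymmetric(unname(adj))) stop("matrix must be symmetric")
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Edge density of an interaction network
#'
#' Proportion of dyads with at least one interaction out of all possible
#' dyads n(n-1)/2.
#'
#' @param matrix symmetric interaction count matrix (NA diagonal allowed).
#' @return density in [0, 1].
#' @export
edge_density <- function(matrix) {
  m <- as.matrix(matrix)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 nodes")
  ut <- m[upper.tri(m)]
  sum(ut >= 1, na.rm = TRUE) / dyad_count(n)
}

#' Connected components of an interaction network
#'
#' @param matrix symmetric interaction count matrix.
#' @return list with `count` and `membership` (named integer vector).
#' @export
graph_components <- function(matrix) {
  g <- as_binary_graph(matrix)
  comp <- igraph::components(g)
  list(count = comp$no, membership = comp$membership, sizes = comp$csize)
}

#' Node degree and local clustering coefficient
#'
#' Degree counts a node's immediate neighbours on the binary graph. The
#' local clustering coefficient is the number of edges among a node's
#' neighbours divided by k(k-1)/2, defined as 0 for nodes of degree < 2.
#'
#' @param matrix symmetric interaction count matrix.
#' @return data.frame with columns `node`, `degree`, `clustering`.
#' @examples
#' m <- matrix(0, 4, 4); m[1, 2] <- m[2, 1] <- 1
#' m[1, 3] <- m[3, 1] <- 1; m[2, 3] <- m[3, 2] <- 1
#' m[1, 4] <- m[4, 1] <- 1  # triangle plus a pendant at node 1
#' degree_and_clustering(m)$clustering[1]  # 1/3
#' @export
degree_and_clustering <- function(matrix) {
  g <- as_binary_graph(matrix)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[deg < 2] <- 0
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_along(deg))
  data.frame(node = nodes, degree = as.integer(deg), clustering = cc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter a weighted network by mean edge weight
#'
#' Visualization aid: retains edges whose weight is at least the mean
#' nonzero edge weight, zeroing the rest. Never used in inference.
#'
#' @param matrix symmetric interaction count matrix.
#' @return matrix of the same shape with sub-mean edges zeroed.
#' @export
filter_by_mean_degree <- function(matrix) {
  m <- as.matrix(matrix)
  ut <- m[upper.tri(m)]
  nz <- ut[!is.na(ut) & ut > 0]
  if (length(nz) == 0) return(matrix)
  thr <- mean(nz)
  out <- m
  drop <- !is.na(out) & out > 0 & out < thr
  out[drop] <- 0
  attributes(out) <- attributes(matrix)
  out
}

#' Element-wise average of interaction matrices
#'
#' Used to build block-averaged networks (e.g. seven four-day blocks from
#' 28 daily matrices) for temporal-stability comparisons.
#'
#' @param matrices list of symmetric matrices with identical dimnames.
#' @return matrix of element-wise means.
#' @export
average_matrices <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  d <- dimnames(matrices[[1]])
  for (m in matrices) {
    if (!identical(dim(m), dim(matrices[[1]])) ||
        !identical(dimnames(m), d))
      stop("matrices must share dimension and roster")
  }
  acc <- Reduce(`+`, lapply(matrices, function(m) {
    mm <- as.matrix(m); mm
  }))
  out <- acc / length(matrices)
  dimnames(out) <- d
  out
}

#' Summary measures for one network
#'
#' @param matrix symmetric interaction count matrix.
#' @return list with `edge_density`, `component_count`, and the per-node
#'   `nodes` data.frame from [degree_and_clustering()].
#' @export
network_measures <- function(matrix) {
  list(edge_density = edge_density(matrix),
       component_count = graph_components(matrix)$count,
       nodes = degree_and_clustering(matrix))
}
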