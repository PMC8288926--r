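#' Multiplex network container
#'
#' A multiplex network is a single set of `n_nodes` nodes (ids `0 .. n_nodes-1`)
#' shared by two or more layers of undirected links. Layers are stored as
#' two-column integer matrices of canonical edges (`min, max`), without
#' self-loops or duplicates.
#'
#' @param layers list of edge sets, each a two-column matrix (or data frame)
#'   of 0-based node ids; self-loops are dropped with a warning count,
#'   duplicate edges are collapsed silently.
#' @param n_nodes number of nodes; defaults to one more than the largest id
#'   seen in any layer.
#' @return An object of class `multiplex_network` with elements `n_nodes`
#'   and `layers`.
#' @examples
#' net <- multiplex_network(list(cbind(0:2, 1:3), cbind(c(0, 1), c(2, 3))), n_nodes = 4)
#' net
#' @export
multiplex_network <- function(layers, n_nodes = NULL) {
  if (!is.list(layers) || length(layers) < 1)
    stop("`layers` must be a non-empty list of edge sets")
  layers <- lapply(layers, as_edge_matrix)
  max_id <- max(c(-1L, unlist(lapply(layers, function(e) if (nrow(e)) max(e) else -1L))))
  if (is.null(n_nodes)) n_nodes <- max_id + 1L
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 1)
    stop("`n_nodes` must be a positive integer")
  if (max_id >= n_nodes)
    stop("node id ", max_id, " out of range [0, ", n_nodes, ")")
  layers <- lapply(layers, canonical_edges)
  structure(list(n_nodes = n_nodes, layers = layers),
            class = "multiplex_network")
}

as_edge_matrix <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0) return(matrix(integer(), ncol = 2))
  if (!is.matrix(edges) || ncol(edges) != 2)
    stop("an edge set must be a two-column matrix of node ids")
  storage.mode(edges) <- "integer"
  if (anyNA(edges)) stop("edge set contains missing node ids")
  if (any(edges < 0)) stop("negative node ids are not allowed")
  edges
}

#' Canonicalize an undirected edge set
#'
#' Reorders each edge as `(min, max)`, drops self-loops (with a warning
#' giving the count), collapses duplicates silently and sorts rows, so two
#' equal edge sets are element-wise identical. The dropped counts are kept
#' as attributes `n_self_loops` and `n_duplicates`.
#'
#' @param edges two-column matrix of 0-based node ids.
#' @return Canonical two-column integer edge matrix.
#' @export
canonical_edges <- function(edges) {
  edges <- as_edge_matrix(edges)
  if (nrow(edges) == 0) {
    return(structure(matrix(integer(), ncol = 2), n_self_loops = 0L, n_duplicates = 0L))
  }
  u <- pmin(edges[, 1], edges[, 2])
  v <- pmax(edges[, 1], edges[, 2])
  loops <- u == v
  n_loops <- sum(loops)
  if (n_loops > 0) {
    warning(n_loops, " self-loop(s) dropped")
    u <- u[!loops]; v <- v[!loops]
  }
  key <- as.double(u) * 2^26 + as.double(v)
  keep <- !duplicated(key)
  n_dup <- sum(!keep)
  u <- u[keep]; v <- v[keep]
  o <- order(u, v)
  structure(cbind(u[o], v[o]), n_self_loops = as.integer(n_loops),
            n_duplicates = as.integer(n_dup))
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat("Multiplex network:", x$n_nodes, "nodes,", length(x$layers), "layers\n")
  for (i in seq_along(x$layers))
    cat("  layer", i, ":", nrow(x$layers[[i]]), "edges\n")
  invisible(x)
}

#' @export
format.multiplex_network <- function(x, ...) {
  sprintf("multiplex_network(N=%d, L=%d, M=%s)", x$n_nodes, length(x$layers),
          paste(vapply(x$layers, nrow, 0L), collapse = "/"))
}

validate_net <- function(net) {
  if (!inherits(net, "multiplex_network"))
    stop("expected a `multiplex_network` object")
  if (length(net$layers) < 1) stop("network has no layers")
  invisible(net)
}

#' Connected components of an edge set
#'
#' Union-find connected components over nodes `0 .. n_nodes-1`. Labels are
#' canonical: every node is labelled with the smallest node id in its
#' component, so two equal partitions are element-wise identical.
#'
#' @param edges two-column matrix of 0-based undirected edges.
#' @param n_nodes number of nodes.
#' @return Integer vector of length `n_nodes` of canonical component labels.
#' @examples
#' components(cbind(c(0, 1), c(1, 2)), 4)  # 0 0 0 3
#' @export
components <- function(edges, n_nodes) {
  edges <- as_edge_matrix(edges)
  n_nodes <- as.integer(n_nodes)
  if (nrow(edges) && max(edges) >= n_nodes)
    stop("node id out of range [0, ", n_nodes, ")")
  cc_labels_cpp(edges, n_nodes)
}

#' Cluster sizes of a partition
#'
#' @param labels canonical component labels as returned by [components()].
#' @param decreasing sort order of the returned sizes.
#' @return Integer vector of cluster sizes (sums to `length(labels)`).
#' @export
cluster_sizes <- function(labels, decreasing = TRUE) {
  sizes <- tabulate(labels + 1L, nbins = length(labels))
  sort(sizes[sizes > 0], decreasing = decreasing)
}
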