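#' Run history-dependent percolation over generations
#'
#' Starting from the universal configuration \eqn{C^0} (all nodes in one
#' cluster), each generation applies the next layer cyclically: a link of the
#' current layer is kept only if both its endpoints belong to the same cluster
#' of the previous configuration, and the new configuration is the connected
#' components of the kept links. Generation 1 is therefore the ordinary
#' percolation of the first layer. Partitions can only refine, so the process
#' reaches a steady state (the "infinite generation") after finitely many
#' steps.
#'
#' For two layers, a single application that leaves the partition unchanged
#' proves steadiness: the unchanged partition is stable under the layer just
#' applied, and it was produced as components under the other layer, so it is
#' stable under both. For more than two layers a full unchanged cycle of
#' `L` applications is required before stopping.
#'
#' @param net a [multiplex_network()].
#' @param max_generations safety cap on the number of generations.
#' @param stop_at_steady stop as soon as the steady state is detected
#'   (default); otherwise run through `max_generations`.
#' @param record_sizes keep the full sorted cluster-size vector of every
#'   generation (needed for cluster-size distributions).
#' @return A `generation_trace` object: per-generation vectors `psi`
#'   (largest-cluster fraction), `second_largest` (nodes), `n_clusters`;
#'   `n_c`, the smallest n with \eqn{C^{n+1} = C^n}; `converged`; the final
#'   canonical `labels`; optionally `sizes`, a list of per-generation sorted
#'   cluster sizes.
#' @examples
#' net <- multiplex_network(list(cbind(0:2, 1:3), cbind(c(0, 1), c(2, 3))), n_nodes = 4)
#' tr <- percolate_generations(net)
#' tr$psi   # 1.0 0.5 0.25 0.25
#' tr$n_c   # 3
#' @export
percolate_generations <- function(net, max_generations = 10000L,
                                  stop_at_steady = TRUE,
                                  record_sizes = FALSE) {
  validate_net(net)
  if (max_generations < 1) stop("`max_generations` must be positive")
  res <- percolate_cpp(net$layers, net$n_nodes, as.integer(max_generations),
                       stop_at_steady, record_sizes)
  res$n_nodes <- net$n_nodes
  class(res) <- "generation_trace"
  res
}

#' @export
print.generation_trace <- function(x, ...) {
  cat("Generation trace:", x$n_generations, "generations recorded",
      if (x$converged) sprintf("(steady at n_c = %d)", x$n_c) else "(not converged)",
      "\n")
  print(utils::head(as.data.frame(x), 10))
  if (x$n_generations > 10) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.generation_trace <- function(x, ...) {
  data.frame(generation = seq_len(x$n_generations),
             psi = x$psi,
             second_largest = x$second_largest,
             n_clusters = x$n_clusters)
}

#' Largest-cluster fraction at a given generation
#'
#' Reads \eqn{\psi^n} off a trace; generations beyond the steady state repeat
#' the steady value, and `n = Inf` reads the steady state itself.
#'
#' @param trace a `generation_trace`.
#' @param n generation (positive integer or `Inf`).
#' @return \eqn{\psi^n} as a fraction of nodes.
#' @export
psi_at <- function(trace, n) {
  stopifnot(inherits(trace, "generation_trace"))
  if (is.infinite(n)) {
    if (!trace$converged)
      warning("trace did not reach steady state; returning last generation")
    return(trace$psi[trace$n_generations])
  }
  if (n < 1) stop("`n` must be >= 1")
  trace$psi[min(n, trace$n_generations)]
}

#' Apply one layer to a partition
#'
#' Keeps the layer's links whose endpoints share a cluster label and returns
#' the connected components of the kept links. The result always refines the
#' input partition.
#'
#' @param labels canonical partition labels (see [components()]).
#' @param layer two-column matrix of 0-based edges over the same node set.
#' @return Canonical labels of the refined partition.
#' @examples
#' apply_layer(c(0L, 0L, 0L, 3L), cbind(c(0, 2), c(1, 3)))  # 0 0 2 3
#' @export
apply_layer <- function(labels, layer) {
  layer <- as_edge_matrix(layer)
  if (nrow(layer) && max(layer) >= length(labels))
    stop("layer references node ids outside the partition")
  apply_layer_cpp(as.integer(labels), layer)
}

#' Bond dilution of a multiplex network
#'
#' Retains each link of each layer independently with probability `p`
#' (an occupied fraction `p`, i.e. a fraction `1 - p` of links removed at
#' random). With `marks` from [coupled_marks()], edges are kept when their
#' pre-assigned uniform mark is below `p`, so occupied sets are nested across
#' a sweep of `p` values.
#'
#' @param net a [multiplex_network()].
#' @param p occupation probability in `[0, 1]`.
#' @param seed RNG seed (required unless `marks` is given).
#' @param marks optional per-layer uniform marks from [coupled_marks()].
#' @return A diluted `multiplex_network` on the same node set.
#' @export
dilute <- function(net, p, seed = NULL, marks = NULL) {
  validate_net(net)
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop("`p` must be a probability in [0, 1]")
  if (is.null(marks)) {
    if (is.null(seed)) stop("supply `seed` or precomputed `marks`")
    marks <- coupled_marks(net, seed)
  }
  layers <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    keep <- marks[[i]] < p
    layers[[i]] <- net$layers[[i]][keep, , drop = FALSE]
  }
  structure(list(n_nodes = net$n_nodes, layers = layers),
            class = "multiplex_network")
}

#' Uniform edge marks for coupled dilution sweeps
#'
#' Assigns every edge of every layer one Uniform(0,1) mark. Diluting with
#' `dilute(net, p, marks = m)` then yields occupied edge sets that are nested
#' as `p` grows, which gives monotone, low-noise sweep curves.
#'
#' @param net a [multiplex_network()].
#' @param seed RNG seed.
#' @return List of numeric mark vectors, one per layer.
#' @export
coupled_marks <- function(net, seed) {
  validate_net(net)
  local_seed(seed, lapply(net$layers, function(e) runif(nrow(e))))
}
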