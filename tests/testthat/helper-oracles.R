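# Independent reference implementations used as oracles. They share no code
# with the package's union-find engine.

# Breadth-first-search connected components, canonical (min-id) labels.
bfs_components <- function(edges, n_nodes) {
  adj <- vector("list", n_nodes)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1] + 1L; v <- edges[e, 2] + 1L
      adj[[u]] <- c(adj[[u]], v)
      adj[[v]] <- c(adj[[v]], u)
    }
  }
  labels <- rep(NA_integer_, n_nodes)
  for (start in seq_len(n_nodes)) {
    if (!is.na(labels[start])) next
    lab <- start - 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      node <- queue[1]; queue <- queue[-1]
      for (nb in adj[[node]]) {
        if (is.na(labels[nb])) { labels[nb] <- lab; queue <- c(queue, nb) }
      }
    }
  }
  labels
}

# Pure-R generational percolation, built on the BFS oracle.
r_percolate <- function(net, max_generations = 100) {
  labels <- rep(0L, net$n_nodes)
  L <- length(net$layers)
  psi <- numeric(0)
  traces <- list()
  for (gen in seq_len(max_generations)) {
    layer <- net$layers[[(gen - 1) %% L + 1]]
    if (nrow(layer)) {
      keep <- labels[layer[, 1] + 1L] == labels[layer[, 2] + 1L]
      layer <- layer[keep, , drop = FALSE]
    }
    new_labels <- bfs_components(layer, net$n_nodes)
    psi[gen] <- max(tabulate(new_labels + 1L, net$n_nodes)) / net$n_nodes
    same <- gen >= 2 && all(new_labels == labels)
    labels <- new_labels
    traces[[gen]] <- labels
    if (same && L == 2) return(list(psi = psi, n_c = gen - 1L, labels = labels))
  }
  list(psi = psi, n_c = NA_integer_, labels = labels)
}

random_edge_set <- function(n_nodes, m) {
  u <- sample.int(n_nodes, m, replace = TRUE) - 1L
  v <- sample.int(n_nodes, m, replace = TRUE) - 1L
  keep <- u != v
  cbind(pmin(u[keep], v[keep]), pmax(u[keep], v[keep]))
}

random_multiplex <- function(n_nodes, m_per_layer, n_layers = 2) {
  suppressWarnings(multiplex_network(
    lapply(seq_len(n_layers), function(i) random_edge_set(n_nodes, m_per_layer)),
    n_nodes = n_nodes))
}

# The two hand-enumerated 4-node worked examples.
worked_example_net <- function() {
  multiplex_network(list(cbind(0:2, 1:3),
                         cbind(c(0L, 1L), c(2L, 3L))), n_nodes = 4)
}
worked_example_empty_b <- function() {
  multiplex_network(list(cbind(0:2, 1:3),
                         matrix(integer(), ncol = 2)), n_nodes = 4)
}
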