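test_that("hand-enumerated 4-node multiplexes give the exact generation traces", {
  tr <- percolate_generations(worked_example_net())
  expect_equal(tr$psi[1:3], c(1, 0.5, 0.25))
  expect_equal(tr$n_c, 3L)
  expect_true(tr$converged)
  # generation 2 clusters are {0,2} and {1,3}
  tr2 <- apply_layer(rep(0L, 4), cbind(c(0L, 1L), c(2L, 3L)))
  expect_equal(tr2, c(0L, 1L, 0L, 1L))

  # empty second layer: everything shatters at generation 2
  trb <- percolate_generations(worked_example_empty_b())
  expect_equal(trb$psi[1:2], c(1, 0.25))
  expect_equal(trb$n_c, 2L)
})

test_that("identical layers are idempotent: steady after one generation", {
  set.seed(11)
  for (i in 1:10) {
    a <- random_edge_set(30, 25)
    net <- suppressWarnings(multiplex_network(list(a, a), n_nodes = 30))
    tr <- percolate_generations(net)
    expect_equal(tr$n_c, 1L)
    expect_true(all(tr$psi == tr$psi[1]))
  }
})

test_that("apply_layer filters edges by shared cluster and refines", {
  # universal partition: plain connected components
  layer <- cbind(c(0L, 2L), c(1L, 3L))
  expect_equal(apply_layer(rep(0L, 5), layer), components(layer, 5))
  # all-singleton partition stays all singletons
  expect_equal(apply_layer(0:4, layer), 0:4)
  # partition {0,1,2},{3}: edge (2,3) straddles clusters and is dropped
  expect_equal(apply_layer(c(0L, 0L, 0L, 3L), cbind(c(0L, 2L), c(1L, 3L))),
               c(0L, 0L, 2L, 3L))
})

test_that("components matches the BFS oracle on random instances", {
  expect_equal(components(matrix(integer(), ncol = 2), 5), 0:4)
  expect_equal(components(cbind(0:1, 1:2), 4), c(0L, 0L, 0L, 3L))
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:64, 1)
    edges <- canonical_edges(random_edge_set(n, sample(0:80, 1)))
    expect_identical(components(edges, n), bfs_components(edges, n))
  }
})

test_that("components agrees with igraph membership up to relabeling", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(5:80, 1)
    edges <- canonical_edges(random_edge_set(n, sample(5:120, 1)))
    g <- igraph::graph_from_edgelist(edges + 1L, directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    memb <- igraph::components(g)$membership
    labels <- components(edges, n)
    # same partition: membership vectors identical after canonical relabel
    expect_true(all(tapply(memb, labels, function(x) length(unique(x))) == 1))
    expect_equal(length(unique(memb)), length(unique(labels)))
  }
})

test_that("engine agrees with a pure-R BFS-based reference on random multiplexes", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    net <- random_multiplex(n, sample(5:50, 1))
    tr <- percolate_generations(net)
    ref <- r_percolate(net)
    expect_equal(tr$psi[seq_along(ref$psi)], ref$psi)
    expect_equal(tr$n_c, ref$n_c)
    expect_identical(tr$labels, ref$labels)
  }
})

test_that("partitions only refine and psi is non-increasing", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    net <- random_multiplex(n, sample(10:60, 1))
    tr <- percolate_generations(net, record_sizes = TRUE)
    expect_true(all(diff(tr$psi) <= 1e-12))
    # refinement: recompute labels per generation and check subset relation
    labels <- rep(0L, n)
    for (g in seq_len(tr$n_generations)) {
      nxt <- apply_layer(labels, net$layers[[(g - 1) %% 2 + 1]])
      # each new cluster maps into exactly one old cluster
      expect_true(all(tapply(labels, nxt, function(x) length(unique(x))) == 1))
      expect_equal(sum(cluster_sizes(nxt)), n)
      labels <- nxt
    }
  }
})

test_that("dilution keeps each edge with probability p and couples across p", {
  net <- random_multiplex(200, 300)
  expect_equal(dilute(net, 1, seed = 1)$layers, net$layers, ignore_attr = TRUE)
  expect_equal(nrow(dilute(net, 0, seed = 1)$layers[[1]]), 0)
  expect_error(dilute(net, 1.2, seed = 1), "probability")

  big <- suppressWarnings(multiplex_network(
    list(canonical_edges(random_edge_set(3000, 120000))), n_nodes = 3000))
  m <- nrow(big$layers[[1]])
  kept <- nrow(dilute(big, 0.5, seed = 5)$layers[[1]])
  expect_lt(abs(kept - 0.5 * m), 4 * sqrt(m * 0.25))

  # coupled marks: occupied sets nested, hence psi monotone in p at fixed n
  marks <- coupled_marks(net, seed = 9)
  prev_edges <- NULL
  prev_psi <- -1
  for (p in c(0.2, 0.5, 0.8, 1)) {
    d <- dilute(net, p, marks = marks)
    if (!is.null(prev_edges))
      expect_true(all(prev_edges %in% paste(d$layers[[1]][, 1], d$layers[[1]][, 2])))
    prev_edges <- paste(d$layers[[1]][, 1], d$layers[[1]][, 2])
    psi <- percolate_generations(d)$psi
    expect_gte(psi[1], prev_psi)
    prev_psi <- psi[1]
  }
})

test_that("generation 1 is the plain percolation of layer A", {
  set.seed(3)
  for (i in 1:10) {
    net <- random_multiplex(50, 60)
    tr <- percolate_generations(net)
    lab <- components(net$layers[[1]], 50)
    expect_equal(tr$psi[1], max(cluster_sizes(lab)) / 50)
  }
})

test_that("validation rejects malformed networks", {
  expect_error(multiplex_network(list()), "non-empty")
  expect_error(multiplex_network(list(cbind(0L, 5L)), n_nodes = 4), "out of range")
  expect_error(multiplex_network(list(cbind(-1L, 2L)), n_nodes = 4), "negative")
  expect_warning(multiplex_network(list(cbind(c(0L, 1L), c(0L, 2L))), n_nodes = 3),
                 "self-loop")
  # duplicates collapse silently
  net <- multiplex_network(list(cbind(c(0L, 1L), c(1L, 0L))), n_nodes = 2)
  expect_equal(nrow(net$layers[[1]]), 1)
})

test_that("steady state is always reached and capped by max_generations", {
  set.seed(21)
  for (i in 1:10) {
    net <- random_multiplex(40, 30)
    tr <- percolate_generations(net)
    expect_true(tr$converged)
    expect_lte(tr$n_c, 40)
  }
  net <- worked_example_net()
  tr <- percolate_generations(net, max_generations = 2)
  expect_false(tr$converged)
  expect_equal(tr$n_generations, 2)
})
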