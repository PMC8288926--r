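#' Erdos-Renyi layer with fixed edge count
#'
#' Draws a uniform simple graph with exactly `M = round(z * n_nodes / 2)`
#' edges (the G(N, M) ensemble). Fixing the edge count rather than the edge
#' probability removes ensemble noise in the control parameter z; the two
#' ensembles coincide as N grows.
#'
#' @param n_nodes number of nodes N.
#' @param z target average degree; `M = round(z N / 2)` must not exceed
#'   `N (N - 1) / 2`.
#' @param seed RNG seed.
#' @return Two-column integer matrix of canonical 0-based edges.
#' @examples
#' nrow(er_layer(100, 4, seed = 1))  # 200
#' @export
er_layer <- function(n_nodes, z, seed) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1) stop("`n_nodes` must be positive")
  if (z < 0) stop("`z` must be non-negative")
  m <- round(z * n_nodes / 2)
  max_m <- n_nodes * (n_nodes - 1) / 2
  if (m > max_m) stop("requested ", m, " edges but only ", max_m, " pairs exist")
  if (m == 0) return(canonical_edges(matrix(integer(), ncol = 2)))
  local_seed(seed, {
    keys <- double(0)
    while (length(keys) < m) {
      k <- ceiling((m - length(keys)) * 1.05) + 16
      u <- sample.int(n_nodes, k, replace = TRUE) - 1L
      v <- sample.int(n_nodes, k, replace = TRUE) - 1L
      ok <- u != v
      a <- pmin(u[ok], v[ok]); b <- pmax(u[ok], v[ok])
      # first-occurrence order keeps the subset uniform over M-subsets
      keys <- unique(c(keys, as.double(a) * n_nodes + b))
    }
    keys <- keys[seq_len(m)]
    a <- floor(keys / n_nodes)
    b <- keys - a * n_nodes
    canonical_edges(cbind(as.integer(a), as.integer(b)))
  })
}

#' Convenience: two-layer ER multiplex
#'
#' Two independent [er_layer()]s of the same average degree over a shared
#' node set, with per-layer seeds derived from `seed`.
#'
#' @inheritParams er_layer
#' @return A [multiplex_network()].
#' @export
er_multiplex <- function(n_nodes, z, seed) {
  multiplex_network(list(er_layer(n_nodes, z, substream_seed(seed, 1)),
                         er_layer(n_nodes, z, substream_seed(seed, 2))),
                    n_nodes = n_nodes)
}

#' Truncated power-law degree distribution
#'
#' Degree probabilities \eqn{p_k \propto k^{-\gamma}} on the support
#' `m, m+1, ..., K`, normalized numerically.
#'
#' @param gamma exponent, > 1.
#' @param m minimum degree.
#' @param K maximum degree, `>= m`.
#' @return Object of class `degree_distribution` with fields `k`, `p`,
#'   `mean` and the normalization constant `c`.
#' @export
power_law_degrees <- function(gamma, m, K) {
  if (gamma <= 1) stop("`gamma` must exceed 1")
  m <- as.integer(m); K <- as.integer(K)
  if (m < 1 || K < m) stop("need 1 <= m <= K")
  k <- m:K
  w <- k^(-gamma)
  p <- w / sum(w)
  structure(list(k = k, p = p, c = 1 / sum(as.double(m:K)^(-gamma)),
                 mean = sum(k * p), gamma = gamma, m = m, K = K),
            class = "degree_distribution")
}

#' Arbitrary finite degree distribution
#'
#' @param k integer support.
#' @param p probabilities (normalized internally).
#' @return A `degree_distribution`.
#' @export
degree_dist <- function(k, p) {
  if (length(k) != length(p) || any(p < 0) || sum(p) <= 0)
    stop("`k` and `p` must match and `p` must be a non-negative weight vector")
  o <- order(k)
  structure(list(k = as.integer(k[o]), p = p[o] / sum(p), c = NA_real_,
                 mean = sum(k[o] * p[o] / sum(p))),
            class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat("Degree distribution on {", min(x$k), "..", max(x$k), "}, mean degree ",
      format(x$mean, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Scale-free layer via the configuration model
#'
#' Samples N degrees i.i.d. from \eqn{p_k \propto k^{-\gamma}} on
#' `m..K` (default `K = floor(sqrt(N))`), fixes parity by resampling the
#' last node's degree until the stub count is even, pairs stubs uniformly at
#' random and then simplifies (self-loops dropped, multi-edges collapsed:
#' the erased configuration model). The edge loss from simplification is
#' o(N) for `gamma = 2.5, K = sqrt(N)` and is reported in attributes.
#'
#' @param n_nodes number of nodes.
#' @param gamma power-law exponent (> 1).
#' @param m minimum degree.
#' @param K maximum degree; `NULL` means `floor(sqrt(n_nodes))`.
#' @param seed RNG seed.
#' @return Canonical edge matrix with attributes `n_self_loops`,
#'   `n_duplicates` (edges lost to simplification) and `degree_sum`.
#' @export
sf_layer <- function(n_nodes, gamma, m, K = NULL, seed) {
  n_nodes <- as.integer(n_nodes)
  if (is.null(K)) K <- floor(sqrt(n_nodes))
  if (K > n_nodes - 1) stop("`K` must be at most N - 1")
  dist <- power_law_degrees(gamma, m, K)
  draw_deg <- function(n)  # length-1 support must not trigger sample(1:k)
    if (length(dist$k) == 1) rep.int(dist$k, n)
    else sample(dist$k, n, replace = TRUE, prob = dist$p)
  local_seed(seed, {
    deg <- draw_deg(n_nodes)
    if (sum(deg) %% 2 == 1) {
      if (dist$m == dist$K)
        stop("degree sum parity unfixable: constant odd degree with odd N")
      for (i in 1:1000) {
        deg[n_nodes] <- draw_deg(1)
        if (sum(deg) %% 2 == 0) break
      }
      if (sum(deg) %% 2 == 1) stop("degree sum parity unfixable")
    }
    stubs <- rep.int(0:(n_nodes - 1L), deg)
    stubs <- sample(stubs)
    half <- length(stubs) / 2
    # erased configuration model: simplification is routine here, so the
    # self-loop warning is silenced; counts remain in the attributes
    edges <- suppressWarnings(
      canonical_edges(cbind(stubs[seq_len(half)], stubs[half + seq_len(half)])))
    attr(edges, "degree_sum") <- sum(deg)
    edges
  })
}

#' Convenience: two-layer scale-free multiplex
#'
#' @inheritParams sf_layer
#' @return A [multiplex_network()] with two independent configuration-model
#'   layers.
#' @export
sf_multiplex <- function(n_nodes, gamma, m, K = NULL, seed) {
  multiplex_network(list(sf_layer(n_nodes, gamma, m, K, substream_seed(seed, 1)),
                         sf_layer(n_nodes, gamma, m, K, substream_seed(seed, 2))),
                    n_nodes = n_nodes)
}

#' Threshold a weighted matrix to its top-weight links
#'
#' Keeps exactly `M = round(z * N / 2)` unordered node pairs with the largest
#' weights (upper triangle of a symmetric matrix), the standard density-based
#' construction of an unweighted network from a weighted connectome. Ties are
#' broken deterministically by (weight descending, then (i, j) lexicographic).
#'
#' @param weights symmetric numeric matrix; diagonal ignored. Asymmetry
#'   beyond `1e-6` (absolute) is an error; below it the matrix is
#'   symmetrized as `(W + t(W)) / 2`.
#' @param z target average degree.
#' @return Canonical edge matrix with exactly `M` edges.
#' @examples
#' W <- matrix(0, 4, 4)
#' W[upper.tri(W)] <- c(.9, .8, .7, .1, .2, .3)
#' W <- W + t(W)
#' threshold_top_weights(W, z = 1.5)  # top-3 pairs
#' @export
threshold_top_weights <- function(weights, z) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("`weights` must be a square matrix")
  if (anyNA(weights) || any(!is.finite(weights)))
    stop("`weights` must be finite")
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-6) stop("matrix asymmetry ", format(asym), " exceeds tolerance 1e-6")
  weights <- (weights + t(weights)) / 2
  n <- nrow(weights)
  m <- round(z * n / 2)
  if (m > n * (n - 1) / 2) stop("target degree infeasible for ", n, " nodes")
  ut <- which(upper.tri(weights), arr.ind = TRUE)
  i <- ut[, 1] - 1L; j <- ut[, 2] - 1L
  w <- weights[ut]
  o <- order(-w, i, j)
  sel <- o[seq_len(m)]
  canonical_edges(cbind(i[sel], j[sel]))
}

#' Synthetic correlated weighted bilayer
#'
#' Generates a pair of symmetric weight matrices emulating a bilayer weighted
#' connectome (e.g. a functional-correlation layer and a morphological-
#' similarity layer over the same parcellation): upper-triangle entries are
#' jointly Gaussian with inter-layer correlation `rho`, plus an optional
#' additive within-community boost shared by both layers. Thresholding both
#' matrices at the same average degree yields layers whose expected link
#' overlap grows monotonically with `rho`.
#'
#' @param n_nodes number of nodes (ROIs).
#' @param rho inter-layer weight correlation in `[-1, 1]`.
#' @param n_communities number of equal-size communities (0 = none).
#' @param community_strength additive weight boost for within-community pairs.
#' @param seed RNG seed.
#' @return List of class `weighted_layer_pair` with symmetric matrices `W1`,
#'   `W2` (zero diagonal) and the community `membership`.
#' @export
synthetic_weighted_pair <- function(n_nodes, rho, n_communities = 0,
                                    community_strength = 0.5, seed = 1) {
  if (rho < -1 || rho > 1) stop("`rho` must lie in [-1, 1]")
  n <- as.integer(n_nodes)
  npair <- n * (n - 1) / 2
  local_seed(seed, {
    g1 <- rnorm(npair)
    g2 <- rnorm(npair)
    w1 <- g1
    w2 <- rho * g1 + sqrt(1 - rho^2) * g2
    membership <- rep(0L, n)
    if (n_communities >= 2) {
      membership <- rep_len(seq_len(n_communities), n)
      ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      same <- membership[ut[, 1]] == membership[ut[, 2]]
      w1[same] <- w1[same] + community_strength
      w2[same] <- w2[same] + community_strength
    }
    W1 <- matrix(0, n, n); W2 <- matrix(0, n, n)
    W1[upper.tri(W1)] <- w1; W2[upper.tri(W2)] <- w2
    W1 <- W1 + t(W1); W2 <- W2 + t(W2)
    structure(list(W1 = W1, W2 = W2, membership = membership, rho = rho),
              class = "weighted_layer_pair")
  })
}

#' @export
print.weighted_layer_pair <- function(x, ...) {
  cat("Weighted bilayer:", nrow(x$W1), "nodes, target correlation",
      format(x$rho, digits = 3), "\n")
  invisible(x)
}

#' Link overlap between the two layers of a multiplex
#'
#' Reports the intersection and union of the two edge sets and the ratios
#' a practitioner might mean by "fraction of shared links": intersection over
#' union (Jaccard), and intersection over each layer's edge count.
#'
#' @param net a two-layer [multiplex_network()].
#' @return List with `n_intersection`, `n_union`, `n_a`, `n_b`,
#'   `jaccard`, `frac_of_a`, `frac_of_b`.
#' @export
layer_overlap <- function(net) {
  validate_net(net)
  if (length(net$layers) != 2) stop("layer overlap is defined for two layers")
  n <- net$n_nodes
  key <- function(e) if (nrow(e)) as.double(e[, 1]) * n + e[, 2] else double(0)
  a <- key(net$layers[[1]]); b <- key(net$layers[[2]])
  ni <- length(intersect(a, b))
  nu <- length(union(a, b))
  list(n_intersection = ni, n_union = nu, n_a = length(a), n_b = length(b),
       jaccard = if (nu) ni / nu else NA_real_,
       frac_of_a = if (length(a)) ni / length(a) else NA_real_,
       frac_of_b = if (length(b)) ni / length(b) else NA_real_)
}
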