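#' Monte Carlo sweep over a control grid
#'
#' Runs the generational percolation over an ensemble of multiplex
#' realizations at every value of a control grid and records the order
#' parameter per requested generation plus the mean second-largest cluster.
#' Two control modes mirror the two ways the transition is driven:
#'
#' * `"degree"`: the grid is average degree z; `builder(z, seed)` must return
#'   a fresh [multiplex_network()] (independent ensembles per grid point).
#' * `"occupation"`: the grid is occupation probability p; `builder(seed)`
#'   returns one network per realization which is then diluted at every p.
#'   By default the dilution reuses one set of uniform edge marks per
#'   realization ([coupled_marks()]), so occupied sets are nested in p and
#'   the sweep curves are smooth; set `coupled = FALSE` to redraw.
#'
#' @param builder network factory (see above).
#' @param grid numeric control values.
#' @param generations integer generations to record; `Inf` means steady state.
#' @param R realizations per grid point.
#' @param seed master seed; per-realization seeds are derived substreams.
#' @param control `"degree"` or `"occupation"`.
#' @param coupled reuse edge marks across the p grid (occupation mode only).
#' @param max_generations safety cap passed to the engine.
#' @return Object of class `sweep_result`: a long-format data frame
#'   `summary` (control, generation, mean_psi, se_psi, mean_n2), plus raw
#'   per-realization `psi_samples` (list over grid of R x #generations
#'   matrices), `n2_samples`, and the run `spec`.
#' @export
ensemble_sweep <- function(builder, grid, generations = Inf, R = 20, seed = 1,
                           control = c("degree", "occupation"),
                           coupled = TRUE, max_generations = 10000L) {
  control <- match.arg(control)
  gens <- generations
  G <- length(grid)
  psi_samples <- vector("list", G)
  n2_samples <- vector("list", G)
  run_one <- function(net) {
    steady <- any(is.infinite(gens))
    n_cap <- if (steady) max_generations else max(gens)
    tr <- percolate_generations(net, max_generations = n_cap,
                                stop_at_steady = TRUE)
    psi <- vapply(gens, function(n) psi_at(tr, n), 0)
    n2 <- tr$second_largest[min(if (any(is.finite(gens))) max(gens[is.finite(gens)]) else tr$n_generations,
                                tr$n_generations)]
    list(psi = psi, n2 = n2)
  }
  if (control == "degree") {
    for (g in seq_len(G)) {
      psi_mat <- matrix(NA_real_, R, length(gens))
      n2_vec <- numeric(R)
      for (r in seq_len(R)) {
        net <- builder(grid[g], substream_seed(seed, g * 100019 + r))
        res <- run_one(net)
        psi_mat[r, ] <- res$psi; n2_vec[r] <- res$n2
      }
      psi_samples[[g]] <- psi_mat; n2_samples[[g]] <- n2_vec
    }
  } else {
    for (g in seq_len(G)) {
      psi_samples[[g]] <- matrix(NA_real_, R, length(gens))
      n2_samples[[g]] <- numeric(R)
    }
    for (r in seq_len(R)) {
      net <- builder(substream_seed(seed, r))
      marks <- coupled_marks(net, substream_seed(seed, 700001 + r))
      for (g in seq_len(G)) {
        mk <- if (coupled) marks else coupled_marks(net, substream_seed(seed, r * 1009 + g))
        res <- run_one(dilute(net, grid[g], marks = mk))
        psi_samples[[g]][r, ] <- res$psi; n2_samples[[g]][r] <- res$n2
      }
    }
  }
  summary <- do.call(rbind, lapply(seq_len(G), function(g) {
    data.frame(control = grid[g], generation = gens,
               mean_psi = colMeans(psi_samples[[g]]),
               se_psi = apply(psi_samples[[g]], 2, sd) / sqrt(R),
               mean_n2 = mean(n2_samples[[g]]))
  }))
  structure(list(summary = summary, psi_samples = psi_samples,
                 n2_samples = n2_samples,
                 spec = list(grid = grid, generations = gens, R = R,
                             seed = seed, control = control, coupled = coupled)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Ensemble sweep:", length(x$spec$grid), "grid points x", x$spec$R,
      "realizations (", x$spec$control, "control )\n")
  print(utils::head(x$summary, 12))
  invisible(x)
}

#' Per-realization order-parameter samples at one control value
#'
#' The raw ingredient of the bimodality analysis: R independent realizations
#' at a single control value, each reduced to its largest-cluster fraction
#' at generation `n` (`Inf` = steady state).
#'
#' @inheritParams ensemble_sweep
#' @param control_value single control value (z for `"degree"` mode).
#' @param n generation.
#' @return Numeric vector of length R.
#' @export
order_parameter_samples <- function(builder, control_value, n = Inf, R = 100,
                                    seed = 1, control = c("degree", "occupation"),
                                    max_generations = 10000L) {
  control <- match.arg(control)
  sw <- ensemble_sweep(builder, control_value, generations = n, R = R,
                       seed = seed, control = control,
                       max_generations = max_generations)
  as.numeric(sw$psi_samples[[1]])
}

#' Classify realizations as percolating vs non-percolating
#'
#' Near a discontinuous transition the per-realization order parameter is
#' bimodal: a mode near zero (non-percolating) and a macroscopic mode. The
#' split point is the deepest histogram valley between the two largest
#' modes, accepted only when it truly separates a microscopic mode from a
#' macroscopic one (lower mode below, upper mode above, the critical
#' largest-cluster scale `c * N^(-1/3)`, and valley depth under half the
#' smaller mode). Otherwise the samples are treated as unimodal and the
#' fixed cutoff `c * N^(-1/3)` is used.
#'
#' @param samples numeric vector of order-parameter samples (>= 20).
#' @param n_nodes system size N (for the fallback cutoff).
#' @param n_bins histogram resolution.
#' @param fallback_c multiplier of the `N^(-1/3)` fallback cutoff.
#' @return List with logical `mask` (percolating), `fraction`, the `cutoff`
#'   used and the `method` ("valley" or "fallback").
#' @export
classify_percolating <- function(samples, n_nodes, n_bins = 30, fallback_c = 5) {
  if (length(samples) < 20) stop("need at least 20 samples to classify")
  method <- "fallback"
  cutoff <- fallback_c * n_nodes^(-1/3)
  if (diff(range(samples)) > .Machine$double.eps^0.5) {
    h <- graphics::hist(samples, breaks = seq(min(samples), max(samples),
                                              length.out = n_bins + 1),
                        plot = FALSE)
    cnt <- h$counts
    nb <- length(cnt)
    # local maxima (plateau-tolerant)
    is_peak <- vapply(seq_len(nb), function(i) {
      l <- if (i > 1) cnt[i - 1] else -1
      r <- if (i < nb) cnt[i + 1] else -1
      cnt[i] > 0 && cnt[i] >= l && cnt[i] >= r && (cnt[i] > l || cnt[i] > r)
    }, TRUE)
    peaks <- which(is_peak)
    if (length(peaks) >= 2) {
      top2 <- peaks[order(cnt[peaks], decreasing = TRUE)[1:2]]
      lo <- min(top2); hi <- max(top2)
      if (hi - lo >= 2) {
        valley <- lo + which.min(cnt[(lo + 1):(hi - 1)])
        # a genuine valley separates a microscopic mode (below the critical
        # largest-cluster scale ~ N^(-1/3)) from a macroscopic one; noise
        # wiggles inside a single mode do not qualify
        if (cnt[valley] < 0.5 * min(cnt[top2]) &&
            h$mids[lo] < cutoff && h$mids[hi] > cutoff) {
          cutoff <- h$mids[valley]
          method <- "valley"
        }
      }
    }
  }
  mask <- samples > cutoff
  list(mask = mask, fraction = mean(mask), cutoff = cutoff, method = method)
}

#' Pseudo-critical point from the second-largest cluster
#'
#' Finite-size estimate of the transition point: the control value maximizing
#' the ensemble-mean second-largest cluster size N2, refined by quadratic
#' interpolation through the argmax and its two neighbours. Errors out when
#' the maximum sits on the grid boundary (the grid failed to span the peak).
#'
#' @inheritParams ensemble_sweep
#' @param n generation at which N2 is read.
#' @return List with `p_c` (interpolated), `p_c_grid` (argmax grid value),
#'   `mean_n2` over the grid, and the `sweep` object.
#' @export
pseudo_critical_point <- function(builder, n, grid, R = 50, seed = 1,
                                  control = c("occupation", "degree"),
                                  coupled = TRUE) {
  control <- match.arg(control)
  sw <- ensemble_sweep(builder, grid, generations = n, R = R, seed = seed,
                       control = control, coupled = coupled)
  n2 <- vapply(sw$n2_samples, mean, 0)
  i <- which.max(n2)
  if (i == 1 || i == length(grid))
    stop("N2 peak at grid boundary; widen the control grid")
  # quadratic through (grid[i-1..i+1], n2[i-1..i+1])
  x <- grid[(i - 1):(i + 1)]; y <- n2[(i - 1):(i + 1)]
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / denom
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / denom
  p_c <- if (a < 0) -b / (2 * a) else grid[i]
  list(p_c = p_c, p_c_grid = grid[i], mean_n2 = n2, sweep = sw)
}

#' Power-law finite-size scaling fit
#'
#' Least-squares fit of `log(value) ~ log(N)`; the decay exponent is
#' reported positive, i.e. `value ~ N^(-exponent)`.
#'
#' @param sizes system sizes (>= 3).
#' @param values positive observable values.
#' @return Object of class `scaling_fit` with `exponent`, `se`,
#'   `prefactor`, residuals and the fit window.
#' @examples
#' fit_power_scaling(2^(10:14), 2^(10:14)^(-1/3))$exponent  # 1/3
#' @export
fit_power_scaling <- function(sizes, values) {
  if (length(sizes) < 3) stop("need at least 3 sizes")
  if (any(values <= 0)) stop("values must be positive for a log-log fit")
  fit <- lm(log(values) ~ log(sizes))
  structure(list(exponent = -unname(coef(fit)[2]),
                 se = sqrt(diag(vcov(fit)))[[2]],
                 prefactor = exp(unname(coef(fit)[1])),
                 residuals = unname(fit$residuals),
                 sizes = sizes, values = values),
            class = "scaling_fit")
}

#' Offset power-law scaling fit
#'
#' Fits `value(N) = c0 + a * N^(-eps)`, the finite-size form of an order
#' parameter that stays finite in the thermodynamic limit (discontinuous
#' transition). The exponent is found by a grid search over `eps` with the
#' linear subproblem `(c0, a)` solved exactly at each candidate, then
#' refined locally; this avoids the initialization sensitivity of a joint
#' nonlinear fit.
#'
#' @param sizes system sizes (>= 4).
#' @param values observable values.
#' @param eps_grid candidate exponents.
#' @return A `scaling_fit` with `offset` (c0), `exponent` (eps),
#'   `amplitude` (a) and residuals.
#' @export
fit_offset_scaling <- function(sizes, values,
                               eps_grid = seq(0.02, 0.98, by = 0.005)) {
  if (length(sizes) < 4) stop("need at least 4 sizes")
  rss_at <- function(eps) {
    x <- sizes^(-eps)
    f <- lm(values ~ x)
    sum(f$residuals^2)
  }
  rss <- vapply(eps_grid, rss_at, 0)
  i <- which.min(rss)
  lo <- eps_grid[max(1, i - 1)]; hi <- eps_grid[min(length(eps_grid), i + 1)]
  opt <- stats::optimize(rss_at, c(lo, hi), tol = 1e-6)
  eps <- opt$minimum
  x <- sizes^(-eps)
  f <- lm(values ~ x)
  if (anyNA(coef(f))) stop("degenerate offset fit: collinear design")
  structure(list(offset = unname(coef(f)[1]), exponent = eps,
                 amplitude = unname(coef(f)[2]),
                 offset_se = sqrt(diag(vcov(f)))[[1]],
                 residuals = unname(f$residuals),
                 sizes = sizes, values = values),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  if (!is.null(x$offset))
    cat(sprintf("Offset scaling fit: c0 = %.4f, eps = %.3f, a = %.3f\n",
                x$offset, x$exponent, x$amplitude))
  else
    cat(sprintf("Power scaling fit: exponent = %.4f (se %.4f)\n",
                x$exponent, x$se))
  invisible(x)
}

#' Pooled cluster-size distribution
#'
#' Logarithmically binned cluster-size distribution `p_s` at generation `n`,
#' pooled over one or more traces (run with `record_sizes = TRUE`); `p_s` is
#' the number of clusters of size s per node, divided by the bin width in s.
#'
#' @param traces a `generation_trace` or list of them.
#' @param n generation (capped at each trace's last generation).
#' @param base log-binning base.
#' @return Data frame with bin bounds, geometric midpoint `s`, and `p_s`.
#' @export
cluster_size_distribution <- function(traces, n = 1, base = 1.3) {
  if (inherits(traces, "generation_trace")) traces <- list(traces)
  if (!length(traces)) stop("need at least one trace")
  sizes <- unlist(lapply(traces, function(tr) {
    if (is.null(tr$sizes)) stop("trace lacks cluster sizes; rerun with record_sizes = TRUE")
    tr$sizes[[min(n, tr$n_generations)]]
  }))
  n_total <- sum(vapply(traces, function(tr) tr$n_nodes, 0))
  smax <- max(sizes)
  edges <- unique(c(1, floor(base^(0:ceiling(log(smax + 1) / log(base)))) + 1))
  edges <- edges[edges <= smax + 1]
  if (edges[length(edges)] <= smax) edges <- c(edges, smax + 1)
  bin <- findInterval(sizes, edges)
  counts <- tabulate(bin, nbins = length(edges) - 1)
  width <- diff(edges)
  data.frame(s_lo = edges[-length(edges)], s_hi = edges[-1] - 1,
             s = sqrt(edges[-length(edges)] * (edges[-1] - 1)),
             p_s = counts / n_total / width)[counts > 0 | TRUE, ]
}
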