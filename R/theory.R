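#' ER giant-cluster function F(x)
#'
#' The mean-field building block \eqn{\mathfrak{F}(x)}: the giant-component
#' fraction (relative to the used nodes) of an ER ensemble with mean degree
#' `z` when a random fraction `x` of nodes is available. It is the largest
#' root \eqn{u \in [0, 1]} of \eqn{u = 1 - e^{-z x u}}, and 0 whenever
#' \eqn{z x \le 1} (subcritical).
#'
#' @param z mean degree of the layer ensemble.
#' @param x usable node fraction in `[0, 1]`.
#' @return Giant-cluster fraction in `[0, 1]`.
#' @examples
#' er_F(4, 1)    # ~0.98
#' er_F(0.9, 1)  # 0
#' @export
er_F <- function(z, x) {
  if (z < 0) stop("`z` must be non-negative")
  vapply(x, function(xi) {
    if (xi < 0 || xi > 1) stop("`x` must lie in [0, 1]")
    a <- z * xi
    if (a <= 1) return(0)
    f <- function(u) u - 1 + exp(-a * u)
    uniroot(f, c(1e-12, 1), tol = 1e-12)$root
  }, 0)
}

#' Occupation-controlled version of a giant-cluster function
#'
#' Link dilution at occupation probability `p` changes the degree
#' distribution so that the usable-fraction argument is scaled:
#' \eqn{\mathfrak{F}(x) \to \mathfrak{F}(p x)}.
#'
#' @param F_base function of one argument x.
#' @param p link occupation probability in `[0, 1]`.
#' @return A function `x -> F_base(p * x)`.
#' @export
occupation_F <- function(F_base, p) {
  if (p < 0 || p > 1) stop("`p` must be a probability")
  function(x) F_base(p * x)
}

#' Configuration-model giant-cluster function
#'
#' Numerical \eqn{\mathfrak{F}(x)} for an arbitrary finite degree
#' distribution, via probability generating functions: with
#' \eqn{G_0(u) = \sum_k p_k u^k} and
#' \eqn{G_1(u) = \sum_k k p_k u^{k-1} / \langle k \rangle}, the probability
#' `u` that an edge fails to reach the giant cluster solves
#' \eqn{u = 1 - x + x G_1(u)} (smallest root in `[0, 1]`), and the giant
#' fraction relative to used nodes is \eqn{1 - G_0(u)}. Reduces to [er_F()]
#' for Poisson degrees.
#'
#' @param dist a `degree_distribution` ([power_law_degrees()], [degree_dist()]).
#' @param x usable node fraction in `[0, 1]`.
#' @return Giant-cluster fraction relative to used nodes.
#' @export
configmodel_F <- function(dist, x) {
  stopifnot(inherits(dist, "degree_distribution"))
  k <- dist$k; p <- dist$p
  meank <- sum(k * p)
  pos <- k > 0                 # degree-0 nodes never carry an edge
  kq <- k[pos]
  q <- kq * p[pos] / meank     # excess-degree weights
  G0 <- function(u) sum(p * u^k)
  G1 <- function(u) sum(q * u^(kq - 1))
  vapply(x, function(xi) {
    if (xi < 0 || xi > 1) stop("`x` must lie in [0, 1]")
    if (xi == 0) return(0)
    h <- function(u) u - (1 - xi) - xi * G1(u)
    hi <- 1 - 1e-9
    if (h(hi) <= 0) return(0)  # subcritical: only the trivial root u = 1
    u <- uniroot(h, c(0, hi), tol = 1e-12)$root
    max(0, 1 - G0(u))
  }, 0)
}

#' Critical usable fraction of a configuration-model ensemble
#'
#' The threshold `x_c = <k> / <k(k-1)>` below which [configmodel_F()] is 0.
#'
#' @param dist a `degree_distribution`.
#' @return Critical usable fraction (may exceed 1 if the ensemble cannot
#'   percolate even intact).
#' @export
configmodel_threshold <- function(dist) {
  k <- dist$k; p <- dist$p
  sum(k * p) / sum(k * (k - 1) * p)
}

#' Generation recursion of the mean-field theory
#'
#' Iterates the two-layer recursion
#' \eqn{\psi^n = S^{n-1} \mathfrak{F}(S^{n-1})} and
#' \eqn{S^n = S^0 \mathfrak{F}(S^{n-1})}, alternating
#' \eqn{\mathfrak{F}_A} (odd n) and \eqn{\mathfrak{F}_B} (even n). With no
#' initial removal, `S0 = 1`; initial node removal sets `S0 = p`; link
#' removal instead rescales the functions (see [occupation_F()]).
#'
#' @param F_A,F_B giant-cluster functions of the two layers (functions of x).
#' @param S0 initial usable fraction.
#' @param n_max maximum number of generations.
#' @param tol stop once `|S^n - S^{n-1}| < tol`.
#' @return Object of class `theory_state`: vectors `S_seq`, `psi_seq`
#'   (entries for generations `1..n`), `S0`, `converged`.
#' @examples
#' FA <- function(x) er_F(3, x)
#' recursion_trace(FA, FA, n_max = 50)$psi_seq[1:3]
#' @export
recursion_trace <- function(F_A, F_B, S0 = 1, n_max = 1000, tol = 1e-10) {
  if (S0 < 0 || S0 > 1) stop("`S0` must lie in [0, 1]")
  S_prev <- S0
  S_seq <- numeric(0); psi_seq <- numeric(0)
  converged <- FALSE
  for (n in seq_len(n_max)) {
    Fn <- if (n %% 2 == 1) F_A else F_B
    f <- Fn(S_prev)
    psi_seq[n] <- S_prev * f
    S_seq[n] <- S0 * f
    if (abs(S_seq[n] - S_prev) < tol) { converged <- TRUE; S_prev <- S_seq[n]; break }
    S_prev <- S_seq[n]
  }
  structure(list(S0 = S0, S_seq = S_seq, psi_seq = psi_seq,
                 converged = converged, n = length(S_seq)),
            class = "theory_state")
}

#' @export
print.theory_state <- function(x, ...) {
  cat("Mean-field recursion: ", x$n, " generations, S0 = ", x$S0,
      if (x$converged) " (converged)" else " (not converged)", "\n", sep = "")
  invisible(x)
}

#' Theoretical order parameter at a given generation
#'
#' Runs the recursion for exactly `n` generations (or to convergence for
#' `n = Inf`) and returns \eqn{\psi^n}.
#'
#' @inheritParams recursion_trace
#' @param n generation (positive integer or `Inf`).
#' @export
theory_psi <- function(n, F_A, F_B = F_A, S0 = 1, tol = 1e-10) {
  if (is.infinite(n)) {
    fp <- infinite_fixed_point(F_A, S0 = S0)
    return(fp["psi"][[1]])
  }
  tr <- recursion_trace(F_A, F_B, S0 = S0, n_max = n, tol = 0)
  tr$psi_seq[n]
}

#' Critical control value of a finite generation
#'
#' Bisection on the control parameter (mean degree z or occupation
#' probability p) for the smallest value at which \eqn{\psi^n} exceeds the
#' numerical-zero tolerance; finite-generation transitions are continuous,
#' so the threshold is approached from above.
#'
#' @param n generation.
#' @param make_F function mapping a control value to the layer function
#'   \eqn{\mathfrak{F}} (used for both layers; supply `make_F_B` if they
#'   differ).
#' @param bracket numeric length-2 interval known to contain the threshold.
#' @param make_F_B optional second-layer factory.
#' @param S0 initial usable fraction.
#' @param tol bisection tolerance on the control value.
#' @param psi_zero numerical-zero threshold on psi.
#' @return Critical control value.
#' @examples
#' finite_generation_threshold(1, function(z) function(x) er_F(z, x),
#'                             bracket = c(0.5, 2))  # 1
#' @export
finite_generation_threshold <- function(n, make_F, bracket,
                                        make_F_B = make_F, S0 = 1,
                                        tol = 1e-4, psi_zero = 1e-8) {
  psi_n <- function(ctrl)
    theory_psi(n, make_F(ctrl), make_F_B(ctrl), S0 = S0)
  lo <- bracket[1]; hi <- bracket[2]
  if (psi_n(lo) > psi_zero || psi_n(hi) <= psi_zero)
    stop("bracket does not straddle the generation-", n, " threshold")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (psi_n(mid) > psi_zero) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Infinite-generation fixed point
#'
#' The steady state of the recursion satisfies \eqn{S = S^0 \mathfrak{F}(S)}
#' (for identical layers). Returns the largest stable solution, found by
#' scanning for a sign change of \eqn{S - S^0\mathfrak{F}(S)} downward from
#' S = 1 and refining by bisection; `(0, 0)` below threshold. The order
#' parameter is \eqn{\psi^\infty = S\,\mathfrak{F}(S)} (equal to \eqn{S^2}
#' under degree control where `S0 = 1`).
#'
#' @param F giant-cluster function of x.
#' @param S0 initial usable fraction.
#' @param grid_n resolution of the fallback bracketing scan.
#' @return Named numeric `c(S, psi)`.
#' @examples
#' infinite_fixed_point(function(x) er_F(4, x))  # S ~ 0.978, psi ~ 0.957
#' @export
infinite_fixed_point <- function(F, S0 = 1, grid_n = 400) {
  g <- function(S) S - S0 * F(S)
  # the nonzero fixed points bound a (possibly very narrow near tangency)
  # negative excursion of g; locate its bottom first
  opt <- stats::optimize(g, c(1e-6, 1), tol = 1e-9)
  lo <- opt$minimum
  if (opt$objective >= 0) {
    # guard against a multimodal g that optimize might miss
    Ss <- seq(1e-6, 1, length.out = grid_n)
    gs <- vapply(Ss, g, 0)
    i <- which(gs < 0)
    if (!length(i)) return(c(S = 0, psi = 0))
    lo <- Ss[max(i)]
  }
  root <- uniroot(g, c(lo, 1), tol = 1e-12)$root
  c(S = root, psi = root * F(root))
}

#' Discontinuous critical point of the infinite generation
#'
#' Bisection on the control value for the smallest value at which
#' \eqn{S = S^0\mathfrak{F}(S)} admits a nonzero fixed point. At that value
#' the fixed point appears tangentially with a jump \eqn{\psi_c^\infty > 0}:
#' a discontinuous transition.
#'
#' @param make_F function mapping a control value to \eqn{\mathfrak{F}}.
#' @param bracket control interval; the lower end must be subcritical and the
#'   upper end supercritical, else an error is thrown.
#' @param S0 initial usable fraction.
#' @param tol bisection tolerance on the control value.
#' @return Object of class `fixed_point_result`: `critical` (control value),
#'   `S_c`, `psi_c` (evaluated at the supercritical bisection endpoint).
#' @export
discontinuous_critical_point <- function(make_F, bracket, S0 = 1, tol = 1e-4) {
  has_fp <- function(ctrl) infinite_fixed_point(make_F(ctrl), S0 = S0)["S"] > 1e-8
  lo <- bracket[1]; hi <- bracket[2]
  if (has_fp(lo)) stop("lower bracket end already admits a nonzero fixed point")
  if (!has_fp(hi)) stop("no nonzero fixed point in bracket: transition not bracketed")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (has_fp(mid)) hi <- mid else lo <- mid
  }
  fp <- infinite_fixed_point(make_F(hi), S0 = S0)
  structure(list(critical = (lo + hi) / 2, S_c = fp[["S"]], psi_c = fp[["psi"]]),
            class = "fixed_point_result")
}

#' @export
print.fixed_point_result <- function(x, ...) {
  cat(sprintf("Discontinuous critical point: control = %.4f, S_c = %.4f, psi_c = %.4f\n",
              x$critical, x$S_c, x$psi_c))
  invisible(x)
}

#' Exact ER infinite-generation critical point (tangency solve)
#'
#' For identical ER layers under degree control the fixed-point equation is
#' \eqn{S = 1 - e^{-z S^2}}. At the critical z the nonzero solution is
#' tangent, which reduces to the scalar condition
#' \eqn{S + 2(1 - S)\log(1 - S) = 0} with
#' \eqn{z_c = 1 / (2 S_c (1 - S_c))} and jump \eqn{\psi_c^\infty = S_c^2};
#' equivalently \eqn{S_c = (1 + \sqrt{1 - 2/z_c})/2}. Solved to 1e-12 by
#' bracketed root-finding, this gives z_c ~ 2.455, S_c ~ 0.715,
#' psi_c ~ 0.512.
#'
#' @return A `fixed_point_result` with `critical` = z_c.
#' @export
er_critical_point <- function() {
  f <- function(S) S + 2 * (1 - S) * log(1 - S)
  S_c <- uniroot(f, c(0.5, 1 - 1e-9), tol = 1e-12)$root
  z_c <- 1 / (2 * S_c * (1 - S_c))
  structure(list(critical = z_c, S_c = S_c, psi_c = S_c^2),
            class = "fixed_point_result")
}
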